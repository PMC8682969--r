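# Readers/writers for every external table the pipeline touches:
# count matrices, group labels, gene lists, STRING-style PPI edge lists,
# GMT gene-set collections and differential-expression tables.
# All tab-delimited UTF-8 with headers (except one-symbol-per-line lists).

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample identifiers with gene identifiers in the
#' first column. Cells must be non-negative integers; duplicate gene or sample
#' identifiers are rejected.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene IDs in count table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(df)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample IDs in count table: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table", call. = FALSE)
  if (anyNA(m)) stop("missing values in count table", call. = FALSE)
  if (any(m < 0)) stop("negative counts in count table", call. = FALSE)
  if (any(m != round(m))) {
    stop("non-integer counts in count table", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#' @param counts gene x sample matrix with dimnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels from a 2-column TSV
#'
#' Columns: sample identifier, group label. For the full pipeline the labels
#' must be Sham/Model/Treated, but any label set is accepted here.
#'
#' @param path TSV path.
#' @return named character vector (names = sample IDs).
#' @export
read_groups <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("group table needs 2 columns: sample_id, group")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a gene list (one identifier per line)
#'
#' Blank lines and lines starting with \code{#} are ignored; duplicates are
#' dropped; case is preserved (identifier matching throughout the package is
#' exact and case-sensitive).
#'
#' @param path text file path.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty gene list: ", path, call. = FALSE)
  unique(lines)
}

#' Read a STRING-style PPI edge list
#'
#' Expects three tab-separated columns -- node, node, combined score in
#' [0, 1000] -- with or without a header. Edges are undirected: symmetric
#' duplicates are collapsed (keeping the maximum score), self-loops are
#' dropped, and edges with score below \code{min_score} are filtered out.
#' The default \code{min_score = 400} is STRING's "medium confidence" cutoff.
#'
#' @param path TSV path.
#' @param min_score minimum combined score to keep an edge.
#' @return data.frame(node_a, node_b, score), canonically oriented
#'   (node_a < node_b) and sorted, with attributes \code{n_self_loops},
#'   \code{n_below_min_score} and \code{n_duplicates} summarizing the load.
#' @export
read_ppi_edges <- function(path, min_score = 400) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PPI edge file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- parts[[1]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))
  start <- if (has_header) 2L else 1L
  if (start > length(parts)) stop("PPI edge file has a header but no rows")
  rows <- parts[start:length(parts)]
  a <- vapply(rows, function(p) if (length(p) >= 1L) p[1] else "", "")
  b <- vapply(rows, function(p) if (length(p) >= 2L) p[2] else "", "")
  s <- suppressWarnings(
    as.numeric(vapply(rows, function(p) if (length(p) >= 3L) p[3] else "", ""))
  )
  bad <- lengths(rows) < 3L | is.na(s) | !nzchar(a) | !nzchar(b)
  if (any(bad)) {
    stop(sprintf("malformed PPI edge row at line %d of %s",
                 which(bad)[1] + start - 1L, path), call. = FALSE)
  }
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; s <- s[!self]
  keep <- s >= min_score
  n_low <- sum(!keep)
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    best <- tapply(s, key, max)
    n_dup <- length(key) - length(best)
    ids <- strsplit(names(best), "\r", fixed = TRUE)
    edges <- data.frame(node_a = vapply(ids, `[`, "", 1L),
                        node_b = vapply(ids, `[`, "", 2L),
                        score = as.numeric(best), stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    n_dup <- 0L
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  attr(edges, "n_self_loops") <- n_self
  attr(edges, "n_below_min_score") <- n_low
  attr(edges, "n_duplicates") <- n_dup
  edges
}

#' Write a PPI edge list as 3-column TSV
#' @param edges data.frame(node_a, node_b, score).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_ppi_edges <- function(edges, path) {
  write.table(edges[, c("node_a", "node_b", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: per line, a set name, a description, then the member genes,
#' all tab-separated. Duplicate genes within a set are stored once; duplicate
#' set names are an error.
#'
#' @param path GMT file path.
#' @return a named list of unique character vectors (class
#'   \code{gene_set_collection}) with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
  }
  nm <- vapply(parts, `[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate gene-set names in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2L), nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection in GMT format
#' @param collection named list of character vectors (optionally with a
#'   \code{descriptions} attribute).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Accepts either this package's own 6-column export (gene_id, log2fc,
#' fold_change, p_value, mean_num, mean_den) or any external 3+-column table
#' whose first columns are gene, log2fc or fold_change, and p-value (so e.g.
#' a DESeq2 result exported as TSV can be dropped in).
#'
#' @param path TSV path with header.
#' @return data.frame with at least gene_id, log2fc, fold_change, p_value.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  nms <- tolower(colnames(df))
  gene_col <- which(nms %in% c("gene_id", "gene", "symbol", "id"))[1]
  if (is.na(gene_col)) gene_col <- 1L
  lfc_col <- which(nms %in% c("log2fc", "log2foldchange", "logfc"))[1]
  fc_col <- which(nms %in% c("fold_change", "foldchange", "fc"))[1]
  p_col <- which(nms %in% c("p_value", "pvalue", "p.value", "p"))[1]
  if (is.na(lfc_col) && is.na(fc_col)) {
    stop("DE table needs a log2fc or fold_change column", call. = FALSE)
  }
  if (is.na(p_col)) stop("DE table needs a p-value column", call. = FALSE)
  gene_id <- as.character(df[[gene_col]])
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) {
    stop("duplicate genes in DE table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  log2fc <- if (!is.na(lfc_col)) as.numeric(df[[lfc_col]]) else
    log2(as.numeric(df[[fc_col]]))
  out <- data.frame(gene_id = gene_id, log2fc = log2fc,
                    fold_change = 2^log2fc,
                    p_value = as.numeric(df[[p_col]]),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$p_value) & (out$p_value < 0 | out$p_value > 1))) {
    stop("p-values outside [0, 1] in DE table", call. = FALSE)
  }
  out
}

#' Write a differential-expression table as TSV
#' @param de a contrast table from \code{\link{contrast_groups}} (or any
#'   data.frame with the same columns).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
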