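# Per-gene fold change and p-value for the two pipeline contrasts
# (Model vs Sham, Treated vs Model). Deliberately simple: CPM normalization,
# pseudocounted log2 fold change of group means, Welch's t-test on log2 CPM.
# Externally produced DE tables (e.g. DESeq2 exports) can be substituted via
# read_de_table(), so this stage is replaceable, not load-bearing.

#' Counts-per-million normalization
#'
#' Divides every column by its library size (column total) and scales by 1e6.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return numeric matrix of the same shape.
#' @export
normalize_cpm <- function(counts) {
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Two-group contrast: fold change and Welch p-value per gene
#'
#' For each gene, the log2 fold change is
#' \code{log2((mean_num + pseudocount) / (mean_den + pseudocount))} of the
#' normalized group means, and the two-sided p-value comes from Welch's
#' unequal-variance t-test on \code{log2(CPM + pseudocount)}. Genes with zero
#' counts in every sample of both groups have no defined fold change; they are
#' excluded and recorded in the \code{excluded} attribute.
#'
#' When both groups have zero variance the t statistic is degenerate: p is 1
#' if the means are equal and 0 otherwise.
#'
#' @param normalized gene x sample CPM matrix (see
#'   \code{\link{normalize_cpm}}).
#' @param groups factor/character of group labels, one per column.
#' @param numerator,denominator group labels to contrast (fold change =
#'   numerator over denominator). Each needs >= 2 samples.
#' @param pseudocount added before logs and ratios; guards zeros.
#' @return data.frame of class \code{contrast_table} with columns gene_id,
#'   log2fc, fold_change, p_value, mean_num, mean_den, and attributes
#'   \code{contrast} (e.g. "Model_vs_Sham") and \code{excluded}.
#' @export
contrast_groups <- function(normalized, groups, numerator, denominator,
                            pseudocount = 0.5) {
  groups <- as.character(groups)
  for (g in c(numerator, denominator)) {
    if (sum(groups == g) < 2L) {
      stop(sprintf("group '%s' absent or has fewer than 2 samples", g),
           call. = FALSE)
    }
  }
  x <- normalized[, groups == numerator, drop = FALSE]
  y <- normalized[, groups == denominator, drop = FALSE]
  all_zero <- rowSums(x) == 0 & rowSums(y) == 0
  excluded <- rownames(normalized)[all_zero]
  x <- x[!all_zero, , drop = FALSE]
  y <- y[!all_zero, , drop = FALSE]

  mean_num <- rowMeans(x)
  mean_den <- rowMeans(y)
  log2fc <- log2((mean_num + pseudocount) / (mean_den + pseudocount))

  p <- welch_p(log2(x + pseudocount), log2(y + pseudocount))

  out <- data.frame(gene_id = rownames(x), log2fc = log2fc,
                    fold_change = 2^log2fc, p_value = p,
                    mean_num = mean_num, mean_den = mean_den,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- paste0(numerator, "_vs_", denominator)
  attr(out, "excluded") <- excluded
  class(out) <- c("contrast_table", class(out))
  out
}

# Row-wise Welch two-sample t-test p-values; degenerate rows (both variances
# zero) give p = 1 for equal means, p = 0 otherwise.
welch_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  unname(p)
}
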