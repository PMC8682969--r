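# Hypergeometric over-representation analysis (ORA) of a gene list against
# GMT gene-set collections, with Benjamini-Hochberg correction across the
# sets of a collection.

#' Over-representation analysis
#'
#' For each set in the collection, intersects the set with the universe and
#' tests the overlap with \code{gene_list} using the hypergeometric upper
#' tail: \eqn{p = P(X \ge k)} where the population is the universe, successes
#' are the in-universe set members, and draws are the gene list. P-values are
#' BH-adjusted across all sets of the collection.
#'
#' The universe should be the population the list was drawn from -- in the
#' pipeline, the genes scored by NTRA (network genes with DE measurements) --
#' since a larger universe inflates significance.
#'
#' @param gene_list character vector of hit genes (must be a subset of
#'   \code{universe}; genes outside it are dropped with a warning).
#' @param collection named list of character vectors (see
#'   \code{\link{read_gmt}}).
#' @param universe character vector, the background population.
#' @param adjust_method multiple-testing method (default "BH").
#' @return data.frame, one row per set, sorted by p-value: set_name,
#'   overlap_count, set_size, list_size, universe_size, p_value, q_value,
#'   overlap_genes (comma-separated).
#' @export
ora <- function(gene_list, collection, universe, adjust_method = "BH") {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(gene_list)) stop("empty gene list", call. = FALSE)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) of the list are outside the universe",
            " and were dropped")
    gene_list <- intersect(gene_list, universe)
    if (!length(gene_list)) stop("gene list and universe are disjoint",
                                 call. = FALSE)
  }
  N <- length(universe)
  k <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(unique(collection[[nm]]), universe)
    K <- length(set_u)
    ov <- intersect(gene_list, set_u)
    x <- length(ov)
    # P(X >= x); phyper's lower.tail=FALSE gives P(X > q), hence q = x - 1
    p <- phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = x, set_size = K,
               list_size = k, universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = adjust_method)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap_count", "set_size", "list_size",
               "universe_size", "p_value", "q_value", "overlap_genes")]
  rownames(out) <- NULL
  out
}
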