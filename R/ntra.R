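# NTRA node prioritization: rank aggregation of topology (degree,
# betweenness) and transcriptome (fold change, p-value) attributes.
#
#   RankT = R(RankB + RankD)
#   RankR = R(RankF + RankP)
#   Rank  = R(RankT + RankR)
#
# where R(.) ranks a vector so that rank 1 is the most important entry and
# ties take the average of the covered positions. Throughout the package a
# *smaller* rank number means a more crucial gene.

#' Importance ranking with average ties
#'
#' The rank operator R(.) used by every NTRA stage: rank 1 goes to the most
#' important value (the largest when \code{higher_is_better}, else the
#' smallest); ties receive the average of the positions they cover.
#'
#' @param values finite numeric vector.
#' @param higher_is_better if \code{TRUE} (default), larger values rank
#'   better (smaller rank number).
#' @param ids optional identifiers used in the error message for
#'   non-finite values.
#' @return numeric rank vector in [1, length(values)].
#' @export
rank_importance <- function(values, higher_is_better = TRUE, ids = NULL) {
  bad <- !is.finite(values)
  if (any(bad)) {
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop("non-finite values cannot be ranked: ", lab, call. = FALSE)
  }
  if (higher_is_better) {
    rank(-values, ties.method = "average")
  } else {
    rank(values, ties.method = "average")
  }
}

#' NTRA rank aggregation over a disease network
#'
#' Joins per-node topology with the disease-contrast DE table (inner join on
#' gene_id; genes present on only one side are excluded and reported in the
#' \code{unmatched} attribute, since all four rank components are required).
#' Component ranks: \code{rank_b} from betweenness and \code{rank_d} from
#' degree (higher is better); \code{rank_f} from the fold-change magnitude
#' |log2FC| (higher is better; set \code{rank_fc_magnitude = FALSE} to rank
#' the signed log2FC instead) and \code{rank_p} from the p-value (lower is
#' better). The aggregated ranks re-rank sums, where a smaller rank sum is
#' better.
#'
#' @param topology data.frame(gene_id, degree, betweenness) from
#'   \code{\link{network_topology}}.
#' @param de DE table for the disease contrast (Model vs Sham) with columns
#'   gene_id, log2fc, p_value.
#' @param rank_fc_magnitude rank |log2fc| (default) or signed log2fc.
#' @return data.frame of class \code{ntra_table}: gene_id, rank_b, rank_d,
#'   rank_t, rank_f, rank_p, rank_r, rank -- sorted by final rank.
#' @export
ntra_rank <- function(topology, de, rank_fc_magnitude = TRUE) {
  need_t <- c("gene_id", "degree", "betweenness")
  need_d <- c("gene_id", "log2fc", "p_value")
  stopifnot(all(need_t %in% colnames(topology)),
            all(need_d %in% colnames(de)))
  m <- merge(topology[, need_t], de[, need_d], by = "gene_id")
  if (!nrow(m)) {
    stop("topology and DE tables share no genes; cannot aggregate ranks",
         call. = FALSE)
  }
  unmatched <- c(setdiff(topology$gene_id, m$gene_id),
                 setdiff(de$gene_id, m$gene_id))
  fc_val <- if (rank_fc_magnitude) abs(m$log2fc) else m$log2fc
  rank_b <- rank_importance(m$betweenness, TRUE, m$gene_id)
  rank_d <- rank_importance(m$degree, TRUE, m$gene_id)
  rank_t <- rank_importance(rank_b + rank_d, FALSE, m$gene_id)
  rank_f <- rank_importance(fc_val, TRUE, m$gene_id)
  rank_p <- rank_importance(m$p_value, FALSE, m$gene_id)
  rank_r <- rank_importance(rank_f + rank_p, FALSE, m$gene_id)
  final <- rank_importance(rank_t + rank_r, FALSE, m$gene_id)
  out <- data.frame(gene_id = m$gene_id,
                    rank_b = rank_b, rank_d = rank_d, rank_t = rank_t,
                    rank_f = rank_f, rank_p = rank_p, rank_r = rank_r,
                    rank = final, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  class(out) <- c("ntra_table", class(out))
  out
}

#' Flag the top NTRA fraction
#'
#' Genes with final rank <= \code{ceiling(fraction * n)} are flagged as
#' candidates for the key-gene set (the pipeline intersects this flag with
#' EoR > 0).
#'
#' @param scores an \code{\link{ntra_rank}} table.
#' @param fraction fraction in (0, 1] to keep; default the top half.
#' @return the table with a logical \code{is_top_fraction} column added.
#' @export
select_top_fraction <- function(scores, fraction = 0.5) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  cutoff <- ceiling(fraction * nrow(scores))
  scores$is_top_fraction <- scores$rank <= cutoff
  scores
}
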