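# Drug-recovery scoring: per-gene recovery level (RL) and efficiency of
# recovery (EoR).
#
#   RL  = Fold Change(Treated/Model) / Fold Change(Sham/Model)
#   EoR = 100% - |100% - RL|
#
# RL = 1 means the treatment moved the gene exactly back to its healthy
# (Sham) level; EoR peaks at 100% there, is 0 at RL = 0 (no movement) and at
# RL = 2 (equal-sized overshoot), and is negative for movement away from Sham
# or overshoot beyond 2x.

#' Recovery level of a gene
#'
#' By default RL is the ratio of log2 fold changes,
#' \code{log2FC(Treated/Model) / log2FC(Sham/Model)}, which makes RL = 1
#' correspond exactly to full return-to-Sham and behaves symmetrically for
#' up- and down-regulated genes. \code{scale = "linear"} instead takes the
#' ratio of linear fold changes \code{2^log2fc}.
#'
#' @param lfc_treated_vs_model log2 fold change of Treated over Model.
#' @param lfc_sham_vs_model log2 fold change of Sham over Model (note the
#'   orientation: the healthy state over the disease state).
#' @param scale "log2" (default) or "linear".
#' @return numeric RL vector (NA where the denominator is 0 on the chosen
#'   scale).
#' @export
compute_rl <- function(lfc_treated_vs_model, lfc_sham_vs_model,
                       scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (scale == "log2") {
    num <- lfc_treated_vs_model
    den <- lfc_sham_vs_model
  } else {
    num <- 2^lfc_treated_vs_model
    den <- 2^lfc_sham_vs_model
  }
  rl <- num / den
  rl[den == 0] <- NA_real_
  rl
}

#' Efficiency of recovery
#'
#' \code{EoR = 100 - |100 - 100 * RL|}, in percent. The maximum is 100 (full
#' recovery at RL = 1); EoR <= 0 indicates no recovery effect. Negative
#' values are retained, not floored.
#'
#' @param rl recovery level (vector).
#' @return EoR in percent, same length as \code{rl}.
#' @export
compute_eor <- function(rl) {
  100 - abs(100 - 100 * rl)
}

#' Score recovery for every gene of a disease contrast
#'
#' Combines the two pipeline contrasts into per-gene RL and EoR. The
#' Sham-vs-Model change is the negated Model-vs-Sham log2FC. Genes whose
#' disease perturbation is negligible, |log2FC(Sham/Model)| <
#' \code{perturbation_epsilon}, are excluded from scoring (RL is numerically
#' unstable there) and recorded with \code{exclusion_reason =
#' "not perturbed"}; recovery is a property of imbalanced genes only.
#'
#' @param de_model_vs_sham,de_treated_vs_model contrast tables (gene_id,
#'   log2fc, p_value) for Model-vs-Sham and Treated-vs-Model.
#' @param scale RL scale, see \code{\link{compute_rl}}.
#' @param perturbation_epsilon guard threshold on |log2FC(Sham/Model)|.
#' @param high_recovery_threshold EoR percent above which a gene counts as
#'   highly recovered (default 80).
#' @return data.frame of class \code{recovery_table}: gene_id, rl,
#'   eor_percent, is_recovered (EoR > 0), is_high_recovery
#'   (EoR > threshold), exclusion_reason (NA for scored genes; excluded genes
#'   have NA rl/eor).
#' @export
score_recovery <- function(de_model_vs_sham, de_treated_vs_model,
                           scale = c("log2", "linear"),
                           perturbation_epsilon = 0.1,
                           high_recovery_threshold = 80) {
  scale <- match.arg(scale)
  m <- merge(de_model_vs_sham[, c("gene_id", "log2fc")],
             de_treated_vs_model[, c("gene_id", "log2fc")],
             by = "gene_id", suffixes = c("_mvs", "_tvm"))
  if (!nrow(m)) stop("the two contrasts share no genes", call. = FALSE)
  lfc_svm <- -m$log2fc_mvs                 # Sham over Model
  guarded <- abs(lfc_svm) < perturbation_epsilon
  rl <- rep(NA_real_, nrow(m))
  rl[!guarded] <- compute_rl(m$log2fc_tvm[!guarded], lfc_svm[!guarded],
                             scale = scale)
  eor <- compute_eor(rl)
  out <- data.frame(
    gene_id = m$gene_id,
    rl = rl,
    eor_percent = eor,
    is_recovered = !is.na(eor) & eor > 0,
    is_high_recovery = !is.na(eor) & eor > high_recovery_threshold,
    exclusion_reason = ifelse(guarded, "not perturbed", NA_character_),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  attr(out, "perturbation_epsilon") <- perturbation_epsilon
  attr(out, "high_recovery_threshold") <- high_recovery_threshold
  class(out) <- c("recovery_table", class(out))
  out
}

#' Summarize a recovery table
#'
#' Counts genes with a recovery trend (EoR > 0) and highly recovered genes
#' (EoR above the threshold), and reports the percentage of the latter among
#' the former, rounded to one decimal. With zero recovered genes the
#' percentage is undefined (NA), not 0.
#'
#' @param results a \code{\link{score_recovery}} table, or a bare numeric
#'   vector of EoR percentages.
#' @param high_recovery_threshold EoR percent cutoff for "high recovery"
#'   (default 80; ignored if \code{results} carries its own threshold
#'   attribute).
#' @return list: n_scored, n_recovered, n_high_recovery,
#'   pct_high_among_recovered.
#' @export
summarize_recovery <- function(results, high_recovery_threshold = 80) {
  if (is.numeric(results)) {
    eor <- results
  } else {
    eor <- results$eor_percent
    thr <- attr(results, "high_recovery_threshold")
    if (!is.null(thr)) high_recovery_threshold <- thr
  }
  eor <- eor[!is.na(eor)]
  if (!length(eor)) stop("no scored genes to summarize", call. = FALSE)
  n_rec <- sum(eor > 0)
  n_high <- sum(eor > high_recovery_threshold)
  pct <- if (n_rec == 0) NA_real_ else round(100 * n_high / n_rec, 1)
  list(n_scored = length(eor), n_recovered = n_rec, n_high_recovery = n_high,
       pct_high_among_recovered = pct)
}
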