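# Synthetic three-group count studies with planted perturbation / recovery
# structure and a matching scale-free PPI graph.

GROUP_LEVELS <- c("Sham", "Model", "Treated")

#' Configuration for the synthetic-study generator
#'
#' Collects and validates every knob of the generator. Counts are drawn from a
#' negative binomial with variance \eqn{\mu + \phi \mu^2} (\code{nb_dispersion}
#' is \eqn{\phi}); baseline gene means are log-normal; per-sample size factors
#' are log-normal with median 1 so expected depth is equal across groups and
#' fold changes are not confounded by design.
#'
#' A subset of the disease genes (\code{frac_perturbed}) receives a nonzero
#' Model-vs-Sham effect with |log2 fold change| drawn uniformly from
#' \code{[effect_log2fc_low, effect_log2fc_high]} and random sign. A sub-subset
#' (\code{frac_recovered}) of the perturbed genes is moved back toward Sham in
#' the Treated group on the log2 scale: the Treated log2-mean equals the Model
#' log2-mean minus \eqn{r \cdot} planted log2FC, with the recovery coefficient
#' \eqn{r} drawn uniformly from \code{[recovery_coef_low, recovery_coef_high]}
#' (\eqn{r = 1} means full return to Sham).
#'
#' Defaults emulate a small murine heart-failure sequencing study: three
#' animals per arm, a ~2000-gene measured universe with a 150-gene disease set,
#' moderate effects (1--3 log2 units) and typical bulk RNA-seq dispersion.
#' The PPI attachment parameter defaults to 25 so the graph has the density
#' of a medium-confidence STRING export (~25 edges per gene on average),
#' without which the induced disease subgraph would be unrealistically sparse.
#'
#' @param n_genes number of genes in the measured universe.
#' @param n_disease_genes size of the disease-gene subset (<= \code{n_genes}).
#' @param n_per_group samples per group (Sham, Model, Treated).
#' @param frac_perturbed fraction in (0,1] of disease genes given a nonzero
#'   Model-vs-Sham effect.
#' @param frac_recovered fraction in [0,1] of perturbed genes whose Treated
#'   mean is moved back toward Sham.
#' @param effect_log2fc_low,effect_log2fc_high bounds of the uniform
#'   distribution of |planted log2 fold change|.
#' @param recovery_coef_low,recovery_coef_high bounds in [0,1] of the planted
#'   recovery coefficient.
#' @param nb_dispersion negative-binomial dispersion \eqn{\phi}
#'   (variance = \eqn{\mu + \phi\mu^2}); 0 gives Poisson counts.
#' @param base_mean_log_mu,base_mean_log_sigma natural-log parameters of the
#'   log-normal baseline gene means.
#' @param library_size_factor_sigma log-normal sigma of per-sample size
#'   factors (median 1).
#' @param ppi_edges_per_node attachment parameter of the scale-free PPI graph.
#' @param ppi_isolated_fraction fraction of genes deliberately left with no
#'   PPI edge, to exercise isolated-node removal downstream.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   studies.
#' @return an object of class \code{sim_config} (a validated list).
#' @seealso \code{\link{generate_study}}
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_disease_genes = 150L,
                              n_per_group = 3L,
                              frac_perturbed = 0.6,
                              frac_recovered = 0.6,
                              effect_log2fc_low = 1.0,
                              effect_log2fc_high = 3.0,
                              recovery_coef_low = 0.5,
                              recovery_coef_high = 1.0,
                              nb_dispersion = 0.1,
                              base_mean_log_mu = log(100),
                              base_mean_log_sigma = 1.2,
                              library_size_factor_sigma = 0.15,
                              ppi_edges_per_node = 25L,
                              ppi_isolated_fraction = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_disease_genes = n_disease_genes,
    n_per_group = n_per_group,
    frac_perturbed = frac_perturbed, frac_recovered = frac_recovered,
    effect_log2fc_low = effect_log2fc_low,
    effect_log2fc_high = effect_log2fc_high,
    recovery_coef_low = recovery_coef_low,
    recovery_coef_high = recovery_coef_high,
    nb_dispersion = nb_dispersion,
    base_mean_log_mu = base_mean_log_mu,
    base_mean_log_sigma = base_mean_log_sigma,
    library_size_factor_sigma = library_size_factor_sigma,
    ppi_edges_per_node = ppi_edges_per_node,
    ppi_isolated_fraction = ppi_isolated_fraction,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("configuration error: '%s' must be an integer >= %d", field,
                 min), call. = FALSE)
  }
}

check_range <- function(x, field, lo, hi, lo_open = FALSE) {
  bad <- length(x) != 1L || !is.numeric(x) || is.na(x) || x > hi ||
    (if (lo_open) x <= lo else x < lo)
  if (bad) {
    stop(sprintf("configuration error: '%s' must be in %s%g, %g]",
                 field, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
}

validate_sim_config <- function(cfg) {
  check_count(cfg$n_genes, "n_genes")
  check_count(cfg$n_disease_genes, "n_disease_genes")
  check_count(cfg$n_per_group, "n_per_group")
  check_count(cfg$ppi_edges_per_node, "ppi_edges_per_node")
  check_count(cfg$seed, "seed", min = -2147483647L)
  if (cfg$n_disease_genes > cfg$n_genes) {
    stop("configuration error: 'n_disease_genes' exceeds 'n_genes'",
         call. = FALSE)
  }
  check_range(cfg$frac_perturbed, "frac_perturbed", 0, 1, lo_open = TRUE)
  check_range(cfg$frac_recovered, "frac_recovered", 0, 1)
  check_range(cfg$ppi_isolated_fraction, "ppi_isolated_fraction", 0, 1)
  check_range(cfg$recovery_coef_low, "recovery_coef_low", 0, 1)
  check_range(cfg$recovery_coef_high, "recovery_coef_high", 0, 1)
  if (cfg$recovery_coef_high < cfg$recovery_coef_low) {
    stop("configuration error: 'recovery_coef_high' < 'recovery_coef_low'",
         call. = FALSE)
  }
  if (cfg$effect_log2fc_low < 0 || cfg$effect_log2fc_high <
      cfg$effect_log2fc_low) {
    stop(paste("configuration error: 'effect_log2fc_low'/'effect_log2fc_high'",
               "must satisfy 0 <= low <= high"), call. = FALSE)
  }
  if (!is.numeric(cfg$nb_dispersion) || is.na(cfg$nb_dispersion) ||
      cfg$nb_dispersion < 0) {
    stop("configuration error: 'nb_dispersion' must be >= 0", call. = FALSE)
  }
  for (f in c("base_mean_log_mu", "base_mean_log_sigma",
              "library_size_factor_sigma")) {
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]])) {
      stop(sprintf("configuration error: '%s' must be numeric", f),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d genes (%d disease), %d samples/group, seed %d\n",
              x$n_genes, x$n_disease_genes, x$n_per_group, x$seed))
  cat(sprintf("  perturbed %.0f%% of disease genes, recovered %.0f%% of those\n",
              100 * x$frac_perturbed, 100 * x$frac_recovered))
  invisible(x)
}

#' Generate a synthetic three-group study with planted ground truth
#'
#' Draws a complete Sham/Model/Treated count study plus a scale-free PPI graph
#' over the gene universe. The single RNG stream seeded from
#' \code{config$seed} is consumed in a fixed order -- baseline means, effect
#' sizes, gene assignments, PPI edges, then counts -- so identical configs give
#' bit-identical studies.
#'
#' Planted structure: Sham mean of gene g is \eqn{\mu_g} (log-normal); the
#' Model mean is \eqn{\mu_g 2^{\mathrm{lfc}_g}} for perturbed genes and
#' \eqn{\mu_g} otherwise; the Treated log2-mean is the Model log2-mean minus
#' \eqn{r_g \mathrm{lfc}_g} for recovered genes and equals the Model log2-mean
#' otherwise.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an object of class \code{synthetic_study}: a list with
#'   \code{counts} (gene x sample integer matrix), \code{sample_groups}
#'   (factor Sham/Model/Treated), \code{gene_ids}, \code{disease_genes},
#'   \code{truth} (data.frame: gene_id, is_perturbed, planted_log2fc,
#'   is_recovered, planted_recovery_coef), \code{group_means} (gene x 3 matrix
#'   of expected means before size factors), \code{ppi_edges} (data.frame:
#'   node_a, node_b, score), and the \code{config}.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))

  ## 1. baseline means
  mu <- rlnorm(n, meanlog = config$base_mean_log_mu,
               sdlog = config$base_mean_log_sigma)

  ## 2. effect sizes (magnitude, sign, recovery coefficient) for every gene;
  ##    only the assigned genes consume theirs, but drawing for all keeps the
  ##    stream layout independent of the assignments.
  lfc_mag <- runif(n, config$effect_log2fc_low, config$effect_log2fc_high)
  lfc_sign <- ifelse(rbinom(n, 1L, 0.5) == 1L, 1, -1)
  rec_coef <- runif(n, config$recovery_coef_low, config$recovery_coef_high)

  ## 3. assignments: disease set, perturbed subset, recovered sub-subset
  disease_genes <- sort(sample(gene_ids, config$n_disease_genes))
  n_pert <- round(config$frac_perturbed * config$n_disease_genes)
  perturbed <- sort(sample(disease_genes, n_pert))
  n_rec <- round(config$frac_recovered * n_pert)
  recovered <- sort(sample(perturbed, n_rec))

  is_pert <- gene_ids %in% perturbed
  is_rec <- gene_ids %in% recovered
  planted_lfc <- ifelse(is_pert, lfc_mag * lfc_sign, 0)
  planted_r <- ifelse(is_rec, rec_coef, 0)

  ## planted expected means per group (before size factors)
  model_mu <- mu * 2^planted_lfc
  treated_mu <- 2^(log2(model_mu) - planted_r * planted_lfc)
  group_means <- cbind(Sham = mu, Model = model_mu, Treated = treated_mu)
  rownames(group_means) <- gene_ids

  ## 4. PPI edges (continues the same stream)
  ppi_edges <- generate_ppi(gene_ids,
                            edges_per_node = config$ppi_edges_per_node,
                            isolated_fraction = config$ppi_isolated_fraction)

  ## 5. counts: per-sample size factors, then NB draws column by column
  n_samp <- 3L * config$n_per_group
  groups <- factor(rep(GROUP_LEVELS, each = config$n_per_group),
                   levels = GROUP_LEVELS)
  sample_ids <- paste0(groups, "_", rep(seq_len(config$n_per_group), 3L))
  sf <- rlnorm(n_samp, 0, config$library_size_factor_sigma)
  counts <- matrix(0L, nrow = n, ncol = n_samp,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samp)) {
    m <- group_means[, as.character(groups[j])] * sf[j]
    counts[, j] <- as.integer(if (config$nb_dispersion > 0) {
      rnbinom(n, mu = m, size = 1 / config$nb_dispersion)
    } else {
      rpois(n, m)
    })
  }

  truth <- data.frame(
    gene_id = gene_ids,
    is_disease = gene_ids %in% disease_genes,
    is_perturbed = is_pert,
    planted_log2fc = planted_lfc,
    is_recovered = is_rec,
    planted_recovery_coef = planted_r,
    stringsAsFactors = FALSE
  )

  structure(list(counts = counts, sample_groups = groups,
                 sample_ids = sample_ids, gene_ids = gene_ids,
                 disease_genes = disease_genes, truth = truth,
                 group_means = group_means, size_factors = sf,
                 ppi_edges = ppi_edges, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d genes x %d samples (%d per group)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_per_group))
  cat(sprintf("  disease genes: %d | perturbed: %d | recovered: %d\n",
              length(x$disease_genes), sum(x$truth$is_perturbed),
              sum(x$truth$is_recovered)))
  cat(sprintf("  PPI: %d edges over the %d-gene universe\n",
              nrow(x$ppi_edges), length(x$gene_ids)))
  invisible(x)
}

#' Generate a scale-free PPI edge list by preferential attachment
#'
#' Grows a Barabasi--Albert-style graph: the seed is a path over the first
#' \code{edges_per_node + 1} genes (in random order) and every subsequent gene
#' attaches \code{edges_per_node} edges to distinct existing genes with
#' probability proportional to their current degree. Each undirected edge
#' carries an integer confidence score drawn uniformly from [400, 1000]
#' (the STRING combined-score dialect, medium confidence and up). A fraction
#' of genes can be left with no edges to exercise isolated-node removal.
#'
#' @param gene_ids character vector of node identifiers.
#' @param edges_per_node attachment parameter m (>= 1).
#' @param seed optional integer seed; if \code{NULL} the current RNG stream is
#'   used (as when called from \code{\link{generate_study}}).
#' @param isolated_fraction fraction of genes (rounded to a count) left with
#'   degree 0.
#' @param score_range integer bounds of the sampled edge scores.
#' @return data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score}; no self-loops, no duplicate undirected pairs.
#' @export
generate_ppi <- function(gene_ids, edges_per_node = 3L, seed = NULL,
                         isolated_fraction = 0, score_range = c(400L, 1000L)) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(edges_per_node)
  if (m < 1L) stop("'edges_per_node' must be >= 1", call. = FALSE)
  check_range(isolated_fraction, "isolated_fraction", 0, 1)
  n_iso <- round(isolated_fraction * length(gene_ids))
  iso <- if (n_iso > 0) sample(gene_ids, n_iso) else character(0)
  active <- setdiff(gene_ids, iso)
  n <- length(active)
  if (n < m + 1L) {
    stop(sprintf("need at least %d connectable genes for edges_per_node = %d, got %d",
                 m + 1L, m, n), call. = FALSE)
  }
  ord <- sample(active)            # arrival order; early nodes become hubs
  deg <- integer(n)
  from <- character(m * (n - m)); to <- character(m * (n - m))
  k <- 0L
  ## seed path on the first m+1 nodes
  for (i in seq_len(m)) {
    k <- k + 1L
    from[k] <- ord[i]; to[k] <- ord[i + 1L]
    deg[i] <- deg[i] + 1L; deg[i + 1L] <- deg[i + 1L] + 1L
  }
  ## preferential attachment for the rest
  for (i in seq_len(n - m - 1L) + m + 1L) {
    existing <- seq_len(i - 1L)
    targets <- sample(existing, m, prob = deg[existing])
    for (t in targets) {
      k <- k + 1L
      from[k] <- ord[i]; to[k] <- ord[t]
      deg[t] <- deg[t] + 1L
    }
    deg[i] <- deg[i] + m
  }
  scores <- sample(score_range[1]:score_range[2], k, replace = TRUE)
  edges <- data.frame(node_a = from[seq_len(k)], node_b = to[seq_len(k)],
                      score = scores, stringsAsFactors = FALSE)
  ## canonical orientation; the construction cannot produce duplicates or
  ## self-loops, but normalize anyway for the I/O round-trip contract
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a synthetic study to plain-text files
#'
#' Writes counts (TSV, genes x samples), group labels (2-column TSV), the
#' truth table (TSV), the PPI edge list (3-column TSV, STRING dialect), the
#' disease-gene list (one symbol per line) and the configuration (JSON) into
#' \code{dir}.
#'
#' @param study a \code{\link{generate_study}} result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the file paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    disease_genes = file.path(dir, "disease_genes.txt"),
    config = file.path(dir, "sim_config.json")
  )
  write_counts(study$counts, paths$counts)
  write.table(data.frame(sample_id = study$sample_ids,
                         group = as.character(study$sample_groups)),
              paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_ppi_edges(study$ppi_edges, paths$ppi)
  writeLines(study$disease_genes, paths$disease_genes)
  jsonlite::write_json(unclass(study$config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
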