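# End-to-end orchestration: inputs (counts+groups or two DE tables, disease
# genes, PPI edges, optional GMT collections) -> disease network -> NTRA ->
# recovery scoring -> key genes -> ORA, with a machine-readable run report.
# Progress is logged to stderr; results only ever go to files / return value.

default_params <- function() {
  list(
    min_score = 400,              # STRING combined-score inclusion cutoff
    pseudocount = 0.5,
    rl_scale = "log2",
    perturbation_epsilon = 0.1,
    top_fraction = 0.5,
    high_recovery_threshold = 80,
    deg_log2fc = 1,               # reporting-only DEG thresholds
    deg_p = 0.05,
    rank_fc_magnitude = TRUE
  )
}

#' Assemble and validate a pipeline run configuration
#'
#' Exactly one input mode must be active: counts mode (a count matrix plus
#' group labels, from which both contrasts are computed) or DE-table mode
#' (externally produced Model-vs-Sham and Treated-vs-Model tables). Inputs
#' may be file paths or in-memory objects (matrix/data.frame/vector); paths
#' are loaded by \code{\link{run_pipeline}}.
#'
#' @param counts count matrix or TSV path (counts mode).
#' @param groups named group vector or 2-column TSV path (counts mode).
#' @param de_model_vs_sham,de_treated_vs_model DE tables or TSV paths
#'   (DE-table mode).
#' @param disease_genes character vector or one-symbol-per-line file.
#' @param ppi_edges edge data.frame or 3-column TSV path.
#' @param gmt named list of collections, or character vector of GMT paths
#'   (optional).
#' @param out_dir output directory.
#' @param seed integer seed echoed into the report (the pipeline itself is
#'   deterministic; the seed matters when the config is paired with
#'   simulation).
#' @param params named list overriding entries of the default parameter set
#'   (min_score, pseudocount, rl_scale, perturbation_epsilon, top_fraction,
#'   high_recovery_threshold, deg_log2fc, deg_p, rank_fc_magnitude).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(counts = NULL, groups = NULL,
                       de_model_vs_sham = NULL, de_treated_vs_model = NULL,
                       disease_genes, ppi_edges, gmt = NULL,
                       out_dir, seed = 1L, params = list()) {
  counts_mode <- !is.null(counts)
  de_mode <- !is.null(de_model_vs_sham) || !is.null(de_treated_vs_model)
  if (counts_mode && de_mode) {
    stop("config error: both counts and DE tables supplied; choose one mode",
         call. = FALSE)
  }
  if (!counts_mode && !de_mode) {
    stop("config error: supply counts+groups or two DE tables", call. = FALSE)
  }
  if (counts_mode && is.null(groups)) {
    stop("config error: counts mode needs group labels", call. = FALSE)
  }
  if (de_mode && (is.null(de_model_vs_sham) || is.null(de_treated_vs_model))) {
    stop("config error: DE-table mode needs both contrasts", call. = FALSE)
  }
  p <- default_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) {
    stop("config error: unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(params)] <- params
  for (nm in c("counts", "groups", "de_model_vs_sham", "de_treated_vs_model",
               "disease_genes", "ppi_edges", "gmt")) {
    x <- get(nm)
    if (is.character(x) && all(grepl("[/.]", x)) && !all(file.exists(x))) {
      stop("config error: input file(s) for '", nm, "' not found: ",
           paste(x[!file.exists(x)], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(counts = counts, groups = groups,
                 de_model_vs_sham = de_model_vs_sham,
                 de_treated_vs_model = de_treated_vs_model,
                 disease_genes = disease_genes, ppi_edges = ppi_edges,
                 gmt = gmt, out_dir = out_dir, seed = as.integer(seed),
                 params = p, mode = if (counts_mode) "counts" else "de_tables"),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML maps directly onto the arguments of \code{\link{run_config}};
#' relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    vapply(p, function(pp) {
      if (file.exists(pp) || grepl("^/", pp)) pp else file.path(base, pp)
    }, "", USE.NAMES = FALSE)
  }
  run_config(counts = resolve(y$counts), groups = resolve(y$groups),
             de_model_vs_sham = resolve(y$de_model_vs_sham),
             de_treated_vs_model = resolve(y$de_treated_vs_model),
             disease_genes = resolve(y$disease_genes),
             ppi_edges = resolve(y$ppi_edges), gmt = resolve(y$gmt),
             out_dir = y$out_dir %||% "netrecov_out",
             seed = y$seed %||% 1L,
             params = y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[netrecov] %-18s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full disease-network recovery pipeline
#'
#' Stages, in order: load inputs; (counts mode only) CPM normalization and
#' the two contrasts; disease-gene / measured-gene intersection; disease
#' network construction with isolated-node removal; topology; NTRA rank
#' aggregation on the Model-vs-Sham contrast; RL/EoR recovery scoring; key
#' genes = top NTRA fraction with EoR > 0; ORA of the key genes against each
#' GMT collection (universe = NTRA-scored genes). All tables are written
#' under \code{config$out_dir} together with \code{report.json}. Given the
#' same config the run is fully deterministic, byte for byte.
#'
#' @param config a \code{\link{run_config}} (or YAML path).
#' @return invisibly, the run report (a list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  out <- config$out_dir
  for (d in c("", "network", "ntra", "recovery", "enrichment")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }

  ## inputs
  disease_genes <- stage("load disease genes",
                         load_input(config$disease_genes, read_gene_list))
  ppi <- stage("load PPI edges", {
    if (is.character(config$ppi_edges)) {
      read_ppi_edges(config$ppi_edges, min_score = p$min_score)
    } else {
      e <- config$ppi_edges
      e[e$score >= p$min_score & e$node_a != e$node_b, , drop = FALSE]
    }
  })

  excluded_all_zero <- character(0)
  if (config$mode == "counts") {
    counts <- load_input(config$counts, read_counts)
    groups_v <- load_input(config$groups, read_groups)
    groups <- as.character(groups_v[colnames(counts)])
    if (anyNA(groups)) {
      stop("samples without a group label: ",
           paste(colnames(counts)[is.na(groups)], collapse = ", "),
           call. = FALSE)
    }
    missing_grp <- setdiff(GROUP_LEVELS, groups)
    if (length(missing_grp)) {
      stop("pipeline needs all three groups; missing: ",
           paste(missing_grp, collapse = ", "), call. = FALSE)
    }
    cpm <- stage("normalize (CPM)", normalize_cpm(counts))
    de_mvs <- stage("contrast Model/Sham",
                    contrast_groups(cpm, groups, "Model", "Sham",
                                    pseudocount = p$pseudocount))
    de_tvm <- stage("contrast Treated/Model",
                    contrast_groups(cpm, groups, "Treated", "Model",
                                    pseudocount = p$pseudocount))
    excluded_all_zero <- union(attr(de_mvs, "excluded"),
                               attr(de_tvm, "excluded"))
  } else {
    de_mvs <- stage("load DE Model/Sham",
                    load_input(config$de_model_vs_sham, read_de_table))
    de_tvm <- stage("load DE Treated/Model",
                    load_input(config$de_treated_vs_model, read_de_table))
  }
  write_de_table(de_mvs, file.path(out, "de_model_vs_sham.tsv"))
  write_de_table(de_tvm, file.path(out, "de_treated_vs_model.tsv"))

  measured <- union(de_mvs$gene_id, de_tvm$gene_id)

  ## network
  inter <- stage("intersect genes", intersect_genes(disease_genes, measured))
  network <- stage("build network", build_network(inter, ppi))
  topo <- stage("topology", network_topology(network))
  export_network(network,
                 graphml_path = file.path(out, "network", "network.graphml"),
                 edges_path = file.path(out, "network", "edges.tsv"),
                 topology_path = file.path(out, "network", "topology.tsv"))

  ## NTRA
  ntra <- stage("NTRA ranks",
                ntra_rank(topo, de_mvs,
                          rank_fc_magnitude = p$rank_fc_magnitude))
  ntra <- select_top_fraction(ntra, fraction = p$top_fraction)
  write.table(ntra, file.path(out, "ntra", "ntra.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## recovery (scored over the NTRA universe: network genes with DE)
  ntra_genes <- ntra$gene_id
  rec <- stage("recovery (RL/EoR)",
               score_recovery(de_mvs[de_mvs$gene_id %in% ntra_genes, ],
                              de_tvm[de_tvm$gene_id %in% ntra_genes, ],
                              scale = p$rl_scale,
                              perturbation_epsilon = p$perturbation_epsilon,
                              high_recovery_threshold =
                                p$high_recovery_threshold))
  ## genes NTRA scored but absent from one contrast (e.g. all-zero in a
  ## group pair) must not vanish silently: record them as excluded
  missing_rec <- setdiff(ntra_genes, rec$gene_id)
  if (length(missing_rec)) {
    rec <- rbind(rec, data.frame(
      gene_id = missing_rec, rl = NA_real_, eor_percent = NA_real_,
      is_recovered = FALSE, is_high_recovery = FALSE,
      exclusion_reason = "not measured in both contrasts",
      stringsAsFactors = FALSE))
    rec <- rec[order(rec$gene_id), , drop = FALSE]
  }
  write.table(rec, file.path(out, "recovery", "recovery.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec_summary <- summarize_recovery(rec)

  ## key genes: top NTRA fraction with EoR > 0
  recovered_genes <- rec$gene_id[rec$is_recovered]
  key_genes <- sort(intersect(ntra$gene_id[ntra$is_top_fraction],
                              recovered_genes))
  writeLines(key_genes, file.path(out, "key_genes.txt"))

  ## enrichment
  enrich_summary <- list()
  if (!is.null(config$gmt) && length(key_genes)) {
    collections <- if (is.character(config$gmt)) {
      cl <- lapply(config$gmt, read_gmt)
      names(cl) <- sub("\\.gmt$", "", basename(config$gmt))
      cl
    } else config$gmt
    for (nm in names(collections)) {
      res <- stage(paste0("ORA ", nm),
                   ora(key_genes, collections[[nm]], universe = ntra_genes))
      write.table(res, file.path(out, "enrichment", paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enrich_summary[[nm]] <- list(
        n_sets = nrow(res),
        n_significant_q05 = sum(res$q_value < 0.05)
      )
    }
  }

  deg_mvs <- sum(abs(de_mvs$log2fc) >= p$deg_log2fc &
                   de_mvs$p_value < p$deg_p)
  deg_tvm <- sum(abs(de_tvm$log2fc) >= p$deg_log2fc &
                   de_tvm$p_value < p$deg_p)

  report <- list(
    tool = "netrecov",
    mode = config$mode,
    seed = config$seed,
    params = p,
    assumptions = list(
      de_test = if (config$mode == "counts")
        "Welch t on log2 CPM (simple stand-in; external DE tables accepted)"
      else "externally supplied DE tables",
      deg_thresholds = sprintf("|log2FC| >= %g & p < %g (reporting only)",
                               p$deg_log2fc, p$deg_p),
      min_score = sprintf("PPI combined-score cutoff %g", p$min_score),
      rl_scale = p$rl_scale,
      perturbation_epsilon = p$perturbation_epsilon,
      enrichment_universe = "genes scored by NTRA (network with DE)"
    ),
    funnel = list(
      n_measured_genes = length(measured),
      n_excluded_all_zero = length(excluded_all_zero),
      n_disease_genes = length(unique(disease_genes)),
      n_intersection = length(inter),
      n_isolated_dropped = length(network$dropped_isolated),
      n_network_nodes = length(network$nodes),
      n_network_edges = nrow(network$edges),
      n_ntra_scored = nrow(ntra),
      n_recovery_scored = rec_summary$n_scored,
      n_recovery_excluded = sum(!is.na(rec$exclusion_reason)),
      n_eor_positive = rec_summary$n_recovered,
      n_eor_high = rec_summary$n_high_recovery,
      pct_high_among_recovered = rec_summary$pct_high_among_recovered,
      n_deg_model_vs_sham = deg_mvs,
      n_deg_treated_vs_model = deg_tvm,
      n_key_genes = length(key_genes)
    ),
    enrichment = enrich_summary
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' One-command demonstration run on generated data
#'
#' Generates a synthetic study (defaults of
#' \code{\link{simulation_config}}, overridable via \code{...}), writes its
#' files under \code{out_dir/input}, and runs the full pipeline on them into
#' \code{out_dir/results}. Identical seeds give byte-identical outputs.
#'
#' @param seed integer seed for the simulation.
#' @param out_dir directory for inputs and results.
#' @param gmt optional GMT collections (paths or named list) for the
#'   enrichment stage; by default a small collection is derived from the
#'   study's own truth table (perturbed / recovered / random sets) so the
#'   stage always runs.
#' @param params pipeline parameter overrides, see \code{\link{run_config}}.
#' @param ... overrides for \code{\link{simulation_config}}.
#' @return invisibly, a list with the \code{study}, the run \code{report}
#'   and \code{out_dir}.
#' @export
demo_run <- function(seed = 1L, out_dir = tempfile("netrecov_demo_"),
                     gmt = NULL, params = list(), ...) {
  cfg <- simulation_config(seed = seed, ...)
  study <- generate_study(cfg)
  in_dir <- file.path(out_dir, "input")
  paths <- write_study(study, in_dir)
  if (is.null(gmt)) {
    truth <- study$truth
    gmt <- list(truth_sets = structure(list(
      perturbed = truth$gene_id[truth$is_perturbed],
      recovered = truth$gene_id[truth$is_recovered],
      first_hundred = head(study$gene_ids, 100L)
    ), class = "gene_set_collection"))
  }
  rc <- run_config(counts = paths$counts, groups = paths$groups,
                   disease_genes = paths$disease_genes,
                   ppi_edges = paths$ppi, gmt = gmt,
                   out_dir = file.path(out_dir, "results"),
                   seed = seed, params = params)
  report <- run_pipeline(rc)
  invisible(list(study = study, report = report, out_dir = out_dir))
}
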