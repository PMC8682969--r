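# Synthetic-study generator: planted structure, determinism, distributional
# contracts of the negative-binomial counts and the scale-free PPI graph.

test_that("planted perturbation and recovery counts follow the fractions", {
  st <- generate_study(simulation_config(
    n_genes = 200L, n_disease_genes = 50L, frac_perturbed = 1.0,
    frac_recovered = 0, seed = 5L))
  expect_equal(sum(st$truth$is_perturbed), 50L)
  expect_equal(sum(st$truth$is_recovered), 0L)

  st2 <- generate_study(simulation_config(
    n_genes = 200L, n_disease_genes = 50L, frac_perturbed = 0.5,
    frac_recovered = 0.5, seed = 5L))
  expect_equal(sum(st2$truth$is_perturbed), 25L)
  expect_equal(sum(st2$truth$is_recovered), 12L)  # round(0.5 * 25)
})

test_that("truth flags are nested: recovered within perturbed within disease", {
  for (seed in c(1L, 2L, 3L)) {
    st <- small_study(seed = seed)
    tr <- st$truth
    expect_true(all(tr$gene_id[tr$is_recovered] %in%
                      tr$gene_id[tr$is_perturbed]))
    expect_true(all(tr$gene_id[tr$is_perturbed] %in% st$disease_genes))
    expect_true(all(st$disease_genes %in% st$gene_ids))
    expect_true(all(tr$planted_log2fc[!tr$is_perturbed] == 0))
    expect_true(all(st$counts >= 0))
    expect_true(all(st$counts == round(st$counts)))
  }
})

test_that("same config and seed give bit-identical studies", {
  a <- small_study(seed = 77L)
  b <- small_study(seed = 77L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ppi_edges, b$ppi_edges)
  expect_identical(a$truth, b$truth)
  c <- small_study(seed = 78L)
  expect_false(identical(a$counts, c$counts))
})

test_that("planted means follow the Sham/Model/Treated contract", {
  st <- generate_study(simulation_config(
    n_genes = 100L, n_disease_genes = 30L, frac_perturbed = 1.0,
    frac_recovered = 1.0, recovery_coef_low = 1, recovery_coef_high = 1,
    seed = 9L))
  gm <- st$group_means
  tr <- st$truth
  # Model mean = Sham mean * 2^lfc for perturbed genes, unchanged otherwise
  expect_equal(log2(gm[, "Model"]) - log2(gm[, "Sham"]),
               setNames(tr$planted_log2fc, tr$gene_id))
  # with r = 1, Treated returns exactly to Sham: the Model-vs-Treated log2
  # difference equals the planted effect
  rec <- tr$is_recovered
  expect_equal(log2(gm[rec, "Model"]) - log2(gm[rec, "Treated"]),
               setNames(tr$planted_log2fc[rec], tr$gene_id[rec]))
  expect_equal(gm[rec, "Treated"], gm[rec, "Sham"])
})

test_that("Sham counts of unperturbed genes converge to mu_g * mean size factor", {
  st <- generate_study(simulation_config(
    n_genes = 150L, n_disease_genes = 30L, n_per_group = 200L,
    nb_dispersion = 0.05, seed = 31L))
  sham <- st$counts[, st$sample_groups == "Sham"]
  sf <- st$size_factors[st$sample_groups == "Sham"]
  expected <- st$group_means[, "Sham"] * mean(sf)
  obs <- rowMeans(sham)
  se <- apply(sham, 1, stats::sd) / sqrt(ncol(sham))
  z <- (obs - expected) / se
  unpert <- !st$truth$is_perturbed
  expect_true(all(abs(z[unpert]) <= 3))
})

test_that("generator rejects invalid configurations, naming the field", {
  expect_error(simulation_config(n_genes = 10.5), "n_genes")
  expect_error(simulation_config(frac_perturbed = 0), "frac_perturbed")
  expect_error(simulation_config(frac_recovered = 1.2), "frac_recovered")
  expect_error(simulation_config(n_genes = 10L, n_disease_genes = 20L),
               "n_disease_genes")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(recovery_coef_low = 0.9,
                                 recovery_coef_high = 0.5),
               "recovery_coef")
})

test_that("preferential-attachment PPI has the expected edge count and shape", {
  genes <- sprintf("g%02d", 1:10)
  e <- generate_ppi(genes, edges_per_node = 2L, seed = 4L)
  expect_gte(nrow(e), 9)
  expect_lte(nrow(e), 16)
  expect_true(all(e$node_a != e$node_b))
  expect_false(any(duplicated(paste(e$node_a, e$node_b))))
  expect_true(all(e$score >= 400 & e$score <= 1000))
  expect_identical(e, generate_ppi(genes, edges_per_node = 2L, seed = 4L))
})

test_that("isolated fraction leaves exactly the requested genes with degree 0", {
  genes <- sprintf("g%03d", 1:100)
  e <- generate_ppi(genes, edges_per_node = 3L, seed = 8L,
                    isolated_fraction = 0.1)
  touched <- unique(c(e$node_a, e$node_b))
  expect_equal(length(setdiff(genes, touched)), 10L)
})

test_that("PPI generation needs enough connectable genes", {
  expect_error(generate_ppi(c("a", "b"), edges_per_node = 2L, seed = 1L),
               "at least")
})

test_that("study round-trips through its on-disk representation", {
  st <- small_study(seed = 13L)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_identical(read_counts(paths$counts), st$counts)
  grp <- read_groups(paths$groups)
  expect_identical(unname(grp), as.character(st$sample_groups))
  ppi <- read_ppi_edges(paths$ppi, min_score = 0)
  expect_equal(ppi$node_a, st$ppi_edges$node_a)
  expect_equal(ppi$node_b, st$ppi_edges$node_b)
  expect_equal(ppi$score, as.numeric(st$ppi_edges$score))
  expect_identical(read_gene_list(paths$disease_genes), st$disease_genes)
})
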