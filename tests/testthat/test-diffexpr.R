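# CPM normalization and the two-group fold-change / Welch-test contrast.

test_that("CPM normalization is scale-invariant and guards empty samples", {
  m <- matrix(c(10L, 20L, 970L, 5L, 5L, 990L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  cpm <- normalize_cpm(m)
  expect_equal(colSums(cpm), c(a = 1e6, b = 1e6))
  # a sample whose library is exactly 1e6 passes through unchanged
  one <- matrix(c(999990L, 10L), nrow = 2,
                dimnames = list(c("g1", "g2"), "s"))
  expect_equal(normalize_cpm(one)[, 1], c(g1 = 999990, g2 = 10))
  # doubling all counts of a sample leaves its CPM unchanged
  expect_equal(normalize_cpm(m * 2L), cpm)
  # all-zero gene stays zero everywhere
  z <- rbind(m, g4 = c(0L, 0L))
  expect_true(all(normalize_cpm(z)["g4", ] == 0))
  # zero-total sample errors, naming it
  bad <- matrix(c(1L, 0L), nrow = 1, dimnames = list("g1", c("ok", "dead")))
  expect_error(normalize_cpm(bad), "dead")
})

test_that("contrast fold changes follow the pseudocounted mean ratio", {
  cpm <- matrix(c(rep(8, 3), rep(2, 3),    # gene A: num mean 8, den mean 2
                  rep(5, 3), rep(5, 3)),   # gene B: identical means
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), paste0("s", 1:6)))
  groups <- rep(c("Model", "Sham"), each = 3)
  ct <- contrast_groups(cpm, groups, "Model", "Sham", pseudocount = 1e-9)
  expect_equal(ct$log2fc[ct$gene_id == "A"], 2, tolerance = 1e-6)
  expect_equal(ct$log2fc[ct$gene_id == "B"], 0)
  expect_equal(ct$fold_change, 2^ct$log2fc)
})

test_that("Welch p-value matches stats::t.test and is 1 for identical groups", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  groups <- rep(c("Model", "Sham"), each = 3)
  ct <- contrast_groups(x, groups, "Model", "Sham")
  expect_equal(ct$p_value, 1)

  set.seed(42)
  m <- matrix(rlnorm(5 * 8, 3, 1), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  grp <- rep(c("Model", "Sham"), each = 4)
  ct2 <- contrast_groups(m, grp, "Model", "Sham", pseudocount = 0.5)
  ref <- apply(log2(m + 0.5), 1, function(v) {
    stats::t.test(v[grp == "Model"], v[grp == "Sham"])$p.value
  })
  expect_equal(ct2$p_value, unname(ref))
})

test_that("swapping numerator and denominator negates log2fc, keeps p", {
  st <- small_study(seed = 21L)
  cpm <- normalize_cpm(st$counts)
  g <- as.character(st$sample_groups)
  fwd <- contrast_groups(cpm, g, "Model", "Sham")
  rev <- contrast_groups(cpm, g, "Sham", "Model")
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p_value, rev$p_value)
})

test_that("all-zero genes are excluded and reported; missing groups error", {
  m <- matrix(c(5L, 6L, 7L, 8L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("live", "dead"), paste0("s", 1:4)))
  grp <- rep(c("Model", "Sham"), each = 2)
  ct <- contrast_groups(m, grp, "Model", "Sham")
  expect_identical(ct$gene_id, "live")
  expect_identical(attr(ct, "excluded"), "dead")
  expect_error(contrast_groups(m, grp, "Treated", "Sham"), "Treated")
})

test_that("estimated log2fc recovers the planted effect at large n", {
  st <- generate_study(simulation_config(
    n_genes = 1000L, n_disease_genes = 30L, n_per_group = 200L,
    frac_perturbed = 0.7, nb_dispersion = 0.02,
    base_mean_log_mu = log(500), base_mean_log_sigma = 0.8,
    effect_log2fc_low = 1, effect_log2fc_high = 2, seed = 1L))
  cpm <- normalize_cpm(st$counts)
  ct <- contrast_groups(cpm, as.character(st$sample_groups),
                        "Model", "Sham", pseudocount = 0.5)
  m <- merge(ct, st$truth, by = "gene_id")
  pert <- m[m$is_perturbed, ]
  expect_gt(nrow(pert), 0)
  expect_true(all(abs(pert$log2fc - pert$planted_log2fc) <= 0.1))
})
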