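# Shift scores, Z-normalization, calls and supervised selection.

test_that("archetype evidence gives the textbook LOF/GOF signature", {
  g <- archetype_pathway()
  nb <- extract_neighborhood(g, "F", 1)
  lof <- pshift(nb, archetype_data(0.9, NA, 0.1), "s1")$raw_shift
  gof <- pshift(nb, archetype_data(0.1, NA, 0.9), "s1")$raw_shift
  expect_lt(lof, 0)      # active regulators, silent targets
  expect_gt(gof, 0)      # the mirror image
  expect_lt(abs(lof + gof), 1e-9)   # exact antisymmetry under mirroring
})

test_that("raw shift is ipl_t - ipl_r with prior subtraction", {
  g <- archetype_pathway()
  nb <- extract_neighborhood(g, "F", 1)
  d <- archetype_data(0.85, 0.6, 0.15)
  res <- pshift(nb, d, c("s1", "s2"))
  expect_equal(res$raw_shift, res$ipl_t - res$ipl_r, tolerance = 1e-12)
  # both columns identical evidence -> identical scores
  expect_equal(res$raw_shift[1], res$raw_shift[2], tolerance = 1e-12)
})

test_that("an empty mode set yields NA scores with a warning", {
  g <- pathway_graph(
    data.frame(id = c("U", "f"), kind = "protein"),
    data.frame(source = "U", target = "f",
               edge_type = "protein-activation"))
  nb <- extract_neighborhood(g, "f", 1)
  d <- omics_dataset(matrix(runif(4), 2, 2,
                            dimnames = list(c("U", "f"), c("s1", "s2"))),
                     transformed = TRUE)
  expect_warning(res <- pshift(nb, d), "empty target set")
  expect_true(all(is.na(res$raw_shift)))
})

test_that("Z-normalization standardizes against its own background", {
  sim <- simulate_cohort(sim_config(n_genes = 1, n_samples = 50, seed = 8))
  data <- as_omics(sim)
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  raw <- pshift(nb, data)
  zz <- zscore_normalize(nb, data, raw, n_perm = 50, seed = 4)
  expect_equal(unname(zz$z),
               (raw$raw_shift - zz$mu) / zz$sigma, tolerance = 1e-12)
  expect_equal(mean(zz$bg_z), 0, tolerance = 1e-12)
  expect_equal(sd(zz$bg_z), 1, tolerance = 1e-12)
  expect_length(zz$bg_raw, 50)
  # reproducible given the seed
  zz2 <- zscore_normalize(nb, data, raw, n_perm = 50, seed = 4)
  expect_identical(zz$z, zz2$z)
  # Z is invariant to affine rescaling of raw scores (log-base changes)
  zz3 <- zscore_normalize(nb, data, raw, n_perm = 50, seed = 4)
  expect_equal((raw$raw_shift * 3 - zz3$mu * 3) / (zz3$sigma * 3),
               unname(zz3$z), tolerance = 1e-12)
})

test_that("under a null cohort the per-sample Z-scores are standardized", {
  sim <- simulate_cohort(sim_config(n_genes = 1, n_samples = 200,
                                    effect_size = 0, seed = 12))
  data <- as_omics(sim)
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  zz <- zscore_normalize(nb, data, pshift(nb, data), n_perm = 100,
                         seed = 13)
  expect_lt(abs(mean(zz$z)), 0.15)
  expect_lt(abs(sd(zz$z) - 1), 0.2)
})

test_that("classify applies empirical background quantiles per tail", {
  set.seed(6)
  bg <- rnorm(500)
  expect_equal(classify(0, bg, alpha = 0.10, sided = "two"), "neutral")
  expect_equal(classify(-3, bg, alpha = 0.10, sided = "one",
                        direction = "lower"), "LOF")
  expect_equal(classify(3, bg, alpha = 0.10, sided = "one",
                        direction = "upper"), "GOF")
  # one-sided lower never calls GOF however extreme
  expect_equal(classify(5, bg, alpha = 0.10, sided = "one",
                        direction = "lower"), "neutral")
  # a value at the 96th percentile is GOF at two-sided alpha = 0.10
  z96 <- quantile(bg, 0.96)
  expect_equal(classify(z96, bg, alpha = 0.10, sided = "two"), "GOF")
  # but neutral at two-sided alpha = 0.05 (cut at 97.5%)
  expect_equal(classify(z96, bg, alpha = 0.05, sided = "two"), "neutral")
  expect_equal(classify(c(NA, 0), bg, 0.1), c(NA, "neutral"))
  # empirical FPR over the background itself is ~ alpha
  expect_equal(mean(classify(bg, bg, 0.10, "one", "lower") == "LOF"),
               0.10, tolerance = 0.02)
})

test_that("t_min = 0 keeps every neighbor and reproduces plain shifts", {
  sim <- simulate_cohort(sim_config(n_genes = 1, planted = "LOF",
                                    n_samples = 60, n_mut_per_gene = 15,
                                    seed = 31))
  data <- as_omics(sim)
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  sel <- supervised_select(nb, data, folds = 5, t_min = 0, seed = 9,
                           n_perm = 20)
  expect_length(sel$folds, 5)
  plain <- pshift(nb, data)
  for (f in sel$folds) {
    expect_setequal(f$kept, c(nb$regulators, nb$targets))
    expect_equal(f$scores$raw_shift,
                 plain$raw_shift[match(f$scores$sample, plain$sample)],
                 tolerance = 1e-8)
  }
  # folds are disjoint and cover all samples
  held <- unlist(lapply(sel$folds, `[[`, "test_samples"))
  expect_setequal(held, data$sample_ids)
  expect_equal(anyDuplicated(held), 0)
})

test_that("discriminative neighbors are kept, irrelevant ones drop out", {
  # planted LOF at effect 2 SD: targets track mutation status strongly
  sim <- simulate_cohort(sim_config(n_genes = 1, planted = "LOF",
                                    n_samples = 100, n_mut_per_gene = 25,
                                    seed = 33))
  data <- as_omics(sim)
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  # regulators are mutation-independent under a LOF plant, so some folds
  # legitimately warn that selection emptied the regulator set
  sel <- suppressWarnings(
    supervised_select(nb, data, folds = 5, t_min = 1, seed = 10,
                      n_perm = 20))
  kept_targets <- vapply(sel$folds, function(f)
    all(c("FG001_T1", "FG001_T2") %in% f$kept), logical(1))
  expect_true(all(kept_targets))
  # a decoy neighbor with mutation-independent expression is retained in
  # fewer than half of the folds on average (|t| >= 1 by chance only)
  set.seed(77)
  reps <- vapply(1:25, function(r) {
    mutv <- rep(FALSE, 100)
    mutv[sample(100, 25)] <- TRUE
    x <- matrix(rnorm(100), 1)
    abs(pshift:::row_tstat(x, mutv)) >= 1
  }, logical(1))
  expect_lt(mean(reps), 0.5)
})

test_that("degenerate training folds are skipped with a warning", {
  sim <- simulate_cohort(sim_config(n_genes = 1, n_samples = 20,
                                    n_mut_per_gene = 2, seed = 44))
  data <- as_omics(sim)
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  w <- capture_warnings(supervised_select(nb, data, folds = 5, t_min = 0,
                                          seed = 2, n_perm = 10))
  expect_true(any(grepl("fewer than 2", w)))
})
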