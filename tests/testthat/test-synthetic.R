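test_that("the generator is deterministic and conserves depth", {
  cfg <- simulation_config(n_samples = 20, n_genera = 15, depth = 500,
                           seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$abundance), unclass(b$abundance))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$brain, b$brain)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_true(all(rowSums(unclass(a$abundance)) == 500))
  expect_true(all(c(1L, 2L) %in% a$truth$latent_label))
  expect_setequal(a$truth$opposite_pair, a$truth$planted_signature[1:2])
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(mixing_proportion = 1), "mixing_proportion")
  expect_error(simulation_config(n_signature = 80), "n_signature")
  expect_error(simulation_config(log_effect = -1), "log_effect")
})

test_that("null cohorts have zero planted effects and conserved depth", {
  co <- null_cohort(simulation_config(n_samples = 16, n_genera = 12,
                                      depth = 300, seed = 5))
  expect_true(all(co$truth$effects == 0))
  expect_true(all(rowSums(unclass(co$abundance)) == 300))
  expect_equal(co$config$cars_shift, 0)
  expect_equal(co$truth$brain$slope, 0)
})

test_that("planted effects point the right way at strong signal", {
  # scaled-down Monte Carlo of the generator contract: with delta = 3 and
  # n = 200, each signature genus should be more abundant (relative) in
  # its favored subpopulation; checked over 20 seeds instead of 100 to
  # stay inside the test-time budget
  frac_ok <- vapply(1:20, function(s) {
    co <- simulate_cohort(simulation_config(n_samples = 200, log_effect = 3,
                                            seed = 100 + s))
    rel <- unclass(to_relative(co$abundance))
    lab <- co$truth$latent_label[rownames(rel)]
    eff <- co$truth$effects[co$truth$planted_signature]
    ok <- vapply(names(eff), function(g) {
      diff <- mean(rel[lab == 2, g]) - mean(rel[lab == 1, g])
      sign(diff) == sign(eff[g])
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(frac_ok), 0.95)
})

test_that("subpopulation 1 is the more even community", {
  co <- simulate_cohort(simulation_config(n_samples = 300, seed = 21))
  a <- alpha_diversity(co$abundance)
  ev <- tapply(a$pielou, co$truth$latent_label[a$sample_id], mean)
  expect_gt(ev[["1"]], ev[["2"]])
})

test_that("CARS totals and severity shift upward in subpopulation 2", {
  co <- simulate_cohort(simulation_config(n_samples = 300, seed = 22))
  md <- co$metadata
  lab <- co$truth$latent_label[md$sample_id]
  expect_gt(mean(md$cars_total[lab == 2]), mean(md$cars_total[lab == 1]))
  expect_equal(md$cars_total, rowSums(md[, paste0("cars", 1:15)]))
})

test_that("cluster recovery improves with effect size (monotone on average)", {
  # 3-point effect grid, 6 seeds each (scaled down from the 20-seed
  # contract for runtime); ARI of signature-based clustering vs truth
  grid <- c(0, 0.75, 1.5)
  mean_ari <- vapply(grid, function(delta) {
    mean(vapply(1:6, function(s) {
      co <- simulate_cohort(simulation_config(n_samples = 60, n_genera = 30,
                                              log_effect = delta,
                                              depth = 5000, seed = 200 + s))
      asg <- cluster_subtypes(co$abundance, co$truth$planted_signature,
                              co$metadata)
      adjusted_rand_index(asg$labels, co$truth$latent_label)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) > 0))
  expect_lt(abs(mean_ari[1]), 0.15)  # exchangeable groups: ARI near 0
})

test_that("reusing truth yields a held-out cohort from the same population", {
  co <- simulate_cohort(simulation_config(n_samples = 30, seed = 31))
  te <- simulate_cohort(simulation_config(n_samples = 20, seed = 32),
                        truth = co$truth, sample_prefix = "T")
  expect_identical(te$truth$planted_signature, co$truth$planted_signature)
  expect_identical(te$truth$effects, co$truth$effects)
  expect_false(any(rownames(te$abundance) %in% rownames(co$abundance)))
})

test_that("write_cohort emits the full artifact set readably", {
  co <- simulate_cohort(simulation_config(n_samples = 10, n_genera = 8,
                                          n_signature = 4, depth = 200,
                                          seed = 41))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_abundance_table(paths["abundance"])
  expect_equal(unclass(back), unclass(co$abundance), ignore_attr = TRUE)
  md <- read_metadata(paths["metadata"])
  expect_equal(md$cars_total, co$metadata$cars_total)
  tree <- read_newick(paths["tree"])
  expect_setequal(tree$tip.label, colnames(co$abundance))
})
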