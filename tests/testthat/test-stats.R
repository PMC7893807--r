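test_that("kruskal-wallis H matches hand and reference computation", {
  res <- kruskal_wallis_perm(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                             B = 500, seed = 2)
  expect_equal(res$statistic, 3.857, tolerance = 1e-3)
  ref <- kruskal.test(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3)))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  # tie correction agrees with the reference implementation
  set.seed(7)
  x <- sample(rep(1:5, 4)); g <- rep(c("a", "b", "c"), length.out = 20)
  res2 <- kruskal_wallis_perm(x, g, B = 100, seed = 3)
  ref2 <- kruskal.test(x, factor(g))
  expect_equal(res2$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(res2$p_asymptotic, ref2$p.value, tolerance = 1e-12)

  degen <- kruskal_wallis_perm(rep(2, 8), rep(c("a", "b"), 4), B = 100,
                               seed = 1)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_perm, 1)
})

test_that("permutation p-values honor the add-one floor and reproduce", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- rep(c("lo", "hi"), each = 4)
  r1 <- kruskal_wallis_perm(x, g, B = 199, seed = 77)
  r2 <- kruskal_wallis_perm(x, g, B = 199, seed = 77)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 200)
  expect_error(kruskal_wallis_perm(1:4, rep("a", 4)), "2 groups")
})

test_that("spearman rho matches the reference and flags degeneracy", {
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  res <- spearman_perm(x, y, B = 200, seed = 5)
  expect_equal(res$statistic, cor(x, y, method = "spearman"),
               tolerance = 1e-12)

  perfect <- spearman_perm(1:10, 1:10, B = 400, seed = 6)
  expect_equal(perfect$statistic, 1)
  expect_equal(perfect$p_perm, 1 / 401)

  const <- spearman_perm(rep(1, 6), 1:6, B = 100, seed = 1)
  expect_equal(const$statistic, 0)
  expect_true(const$degenerate)
})

test_that("odds ratio reproduces the printed severity contrast", {
  ct <- contingency_2x2(13, 19, 14, 4)
  res <- odds_ratio(ct)
  expect_equal(res$odds_ratio, 52 / 266, tolerance = 1e-12)
  expect_equal(round(res$odds_ratio, 1), 0.2)
  expect_false(res$corrected)

  expect_equal(odds_ratio(contingency_2x2(5, 5, 5, 5))$odds_ratio, 1)

  zero <- odds_ratio(contingency_2x2(10, 0, 0, 10))
  expect_true(zero$corrected)
  expect_equal(zero$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("fisher exact p matches exhaustive hypergeometric enumeration", {
  for (a in 0:4) for (b in 0:4) for (c in 0:3) for (d in 0:3) {
    if ((a + b == 0 && c + d == 0) || (a + c == 0 && b + d == 0)) next
    m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    if (sum(m) == 0 || sum(m) > 12) next
    ct <- contingency_2x2(a, b, c, d)
    expect_equal(odds_ratio(ct)$fisher_p, brute_fisher(m), tolerance = 1e-9,
                 label = paste(a, b, c, d))
  }
})

test_that("chi-square closed form and yates inequality hold", {
  res <- chi_square(contingency_2x2(13, 19, 14, 4))
  expect_equal(res$statistic, 6.40, tolerance = 5e-3)
  ref <- suppressWarnings(
    chisq.test(matrix(c(13, 19, 14, 4), 2, 2, byrow = TRUE),
               correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  expect_equal(chi_square(contingency_2x2(5, 5, 5, 5))$statistic, 0)

  set.seed(12)
  for (i in 1:20) {
    cells <- rpois(4, 6) + 1
    ct <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_lte(chi_square(ct, yates = TRUE)$statistic,
               chi_square(ct)$statistic + 1e-12)
  }
  expect_error(chi_square(contingency_2x2(0, 0, 3, 4)), "margin")
})

test_that("benjamini-hochberg adjustment is the step-up procedure", {
  expect_equal(bh_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(2)
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("the dominance-flip test detects the planted opposite pair", {
  rejected <- vapply(1:10, function(s) {
    co <- simulate_cohort(simulation_config(n_samples = 60, log_effect = 2.5,
                                            seed = 300 + s))
    truth_lab <- ifelse(co$truth$latent_label == 1, "mp1", "mp2")
    res <- opposite_pattern_test(co$abundance,
                                 co$truth$opposite_pair["a"],
                                 co$truth$opposite_pair["b"], truth_lab)
    res$test$p_asymptotic < 0.01
  }, logical(1))
  expect_gte(mean(rejected), 0.9)

  co <- simulate_cohort(simulation_config(n_samples = 20, seed = 50))
  lab <- ifelse(co$truth$latent_label == 1, "mp1", "mp2")
  g <- co$truth$opposite_pair["a"]
  expect_error(opposite_pattern_test(co$abundance, g, g, lab), "margin")
  expect_error(opposite_pattern_test(co$abundance, "NoSuchGenus", g, lab),
               "missing")
})

test_that("group_profile reruns bit-identically and reports all families", {
  co <- simulate_cohort(simulation_config(n_samples = 30, seed = 60,
                                          n_regions = 4,
                                          n_linked_regions = 2))
  lab <- setNames(ifelse(co$truth$latent_label == 1, "mp1", "mp2"),
                  names(co$truth$latent_label))
  p1 <- group_profile(co$metadata, lab, brain = co$brain, B = 200, seed = 8)
  p2 <- group_profile(co$metadata, lab, brain = co$brain, B = 200, seed = 8)
  expect_identical(p1, p2)
  expect_named(p1$clinical,
               c("cars_total", "ados_total", "items_ge3",
                 "social_impairment", "negative_emotionality",
                 "distorted_sensory_response"))
  expect_equal(length(p1$brain$regions), 4)
  expect_true(all(vapply(p1$brain$regions, function(t) t$p_bh >= t$p_perm,
                         logical(1))))
})
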