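test_that("well-separated blocks are recovered exactly and labelled by severity", {
  md <- made_metadata(c(rep(25, 5), rep(45, 5)))
  set.seed(4)
  m <- rbind(matrix(rpois(5 * 4, c(100, 100, 5, 5)), 5, 4, byrow = TRUE),
             matrix(rpois(5 * 4, c(5, 5, 100, 100)), 5, 4, byrow = TRUE))
  tab <- tiny_table(m, samples = md$sample_id)
  asg <- cluster_subtypes(tab, colnames(tab), md)
  truth <- rep(c(1, 2), each = 5)
  expect_equal(adjusted_rand_index(asg$labels, truth), 1)
  lab <- asg$labels[md$sample_id]
  expect_lt(mean(md$cars_total[lab == "mp1"]),
            mean(md$cars_total[lab == "mp2"]))
})

test_that("average linkage agrees with a brute-force oracle at n = 4..6", {
  set.seed(10)
  for (n in 4:6) for (rep in 1:5) {
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    oracle <- brute_upgma(d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-12)
    part <- cutree(hc, k = 2)
    expect_equal(adjusted_rand_index(part, oracle$partition), 1)
  }
})

test_that("merge heights are monotone and assignment is order-invariant", {
  co <- simulate_cohort(simulation_config(n_samples = 24, n_genera = 16,
                                          n_signature = 6, depth = 3000,
                                          seed = 81))
  sig <- co$truth$planted_signature
  asg <- cluster_subtypes(co$abundance, sig, co$metadata)
  expect_true(all(diff(asg$hclust$height) >= -1e-12))

  perm <- withr::with_seed(2, sample(nrow(co$abundance)))
  shuffled <- abundance_table(unclass(co$abundance)[perm, ], mode = "counts")
  asg2 <- cluster_subtypes(shuffled, sig, co$metadata)
  expect_identical(asg$labels[sort(names(asg$labels))],
                   asg2$labels[sort(names(asg2$labels))])

  # genus order cannot matter either
  asg3 <- cluster_subtypes(co$abundance, rev(sig), co$metadata)
  expect_identical(asg$labels, asg3$labels)

  flat <- tiny_table(matrix(5, 4, 3))
  md <- made_metadata(c(20, 25, 40, 45))
  expect_error(cluster_subtypes(flat, colnames(flat), md), "degenerate")
})

test_that("kNN prediction matches identity and brute-force enumeration", {
  md <- made_metadata(c(rep(20, 5), rep(45, 5)))
  set.seed(6)
  m <- rbind(matrix(rpois(5 * 4, c(80, 80, 5, 5)), 5, 4, byrow = TRUE),
             matrix(rpois(5 * 4, c(5, 5, 80, 80)), 5, 4, byrow = TRUE)) + 1
  tab <- tiny_table(m, samples = md$sample_id)
  labels <- setNames(rep(c("mp1", "mp2"), each = 5), md$sample_id)
  model <- fit_knn(tab, colnames(tab), labels, k = 1)
  expect_identical(predict(model, tab), labels)
  expect_error(fit_knn(tab, colnames(tab), labels, k = 4), "odd")
  expect_error(fit_knn(tab, colnames(tab), labels, k = 11), "training")

  # 50 random 10-point configurations vs the brute-force oracle
  set.seed(33)
  for (rep in 1:50) {
    train <- matrix(runif(10 * 3, 0.05, 1), 10, 3)
    train <- train / rowSums(train)
    rownames(train) <- paste0("t", 1:10)
    colnames(train) <- paste0("g", 1:3)
    lab <- setNames(sample(c("mp1", "mp2"), 10, replace = TRUE),
                    rownames(train))
    if (length(unique(lab)) < 2) next
    k <- sample(c(1, 3, 5), 1)
    mod <- structure(list(train = train, labels = lab, k = k,
                          distance = "bray_curtis",
                          signature = colnames(train)),
                     class = "knn_model")
    q <- runif(3, 0.05, 1); q <- q / sum(q)
    expect_identical(unname(predict(mod, rbind(q = q))),
                     brute_knn(q, train, lab, k, distance = "bray_curtis"))
  }
})

test_that("LOOCV is perfect on separated blobs and duplicated points", {
  md <- made_metadata(c(rep(20, 6), rep(45, 6)))
  m <- rbind(matrix(rep(c(90, 90, 2, 2), 6), 6, 4, byrow = TRUE),
             matrix(rep(c(2, 2, 90, 90), 6), 6, 4, byrow = TRUE))
  m <- m + matrix(rpois(48, 2), 12, 4)
  tab <- tiny_table(m, samples = md$sample_id)
  labels <- setNames(rep(c("mp1", "mp2"), each = 6), md$sample_id)
  expect_equal(loocv_accuracy(tab, colnames(tab), labels, k = 3)$accuracy, 1)

  dup <- tiny_table(rbind(c(10, 1), c(10, 1), c(1, 10), c(1, 10)))
  dlab <- setNames(c("mp1", "mp1", "mp2", "mp2"), rownames(dup))
  expect_equal(loocv_accuracy(dup, colnames(dup), dlab, k = 1)$accuracy, 1)
})

test_that("null-cohort LOOCV accuracy tracks the majority proportion", {
  acc <- vapply(1:8, function(s) {
    co <- null_cohort(simulation_config(n_samples = 40, n_genera = 20,
                                        n_signature = 4, depth = 3000,
                                        seed = 500 + s))
    lab <- setNames(ifelse(co$truth$latent_label == 1, "mp1", "mp2"),
                    names(co$truth$latent_label))
    loocv_accuracy(co$abundance, co$truth$planted_signature, lab,
                   k = 3)$accuracy
  }, numeric(1))
  # labels carry no signal: accuracy about the majority share (0.6),
  # certainly far from the separable-case 1.0
  expect_lt(mean(acc), 0.75)
  expect_gt(mean(acc), 0.35)
})

test_that("kNN models round trip through their text serialization", {
  co <- simulate_cohort(simulation_config(n_samples = 20, n_genera = 12,
                                          n_signature = 4, depth = 2000,
                                          seed = 91))
  lab <- setNames(ifelse(co$truth$latent_label == 1, "mp1", "mp2"),
                  names(co$truth$latent_label))
  model <- fit_knn(co$abundance, co$truth$planted_signature, lab, k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_knn_model(model, path)
  back <- read_knn_model(path)
  expect_equal(back$train, model$train, tolerance = 1e-12)
  expect_identical(predict(back, co$abundance), predict(model, co$abundance))
})
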