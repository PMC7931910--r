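test_that("cPAT assignment applies the z-score over-expression criterion", {
  # all z-scores <= 0: pattern is empty
  p <- rbind(A = c(1, 1, 1, 1), B = c(2, 2, 2, 2))
  cp <- assign_cpats(make_spot_set(p))
  expect_equal(cp$cpat, rep("", 4))

  # one clearly over-expressed spot: singleton pattern
  p2 <- rbind(A = c(0, 0, 0, 0, 0, 10), B = c(1, 1, 1, 1, 1, 1))
  cp2 <- assign_cpats(make_spot_set(p2))
  expect_equal(cp2$cpat, c(rep("", 5), "A"))

  # counting is order-invariant and counts sum to n_samples
  tab <- enumerate_cpats(cp2, min_count = 2)
  expect_equal(sum(tab$n), 6)
  expect_equal(tab$major, c(TRUE, FALSE))
})

test_that("modal cPATs recover the planted subtype combinations", {
  an <- default_analysis()
  mm <- an$matching
  truth <- an$cohort$truth
  boosts <- truth$config$subtype_boosts
  spot_of_module <- stats::setNames(mm$spot_id, mm$module)
  ok <- 0L; total <- 0L
  for (st in names(boosts)) {
    spots_expected <- sort(spot_of_module[as.character(boosts[[st]])])
    if (anyNA(spots_expected)) next
    expected <- paste(sort(spots_expected), collapse = "+")
    ids <- truth$sample_type$sample_id[truth$sample_type$subtype == st]
    pats <- an$cpats$cpat[match(ids, an$cpats$sample_id)]
    modal <- names(sort(table(pats), decreasing = TRUE))[1]
    total <- total + 1L
    if (modal == expected) ok <- ok + 1L
  }
  expect_gte(total, 7L)
  expect_gte(ok / total, 0.8)
})

test_that("the type-count estimate finds constructed and planted group counts", {
  # two well-separated centroid groups -> k = 2
  set.seed(20)
  K <- 16
  cb <- matrix(0, K, 40)
  cb[, 1:20] <- 5    # group 1 samples high everywhere
  cb[, 21:40] <- -5
  cb <- cb + matrix(rnorm(K * 40, sd = 0.1), K, 40)
  m <- make_model(cb, 4, 4)
  cpats <- tibble::tibble(
    sample_id = m$sample_ids,
    cpat = rep(c("A", "A+B", "C", "C+D"), each = 10)
  )
  expect_equal(as.integer(estimate_type_count(m, cpats, min_count = 5)), 2L)

  # identical centroids -> forced lower bound with a warning
  cb2 <- matrix(1, K, 40)
  m2 <- make_model(cb2, 4, 4)
  expect_warning(k2 <- estimate_type_count(m2, cpats, min_count = 5),
                 "degenerate|forced")
  expect_equal(as.integer(k2), 2L)

  # single major pattern -> k = 1 with a warning
  cpats1 <- tibble::tibble(sample_id = m$sample_ids, cpat = "A")
  expect_warning(k1 <- estimate_type_count(m, cpats1), "single")
  expect_equal(as.integer(k1), 1L)

  # planted count on the default cohort, across seeds
  runs <- multi_seed_runs()
  ks <- vapply(runs, `[[`, 1L, "k")
  expect_equal(stats::median(ks), 3)
})

test_that("K-means stratification splits clouds and is seed-deterministic", {
  set.seed(21)
  cb <- cbind(matrix(4, 9, 15), matrix(-4, 9, 15)) +
    matrix(rnorm(9 * 30, sd = 0.2), 9, 30)
  m <- make_model(cb, 3, 3)
  a1 <- cluster_types(m, k = 2, n_subtypes = 1, seed = 5)
  a2 <- cluster_types(m, k = 2, n_subtypes = 1, seed = 5)
  expect_identical(a1, a2)
  expect_equal(adjusted_rand_index(a1$type, rep(c("x", "y"), each = 15)), 1)
  expect_error(cluster_types(m, k = 50), "exceeds")

  # relabeling rule: "1" anchors to the lowest reference-spot expression
  expect_setequal(unique(a1$type), c("1", "2"))
})

test_that("types and subtypes recover the planted stratification", {
  runs <- multi_seed_runs()
  aris <- vapply(runs, `[[`, 1, "ari_type")
  expect_gte(stats::median(aris), 0.9)
  subaris <- vapply(runs, `[[`, 1, "ari_subtype")
  expect_gte(stats::median(subaris), 0.7)
  # every sample labeled; subtype prefixes equal their type
  asg <- runs[[1]]$assignment
  expect_equal(nrow(asg), 300)
  expect_true(all(startsWith(asg$subtype, paste0(asg$type, "."))))
  expect_equal(glance(asg)$n_subtypes, 9)
})

test_that("pairwise portrait correlations behave at the extremes", {
  cb <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), d = c(-1, -2, -3, -4),
              z = rep(1, 4))
  m <- make_model(cb, 2, 2, sample_ids = c("a", "b", "d", "z"))
  R <- pairwise_correlation(m)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "d"], -1)
  expect_equal(R["a", "z"], 0)  # zero-variance portrait

  an <- default_analysis()
  R2 <- pairwise_correlation(an$model)
  tt <- an$cohort$truth$sample_type
  t1 <- tt$sample_id[tt$type == "1"]; t2 <- tt$sample_id[tt$type == "2"]
  expect_lt(mean(R2[t1, t2]), 0)
})

test_that("holdout validation separates real structure from shuffled labels", {
  set.seed(22)
  cb <- cbind(matrix(4, 9, 30), matrix(-4, 9, 30)) +
    matrix(rnorm(9 * 60, sd = 0.2), 9, 60)
  m <- make_model(cb, 3, 3)
  labels <- rep(c("1", "2"), each = 30)
  expect_equal(as.numeric(validate_types(m, labels, seed = 1)), 0)

  shuffled <- sample(labels)
  r <- as.numeric(validate_types(m, shuffled, n_rounds = 20, seed = 2))
  expect_gt(r, 0.3)
  expect_lt(r, 0.7)

  # recovered types on the default cohort reclassify within 10%
  runs <- multi_seed_runs()
  mis <- as.numeric(validate_types(runs[[1]]$model, runs[[1]]$assignment,
                                   seed = 1))
  expect_lte(mis, 0.10)
})

test_that("the adjusted Rand index matches its closed form on small cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "b", "a", "b")),
               -0.5)
  expect_equal(adjusted_rand_index(rep(1, 4), rep(1, 4)), 1)
})
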