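test_that("noise-free generation is deterministic and degenerate as expected", {
  cfg <- cohort_config(n_genes = 20, n_samples = 10, n_modules = 1,
                       module_size = 5, n_types = 1,
                       n_subtypes_per_type = 1, noise_sd = 0,
                       phenotype_effects = NULL, seed = 7)
  cohort <- generate_cohort(cfg)
  mod_rows <- cohort$expression[1:5, ]
  # identical activation, zero noise: the five module rows are one vector
  expect_true(all(apply(mod_rows, 2, function(col) diff(range(col)) == 0)))
  # background rows are exactly zero
  expect_true(all(cohort$expression[6:20, ] == 0))
})

test_that("generation is bit-identical under a repeated seed", {
  a <- generate_cohort(cohort_config(n_genes = 300, n_samples = 40,
                                     n_modules = 4, module_size = 10,
                                     seed = 42))
  b <- generate_cohort(cohort_config(n_genes = 300, n_samples = 40,
                                     n_modules = 4, module_size = 10,
                                     seed = 42))
  expect_identical(a$expression, b$expression)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$module_activation, b$truth$module_activation)
})

test_that("module overflow and malformed configs are rejected", {
  expect_error(cohort_config(n_genes = 100, n_modules = 5, module_size = 30),
               "config error")
  expect_error(cohort_config(n_types = 0), "config error")
  bad_act <- matrix(rep(1:13, each = 3), 3, 13)  # extreme rows correlated
  expect_error(cohort_config(activation_matrix = bad_act),
               "anti-correlated")
})

test_that("planted correlation structure matches the variance decomposition", {
  # oracle: var(signal) / (var(signal) + noise^2); with the default
  # activation geometry within-module correlation must average >= 0.8 and
  # genes of opposite extreme-type modules <= -0.3 (5 seeds)
  within <- cross <- c()
  for (seed in 1:5) {
    cohort <- generate_cohort(cohort_config(seed = seed))
    E <- cohort$expression
    gm <- cohort$truth$gene_module
    for (m in 1:12) {
      g <- which(!is.na(gm$module) & gm$module == m)[1:4]
      within <- c(within, stats::cor(t(E[g, ]))[upper.tri(diag(4))])
    }
    lo <- which(!is.na(gm$module) & gm$module <= 6)
    hi <- which(!is.na(gm$module) & gm$module %in% 7:12)
    set.seed(seed)
    cross <- c(cross, vapply(1:40, function(i) {
      stats::cor(E[sample(lo, 1), ], E[sample(hi, 1), ])
    }, 1))
  }
  expect_gte(mean(within), 0.8)
  expect_lte(mean(cross), -0.3)
})

test_that("labels balance and the noise-free rank equals the activation rank", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  counts <- table(cohort$truth$sample_type$subtype)
  expect_length(counts, 9)
  expect_true(max(counts) - min(counts) <= 1)

  cfg <- cohort_config(n_genes = 600, n_samples = 60, n_modules = 6,
                       module_size = 20, noise_sd = 0,
                       phenotype_effects = NULL, seed = 2)
  cohort0 <- generate_cohort(cfg)
  r_expr <- qr(cohort0$expression)$rank
  r_act <- qr(cohort0$truth$module_activation)$rank
  expect_equal(r_expr, r_act)
})

test_that("phenotype coupling imprints its sign on the realized activation", {
  pe <- tibble::tibble(phenotype = c("age", "bmi"), module = c(2L, 5L),
                       beta = c(1, -1))
  cohort <- generate_cohort(cohort_config(phenotype_effects = pe, seed = 11))
  A <- cohort$truth$module_activation
  expect_gt(stats::cor(cohort$phenotypes$age, A[, 2]), 0.7)
  expect_lt(stats::cor(cohort$phenotypes$bmi, A[, 5]), -0.7)
})

test_that("match_modules scores identity, unions and emptiness correctly", {
  cohort <- generate_cohort(cohort_config(n_genes = 300, n_samples = 30,
                                          n_modules = 4, module_size = 20,
                                          seed = 5))
  gm <- cohort$truth$gene_module
  planted <- lapply(1:4, function(m) gm$gene_id[!is.na(gm$module) & gm$module == m])
  names(planted) <- paste0("S", 1:4)

  mm <- match_modules(planted, cohort$truth)
  expect_equal(mm$jaccard, rep(1, 4))
  expect_equal(attr(mm, "n_unmatched_spots"), 0L)

  merged <- list(U = c(planted[[1]], planted[[2]]))
  mm2 <- match_modules(merged, cohort$truth)
  expect_equal(max(mm2$jaccard), 0.5)
  expect_equal(sum(mm2$jaccard > 0), 1)

  mm3 <- match_modules(list(), cohort$truth)
  expect_equal(mm3$jaccard, rep(0, 4))
  expect_equal(attr(mm3, "n_unmatched_modules"), 4L)
})

test_that("random equal-size sets score near the hypergeometric Jaccard", {
  # analytic oracle: E[J] = E[X / (2k - X)], X ~ Hypergeometric(N, k, k)
  N <- 2000; k <- 40
  xs <- 0:k
  px <- stats::dhyper(xs, k, N - k, k)
  expected_j <- sum(px * xs / (2 * k - xs))

  cohort <- generate_cohort(cohort_config(n_genes = N, n_samples = 10,
                                          n_modules = 1, module_size = k,
                                          n_types = 1,
                                          n_subtypes_per_type = 1,
                                          phenotype_effects = NULL,
                                          seed = 8))
  universe <- cohort$truth$gene_module$gene_id
  set.seed(99)
  scored <- replicate(200, {
    mm <- match_modules(list(R = sample(universe, k)), cohort$truth)
    mm$jaccard[1]
  })
  expect_equal(mean(scored), expected_j, tolerance = 0.3)
})
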