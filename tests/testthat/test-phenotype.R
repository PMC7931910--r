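test_that("correlation maps reproduce exact small-sample correlations", {
  cb <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 0, 0, 0), c(1, 1, 2, 2))
  m <- make_model(cb, 2, 2)
  ph <- tibble::tibble(sample_id = m$sample_ids,
                       f = c(1, 2, 3, 4),
                       b = c(0, 0, 1, 1))
  cm <- correlation_map(m, ph, "f")
  expect_equal(cm$grid[1, 1], 1)           # feature equals unit 1's profile
  expect_equal(cm$grid[1, 2], -1)
  expect_equal(cm$grid[2, 1], 0)           # zero-variance unit -> r = 0
  expect_equal(unname(cm$argmax), c(1, 1))

  # point-biserial on (1,2,3,4) vs (0,0,1,1): r = 2 / sqrt(5)
  cmb <- correlation_map(m, ph, "b")
  expect_equal(cmb$grid[1, 1], 2 / sqrt(5), tolerance = 1e-12)
})

test_that("binary maps equal Pearson-on-indicator to machine precision", {
  an <- default_analysis()
  ph <- an$cohort$phenotypes
  m_bin <- correlation_map(an$model, ph, "sex")
  ph2 <- ph
  ph2$sex_num <- as.numeric(ph$sex)
  m_num <- correlation_map(an$model, ph2, "sex_num")
  expect_equal(m_bin$grid, m_num$grid, tolerance = 1e-14)
})

test_that("correlation maps are affine-invariant and flip with negative scale", {
  an <- default_analysis()
  ph <- an$cohort$phenotypes
  base <- correlation_map(an$model, ph, "age")
  ph$age2 <- 3 * ph$age - 100
  ph$age3 <- -0.5 * ph$age
  expect_equal(correlation_map(an$model, ph, "age2")$grid, base$grid,
               tolerance = 1e-12)
  expect_equal(correlation_map(an$model, ph, "age3")$grid, -base$grid,
               tolerance = 1e-12)
  ph$flat <- 1
  expect_error(correlation_map(an$model, ph, "flat"), "zero variance")
})

test_that("categorical features expand one-vs-rest and drop missing pairwise", {
  an <- default_analysis()
  ph <- an$cohort$phenotypes
  ph$bmi_class <- cut(ph$bmi, c(-Inf, 25, 30, Inf),
                      labels = c("normal", "overweight", "obese"))
  maps <- correlation_map(an$model, ph, "bmi_class")
  expect_named(maps, c("normal", "overweight", "obese"),
               ignore.order = TRUE)
  expect_s3_class(maps$obese, "correlation_map")

  ph$age_miss <- ph$age
  ph$age_miss[1:25] <- NA
  cm <- correlation_map(an$model, ph, "age_miss")
  expect_equal(cm$n_used, 275)
  expect_true(all(abs(cm$grid) <= 1))
})

test_that("a strongly coupled phenotype peaks inside its module's spot", {
  pe <- tibble::tibble(phenotype = "age", module = 2L, beta = 0.2)
  cohort <- generate_cohort(cohort_config(phenotype_effects = pe, seed = 13))
  x <- preprocess_expression(cohort$expression)
  model <- train_som(x, 16, 16, epochs = 20, seed = 13)
  cm <- correlation_map(model, cohort$phenotypes, "age")
  peak_unit <- (cm$argmax["row"] - 1) * model$grid_cols + cm$argmax["col"]
  gm <- cohort$truth$gene_module
  mod2_units <- unique(model$gene_bmu[gm$gene_id[!is.na(gm$module) &
                                                   gm$module == 2]])
  # neighborhood smoothing can move the peak onto an adjacent geneless
  # unit; the peak must sit within one grid step of the module's units
  co <- tidy(model)
  peak_rc <- co[co$unit == peak_unit, c("row", "col")]
  mod_rc <- co[match(mod2_units, co$unit), c("row", "col")]
  cheb <- pmax(abs(mod_rc$row - peak_rc$row), abs(mod_rc$col - peak_rc$col))
  expect_lte(min(cheb), 1)
})

test_that("type enrichment flags planted associations and respects margins", {
  an <- default_analysis()
  truth <- an$cohort$truth$sample_type
  asg <- tibble::tibble(sample_id = truth$sample_id, type = truth$type)
  ph <- an$cohort$phenotypes

  res <- type_enrichment(asg, ph, "disease")
  expect_equal(sum(res$n_type[res$level == res$level[1]]), 300)
  hit <- res[res$type == "1" & res$level == "1", ]
  expect_equal(hit$direction, "enriched")
  expect_lt(hit$fdr, 0.05)

  # an extreme table: level present only inside one type
  ph$only1 <- as.integer(truth$type == "1")
  res2 <- type_enrichment(asg, ph, "only1")
  best <- res2[which.min(res2$p), ]
  expect_equal(best$type, "1")
  expect_equal(best$level, "1")

  expect_error(type_enrichment(asg, ph, "age_not_there"), "feature")
})

test_that("independent binary features yield calibrated enrichment p-values", {
  set.seed(33)
  n <- 400
  asg <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        type = sample(c("1", "M", "2"), n, replace = TRUE))
  ps <- replicate(60, {
    ph <- tibble::tibble(sample_id = asg$sample_id,
                         flag = stats::rbinom(n, 1, 0.4))
    res <- type_enrichment(asg, ph, "flag")
    res$p
  })
  frac_small <- mean(ps < 0.05)
  expect_lt(frac_small, 0.12)
  expect_gt(mean(ps), 0.35)
})

test_that("spot regression returns standardized effects with exact identities", {
  set.seed(34)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.8 * x1 + rnorm(n, sd = 0.3)
  prof <- rbind(S = y)
  colnames(prof) <- sprintf("s%d", 1:n)
  ss <- make_spot_set(prof)
  ph <- tibble::tibble(sample_id = colnames(prof), x1 = x1, x2 = x2)

  res <- spot_regression(ss, ph)
  b1 <- res[res$term == "x1", ]
  b2 <- res[res$term == "x2", ]
  expect_lt(b1$p, 1e-10)
  expect_gt(b2$p, 0.01)

  # single standardized predictor: beta equals the Pearson correlation
  res1 <- spot_regression(ss, ph, features = "x1")
  expect_equal(res1$beta_std, stats::cor(y, x1), tolerance = 1e-12)

  # collinear columns are dropped with a warning
  ph$x3 <- 2 * ph$x1
  expect_warning(res3 <- spot_regression(ss, ph), "collinear")
  expect_false("x3" %in% res3$term)
})

test_that("noise-free regression on an orthonormal design solves exactly", {
  n <- 64
  x1 <- rep(c(1, -1), n / 2)
  x2 <- rep(c(1, 1, -1, -1), n / 4)
  y <- 2 * x1 - 3 * x2
  prof <- rbind(S = y); colnames(prof) <- sprintf("s%d", 1:n)
  ph <- tibble::tibble(sample_id = colnames(prof), x1 = x1, x2 = x2)
  res <- suppressWarnings(spot_regression(make_spot_set(prof), ph))
  b <- stats::setNames(res$beta_std, res$term)
  expect_equal(unname(b["x1"]), 2 / stats::sd(y) * stats::sd(x1),
               tolerance = 1e-9)
  expect_equal(unname(b["x2"]), -3 / stats::sd(y) * stats::sd(x2),
               tolerance = 1e-9)
})

test_that("LOESS trends honor exactness, grouping and degenerate spans", {
  d <- tibble::tibble(x = seq(0, 10, length.out = 60), g = rep(c("f", "m"), 30))
  d$y_const <- 5
  tr <- loess_trend(d, "x", "y_const")
  expect_equal(tr$fitted, rep(5, 100), tolerance = 1e-9)

  d$y_lin <- 2 * d$x + 1
  tr2 <- loess_trend(d, "x", "y_lin", span = 0.4)
  expect_equal(tr2$fitted, 2 * tr2$x + 1, tolerance = 1e-6)

  # separate fits per group
  d$y_g <- ifelse(d$g == "f", d$x, -d$x)
  tr3 <- loess_trend(d, "x", "y_g", group = "g")
  expect_setequal(unique(tr3$group), c("f", "m"))
  f_curve <- tr3[tr3$group == "f", ]
  expect_equal(f_curve$fitted, f_curve$x, tolerance = 1e-6)

  # a planted turning point is localized within one grid step
  set.seed(35)
  xx <- seq(0, 10, length.out = 200)
  yy <- ifelse(xx < 6, xx, 12 - xx) + rnorm(200, sd = 0.05)
  tr4 <- loess_trend(tibble::tibble(x = xx, y = yy), "x", "y", span = 0.3)
  curv <- abs(diff(tr4$fitted, differences = 2))
  x_turn <- tr4$x[which.max(curv) + 1]
  expect_lt(abs(x_turn - 6), 2 * diff(tr4$x[1:2]) + 1e-9)

  expect_error(loess_trend(d[1:5, ], "x", "y_lin"), ">= 10")
  expect_warning(loess_trend(tibble::tibble(x = 1:12, y = rnorm(12)),
                             "x", "y", span = 0.1), "widened")
})
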