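test_that("fold assignment is balanced, covering and deterministic", {
  ids <- paste0("g", 1:10)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_equal(sort(as.integer(table(f))), rep(2L, 5))
  expect_setequal(names(f), ids)
  expect_identical(f, make_folds(ids, k = 5, seed = 3))

  f11 <- make_folds(paste0("g", 1:11), k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f11))), c(2L, 2L, 2L, 2L, 3L))
  expect_error(make_folds(ids[1:3], k = 5), "fewer ids")
})

test_that("predictive ability is Pearson correlation with its guards", {
  y <- c(a = 1, b = 2, c = 3)
  expect_equal(predictive_ability(y, y), 1)
  expect_equal(predictive_ability(y, rev(unname(y)) * 1), -1,
               tolerance = 1e-12)
  expect_equal(predictive_ability(c(1, 2, 3, 4), c(1, 1, 2, 2)),
               0.8944272, tolerance = 1e-6)
  expect_error(predictive_ability(y, c(a = 1, b = 1, c = 1)), "constant")
  # affine invariance with positive slope
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(predictive_ability(a, b),
               predictive_ability(2 * a + 3, 0.5 * b - 1))
})

test_that("prediction accuracy scales by sqrt(hc2) and flags values over 1", {
  expect_equal(as.numeric(prediction_accuracy(0.4, 0.25)), 0.8)
  expect_equal(as.numeric(prediction_accuracy(0.3, 1)), 0.3)
  p1 <- prediction_accuracy(0.36, 0.16)
  expect_equal(as.numeric(p1), 0.9)
  expect_false(attr(p1, "flagged"))
  p2 <- prediction_accuracy(0.5, 0.16)
  expect_equal(as.numeric(p2), 1.25)
  expect_true(attr(p2, "flagged"))
  # literal mode divides by hc2 itself
  expect_equal(as.numeric(prediction_accuracy(0.4, 0.25,
                                              sqrt_scaling = FALSE)), 1.6)
  expect_error(prediction_accuracy(0.4, 0), "positive")
})

test_that("cross-validation is deterministic, null-calibrated and h2-responsive", {
  set.seed(1)
  n <- 200; p <- 600
  m <- rand_markers(n, p, seed = 8)
  Xc <- sweep(m$dosages, 2, 2 * m$freqs)
  g <- as.numeric(scale(Xc[, 1:60] %*% rnorm(60)))
  noise <- rnorm(n)
  ids <- rownames(m$dosages)

  y0 <- setNames(rnorm(n), ids)           # h2 = 0
  cv0 <- cross_validate(y0, m, "GBLUP", k = 5, seed = 2)
  expect_lt(abs(cv0$pa), 2 / sqrt(n))

  y5 <- setNames(g + noise, ids)          # h2 = 0.5
  cv5 <- cross_validate(y5, m, "GBLUP", k = 5, seed = 2, hc2 = 0.5)
  expect_gt(cv5$pa, cv0$pa)
  expect_equal(as.numeric(cv5$pacc), cv5$pa / sqrt(0.5))

  cv5b <- cross_validate(y5, m, "GBLUP", k = 5, seed = 2, hc2 = 0.5)
  expect_identical(cv5$pa, cv5b$pa)
  expect_identical(cv5$folds, cv5b$folds)
})

test_that("true validation degenerates to the in-sample fit on identical trials", {
  set.seed(4)
  m <- rand_markers(60, 150, seed = 9)
  ids <- rownames(m$dosages)
  Xc <- sweep(m$dosages, 2, 2 * m$freqs)
  y <- setNames(as.numeric(scale(Xc[, 1:20] %*% rnorm(20))) + rnorm(60), ids)
  tv <- true_validate(y, y, m, "GBLUP")
  K <- bend_psd(grm_yang(m))
  fit <- fit_kernel_blup(y, K)
  expect_equal(tv$pa, cor(y, fit$gebv[ids]), tolerance = 1e-8)
})

test_that("selection efficiency reproduces forced examples and the null", {
  comp <- setNames(as.numeric(10:1), letters[1:10])
  expect_equal(selection_efficiency(comp, comp, 0.10), 100)
  expect_equal(selection_efficiency(comp, comp, 1), 100)

  inc <- comp; inc[["c"]] <- 99  # picks the individual with complete value 8
  expect_equal(selection_efficiency(inc, comp, 0.10),
               100 * (8 - 5.5) / (10 - 5.5), tolerance = 1e-10)

  # random rankings: expected efficiency ~ 0, and never above 100
  set.seed(7)
  effs <- replicate(1000, {
    r <- setNames(sample(10), names(comp))
    selection_efficiency(r, comp, 0.2)
  })
  expect_lt(abs(mean(effs)), 6)       # MC error of the permutation mean
  expect_true(all(effs <= 100 + 1e-9))
})

test_that("method means exclude PBLUP and average per-trait means overall", {
  tab <- .rbindlist <- rbind(
    data.frame(trait = "t1", method = c("GBLUP", "BayesB", "BayesC",
                                        "BRR", "BL", "RKHS", "PBLUP"),
               value = c(0.6, 0.7, 0.65, 0.6, 0.55, 0.6, 0.4)),
    data.frame(trait = "t2", method = c("GBLUP", "BayesB", "BayesC",
                                        "BRR", "BL", "RKHS", "PBLUP"),
               value = c(0.3, 0.4, 0.35, 0.3, 0.25, 0.3, 0.2)))
  s <- methods_summary_table(tab)
  expect_equal(s$per_trait$mean,
               c(mean(c(0.6, 0.7, 0.65, 0.6, 0.55, 0.6)),
                 mean(c(0.3, 0.4, 0.35, 0.3, 0.25, 0.3))))
  expect_equal(s$overall, mean(s$per_trait$mean))
  expect_equal(s$pblup_mean, 0.3)
  expect_length(s$missing, 0)

  # single-method table: mean column equals that method's column
  one <- data.frame(trait = c("t1", "t2"), method = "GBLUP",
                    value = c(0.5, 0.7))
  s1 <- methods_summary_table(one)
  expect_equal(s1$per_trait$mean, c(0.5, 0.7))
  expect_equal(length(s1$missing), 10)  # five absent methods per trait
})
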