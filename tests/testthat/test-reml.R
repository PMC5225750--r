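test_that("REML equals the balanced one-way ANOVA decomposition", {
  # groups {1,2} and {3,4}: MSB = 4, MSW = 0.5 -> sigma_g = 1.75, sigma_e = 0.5
  y <- c(1, 2, 3, 4)
  g <- factor(c("a", "a", "b", "b"))
  fit <- reml_fit(y, matrix(1, 4, 1),
                  list(group = list(Z = clonalGS:::incidence(g))),
                  tol_loglik = 1e-12, tol_comp = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$sigma2[["group"]], 1.75, tolerance = 1e-8)
  expect_equal(fit$sigma2[["residual"]], 0.5, tolerance = 1e-8)

  # larger balanced design against the closed-form ANOVA estimator
  set.seed(5)
  ng <- 30; r <- 4
  u <- rnorm(ng, 0, sqrt(2))
  gg <- factor(rep(seq_len(ng), each = r))
  yy <- 3 + u[as.integer(gg)] + rnorm(ng * r)
  msb <- r * var(tapply(yy, gg, mean))
  msw <- sum((yy - ave(yy, gg))^2) / (ng * (r - 1))
  fit2 <- reml_fit(yy, matrix(1, length(yy), 1),
                   list(group = list(Z = clonalGS:::incidence(gg))),
                   tol_loglik = 1e-12, tol_comp = 1e-10)
  expect_equal(fit2$sigma2[["group"]], (msb - msw) / r, tolerance = 1e-8)
  expect_equal(fit2$sigma2[["residual"]], msw, tolerance = 1e-8)
})

test_that("an additive term with identity covariance collapses to one-way ANOVA", {
  set.seed(8)
  g <- factor(rep(1:20, each = 3))
  y <- rnorm(20, 0, 1.2)[as.integer(g)] + rnorm(60, 0, 0.7)
  Z <- clonalGS:::incidence(g)
  plain <- reml_fit(y, matrix(1, 60, 1), list(a = list(Z = Z)))
  withG <- reml_fit(y, matrix(1, 60, 1),
                    list(a = list(Z = Z, G = diag(20))))
  expect_equal(plain$sigma2, withG$sigma2, tolerance = 1e-6)
  expect_equal(plain$loglik, withG$loglik, tolerance = 1e-6)
})

test_that("REML is invariant to the fixed-effect constraint choice", {
  set.seed(9)
  rep_f <- factor(rep(1:3, times = 20))
  g <- factor(rep(1:20, each = 3))
  y <- rnorm(3)[as.integer(rep_f)] + rnorm(20, 0, 1)[as.integer(g)] +
    rnorm(60, 0, 0.5)
  Z <- clonalGS:::incidence(g)
  Xref <- cbind(1, clonalGS:::incidence(rep_f)[, -1])       # reference level
  C <- contr.sum(3)
  Xsum <- cbind(1, clonalGS:::incidence(rep_f) %*% C)        # sum-to-zero
  f1 <- reml_fit(y, Xref, list(a = list(Z = Z)))
  f2 <- reml_fit(y, Xsum, list(a = list(Z = Z)))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
})

test_that("variance components of the clonal-trial model are recovered", {
  # all variance fractions equal, moderate size, fixed seed: estimates
  # within 3 AI standard errors of the truth
  set.seed(21)
  ng <- 180; r <- 3
  gen <- factor(rep(seq_len(ng), each = r))
  bed <- factor(rep(rep(1:9, length.out = ng), each = r) * 10 +
                  rep(1:r, times = ng))  # bed nested in rep
  u_g <- rnorm(ng, 0, 1); u_b <- rnorm(nlevels(bed), 0, 1)
  e <- rnorm(ng * r, 0, 1)
  y <- 5 + u_g[as.integer(gen)] + u_b[as.integer(bed)] + e
  fit <- reml_fit(y, matrix(1, ng * r, 1),
                  list(bed = list(Z = clonalGS:::incidence(bed)),
                       genotype = list(Z = clonalGS:::incidence(gen))))
  se <- sqrt(pmax(diag(fit$ai_cov), 0))
  # compare against the realised variances of the drawn effects (the AI
  # standard errors are conditional on the realised levels)
  realized <- c(var(u_b), var(u_g), var(e))
  for (k in seq_along(fit$sigma2))
    expect_lt(abs(fit$sigma2[k] - realized[k]), 3 * se[k] + 1e-6)
})

test_that("heritability ratios are wired to the estimated components", {
  cfg <- sim_config(n_parents = 12, progeny_per_cross = 8, n_markers = 400,
                    h2 = 0.3, seed = 31)
  sim <- simulate_breeding_trials(cfg)
  A <- pedigree_numerator_matrix(sim$ped)
  fit <- single_trial_analysis(sim$data, "trait", A = A)
  cc <- fit$components
  st2 <- sum(cc)
  r <- fit$harmonic_reps
  expect_equal(unname(fit$h2[["estimate"]]), unname(cc[["additive"]] / st2))
  expect_equal(unname(fit$H2[["estimate"]]),
               unname((cc[["additive"]] + cc[["family"]] + cc[["clone"]]) / st2))
  expect_equal(unname(fit$hc2[["estimate"]]),
               unname(cc[["additive"]] /
                        (st2 - cc[["residual"]] + cc[["residual"]] / r)))
  expect_lte(fit$h2[["estimate"]], fit$H2[["estimate"]])
  expect_gte(fit$h2[["estimate"]], 0)
  expect_lte(fit$H2[["estimate"]], 1)

  # clone-mean mode divides bed, plot and residual by r
  fit2 <- single_trial_analysis(sim$data, "trait", A = A,
                                hc2_mode = "clone_mean")
  cc2 <- fit2$components
  expect_equal(unname(fit2$hc2[["estimate"]]),
               unname(cc2[["additive"]] /
                        ((cc2[["bed"]] + cc2[["plot"]] + cc2[["residual"]]) / r +
                         cc2[["additive"]] + cc2[["family"]] + cc2[["clone"]])))
})

test_that("Wald test decides the covariate and holds its size", {
  # a null covariate is dropped, an strong one kept
  set.seed(15)
  n <- 90
  g <- factor(rep(1:30, each = 3))
  w <- rnorm(n, 10, 2)
  Z <- clonalGS:::incidence(g)
  y0 <- rnorm(30)[as.integer(g)] + rnorm(n, 0, 1)
  f0 <- reml_fit(y0, cbind(`(Intercept)` = 1, w = w), list(a = list(Z = Z)))
  y1 <- y0 + 0.8 * w
  f1 <- reml_fit(y1, cbind(`(Intercept)` = 1, w = w), list(a = list(Z = Z)))
  expect_true(wald_covariate(f1, "w")$keep)
  expect_equal(wald_covariate(f0, "w")$statistic,
               (f0$beta[["w"]] / f0$beta_se[["w"]])^2)

  # type-I error near 5% for a null covariate
  set.seed(16)
  rej <- 0; nrep <- 300; n <- 120
  g <- factor(rep(1:40, each = 3)); Z <- clonalGS:::incidence(g)
  for (i in seq_len(nrep)) {
    w <- rnorm(n)
    y <- rnorm(40)[as.integer(g)] + rnorm(n)
    f <- reml_fit(y, cbind(`(Intercept)` = 1, w = w),
                  list(a = list(Z = Z)), max_iter = 50)
    if (wald_covariate(f, "w")$keep) rej <- rej + 1
  }
  mc_se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej / nrep - 0.05), 3 * mc_se)
})

test_that("adjusted means equal GLS means and collapse to raw means", {
  # one genotype, two plots, no design variance -> plain average
  d1 <- data.frame(trial = "T1", rep = c("R1", "R2"), bed = "B1",
                   plot = "S1", genotype = "g1", family = "f1",
                   trait = c(10, 12))
  # a second genotype so the response is not constant
  d1 <- rbind(d1, within(d1, { genotype <- "g2"; trait <- c(14, 16) }))
  am <- adjusted_means(d1, "trait")
  expect_equal(unname(am$y_adj["g1"]), 11)
  expect_equal(unname(am$y_adj["g2"]), 15)

  # balanced design with negligible bed/plot variance -> raw genotype means
  tr <- toy_trial(g = 8, r = 3, seed = 4)
  am2 <- adjusted_means(tr, "trait")
  raw <- tapply(tr$trait, tr$genotype, mean)
  expect_equal(unname(am2$y_adj[names(raw)]), as.numeric(raw),
               tolerance = 1e-3)
})

test_that("adjusted means match a direct dense GLS solve", {
  # unbalanced two-bed layout with real bed effects
  set.seed(33)
  g <- c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g5", "g5", "g5")
  bed <- c("B1", "B2", "B1", "B1", "B2", "B2", "B1", "B2", "B1", "B2")
  y <- rnorm(5)[as.integer(factor(g))] +
    c(1, -1)[as.integer(factor(bed))] + rnorm(10, 0, 0.3)
  d <- data.frame(trial = "T1", rep = "R1", bed = bed, plot = "S1",
                  genotype = g, family = "f", trait = y)
  am <- adjusted_means(d, "trait")
  # oracle: explicit GLS with the same estimated covariance
  s2 <- am$fit$sigma2
  Zb <- clonalGS:::incidence(factor(paste("R1", bed, sep = ":")))
  Zp <- clonalGS:::incidence(
    factor(paste("R1", bed, "S1", sep = ":")))
  V <- s2[["bed"]] * tcrossprod(Zb) + s2[["plot"]] * tcrossprod(Zp) +
    s2[["residual"]] * diag(10)
  X <- cbind(1, clonalGS:::incidence(factor(g))[, -1])
  bhat <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  oracle <- c(bhat[1], bhat[1] + bhat[-1])
  expect_equal(unname(am$y_adj), unname(oracle), tolerance = 1e-6)
})
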