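#' Validate plot-level trial data
#'
#' Checks the long-format field-trial table used throughout the package:
#' one row per single-plant plot with design strata (`trial`, `rep`, `bed`,
#' `plot`), `genotype`, `family`, an optional transplant-weight covariate
#' `weight`, and one column per trait. Beds are nested in replicates and
#' subplots in beds; every genotype must map to exactly one family.
#'
#' @param data data.frame with at least columns `trial`, `rep`, `bed`,
#'   `plot`, `genotype`, `family`.
#' @return the data, invisibly, with strata coerced to factors.
#' @export
check_trial_data <- function(data) {
  need <- c("trial", "rep", "bed", "plot", "genotype", "family")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing trial-data columns: ", paste(miss, collapse = ", "))
  gf <- unique(data[, c("genotype", "family")])
  if (anyDuplicated(gf$genotype))
    stop("genotype mapped to more than one family: ",
         paste(gf$genotype[duplicated(gf$genotype)], collapse = ", "))
  for (cl in need) data[[cl]] <- as.factor(data[[cl]])
  invisible(data)
}

# nested stratum labels within one trial
.strata <- function(d) {
  list(rep = factor(d$rep),
       bed = interaction(d$rep, d$bed, drop = TRUE, sep = ":"),
       plot = interaction(d$rep, d$bed, d$plot, drop = TRUE, sep = ":"))
}

# harmonic mean of per-genotype replicate counts
.harmonic_reps <- function(genotype) {
  cnt <- table(genotype)
  length(cnt) / sum(1 / as.numeric(cnt))
}

# delta-method SE of fun(sigma2) using the AI covariance
.delta_se <- function(sigma2, ai_cov, fun) {
  if (is.null(ai_cov)) return(NA_real_)
  g <- numeric(length(sigma2))
  for (k in seq_along(sigma2)) {
    h <- 1e-6 * max(sigma2[k], 1e-6)
    up <- sigma2; up[k] <- up[k] + h
    dn <- sigma2; dn[k] <- max(dn[k] - h, 0)
    g[k] <- (fun(up) - fun(dn)) / (up[k] - dn[k])
  }
  v <- as.numeric(t(g) %*% ai_cov %*% g)
  if (v < 0) {
    # AI matrix can be indefinite near boundary components; project to PSD
    e <- eigen((ai_cov + t(ai_cov)) / 2, symmetric = TRUE)
    cov_psd <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    v <- as.numeric(t(g) %*% cov_psd %*% g)
  }
  if (v < 0) NA_real_ else sqrt(v)
}

# per-trial covariate columns (slope per trial where the weight was recorded)
.covariate_cols <- function(d) {
  if (!"weight" %in% names(d)) return(NULL)
  out <- NULL
  for (tr in levels(factor(d$trial))) {
    sel <- d$trial == tr
    w <- d$weight[sel]
    if (all(is.na(w))) next
    col <- numeric(nrow(d))
    col[sel] <- ifelse(is.na(w), mean(w, na.rm = TRUE), w)
    out <- cbind(out, col)
    colnames(out)[ncol(out)] <- paste0("weight.", tr)
  }
  out
}

#' Single-trial genetic-parameter analysis
#'
#' Fits the clonal-trial model for one trial and trait: fixed intercept,
#' replicate and (when Wald-significant at 5%) the transplant-weight
#' covariate; random bed-within-replicate, subplot-within-bed, additive
#' genotype (covariance `A`), family, and clone-within-family; iid
#' residual. Reports variance components and derived parameters:
#' \itemize{
#'   \item narrow-sense `h2 = sa2 / st2` with
#'     `st2 = sb2 + sp2 + sa2 + sf2 + sc2 + se2`;
#'   \item broad-sense `H2 = (sa2 + sf2 + sc2) / st2`;
#'   \item ad-hoc clonal-mean `hc2 = sa2 / scbar2`, where under the default
#'     `hc2_mode = "literal"` only the residual is divided by the harmonic
#'     mean replicate number `r`
#'     (`scbar2 = sb2 + sp2 + sa2 + sf2 + sc2 + se2 / r`), and under
#'     `"clone_mean"` the bed, plot and residual variances are all divided
#'     by `r`.
#' }
#' Standard errors of the ratios are delta-method approximations from the
#' average-information matrix.
#'
#' @param data plot-level data for exactly one trial (see
#'   [check_trial_data()]).
#' @param trait trait column name.
#' @param A additive [relationship_matrix()] over (at least) the observed
#'   genotypes; identity when `NULL`.
#' @param use_covariate `"auto"` (Wald test at 5%), `TRUE` or `FALSE`.
#' @param hc2_mode `"literal"` or `"clone_mean"` (see above).
#' @param include_family,include_clone include the family and
#'   clone-within-family terms (drop the clone term when `A` is identity,
#'   where it would be confounded with the additive term).
#' @param ... passed to [reml_fit()].
#' @return list of class `single_trial_fit` with `components`, `h2`, `H2`,
#'   `hc2` (each with a delta-method `se`), `harmonic_reps`, the covariate
#'   `wald` decision, `hc2_mode`, and the underlying `fit`.
#' @export
single_trial_analysis <- function(data, trait, A = NULL,
                                  use_covariate = "auto",
                                  hc2_mode = c("literal", "clone_mean"),
                                  include_family = TRUE,
                                  include_clone = TRUE, ...) {
  hc2_mode <- match.arg(hc2_mode)
  data <- check_trial_data(data)
  if (nlevels(factor(data$trial)) != 1) stop("single_trial_analysis needs one trial")
  y <- data[[trait]]
  if (is.null(y)) stop("trait not found: ", trait)
  ok <- is.finite(y)
  data <- data[ok, , drop = FALSE]; y <- y[ok]
  st <- .strata(data)

  X <- cbind(`(Intercept)` = 1, incidence(st$rep)[, -1, drop = FALSE])
  wcols <- .covariate_cols(data)
  wald <- NULL
  use_w <- !is.null(wcols) && !identical(use_covariate, FALSE)

  build_random <- function() {
    r <- list(bed = list(Z = incidence(st$bed)),
              plot = list(Z = incidence(st$plot)))
    Zg <- incidence(data$genotype)
    if (!is.null(A)) {
      Av <- if (inherits(A, "relationship_matrix")) A$values else A
      labs <- rownames(Av)
      if (!all(colnames(Zg) %in% labs))
        stop("genotypes missing from relationship matrix: ",
             paste(setdiff(colnames(Zg), labs), collapse = ", "))
      Zfull <- matrix(0, nrow(data), length(labs), dimnames = list(NULL, labs))
      Zfull[, colnames(Zg)] <- Zg
      r$additive <- list(Z = Zfull, G = Av)
    } else {
      r$additive <- list(Z = Zg)
    }
    if (include_family && nlevels(factor(data$family)) > 1)
      r$family <- list(Z = incidence(data$family))
    if (include_clone && !is.null(A))
      r$clone <- list(Z = Zg)
    r
  }
  rnd <- build_random()

  if (use_w) {
    fit_w <- reml_fit(y, cbind(X, wcols), rnd, ...)
    wname <- colnames(wcols)[1]
    wald <- wald_covariate(fit_w, wname)
    keep_w <- if (identical(use_covariate, TRUE)) TRUE else wald$keep
    fit <- if (keep_w) fit_w else reml_fit(y, X, rnd, ...)
  } else {
    fit <- reml_fit(y, X, rnd, ...)
  }

  s2 <- fit$sigma2
  pick <- function(s, nm) if (nm %in% names(s)) s[[nm]] else 0
  comp <- c(bed = pick(s2, "bed"), plot = pick(s2, "plot"),
            additive = pick(s2, "additive"), family = pick(s2, "family"),
            clone = pick(s2, "clone"), residual = pick(s2, "residual"))
  r_h <- .harmonic_reps(data$genotype)

  idx <- match(names(s2), names(comp))  # map fit components -> named slots
  as_comp <- function(s) {
    out <- comp * 0; out[idx[!is.na(idx)]] <- s[!is.na(idx)]; out
  }
  h2_fun <- function(s) { cc <- as_comp(s); cc[["additive"]] / sum(cc) }
  H2_fun <- function(s) { cc <- as_comp(s)
    (cc[["additive"]] + cc[["family"]] + cc[["clone"]]) / sum(cc) }
  hc2_fun <- function(s) {
    cc <- as_comp(s)
    den <- if (hc2_mode == "literal")
      cc[["bed"]] + cc[["plot"]] + cc[["additive"]] + cc[["family"]] +
        cc[["clone"]] + cc[["residual"]] / r_h
    else
      (cc[["bed"]] + cc[["plot"]] + cc[["residual"]]) / r_h +
        cc[["additive"]] + cc[["family"]] + cc[["clone"]]
    cc[["additive"]] / den
  }
  st2 <- sum(comp)
  if (st2 <= 0) stop("total phenotypic variance is zero")

  structure(list(
    components = comp,
    h2 = c(estimate = h2_fun(s2), se = .delta_se(s2, fit$ai_cov, h2_fun)),
    H2 = c(estimate = H2_fun(s2), se = .delta_se(s2, fit$ai_cov, H2_fun)),
    hc2 = c(estimate = hc2_fun(s2), se = .delta_se(s2, fit$ai_cov, hc2_fun)),
    harmonic_reps = r_h, wald = wald, hc2_mode = hc2_mode,
    trait = trait, fit = fit), class = "single_trial_fit")
}

#' @export
print.single_trial_fit <- function(x, ...) {
  cat("Single-trial analysis of", x$trait, "\n")
  print(round(x$components, 4))
  cat(sprintf("h2 = %.3f (%.3f)  H2 = %.3f (%.3f)  hc2[%s] = %.3f (%.3f)  r = %.2f\n",
              x$h2[1], x$h2[2], x$H2[1], x$H2[2], x$hc2_mode,
              x$hc2[1], x$hc2[2], x$harmonic_reps))
  invisible(x)
}

#' Combined two-trial analysis and Type-B genetic correlation
#'
#' Fits the paired-trial model with trial-heterogeneous bed, subplot and
#' residual variances (a separate variance per trial), shared additive
#' (covariance `A`), family and clone terms, and genotype-by-trial,
#' family-by-trial and clone-by-trial interactions. The Type-B additive
#' correlation is `rB = sa2 / (sa2 + sta2)`; values near one indicate
#' consistent genotype rankings across trials (low G-by-E).
#'
#' @param data plot-level data for exactly two trials.
#' @param trait trait column name.
#' @param A additive [relationship_matrix()] (identity when `NULL`).
#' @param include_family,include_clone as in [single_trial_analysis()].
#' @param ... passed to [reml_fit()].
#' @return list of class `combined_trial_fit` with `components`,
#'   `type_b` (estimate and delta-method se), `connected` flag, `fit`.
#' @export
combined_trial_analysis <- function(data, trait, A = NULL,
                                    include_family = TRUE,
                                    include_clone = TRUE, ...) {
  data <- check_trial_data(data)
  trl <- factor(data$trial)
  if (nlevels(trl) != 2) stop("combined_trial_analysis needs exactly two trials")
  y <- data[[trait]]
  ok <- is.finite(y)
  data <- data[ok, , drop = FALSE]; y <- y[ok]; trl <- factor(data$trial)

  shared <- Reduce(intersect, lapply(split(data$genotype, trl), unique))
  connected <- length(shared) > 0 || !is.null(A)
  if (!connected)
    warning("trials share no genotypes and no pedigree: Type-B estimate unreliable")

  reptrial <- interaction(trl, data$rep, drop = TRUE)
  X <- cbind(`(Intercept)` = 1, incidence(trl)[, -1, drop = FALSE],
             incidence(reptrial)[, -1, drop = FALSE])
  wcols <- .covariate_cols(data)
  if (!is.null(wcols)) X <- cbind(X, wcols)

  bed <- interaction(trl, data$rep, data$bed, drop = TRUE)
  plt <- interaction(trl, data$rep, data$bed, data$plot, drop = TRUE)
  rnd <- list()
  for (tr in levels(trl)) {   # trial-heterogeneous D structures
    sel <- trl == tr
    Zb <- incidence(bed)[, levels(bed) %in% unique(bed[sel]), drop = FALSE]
    Zp <- incidence(plt)[, levels(plt) %in% unique(plt[sel]), drop = FALSE]
    rnd[[paste0("bed.", tr)]] <- list(Z = Zb)
    rnd[[paste0("plot.", tr)]] <- list(Z = Zp)
  }
  Zg <- incidence(data$genotype)
  if (!is.null(A)) {
    Av <- if (inherits(A, "relationship_matrix")) A$values else A
    labs <- rownames(Av)
    if (!all(colnames(Zg) %in% labs))
      stop("genotypes missing from relationship matrix")
    Zfull <- matrix(0, nrow(data), length(labs), dimnames = list(NULL, labs))
    Zfull[, colnames(Zg)] <- Zg
    rnd$additive <- list(Z = Zfull, G = Av)
  } else rnd$additive <- list(Z = Zg)
  # additive-by-trial deviations keep the additive covariance within each
  # trial (block-diagonal A); a plain identity here would be confounded
  # with the clone-by-trial term
  gt <- interaction(data$genotype, trl, drop = TRUE, sep = "\r")
  Zgt <- incidence(gt)
  if (!is.null(A)) {
    Av <- if (inherits(A, "relationship_matrix")) A$values else A
    gt_geno <- sub("\r.*$", "", colnames(Zgt))
    gt_trial <- sub("^.*\r", "", colnames(Zgt))
    Gta <- Av[gt_geno, gt_geno] *
      outer(gt_trial, gt_trial, function(a, b) as.numeric(a == b))
    dimnames(Gta) <- list(colnames(Zgt), colnames(Zgt))
    rnd$additive_x_trial <- list(Z = Zgt, G = Gta)
  } else {
    rnd$additive_x_trial <- list(Z = Zgt)
  }
  if (include_family && nlevels(factor(data$family)) > 1) {
    rnd$family <- list(Z = incidence(data$family))
    rnd$family_x_trial <-
      list(Z = incidence(interaction(data$family, trl, drop = TRUE)))
  }
  if (include_clone && !is.null(A)) {
    rnd$clone <- list(Z = Zg)
    rnd$clone_x_trial <- list(Z = incidence(gt))
  }

  fit <- reml_fit(y, X, rnd, resid_groups = trl, ...)
  s2 <- fit$sigma2
  ia <- which(names(s2) == "additive")
  it <- which(names(s2) == "additive_x_trial")
  rb_fun <- function(s) s[[ia]] / (s[[ia]] + s[[it]])
  structure(list(components = s2,
                 type_b = c(estimate = rb_fun(s2),
                            se = .delta_se(s2, fit$ai_cov, rb_fun)),
                 connected = connected, trait = trait, fit = fit),
            class = "combined_trial_fit")
}

#' @export
print.combined_trial_fit <- function(x, ...) {
  cat("Combined-trial analysis of", x$trait, "\n")
  print(round(x$components, 4))
  cat(sprintf("Type-B additive correlation rB = %.3f (%.3f)\n",
              x$type_b[1], x$type_b[2]))
  invisible(x)
}

#' Adjusted clonal means
#'
#' Fits the adjusted-means model for a single trial: genotype (total clonal
#' value) as a fixed effect, replicate, bed-within-replicate and
#' subplot-within-bed as random design effects, plus the transplant-weight
#' covariate when present. The adjusted value of a genotype is its
#' generalized-least-squares mean (intercept + genotype effect, covariate
#' evaluated at its mean).
#'
#' @param data plot-level data for one trial.
#' @param trait trait column name.
#' @param use_covariate include the weight covariate if available.
#' @param replicate_random treat replicate as random (default) or fixed.
#' @param ... passed to [reml_fit()].
#' @return list of class `adjusted_means` with `y_adj` (named numeric),
#'   `inestimable` (genotypes confounded with the design), `fit`.
#' @export
adjusted_means <- function(data, trait, use_covariate = TRUE,
                           replicate_random = TRUE, ...) {
  data <- check_trial_data(data)
  if (nlevels(factor(data$trial)) != 1) stop("adjusted_means needs one trial")
  y <- data[[trait]]
  ok <- is.finite(y)
  data <- data[ok, , drop = FALSE]; y <- y[ok]
  st <- .strata(data)
  gen <- factor(data$genotype)

  Xg <- incidence(gen)
  X <- cbind(`(Intercept)` = 1, Xg[, -1, drop = FALSE])
  wmean <- 0; wname <- NULL
  if (use_covariate) {
    wcols <- .covariate_cols(data)
    if (!is.null(wcols)) {
      X <- cbind(X, wcols)
      wname <- colnames(wcols)[1]
      wmean <- mean(wcols[, 1])
    }
  }
  rnd <- list(bed = list(Z = incidence(st$bed)),
              plot = list(Z = incidence(st$plot)))
  if (replicate_random && nlevels(st$rep) > 1)
    rnd <- c(list(rep = list(Z = incidence(st$rep))), rnd)
  else if (nlevels(st$rep) > 1)
    X <- cbind(X, incidence(st$rep)[, -1, drop = FALSE])

  fit <- reml_fit(y, X, rnd, ...)
  levs <- levels(gen)
  eff <- setNames(numeric(length(levs)), levs)
  coefs <- fit$beta
  for (g in levs[-1]) {
    if (g %in% names(coefs)) eff[g] <- coefs[g] else eff[g] <- NA_real_
  }
  mu <- coefs[["(Intercept)"]]
  wadd <- if (!is.null(wname) && wname %in% names(coefs))
    coefs[[wname]] * wmean else 0
  y_adj <- mu + eff + wadd
  inest <- names(y_adj)[is.na(y_adj)]
  structure(list(y_adj = y_adj[!is.na(y_adj)], inestimable = inest,
                 trait = trait, fit = fit),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("Adjusted clonal means for", x$trait, ":", length(x$y_adj),
      "genotypes\n")
  if (length(x$inestimable))
    cat("inestimable:", paste(x$inestimable, collapse = ", "), "\n")
  invisible(x)
}
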