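#' Random k-fold assignment
#'
#' Partitions ids into `k` folds with sizes differing by at most one;
#' deterministic for a given seed.
#'
#' @param ids character vector of unique ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector of fold numbers (1..k) per id.
#' @export
make_folds <- function(ids, k = 5, seed = 1) {
  ids <- as.character(ids)
  n <- length(ids)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("fewer ids than folds")
  set.seed(seed)
  f <- sample(rep(seq_len(k), length.out = n))
  names(f) <- ids
  f
}

#' Predictive ability
#'
#' Pearson correlation between adjusted phenotypic values and GEBVs.
#'
#' @param y_adj,gebv aligned numeric vectors (matched by names when both
#'   are named), length >= 3, both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
predictive_ability <- function(y_adj, gebv) {
  if (!is.null(names(y_adj)) && !is.null(names(gebv))) {
    common <- intersect(names(y_adj), names(gebv))
    if (length(common) < 3) stop("fewer than 3 shared individuals")
    y_adj <- y_adj[common]; gebv <- gebv[common]
  }
  if (length(y_adj) != length(gebv)) stop("unequal lengths")
  if (length(y_adj) < 3) stop("need at least 3 pairs")
  if (sd(y_adj) == 0 || sd(gebv) == 0) stop("constant vector")
  cor(as.numeric(y_adj), as.numeric(gebv))
}

#' Prediction accuracy from predictive ability
#'
#' `PACC = PA / sqrt(hc2)` by default. Published formulas are sometimes
#' typeset as a plain division by the ad-hoc heritability, but reported
#' accuracy magnitudes are only consistent with the square-root scaling
#' (the classical relation `corr(a, ahat) = corr(y, ahat) / h`); the
#' literal division is available with `sqrt_scaling = FALSE`. Values above
#' 1 are possible for low heritability and are flagged, not truncated.
#'
#' @param pa predictive ability.
#' @param hc2 ad-hoc (clonal-mean) heritability, in `(0, 1]`.
#' @param sqrt_scaling divide by `sqrt(hc2)` (default) or by `hc2`.
#' @return numeric with attribute `flagged` = TRUE when `|PACC| > 1`.
#' @export
prediction_accuracy <- function(pa, hc2, sqrt_scaling = TRUE) {
  if (hc2 <= 0) stop("hc2 must be positive")
  if (hc2 > 1) stop("hc2 must be at most 1")
  pacc <- if (sqrt_scaling) pa / sqrt(hc2) else pa / hc2
  attr(pacc, "flagged") <- abs(pacc) > 1
  attr(pacc, "scaling") <- if (sqrt_scaling) "sqrt" else "literal"
  pacc
}

# train any of the supported methods on named phenotypes and predict ids
.train_predict <- function(method, y_train, m, predict_ids,
                           A = NULL, kernels = NULL,
                           wgr = wgr_config(), rkhs_h = 0.5, ...) {
  method <- match.arg(method, c("GBLUP", "PBLUP", "RKHS",
                                "BayesB", "BayesC", "BRR", "BL"))
  if (method %in% c("BayesB", "BayesC", "BRR", "BL")) {
    cfg <- wgr; cfg$model <- method
    msub <- marker_matrix(m$dosages[names(y_train), , drop = FALSE])
    fit <- fit_wgr(y_train, msub, cfg)
    mpred <- marker_matrix(m$dosages[predict_ids, , drop = FALSE])
    return(predict_gebv(fit, mpred))
  }
  K <- if (!is.null(kernels) && !is.null(kernels[[method]])) kernels[[method]]
  else switch(method,
              GBLUP = bend_psd(grm_yang(m)),
              RKHS = bend_psd(gaussian_kernel(m, h = rkhs_h)),
              PBLUP = {
                if (is.null(A)) stop("PBLUP requires a pedigree relationship matrix")
                bend_psd(A)
              })
  fit <- fit_kernel_blup(y_train, K, ...)
  fit$gebv[predict_ids]
}

#' K-fold cross-validation of a genomic prediction method
#'
#' Per fold, the method is trained on the remaining folds and GEBVs are
#' predicted for the held-out individuals; out-of-fold predictions are
#' pooled and a single predictive ability is computed over all
#' individuals (per-fold correlations are also returned). Kernel methods
#' are cross-validated by withholding phenotypes — the kernel itself uses
#' all genotypes, mirroring how unphenotyped candidates are predicted in
#' practice.
#'
#' @param y_adj named adjusted phenotypic values for the trial.
#' @param m complete [marker_matrix()] covering the phenotyped ids.
#' @param method one of "GBLUP", "PBLUP", "RKHS", "BayesB", "BayesC",
#'   "BRR", "BL".
#' @param k,seed fold controls ([make_folds()]).
#' @param hc2 ad-hoc heritability used for PACC (optional).
#' @param A pedigree [relationship_matrix()] (PBLUP only).
#' @param wgr a [wgr_config()] for the Bayesian methods.
#' @param rkhs_h Gaussian-kernel bandwidth.
#' @return object of class `validation_result`.
#' @export
cross_validate <- function(y_adj, m, method = "GBLUP", k = 5, seed = 1,
                           hc2 = NULL, A = NULL, wgr = wgr_config(),
                           rkhs_h = 0.5) {
  ids <- names(y_adj)
  if (is.null(ids)) stop("y_adj must be named")
  folds <- make_folds(ids, k = k, seed = seed)
  kernels <- NULL
  if (method %in% c("GBLUP", "RKHS", "PBLUP")) {
    kernels <- list()
    kernels[[method]] <- switch(method,
      GBLUP = bend_psd(grm_yang(m)),
      RKHS = bend_psd(gaussian_kernel(m, h = rkhs_h)),
      PBLUP = { if (is.null(A)) stop("PBLUP requires A"); bend_psd(A) })
  }
  pred <- setNames(rep(NA_real_, length(ids)), ids)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- ids[folds == f]; train <- ids[folds != f]
    g <- tryCatch(
      .train_predict(method, y_adj[train], m, test, A = A,
                     kernels = kernels, wgr = wgr, rkhs_h = rkhs_h),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    pred[test] <- g
    per_fold[f] <- if (sd(y_adj[test]) > 0 && sd(g) > 0)
      cor(y_adj[test], g) else NA_real_
  }
  pa <- predictive_ability(y_adj, pred)
  pacc <- if (!is.null(hc2)) prediction_accuracy(pa, hc2) else NA_real_
  structure(list(scheme = "cv", method = method, pa = pa,
                 pa_per_fold = per_fold, pacc = pacc, hc2 = hc2,
                 folds = folds, seed = seed, predictions = pred),
            class = "validation_result")
}

#' True validation across trials
#'
#' Trains on all individuals of the training trial and predicts the test
#' trial's individuals from their markers only; predictive ability is
#' scored against the test trial's adjusted means, and PACC (by default)
#' uses the test trial's ad-hoc heritability.
#'
#' @param y_train,y_test named adjusted values of the training and test
#'   trials.
#' @param m complete [marker_matrix()] covering both trials' individuals.
#' @param method as in [cross_validate()].
#' @param hc2 test-trial ad-hoc heritability for PACC (optional; pass the
#'   training trial's value to use the alternative convention).
#' @param A pedigree matrix (PBLUP), covering both trials.
#' @param wgr,rkhs_h method options.
#' @return object of class `validation_result` (scheme "true").
#' @export
true_validate <- function(y_train, y_test, m, method = "GBLUP",
                          hc2 = NULL, A = NULL, wgr = wgr_config(),
                          rkhs_h = 0.5) {
  if (is.null(names(y_train)) || is.null(names(y_test)))
    stop("y_train and y_test must be named")
  test_ids <- setdiff(names(y_test), character(0))
  missing_mk <- setdiff(c(names(y_train), test_ids), rownames(m$dosages))
  if (length(missing_mk))
    stop("individuals missing from marker matrix: ",
         paste(head(missing_mk, 5), collapse = ", "))
  g <- .train_predict(method, y_train, m, test_ids, A = A, wgr = wgr,
                      rkhs_h = rkhs_h)
  pa <- predictive_ability(y_test, g)
  pacc <- if (!is.null(hc2)) prediction_accuracy(pa, hc2) else NA_real_
  structure(list(scheme = "true", method = method, pa = pa, pacc = pacc,
                 hc2 = hc2, predictions = g),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("%s validation [%s]: PA = %.3f", x$scheme, x$method, x$pa))
  if (!is.na(x$pacc[1])) cat(sprintf(", PACC = %.3f", as.numeric(x$pacc)))
  cat("\n")
  invisible(x)
}

#' Selection efficiency of incomplete-information rankings
#'
#' Realised fraction of the genetic gain achievable with complete
#' information: the top fraction is selected once by the incomplete
#' ranking (markers only) and once by the complete ranking
#' (phenotype + markers); gain of a set is the mean complete-information
#' GEBV of the set minus the population mean, and efficiency is
#' `100 * gain(incomplete selection) / gain(complete selection)`. Ties are
#' broken by id order (stable). With `top_fraction = 1` both sets are the
#' whole population and efficiency is 100% by convention.
#'
#' @param gebv_incomplete,gebv_complete named numeric over the same
#'   candidate set.
#' @param top_fraction selected proportion, e.g. 0.05 or 0.10.
#' @return efficiency in percent.
#' @export
selection_efficiency <- function(gebv_incomplete, gebv_complete,
                                 top_fraction = 0.10) {
  if (is.null(names(gebv_incomplete)) || is.null(names(gebv_complete)))
    stop("vectors must be named")
  ids <- names(gebv_complete)
  if (!setequal(ids, names(gebv_incomplete)))
    stop("candidate sets differ")
  gebv_incomplete <- gebv_incomplete[ids]
  n <- length(ids)
  n_top <- floor(n * top_fraction + 1e-9)
  if (n_top < 1) stop("top fraction selects no individuals")
  if (n_top >= n) return(100)
  rank_by <- function(v) ids[order(-v, ids)][seq_len(n_top)]
  s_inc <- rank_by(gebv_incomplete)
  s_comp <- rank_by(gebv_complete)
  base <- mean(gebv_complete)
  gain_comp <- mean(gebv_complete[s_comp]) - base
  if (gain_comp == 0) stop("complete-information gain is zero")
  gain_inc <- mean(gebv_complete[s_inc]) - base
  100 * gain_inc / gain_comp
}

#' Per-trait means across genomic selection methods
#'
#' Given a trait x method table of accuracies, computes the per-trait
#' arithmetic mean over the six GS methods (GBLUP, Bayes B, Bayes C, BRR,
#' BL, RKHS), excluding PBLUP which is averaged separately, and the
#' overall average of the per-trait means.
#'
#' @param results data.frame with columns `trait`, `method`, `value`.
#' @return list with `per_trait` (data.frame trait/mean), `overall`
#'   (mean of per-trait GS means), `pblup_mean` (mean of the PBLUP
#'   column, `NA` if absent), `missing` (trait x method cells absent).
#' @export
methods_summary_table <- function(results) {
  stopifnot(all(c("trait", "method", "value") %in% names(results)))
  gs <- c("GBLUP", "BayesB", "BayesC", "BRR", "BL", "RKHS")
  traits <- unique(results$trait)
  missing <- character(0)
  per_trait <- data.frame(trait = traits, mean = NA_real_)
  for (i in seq_along(traits)) {
    sel <- results[results$trait == traits[i] & results$method %in% gs, ]
    absent <- setdiff(gs, sel$method)
    if (length(absent))
      missing <- c(missing, paste(traits[i], absent, sep = ":"))
    per_trait$mean[i] <- mean(sel$value)
  }
  pb <- results[results$method == "PBLUP", ]
  list(per_trait = per_trait,
       overall = mean(per_trait$mean),
       pblup_mean = if (nrow(pb)) mean(pb$value) else NA_real_,
       missing = missing)
}
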