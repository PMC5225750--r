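#' Average-information REML for linear mixed models
#'
#' Fits `y = X b + sum_k Z_k u_k + e` with `u_k ~ N(0, sigma2_k G_k)` and a
#' residual variance per residual group, by maximising the REML
#' log-likelihood. Updates are average-information (AI) steps with an
#' expectation-maximisation (EM) fallback whenever an AI step would leave
#' the parameter space or the AI matrix is not positive definite; the first
#' iteration is always EM. Variance components are constrained to
#' `>= 1e-8 * var(y)` by projection, and components pinned at that bound
#' are flagged.
#'
#' This is a dense-matrix engine intended for trial-sized problems (a few
#' thousand records); relationship-structured terms take an explicit
#' covariance `G`.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (aliased columns are dropped via a
#'   pivoted QR and reported).
#' @param random named list; each element a list with `Z` (n x q incidence
#'   matrix) and optional `G` (q x q covariance, identity when `NULL`).
#' @param resid_groups optional factor of length n giving heterogeneous
#'   residual strata (one variance per level); `NULL` = a single residual.
#' @param init optional named numeric of starting values for all components.
#' @param max_iter,tol_loglik,tol_comp iteration controls: convergence
#'   requires relative log-likelihood change `< tol_loglik` and relative
#'   component change `< tol_comp`.
#' @param verbose print the iteration trace.
#'
#' @return object of class `reml_fit`: `sigma2` (named components,
#'   residual(s) last), `loglik`, `converged`, `iterations`, `boundary`
#'   (logical per component), `beta`/`beta_se`/`beta_cov` (BLUEs),
#'   `blup` (named list of BLUP vectors), `ai_cov` (asymptotic
#'   variance-covariance of the components), `fixed_names`, `dropped_fixed`.
#' @export
reml_fit <- function(y, X, random = list(), resid_groups = NULL,
                     init = NULL, max_iter = 200,
                     tol_loglik = 1e-8, tol_comp = 1e-6, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(is.finite(y))) stop("non-finite response values")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match length(y)")
  vy <- var(y)
  if (vy <= 0) stop("zero-variance response")

  # drop aliased fixed-effect columns
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  dropped_fixed <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, sort(keep), drop = FALSE]
  px <- ncol(X)
  # log det(X'X): makes the REML log-likelihood invariant to the
  # fixed-effect parameterisation (reference-level vs sum-to-zero)
  ld_XtX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))

  K <- length(random)
  if (K > 0 && is.null(names(random)))
    names(random) <- paste0("u", seq_len(K))
  Qs <- vector("list", K)
  qlev <- numeric(K)
  for (k in seq_len(K)) {
    Z <- as.matrix(random[[k]]$Z)
    G <- random[[k]]$G
    if (inherits(G, "relationship_matrix")) G <- G$values
    Qs[[k]] <- if (is.null(G)) tcrossprod(Z) else Z %*% G %*% t(Z)
    qlev[k] <- ncol(Z)
  }
  if (is.null(resid_groups)) resid_groups <- factor(rep("e", n))
  resid_groups <- droplevels(as.factor(resid_groups))
  rlev <- levels(resid_groups)
  R <- length(rlev)
  rmask <- lapply(rlev, function(l) as.numeric(resid_groups == l))
  nr <- vapply(rmask, sum, 0)

  comp_names <- c(names(random),
                  if (R == 1) "residual" else paste0("residual.", rlev))
  M <- K + R
  lb <- 1e-8 * vy
  sigma2 <- if (!is.null(init)) pmax(as.numeric(init[comp_names]), lb)
            else rep(vy / M, M)

  build_V <- function(s2) {
    V <- matrix(0, n, n)
    for (k in seq_len(K)) V <- V + s2[k] * Qs[[k]]
    dV <- numeric(n)
    for (t in seq_len(R)) dV <- dV + s2[K + t] * rmask[[t]]
    diag(V) <- diag(V) + dV
    V
  }

  reml_pieces <- function(s2) {
    V <- build_V(s2)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    B <- Vinv %*% X
    XtViX <- crossprod(X, B)
    cx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cx)) stop("singular fixed-effect block")
    XtViX_inv <- chol2inv(cx)
    P <- Vinv - B %*% XtViX_inv %*% t(B)
    Py <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) -
                  ld_XtX + sum(y * Py))
    list(P = P, Py = Py, ll = ll, XtViX_inv = XtViX_inv, Vinv = Vinv)
  }

  trPQ_yPQPy <- function(pc, s2) {
    trv <- numeric(M); quad <- numeric(M)
    for (k in seq_len(K)) {
      trv[k] <- sum(pc$P * Qs[[k]])
      w <- as.numeric(Qs[[k]] %*% pc$Py)
      quad[k] <- sum(pc$Py * w)
    }
    for (t in seq_len(R)) {
      trv[K + t] <- sum(diag(pc$P) * rmask[[t]])
      quad[K + t] <- sum(pc$Py^2 * rmask[[t]])
    }
    list(tr = trv, quad = quad)
  }

  pc <- reml_pieces(sigma2)
  if (is.null(pc)) stop("initial variance matrix not positive definite")
  ll_old <- pc$ll
  converged <- FALSE
  plateau <- 0L
  AI <- NULL
  trace <- data.frame(iter = integer(), loglik = numeric(), step = character())

  for (it in seq_len(max_iter)) {
    tq <- trPQ_yPQPy(pc, sigma2)
    score <- -0.5 * (tq$tr - tq$quad)

    # average information: AI_kl = 0.5 * (Q_k Py)' P (Q_l Py)
    Tm <- matrix(0, n, M)
    for (k in seq_len(K)) Tm[, k] <- as.numeric(Qs[[k]] %*% pc$Py)
    for (t in seq_len(R)) Tm[, K + t] <- pc$Py * rmask[[t]]
    AI <- 0.5 * crossprod(Tm, pc$P %*% Tm)

    qk <- c(qlev, nr)
    em_step <- sigma2 + (sigma2^2 / qk) * (tq$quad - tq$tr)

    use_em <- it == 1
    prop <- NULL
    if (!use_em) {
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(delta)) use_em <- TRUE else prop <- sigma2 + delta
    }
    if (use_em) prop <- em_step
    step_kind <- if (use_em) "EM" else "AI"
    prop <- pmax(prop, lb)

    # step-halving toward current point if likelihood evaluation fails
    pc_new <- reml_pieces(prop)
    tries <- 0
    while (is.null(pc_new) && tries < 10) {
      prop <- (prop + sigma2) / 2
      pc_new <- reml_pieces(prop)
      tries <- tries + 1
    }
    if (is.null(pc_new)) stop("variance matrix became indefinite")
    # AI steps can overshoot; fall back to EM if likelihood drops clearly
    if (step_kind == "AI" && pc_new$ll < ll_old - 1e-6) {
      prop2 <- pmax(em_step, lb)
      pc2 <- reml_pieces(prop2)
      if (!is.null(pc2) && pc2$ll > pc_new$ll) {
        prop <- prop2; pc_new <- pc2; step_kind <- "EM*"
      }
    }

    rel_comp <- max(abs(prop - sigma2) / pmax(sigma2, lb))
    rel_ll <- abs(pc_new$ll - ll_old) / (abs(ll_old) + 1)
    sigma2 <- prop
    pc <- pc_new
    trace <- rbind(trace, data.frame(iter = it, loglik = pc$ll,
                                     step = step_kind))
    if (verbose)
      message(sprintf("it %d [%s] ll = %.8f", it, step_kind, pc$ll))
    if (it > 1 && rel_ll < tol_loglik && rel_comp < tol_comp) {
      converged <- TRUE
      break
    }
    # flat likelihood ridge: components may keep drifting while the
    # log-likelihood is numerically stationary — accept after 5 such steps
    plateau <- if (it > 1 && rel_ll < tol_loglik) plateau + 1L else 0L
    if (plateau >= 5L) {
      converged <- TRUE
      break
    }
    ll_old <- pc$ll
  }

  names(sigma2) <- comp_names
  boundary <- sigma2 <= lb * (1 + 1e-6)

  beta <- as.numeric(pc$XtViX_inv %*% crossprod(X, pc$Vinv %*% y))
  names(beta) <- colnames(X)
  beta_cov <- pc$XtViX_inv
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  blup <- vector("list", K); names(blup) <- names(random)
  for (k in seq_len(K)) {
    Z <- as.matrix(random[[k]]$Z)
    G <- random[[k]]$G
    if (inherits(G, "relationship_matrix")) G <- G$values
    ZtPy <- crossprod(Z, pc$Py)
    u <- if (is.null(G)) sigma2[k] * ZtPy else sigma2[k] * (G %*% ZtPy)
    u <- as.numeric(u)
    names(u) <- colnames(Z)
    blup[[k]] <- u
  }

  ai_cov <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(ai_cov)) dimnames(ai_cov) <- list(comp_names, comp_names)

  structure(list(sigma2 = sigma2, loglik = pc$ll, converged = converged,
                 iterations = it, boundary = boundary,
                 beta = beta, beta_se = sqrt(diag(beta_cov)),
                 beta_cov = beta_cov, blup = blup, ai_cov = ai_cov,
                 fixed_names = colnames(X), dropped_fixed = dropped_fixed,
                 n = n, trace = trace),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n, "records,",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; logLik =",
      format(x$loglik, digits = 8), "\n")
  print(round(x$sigma2, 6))
  invisible(x)
}

# incidence matrix of a factor (one column per level)
incidence <- function(f) {
  f <- droplevels(as.factor(f))
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Wald test of a fixed-effect coefficient
#'
#' `W = (beta / se)^2` compared with a chi-square with one degree of
#' freedom; the term is kept when `p <= alpha`.
#'
#' @param fit a [reml_fit()].
#' @param term coefficient name.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `keep`.
#' @export
wald_covariate <- function(fit, term, alpha = 0.05) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!term %in% names(fit$beta)) stop("term not in fixed effects: ", term)
  se <- fit$beta_se[term]
  if (se <= 0) stop("zero standard error for term ", term)
  w <- (fit$beta[term] / se)^2
  p <- pchisq(w, df = 1, lower.tail = FALSE)
  list(statistic = unname(w), p_value = unname(p), keep = unname(p <= alpha))
}
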