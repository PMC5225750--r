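#' Gaussian kernel from marker dosages
#'
#' `K[j,k] = exp(-h * d2[j,k] / mean(d2))` where `d2` is the squared
#' Euclidean distance between dosage rows and `mean(d2)` is taken over
#' off-diagonal pairs. Normalising by the mean distance makes the
#' bandwidth `h` unit-free; the diagonal is exactly 1.
#'
#' @param m a complete [marker_matrix()] with at least two individuals.
#' @param h bandwidth on the normalised-distance scale (default 0.5).
#' @return a [relationship_matrix()] of kind "kernel"; the normalisation
#'   constant and bandwidth are attached as attributes.
#' @export
gaussian_kernel <- function(m, h = 0.5) {
  stopifnot(inherits(m, "marker_matrix"), h > 0)
  d <- m$dosages
  if (anyNA(d)) stop("missing dosages: impute first")
  if (nrow(d) < 2) stop("need at least two individuals to normalise distances")
  sq <- rowSums(d^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(d)
  d2[d2 < 0] <- 0
  md2 <- mean(d2[upper.tri(d2)])
  if (md2 <= 0) stop("all individuals identical: zero mean distance")
  K <- exp(-h * d2 / md2)
  diag(K) <- 1
  dimnames(K) <- list(rownames(d), rownames(d))
  out <- relationship_matrix(K, kind = "kernel")
  attr(out, "bandwidth") <- h
  attr(out, "mean_d2") <- md2
  out
}

#' Kernel BLUP (GBLUP / PBLUP / RKHS)
#'
#' Fits the individual model `y = 1 mu + Z a + e` with
#' `a ~ N(0, sigma_a^2 K)` by REML and returns BLUPs for every individual
#' carried in the kernel, including unphenotyped ones — this is how true
#' validation works for kernel methods: prediction individuals appear in
#' `K` but contribute no phenotype. GBLUP uses the genomic relationship
#' matrix, PBLUP the pedigree numerator matrix, RKHS a
#' [gaussian_kernel()].
#'
#' @param y_adj named numeric of adjusted values; names must be a subset
#'   of the kernel labels.
#' @param k a [relationship_matrix()], bent PSD ([bend_psd()] is applied
#'   if needed).
#' @param fixed_variances optional `c(sigma_a2, sigma_e2)` to skip REML
#'   (used by oracle checks).
#' @param ... passed to [reml_fit()].
#' @return list of class `kernel_blup`: `gebv` (named, all kernel
#'   individuals), `sigma_a2`, `sigma_e2`, `mu`, `fit`.
#' @export
fit_kernel_blup <- function(y_adj, k, fixed_variances = NULL, ...) {
  stopifnot(inherits(k, "relationship_matrix"))
  if (is.null(names(y_adj))) stop("y_adj must be named")
  if (!all(names(y_adj) %in% k$labels))
    stop("phenotyped individuals missing from the kernel: ",
         paste(setdiff(names(y_adj), k$labels), collapse = ", "))
  if (!k$psd) k <- bend_psd(k)
  K <- k$values
  n <- length(y_adj)
  Z <- matrix(0, n, ncol(K), dimnames = list(NULL, colnames(K)))
  Z[cbind(seq_len(n), match(names(y_adj), colnames(K)))] <- 1
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  if (is.null(fixed_variances)) {
    fit <- reml_fit(as.numeric(y_adj), X,
                    list(additive = list(Z = Z, G = K)), ...)
    sa2 <- fit$sigma2[["additive"]]; se2 <- fit$sigma2[["residual"]]
    a <- fit$blup$additive
    mu <- fit$beta[["(Intercept)"]]
  } else {
    sa2 <- fixed_variances[1]; se2 <- fixed_variances[2]
    V <- sa2 * Z %*% K %*% t(Z) + se2 * diag(n)
    Vinv <- chol2inv(chol(V))
    mu <- as.numeric(solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% y_adj))
    Py <- Vinv %*% (y_adj - mu)
    a <- as.numeric(sa2 * K %*% t(Z) %*% Py)
    names(a) <- colnames(K)
    fit <- NULL
  }
  structure(list(gebv = a, sigma_a2 = sa2, sigma_e2 = se2, mu = mu,
                 kind = k$kind, fit = fit),
            class = "kernel_blup")
}

#' @export
print.kernel_blup <- function(x, ...) {
  cat(sprintf("kernel BLUP (%s): sigma_a2 = %.4f, sigma_e2 = %.4f, %d individuals\n",
              x$kind, x$sigma_a2, x$sigma_e2, length(x$gebv)))
  invisible(x)
}
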