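#' Pedigree table
#'
#' Validated (id, sire, dam) records, topologically ordered so that every
#' parent precedes its offspring. Unknown parents are `NA` and are treated
#' as unique unrelated non-inbred founders.
#'
#' @param id,sire,dam character vectors (or a data.frame via `ped`);
#'   `NA`/"" = unknown parent.
#' @return data.frame of class `pedigree_table`.
#' @export
pedigree_table <- function(id, sire = NULL, dam = NULL) {
  if (is.data.frame(id)) {
    df <- id
    id <- df[[1]]; sire <- df[[2]]; dam <- df[[3]]
  }
  id <- as.character(id)
  clean <- function(x) { x <- as.character(x); x[!is.na(x) & x == ""] <- NA; x }
  sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  pos <- match(id, id)
  for (p in list(sire, dam)) {
    known <- !is.na(p)
    if (any(!(p[known] %in% id)))
      stop("parent without a record: ",
           paste(unique(p[known][!(p[known] %in% id)]), collapse = ", "))
  }
  sp <- match(sire, id); dp <- match(dam, id)
  n <- length(id)
  # parents must come first; also catches cycles (an ancestor of itself can
  # never be ordered parents-before-offspring)
  ord <- order(.ped_depth(sp, dp))
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  sp <- match(sire, id); dp <- match(dam, id)
  for (i in seq_len(n)) {
    if ((!is.na(sp[i]) && sp[i] >= i) || (!is.na(dp[i]) && dp[i] >= i))
      stop("pedigree cannot be ordered parents-before-offspring (cycle?)")
  }
  structure(data.frame(id = id, sire = sire, dam = dam,
                       stringsAsFactors = FALSE),
            class = c("pedigree_table", "data.frame"))
}

# generation depth; errors on cycles
.ped_depth <- function(sp, dp) {
  n <- length(sp)
  depth <- rep(NA_integer_, n)
  f <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) stop("cycle detected in pedigree")
    seen[i] <- TRUE
    d <- 0L
    if (!is.na(sp[i])) d <- max(d, f(sp[i], seen) + 1L)
    if (!is.na(dp[i])) d <- max(d, f(dp[i], seen) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) f(i, rep(FALSE, n))
  depth
}

#' Labelled relationship matrix
#'
#' Symmetric matrix of additive relationships (pedigree numerator A,
#' genomic A_g, or kernel K) with PSD bookkeeping.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param kind one of "pedigree", "genomic", "kernel".
#' @param bend_applied logical, set by [bend_psd()].
#' @return object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, kind = c("genomic", "pedigree", "kernel"),
                                bend_applied = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (max(abs(values - t(values))) > 1e-10) stop("matrix must be symmetric")
  values <- (values + t(values)) / 2
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("ind", seq_len(nrow(values))),
                             paste0("ind", seq_len(nrow(values))))
  ev_min <- min(eigen(values, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(values = values, labels = rownames(values), kind = kind,
                 psd = ev_min >= -1e-8, min_eigenvalue = ev_min,
                 bend_applied = bend_applied),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s): %d x %d, psd = %s, bent = %s\n",
              x$kind, nrow(x$values), ncol(x$values), x$psd, x$bend_applied))
  invisible(x)
}

#' Pedigree numerator relationship matrix
#'
#' Tabular-method recursion over a parents-first ordering:
#' `A[i,i] = 1 + 0.5 * A[sire, dam]` (0 when either parent is unknown) and
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])` for earlier `j`.
#'
#' @param ped a [pedigree_table()].
#' @return a [relationship_matrix()] of kind "pedigree".
#' @export
pedigree_numerator_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  sp <- match(ped$sire, ped$id); dp <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
  }
  relationship_matrix(A, kind = "pedigree")
}

#' Genomic relationship matrix (Yang et al. estimator)
#'
#' Off-diagonal `A[j,k]` is the average over markers non-missing in both
#' individuals of `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`; the
#' diagonal is `1 + mean((x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p)))` over
#' the individual's non-missing markers. Pairwise complete-case averaging
#' means no imputation is required (or used) — missing calls simply drop
#' out of each pair's average.
#'
#' @param m a [marker_matrix()]; every marker must have `0 < p < 1`
#'   (run [qc_filter()] first).
#' @param freqs optional frequencies to centre with (defaults to those of
#'   `m`, e.g. reuse training frequencies).
#' @return a [relationship_matrix()] of kind "genomic".
#' @export
grm_yang <- function(m, freqs = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  p <- if (is.null(freqs)) m$freqs else freqs
  if (any(is.na(p)) || any(p <= 0 | p >= 1))
    stop("grm_yang requires 0 < p < 1 for every marker; run qc_filter first")
  d <- m$dosages
  den <- 2 * p * (1 - p)
  W <- sweep(d, 2, 2 * p)              # x - 2p, NA where missing
  Ws <- sweep(W, 2, sqrt(den), "/")
  obs <- !is.na(Ws)
  Ws0 <- Ws; Ws0[!obs] <- 0
  num <- tcrossprod(Ws0)              # sum over shared markers
  cnt <- tcrossprod(obs * 1)          # markers non-missing in both
  if (any(cnt == 0)) stop("individual pair with no shared non-missing marker")
  A <- num / cnt
  # Yang diagonal differs from the cross-product diagonal
  Dnum <- d^2 - sweep(d, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow(d), ncol(d), byrow = TRUE)
  D <- sweep(Dnum, 2, den, "/")
  diag(A) <- 1 + rowMeans(D, na.rm = TRUE)
  relationship_matrix(A, kind = "genomic")
}

#' Bend a relationship matrix to positive semi-definiteness
#'
#' Eigendecomposes, replaces every eigenvalue below `eps` by `eps`, and
#' reconstructs. Already-PSD input (minimum eigenvalue >= `eps`) is
#' returned unchanged; the operation is idempotent.
#'
#' @param k a [relationship_matrix()] or symmetric matrix.
#' @param eps eigenvalue floor (default `1e-6`).
#' @return a [relationship_matrix()] with `psd = TRUE`; `bend_applied`
#'   records whether the spectrum was modified.
#' @export
bend_psd <- function(k, eps = 1e-6) {
  was_rm <- inherits(k, "relationship_matrix")
  kind <- if (was_rm) k$kind else "genomic"
  prev_bent <- if (was_rm) k$bend_applied else FALSE
  v <- if (was_rm) k$values else as.matrix(k)
  if (max(abs(v - t(v))) > 1e-10) stop("bend_psd requires a symmetric matrix")
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) {
    out <- relationship_matrix(v, kind = kind, bend_applied = prev_bent)
    return(out)
  }
  lam <- pmax(e$values, eps)
  vb <- e$vectors %*% (lam * t(e$vectors))
  dimnames(vb) <- dimnames(v)
  relationship_matrix((vb + t(vb)) / 2, kind = kind, bend_applied = TRUE)
}

#' Read a pedigree CSV (columns id, sire, dam; empty/NA = unknown)
#' @param path file path.
#' @return a [pedigree_table()].
#' @export
read_pedigree_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pedigree_table(df)
}
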