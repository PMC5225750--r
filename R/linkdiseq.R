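#' Genetic map
#'
#' Marker positions on linkage groups, in centimorgans.
#'
#' @param marker,lg,cm vectors (or a data.frame with those columns).
#' @return data.frame of class `genetic_map`.
#' @export
genetic_map <- function(marker, lg = NULL, cm = NULL) {
  if (is.data.frame(marker)) {
    df <- marker
    marker <- df$marker; lg <- df$lg; cm <- df$cm
  }
  marker <- as.character(marker)
  if (anyDuplicated(marker)) stop("marker on more than one map position")
  if (any(cm < 0)) stop("negative map positions")
  structure(data.frame(marker = marker, lg = as.character(lg),
                       cm = as.numeric(cm), stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Within-linkage-group pairwise LD (r2)
#'
#' Squared Pearson correlation between dosage vectors (composite LD on
#' unphased dosages) for every unordered marker pair on one linkage
#' group. Monomorphic markers are excluded with a warning.
#'
#' @param m complete [marker_matrix()].
#' @param map a [genetic_map()].
#' @param lg linkage group label.
#' @return data.frame of class `ld_result`: `lg`, `marker_i`, `marker_j`,
#'   `dist_cm`, `r2`.
#' @export
pairwise_r2 <- function(m, map, lg) {
  stopifnot(inherits(m, "marker_matrix"), inherits(map, "genetic_map"))
  sub <- map[map$lg == lg & map$marker %in% colnames(m$dosages), ]
  if (nrow(sub) < 2) stop("fewer than 2 mapped markers on LG ", lg)
  d <- m$dosages[, sub$marker, drop = FALSE]
  if (anyNA(d)) stop("missing dosages: impute first")
  sds <- apply(d, 2, sd)
  if (any(sds == 0)) {
    warning("excluding monomorphic marker(s): ",
            paste(colnames(d)[sds == 0], collapse = ", "))
    keep <- sds > 0
    d <- d[, keep, drop = FALSE]; sub <- sub[keep, ]
    if (ncol(d) < 2) stop("fewer than 2 polymorphic markers on LG ", lg)
  }
  r2 <- cor(d)^2
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  out <- data.frame(lg = lg,
                    marker_i = sub$marker[ut[, 1]],
                    marker_j = sub$marker[ut[, 2]],
                    dist_cm = abs(sub$cm[ut[, 1]] - sub$cm[ut[, 2]]),
                    r2 = r2[ut], stringsAsFactors = FALSE)
  class(out) <- c("ld_result", "data.frame")
  out
}

#' Relatedness-corrected pairwise LD (rv2)
#'
#' Removes the LD inflation caused by genetic relatedness among the
#' sampled individuals: with `V` the (bent-PSD) genomic relationship
#' matrix built from the markers of the same linkage group, each dosage
#' vector is GLS-centred (subtracting the generalised mean
#' `1 (1' V^-1 1)^-1 1' V^-1 x`) and whitened by the Cholesky factor of
#' `V`; `rv2` is the squared Pearson correlation of the whitened vectors.
#' With `V` proportional to the identity, `rv2` equals `r2` exactly.
#'
#' @param m complete [marker_matrix()].
#' @param map a [genetic_map()].
#' @param lg linkage group label.
#' @param v optional [relationship_matrix()] aligned to the individuals;
#'   by default the LG-specific Yang relationship matrix is built from
#'   the markers of `lg` and bent.
#' @return data.frame of class `ld_result` with columns as
#'   [pairwise_r2()] plus `rv2`.
#' @export
corrected_r2 <- function(m, map, lg, v = NULL) {
  base <- pairwise_r2(m, map, lg)
  mk <- unique(c(base$marker_i, base$marker_j))
  d <- m$dosages[, mk, drop = FALSE]
  if (is.null(v)) {
    mlg <- marker_matrix(d)
    keep <- mlg$freqs > 0 & mlg$freqs < 1
    v <- bend_psd(grm_yang(marker_matrix(d[, keep, drop = FALSE])))
  } else if (!inherits(v, "relationship_matrix")) {
    v <- relationship_matrix(as.matrix(v))
  }
  if (!v$psd) v <- bend_psd(v)
  V <- v$values
  if (!is.null(rownames(V))) {
    if (!all(rownames(d) %in% rownames(V)))
      stop("relationship matrix does not cover all individuals")
    V <- V[rownames(d), rownames(d)]
  }
  ch <- tryCatch(chol(V), error = function(e)
    stop("relationship matrix singular after bending"))
  Vinv1 <- backsolve(ch, forwardsolve(t(ch), rep(1, nrow(V))))
  denom <- sum(Vinv1)
  gls_mean <- as.numeric(crossprod(Vinv1, d)) / denom
  centred <- sweep(d, 2, gls_mean)
  white <- forwardsolve(t(ch), centred)   # L^-1 (x - mean), V = L L'
  rv <- cor(white)^2
  key <- function(a, b) paste(a, b)
  idx_i <- match(base$marker_i, mk); idx_j <- match(base$marker_j, mk)
  base$rv2 <- rv[cbind(idx_i, idx_j)]
  base
}

#' LD-decay profile
#'
#' Bins pairwise LD by map distance (`[0, w), [w, 2w), ...`) and reports
#' per-bin means and pair counts, plus genome-wide averages over all
#' within-LG pairs.
#'
#' @param ld an `ld_result` (possibly several LGs row-bound).
#' @param bin_width bin width in cM (default 1).
#' @return list with `bins` (data.frame `bin_start`, `bin_end`,
#'   `n_pairs`, `mean_r2`, and `mean_rv2` if present; empty bins are kept
#'   and flagged by `n_pairs = 0`) and `overall` (named means).
#' @export
ld_decay_profile <- function(ld, bin_width = 1) {
  stopifnot(is.data.frame(ld), bin_width > 0)
  maxd <- max(ld$dist_cm)
  edges <- seq(0, maxd + bin_width, by = bin_width)
  bin <- findInterval(ld$dist_cm, edges, rightmost.closed = FALSE)
  nb <- max(bin)
  has_rv <- "rv2" %in% names(ld)
  bins <- data.frame(bin_start = edges[seq_len(nb)],
                     bin_end = edges[seq_len(nb) + 1],
                     n_pairs = 0L, mean_r2 = NA_real_)
  if (has_rv) bins$mean_rv2 <- NA_real_
  for (b in seq_len(nb)) {
    sel <- bin == b
    bins$n_pairs[b] <- sum(sel)
    if (any(sel)) {
      bins$mean_r2[b] <- mean(ld$r2[sel])
      if (has_rv) bins$mean_rv2[b] <- mean(ld$rv2[sel])
    }
  }
  overall <- c(mean_r2 = mean(ld$r2))
  if (has_rv) overall <- c(overall, mean_rv2 = mean(ld$rv2))
  list(bins = bins, overall = overall)
}

#' Marker density of a genetic map
#'
#' Markers per centimorgan: number of mapped markers divided by total map
#' length (sum of per-LG lengths by default, or an explicit length).
#'
#' @param map a [genetic_map()].
#' @param total_length_cm optional known total map length.
#' @return markers per cM.
#' @export
marker_density <- function(map, total_length_cm = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(total_length_cm)) {
    lens <- tapply(map$cm, map$lg, function(x) max(x) - min(x))
    total_length_cm <- sum(lens)
  }
  nrow(map) / total_length_cm
}
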