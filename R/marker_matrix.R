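#' Marker dosage matrix
#'
#' Container for biallelic SNP dosages (0/1/2, `NA` = missing) for a set of
#' individuals, together with per-marker alternate-allele frequencies
#' computed on the non-missing calls.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns.
#'   Non-missing entries must be 0, 1 or 2. Dimnames supply the ids unless
#'   given explicitly.
#' @param individual_ids,marker_ids optional character vectors of unique
#'   labels; default to the dimnames of `dosages`.
#'
#' @return An object of class `marker_matrix` with elements `dosages`
#'   (named numeric matrix) and `freqs` (per-marker alternate-allele
#'   frequency; `NA` for an all-missing marker, which is flagged rather
#'   than silently set to 0).
#' @export
marker_matrix <- function(dosages, individual_ids = NULL, marker_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) individual_ids <- rownames(dosages)
  if (is.null(marker_ids)) marker_ids <- colnames(dosages)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(dosages)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (length(individual_ids) != nrow(dosages) || length(marker_ids) != ncol(dosages))
    stop("id lengths do not match dosage dimensions")
  vals <- dosages[!is.na(dosages)]
  # raw calls are {0,1,2}; mean-imputed dosages 2p are real-valued in [0,2]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2))
    stop("dosage entries must lie in [0, 2]")
  dimnames(dosages) <- list(individual_ids, marker_ids)
  obj <- structure(list(dosages = dosages, freqs = NULL),
                   class = "marker_matrix")
  obj$freqs <- .marker_freqs(dosages)
  obj
}

.marker_freqs <- function(d) {
  nonmiss <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nonmiss)
  p[nonmiss == 0] <- NA_real_
  p
}

#' @export
print.marker_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("marker_matrix: %d individuals x %d markers, %.2f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

#' Allele frequencies and MAF
#'
#' Per-marker alternate-allele frequency `p = sum(dosage) / (2 * n_called)`
#' over non-missing calls, and the minor-allele frequency
#' `MAF = min(p, 1 - p)`.
#'
#' @param m a [marker_matrix()].
#' @return data.frame with columns `marker`, `p`, `maf`, `missing_rate`.
#'   A marker with no non-missing call has no defined frequency and is an
#'   error (it must be dropped before any frequency-based step).
#' @export
compute_allele_freq <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosages
  nonmiss <- colSums(!is.na(d))
  if (any(nonmiss == 0))
    stop("allele frequency undefined for all-missing marker(s): ",
         paste(colnames(d)[nonmiss == 0], collapse = ", "))
  p <- colSums(d, na.rm = TRUE) / (2 * nonmiss)
  data.frame(marker = colnames(d), p = unname(p),
             maf = unname(pmin(p, 1 - p)),
             missing_rate = unname(colMeans(is.na(d))),
             stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Retains markers with `MAF >= maf_min` and missing rate `<= miss_max`.
#' Markers exactly at a threshold are kept (elimination rules are strict
#' inequalities); set the thresholds to open-interval values to reproduce
#' the opposite convention.
#'
#' @param m a [marker_matrix()].
#' @param maf_min minimum minor-allele frequency, in `[0, 0.5]`.
#' @param miss_max maximum missing rate, in `[0, 1]`.
#' @return list with `markers` (the filtered [marker_matrix()]) and
#'   `report`: counts kept/dropped per rule and jointly. The individual
#'   set is never changed.
#' @export
qc_filter <- function(m, maf_min = 0.05, miss_max = 0.05) {
  stopifnot(inherits(m, "marker_matrix"),
            maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  fr <- compute_allele_freq(m)
  # epsilon guards the keep-at-boundary convention against floating-point
  # representation of rates like 3/60
  eps <- 1e-12
  keep_maf <- fr$maf >= maf_min - eps
  keep_miss <- fr$missing_rate <= miss_max + eps
  keep <- keep_maf & keep_miss
  if (!any(keep)) stop("no markers survive QC: empty panel")
  report <- list(
    n_input = nrow(fr),
    n_kept = sum(keep),
    dropped_maf = sum(!keep_maf),
    dropped_missing = sum(!keep_miss),
    dropped_either = sum(!keep),
    maf_min = maf_min, miss_max = miss_max)
  list(markers = marker_matrix(m$dosages[, keep, drop = FALSE]),
       report = report)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing call of marker `i` by its expected dosage
#' `2 * p_i` under the observed allele frequency. Imputed values are
#' real-valued by default because downstream relationship matrices and
#' samplers operate on real dosages; `round` gives hard calls instead.
#'
#' @param m a [marker_matrix()]; every marker must have a defined frequency.
#' @param round logical; round imputed values to the nearest integer dosage.
#' @return list with `markers` (complete matrix) and `imputed_fraction`
#'   (missing cells / total cells before imputation).
#' @export
impute_mean <- function(m, round = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosages
  if (anyNA(m$freqs))
    stop("cannot impute markers with undefined frequency: ",
         paste(colnames(d)[is.na(m$freqs)], collapse = ", "))
  miss <- is.na(d)
  frac <- mean(miss)
  if (frac > 0) {
    fill <- 2 * m$freqs
    if (round) fill <- round(fill)
    idx <- which(miss, arr.ind = TRUE)
    d[miss] <- fill[idx[, 2]]
  }
  list(markers = marker_matrix(d), imputed_fraction = frac)
}

#' Read a genotype CSV
#'
#' Wide layout: header row of marker ids, first column the individual id,
#' missing coded as an empty cell or `NA`.
#'
#' @param path file path.
#' @return a [marker_matrix()].
#' @export
read_genotypes_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  marker_matrix(d)
}

#' Write a genotype CSV
#' @param m a [marker_matrix()].
#' @param path file path.
#' @export
write_genotypes_csv <- function(m, path) {
  df <- data.frame(id = rownames(m$dosages), m$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
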