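#' Published prediction-accuracy summary
#'
#' Bundled summary table from a published strawberry genomic-selection
#' evaluation: prediction accuracies (PACC) of seven methods for five
#' yield and fruit-quality traits (AWT average fruit weight, EMY early
#' marketable yield, SSC soluble solids content, TC total culls, TMY
#' total marketable yield), from a model trained in an advanced-selection
#' trial and validated in the following season's trial, together with the
#' printed per-trait method means and the training trial's ad-hoc
#' heritabilities. Used to check the package's summary arithmetic against
#' published values.
#'
#' @return data.frame with one row per trait.
#' @export
published_accuracy_table <- function() {
  read.csv(system.file("extdata", "published_accuracy_summary.csv",
                       package = "clonalGS"), stringsAsFactors = FALSE)
}

#' Published genetic-map summary
#'
#' Marker count, linkage-group count and total length (cM) of the
#' published linkage map underlying the bundled accuracy summary.
#'
#' @return named numeric vector.
#' @export
published_map_summary <- function() {
  df <- read.csv(system.file("extdata", "published_map_summary.csv",
                             package = "clonalGS"), stringsAsFactors = FALSE)
  setNames(df$value, df$quantity)
}

# long format of the published accuracy table for methods_summary_table()
.published_accuracy_long <- function() {
  wide <- published_accuracy_table()
  methods <- c("PBLUP", "GBLUP", "BayesB", "BayesC", "BRR", "BL", "RKHS")
  do.call(rbind, lapply(methods, function(m)
    data.frame(trait = wide$trait, method = m, value = wide[[m]],
               stringsAsFactors = FALSE)))
}
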