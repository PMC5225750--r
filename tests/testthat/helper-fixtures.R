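# small in-code fixtures shared across test files

# random dosage matrix with controllable missingness
rand_markers <- function(n, p, miss = 0, freq = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(p, 0.1, 0.9)
  d <- matrix(rbinom(n * p, 2, rep(freq, each = n)), n, p,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("m", seq_len(p))))
  if (miss > 0) d[sample(length(d), round(miss * length(d)))] <- NA
  marker_matrix(d)
}

# two founders, two full-sib offspring, one selfed offspring of A
toy_pedigree <- function() {
  pedigree_table(id = c("A", "B", "S1", "S2", "X"),
                 sire = c(NA, NA, "A", "A", "A"),
                 dam = c(NA, NA, "B", "B", "A"))
}

# small clonal trial: g genotypes x r reps, one bed of one plot per rep,
# with known effects (used where an analytic expectation exists)
toy_trial <- function(g = 6, r = 3, seed = 1, bed_sd = 0, e_sd = 0.5,
                      gen_effects = NULL) {
  set.seed(seed)
  if (is.null(gen_effects)) gen_effects <- rnorm(g)
  rows <- expand.grid(genotype = paste0("g", seq_len(g)),
                      rep = paste0("R", seq_len(r)))
  rows$trial <- "T1"
  rows$bed <- "B1"
  rows$plot <- "S1"
  rows$family <- "famA"
  rows$trait <- gen_effects[as.integer(factor(rows$genotype))] +
    rnorm(nrow(rows), 0, e_sd)
  rows
}
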