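#' Simulation configuration for a clonal breeding population
#'
#' Defaults emulate the structure of a strawberry-like breeding program:
#' a circular mating design among the parents, markers spread over 28
#' linkage groups of about 60 cM (a genome of ~1700 cM), founder LD
#' decaying over roughly 10 cM, traits with many small-effect QTL, and
#' clonally replicated trials with beds and subplots as nuisance strata.
#' Population sizes are scaled-down stand-ins for seedling-trial
#' magnitudes so that end-to-end analyses run at desk scale; every
#' stochastic call takes the seed from the config.
#'
#' @param n_parents parents in the circular mating design.
#' @param progeny_per_cross full sibs per cross.
#' @param pedigree_depth 1 = parents are unrelated founders; 2 (default) =
#'   parents are themselves a circular-mating generation bred from
#'   unrelated grandparents, so tested families are linked through shared
#'   ancestors as in a long-running breeding program. Ancestry depth is
#'   what identifies additive variance against family and clone effects.
#' @param n_markers,n_lgs,lg_length_cm marker panel geometry.
#' @param block_length_cm founder-LD copy-chain scale (adjacent-marker
#'   allele copying decays as `exp(-d / block_length_cm)`).
#' @param freq_range founder allele-frequency law (uniform on this range).
#' @param n_qtl QTL per trait, drawn from the marker panel.
#' @param h2 target within-trial narrow-sense heritability.
#' @param family_frac,clone_frac non-additive family and
#'   clone-within-family variance fractions.
#' @param bed_frac,plot_frac design-strata variance fractions.
#' @param n_reps,beds_per_rep,plot_size clonal replicates, beds per
#'   replicate, single-plant plots per subplot.
#' @param type_b target cross-trial Type-B additive correlation
#'   (two-trial mode).
#' @param trial_overlap fraction of genotypes tested in both trials
#'   (two-trial mode); the remainder is split between trials, mirroring
#'   paired trials that share checks and some selections but consist
#'   mostly of different individuals.
#' @param covariate_beta transplant-weight effect (per g, on the trait
#'   scale); 0 disables the covariate.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 22, progeny_per_cross = 10,
                       pedigree_depth = 2,
                       n_markers = 2000, n_lgs = 28, lg_length_cm = 60,
                       block_length_cm = 10, freq_range = c(0.1, 0.9),
                       n_qtl = 100, h2 = 0.25, family_frac = 0.10,
                       clone_frac = 0.10, bed_frac = 0.05,
                       plot_frac = 0.05, n_reps = 3, beds_per_rep = 3,
                       plot_size = 8, type_b = 1, trial_overlap = 0.2,
                       covariate_beta = 0, seed = 1) {
  cfg <- list(n_parents = n_parents, progeny_per_cross = progeny_per_cross,
              pedigree_depth = pedigree_depth,
              n_markers = n_markers, n_lgs = n_lgs,
              lg_length_cm = lg_length_cm,
              block_length_cm = block_length_cm, freq_range = freq_range,
              n_qtl = n_qtl, h2 = h2, family_frac = family_frac,
              clone_frac = clone_frac, bed_frac = bed_frac,
              plot_frac = plot_frac, n_reps = n_reps,
              beds_per_rep = beds_per_rep, plot_size = plot_size,
              type_b = type_b, trial_overlap = trial_overlap,
              covariate_beta = covariate_beta, seed = seed)
  if (trial_overlap < 0 || trial_overlap > 1) stop("trial_overlap in [0, 1]")
  frac <- h2 + family_frac + clone_frac + bed_frac + plot_frac
  if (frac > 1) stop("variance fractions exceed 1")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (type_b <= 0 || type_b > 1) stop("type_b must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate founder haplotypes with decaying LD
#'
#' Markers are placed uniformly at random along each linkage group. Each
#' founder haplotype is generated by a copy chain: the allele at a marker
#' copies the previous marker's allele with probability
#' `exp(-d / block_length_cm)` (d = map distance) and is otherwise a
#' fresh Bernoulli draw at that marker's target frequency, giving LD that
#' decays with map distance and vanishes as the block length goes to 0.
#'
#' @param cfg a [sim_config()]; `founder_ids` overrides the default
#'   parent labels.
#' @param founder_ids optional character labels (default
#'   `P1..P{n_parents}`).
#' @return list with `h1`, `h2` (founder x marker 0/1 matrices), `map`
#'   (a [genetic_map()]), `target_freqs`.
#' @export
simulate_founder_haplotypes <- function(cfg, founder_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_markers < 1 || cfg$n_parents < 1) stop("need markers and founders")
  set.seed(cfg$seed)
  if (is.null(founder_ids)) founder_ids <- paste0("P", seq_len(cfg$n_parents))
  n_f <- length(founder_ids)
  per_lg <- diff(round(seq(0, cfg$n_markers, length.out = cfg$n_lgs + 1)))
  mk <- character(0); lg <- character(0); pos <- numeric(0)
  for (g in seq_len(cfg$n_lgs)) {
    if (per_lg[g] == 0) next
    p <- sort(runif(per_lg[g], 0, cfg$lg_length_cm))
    lgname <- paste0("LG", g)
    mk <- c(mk, paste0(lgname, "_m", seq_len(per_lg[g])))
    lg <- c(lg, rep(lgname, per_lg[g]))
    pos <- c(pos, p)
  }
  map <- genetic_map(mk, lg, pos)
  p_tgt <- runif(nrow(map), cfg$freq_range[1], cfg$freq_range[2])
  n_hap <- 2 * n_f
  H <- matrix(0L, n_hap, nrow(map))
  start <- 0L
  for (g in unique(map$lg)) {
    idx <- which(map$lg == g)
    d <- diff(map$cm[idx])
    rho <- if (cfg$block_length_cm > 0) exp(-d / cfg$block_length_cm)
           else rep(0, length(d))
    H[, idx[1]] <- rbinom(n_hap, 1, p_tgt[idx[1]])
    for (i in seq_along(d)) {
      copy <- runif(n_hap) < rho[i]
      fresh <- rbinom(n_hap, 1, p_tgt[idx[i + 1]])
      H[, idx[i + 1]] <- ifelse(copy, H[, idx[i]], fresh)
    }
  }
  h1 <- H[seq(1, n_hap, 2), , drop = FALSE]
  h2 <- H[seq(2, n_hap, 2), , drop = FALSE]
  dimnames(h1) <- dimnames(h2) <- list(founder_ids, map$marker)
  list(h1 = h1, h2 = h2, map = map, target_freqs = p_tgt)
}

#' Circular mating pedigree
#'
#' Crosses parent i with parent i+1, closing the circle
#' (`(1,2), (2,3), ..., (n,1)`), with `progeny_per_cross` full sibs per
#' cross; `extra_crosses` (a two-column matrix of parent labels) appends
#' additional matings.
#'
#' @param parent_ids at least 3 unique labels.
#' @param progeny_per_cross full sibs per family.
#' @param extra_crosses optional matrix/data.frame of additional
#'   (sire, dam) pairs.
#' @return a [pedigree_table()] of founders and progeny; progeny ids are
#'   `F{family}_{k}`.
#' @export
make_circular_pedigree <- function(parent_ids, progeny_per_cross = 10,
                                   extra_crosses = NULL) {
  parent_ids <- as.character(parent_ids)
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  n <- length(parent_ids)
  if (n < 3) stop("a circular mating design needs at least 3 parents")
  crosses <- cbind(parent_ids, parent_ids[c(2:n, 1)])
  if (!is.null(extra_crosses))
    crosses <- rbind(crosses, as.matrix(extra_crosses))
  id <- parent_ids; sire <- rep(NA_character_, n); dam <- sire
  for (f in seq_len(nrow(crosses))) {
    kid <- paste0("F", f, "_", seq_len(progeny_per_cross))
    id <- c(id, kid)
    sire <- c(sire, rep(crosses[f, 1], progeny_per_cross))
    dam <- c(dam, rep(crosses[f, 2], progeny_per_cross))
  }
  pedigree_table(id, sire, dam)
}

#' Drop genes through a pedigree
#'
#' Mendelian transmission with Haldane recombination: the crossover
#' probability between adjacent markers at map distance d cM is
#' `0.5 * (1 - exp(-2 d / 100))`; each gamete starts from a random
#' parental haplotype per linkage group.
#'
#' @param ped a [pedigree_table()]; its founders must all have haplotypes.
#' @param founders output of [simulate_founder_haplotypes()].
#' @param seed integer seed.
#' @return list with `markers` (a [marker_matrix()] of dosages for every
#'   pedigree member) and `h1`, `h2` (haplotypes, for allele-frequency
#'   book-keeping).
#' @export
gene_drop <- function(ped, founders, seed = 1) {
  stopifnot(inherits(ped, "pedigree_table"))
  map <- founders$map
  M <- nrow(map)
  if (ncol(founders$h1) != M) stop("marker/map mismatch")
  set.seed(seed)
  n <- nrow(ped)
  H1 <- matrix(0L, n, M, dimnames = list(ped$id, map$marker))
  H2 <- H1
  lg_idx <- split(seq_len(M), map$lg)
  rec_frac <- lapply(lg_idx, function(ix)
    0.5 * (1 - exp(-2 * diff(map$cm[ix]) / 100)))
  founder_rows <- match(rownames(founders$h1), ped$id)
  if (anyNA(founder_rows[ped$id[is.na(ped$sire)] %in% rownames(founders$h1)]))
    stop("founder haplotypes do not cover pedigree founders")
  gamete <- function(h1, h2) {
    g <- integer(M)
    for (l in seq_along(lg_idx)) {
      ix <- lg_idx[[l]]
      cr <- rec_frac[[l]]
      x <- c(rbinom(1, 1, 0.5), rbinom(length(cr), 1, cr))
      phase <- cumsum(x) %% 2
      g[ix] <- ifelse(phase == 0, h1[ix], h2[ix])
    }
    g
  }
  sp <- match(ped$sire, ped$id); dp <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (is.na(sp[i]) && is.na(dp[i])) {
      r <- match(ped$id[i], rownames(founders$h1))
      if (is.na(r)) stop("no haplotypes for founder ", ped$id[i])
      H1[i, ] <- founders$h1[r, ]
      H2[i, ] <- founders$h2[r, ]
    } else {
      if (is.na(sp[i]) || is.na(dp[i]))
        stop("individual with a single known parent: ", ped$id[i])
      H1[i, ] <- gamete(H1[sp[i], ], H2[sp[i], ])
      H2[i, ] <- gamete(H1[dp[i], ], H2[dp[i], ])
    }
  }
  list(markers = marker_matrix(H1 + H2), h1 = H1, h2 = H2)
}

# polygenic draw down the pedigree: founders ~ N(0, s2), offspring =
# mid-parent + Mendelian sampling N(0, s2/2); marginal variance s2 for
# non-inbred pedigrees
.polygenic_draw <- function(ped, s2) {
  n <- nrow(ped)
  sp <- match(ped$sire, ped$id); dp <- match(ped$dam, ped$id)
  g <- numeric(n)
  for (i in seq_len(n)) {
    g[i] <- if (is.na(sp[i])) rnorm(1, 0, sqrt(s2))
            else 0.5 * (g[sp[i]] + g[dp[i]]) + rnorm(1, 0, sqrt(s2 / 2))
  }
  setNames(g, ped$id)
}

# family label per pedigree member (cross of the parents; founders alone)
.family_of <- function(ped) {
  fam <- ifelse(is.na(ped$sire), paste0("fam_", ped$id),
                paste0("fam_", ped$sire, "x", ped$dam))
  setNames(fam, ped$id)
}

#' Simulate clonally replicated trial phenotypes
#'
#' Builds one or two randomized-complete-block trials over the given
#' genotypes. The additive genetic value is the sum of `n_qtl` marker
#' effects rescaled so its empirical variance hits the target; in
#' two-trial mode the marker-determined part is shared across trials and
#' a pedigree-polygenic genotype-by-trial deviation is added so that
#' `type_b = shared additive variance / within-trial additive variance`.
#' Family and clone-within-family deviations, bed and subplot effects and
#' plot residuals are iid normal at the configured variance fractions
#' (total phenotypic variance 1). The transplant-weight covariate, when
#' enabled, is drawn per plot and only recorded in trial 1 (mirroring a
#' seedling trial where transplants are weighed).
#'
#' @param m a [marker_matrix()] of the genotypes to field-test.
#' @param ped the [pedigree_table()] (source of family labels).
#' @param cfg a [sim_config()].
#' @param n_trials 1 or 2.
#' @param genotype_ids which individuals to test (default: all
#'   non-founders in `m`).
#' @return list with `data` (plot-level data.frame with trait column
#'   `trait`), and `truth`: true breeding values (`tbv_shared`,
#'   `tbv_by_trial`), QTL ids and effects, the component values, and the
#'   realised Type-B ratio.
#' @export
simulate_phenotypes <- function(m, ped, cfg, n_trials = 1,
                                genotype_ids = NULL) {
  stopifnot(inherits(m, "marker_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  if (is.null(genotype_ids))
    genotype_ids <- ped$id[!is.na(ped$sire)]
  gen <- as.character(genotype_ids)
  d <- m$dosages[gen, , drop = FALSE]
  ng <- length(gen)
  if (cfg$n_qtl > ncol(d)) stop("more QTL than markers")

  qtl <- sample(colnames(d), cfg$n_qtl)
  eff <- rnorm(cfg$n_qtl)
  raw <- as.numeric(scale(d[, qtl, drop = FALSE] %*% eff))
  sa_within <- cfg$h2                       # total variance is 1
  sa_shared <- cfg$type_b * sa_within
  sa_gxe <- sa_within - sa_shared
  tbv_shared <- raw * sqrt(sa_shared)
  names(tbv_shared) <- gen

  fam <- .family_of(ped)[gen]
  fam_levels <- unique(fam)
  fam_eff <- setNames(rnorm(length(fam_levels), 0, sqrt(cfg$family_frac)),
                      fam_levels)
  clone_eff <- setNames(rnorm(ng, 0, sqrt(cfg$clone_frac)), gen)

  resid_frac <- 1 - cfg$h2 - cfg$family_frac - cfg$clone_frac -
    cfg$bed_frac - cfg$plot_frac

  # genotype-to-trial assignment: shared checks plus a split of the rest
  gen_by_trial <- list(gen)
  if (n_trials == 2) {
    shared <- sample(gen, round(cfg$trial_overlap * ng))
    rest <- setdiff(gen, shared)
    half <- sample(rest, floor(length(rest) / 2))
    gen_by_trial <- list(c(shared, half), c(shared, setdiff(rest, half)))
  } else if (n_trials > 2) stop("n_trials must be 1 or 2")

  rows <- list()
  tbv_by_trial <- list()
  for (tr in seq_len(n_trials)) {
    trial_id <- paste0("T", tr)
    gen_t <- gen_by_trial[[tr]]
    # trial-specific additive deviations are themselves additive, so they
    # are drawn as a pedigree polygenic effect (not iid noise)
    gxe <- if (sa_gxe > 0) .polygenic_draw(ped, sa_gxe)[gen]
           else setNames(numeric(ng), gen)
    tbv_t <- tbv_shared + gxe
    tbv_by_trial[[trial_id]] <- setNames(tbv_t, gen)
    nt <- length(gen_t)
    for (r in seq_len(cfg$n_reps)) {
      ord <- sample(gen_t)
      n_beds <- cfg$beds_per_rep
      bed_of <- rep(seq_len(n_beds), length.out = nt)[order(runif(nt))]
      bed_eff <- rnorm(n_beds, 0, sqrt(cfg$bed_frac))
      for (b in seq_len(n_beds)) {
        inbed <- ord[bed_of == b]
        if (!length(inbed)) next
        n_plots <- max(1, ceiling(length(inbed) / cfg$plot_size))
        plot_of <- rep(seq_len(n_plots), each = cfg$plot_size,
                       length.out = length(inbed))
        plot_eff <- rnorm(n_plots, 0, sqrt(cfg$plot_frac))
        w <- if (cfg$covariate_beta != 0 && tr == 1)
          rnorm(length(inbed), 10, 2) else rep(NA_real_, length(inbed))
        e <- rnorm(length(inbed), 0, sqrt(resid_frac))
        y <- tbv_t[inbed] + fam_eff[fam[inbed]] + clone_eff[inbed] +
          bed_eff[b] + plot_eff[plot_of] + e +
          ifelse(is.na(w), 0, cfg$covariate_beta * w)
        rows[[length(rows) + 1]] <- data.frame(
          trial = trial_id, rep = paste0("R", r), bed = paste0("B", b),
          plot = paste0("S", plot_of), genotype = inbed,
          family = fam[inbed], weight = w, trait = as.numeric(y),
          stringsAsFactors = FALSE)
      }
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- list(tbv_shared = tbv_shared, tbv_by_trial = tbv_by_trial,
                qtl = qtl, qtl_effects = eff,
                components = c(additive_within = sa_within,
                               additive_shared = sa_shared,
                               additive_gxe = sa_gxe,
                               family = cfg$family_frac,
                               clone = cfg$clone_frac,
                               bed = cfg$bed_frac, plot = cfg$plot_frac,
                               residual = resid_frac),
                type_b = cfg$type_b,
                family_of = fam,
                family_effects = fam_eff, clone_effects = clone_eff)
  list(data = data, truth = truth)
}

#' Simulate a complete breeding-trial dataset
#'
#' Convenience wrapper: founder haplotypes, circular pedigree, gene drop
#' and trial phenotypes in one call.
#'
#' @param cfg a [sim_config()].
#' @param n_trials 1 or 2.
#' @return list with `markers`, `ped`, `map`, `data`, `truth`, `founders`.
#' @export
simulate_breeding_trials <- function(cfg = sim_config(), n_trials = 1) {
  founders <- simulate_founder_haplotypes(cfg)
  fnd <- rownames(founders$h1)
  if (isTRUE(cfg$pedigree_depth >= 2)) {
    # parents are themselves a circular generation from the founders, so
    # the tested families share grandparents (half-sib links between
    # neighbouring parents)
    n <- length(fnd)
    parents <- paste0("Q", seq_len(n))
    g1 <- data.frame(id = parents, sire = fnd, dam = fnd[c(2:n, 1)],
                     stringsAsFactors = FALSE)
    g2_s <- rep(parents, each = cfg$progeny_per_cross)
    g2_d <- rep(parents[c(2:n, 1)], each = cfg$progeny_per_cross)
    g2 <- data.frame(
      id = paste0("F", rep(seq_len(n), each = cfg$progeny_per_cross), "_",
                  rep(seq_len(cfg$progeny_per_cross), n)),
      sire = g2_s, dam = g2_d, stringsAsFactors = FALSE)
    ped <- pedigree_table(rbind(
      data.frame(id = fnd, sire = NA_character_, dam = NA_character_,
                 stringsAsFactors = FALSE), g1, g2))
    tested <- g2$id
  } else {
    ped <- make_circular_pedigree(fnd, cfg$progeny_per_cross)
    tested <- ped$id[!is.na(ped$sire)]
  }
  drop <- gene_drop(ped, founders, seed = cfg$seed + 2L)
  sim <- simulate_phenotypes(drop$markers, ped, cfg, n_trials = n_trials,
                             genotype_ids = tested)
  list(markers = drop$markers, ped = ped, map = founders$map,
       data = sim$data, truth = sim$truth, founders = founders)
}
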