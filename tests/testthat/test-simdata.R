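test_that("circular pedigree wraps around and validates", {
  ped <- make_circular_pedigree(paste0("P", 1:4), progeny_per_cross = 2)
  crosses <- unique(ped[!is.na(ped$sire), c("sire", "dam")])
  expect_equal(nrow(crosses), 4)
  expect_true(all(paste0("P", c(1, 2, 3, 4)) == crosses$sire))
  expect_equal(crosses$dam, paste0("P", c(2, 3, 4, 1)))

  ped22 <- make_circular_pedigree(paste0("P", 1:22), progeny_per_cross = 1)
  fams <- unique(ped22[!is.na(ped22$sire), c("sire", "dam")])
  expect_equal(nrow(fams), 22)

  expect_error(make_circular_pedigree(c("a", "b")), "at least 3")
  expect_error(make_circular_pedigree(c("a", "a", "b")), "duplicate")
})

test_that("founder haplotypes are reproducible with controlled LD", {
  cfg <- sim_config(n_parents = 50, n_markers = 200, n_lgs = 2, seed = 7)
  f1 <- simulate_founder_haplotypes(cfg)
  f2 <- simulate_founder_haplotypes(cfg)
  expect_identical(f1$h1, f2$h1)
  expect_identical(f1$map, f2$map)

  # no-LD limit: adjacent-marker r2 near zero when block length -> 0
  cfg0 <- sim_config(n_parents = 1000, n_markers = 60, n_lgs = 1,
                     block_length_cm = 0, seed = 8)
  f0 <- simulate_founder_haplotypes(cfg0)
  m0 <- marker_matrix(f0$h1 + f0$h2)
  adj <- sapply(seq_len(59), function(j)
    cor(m0$dosages[, j], m0$dosages[, j + 1])^2)
  expect_lt(mean(adj), 0.01)

  # blocky founders: short-range LD exceeds long-range LD
  cfgB <- sim_config(n_parents = 1000, n_markers = 120, n_lgs = 1,
                     lg_length_cm = 60, block_length_cm = 5, seed = 9)
  fB <- simulate_founder_haplotypes(cfgB)
  mB <- marker_matrix(fB$h1 + fB$h2)
  ld <- pairwise_r2(mB, fB$map, "LG1")
  near <- ld$r2[ld$dist_cm < 1]; far <- ld$r2[ld$dist_cm > 10]
  expect_gt(mean(near), mean(far))
})

test_that("gene drop follows Mendel and Haldane", {
  # zero map distance: every gamete is an intact parental haplotype
  cfg <- sim_config(n_parents = 4, n_markers = 30, n_lgs = 1, seed = 3)
  f <- simulate_founder_haplotypes(cfg)
  f$map$cm[] <- 0
  ped <- make_circular_pedigree(rownames(f$h1), 5)
  gd <- gene_drop(ped, f, seed = 4)
  prog <- ped$id[!is.na(ped$sire)]
  for (id in prog[1:5]) {
    s <- ped$sire[ped$id == id]
    ok <- any(sapply(list(f$h1[s, ], f$h2[s, ]),
                     function(h) all(gd$h1[id, ] == h)))
    expect_true(ok)
  }

  # Haldane: d = 50 cM -> recombination fraction 0.5(1 - exp(-1))
  expect_equal(0.5 * (1 - exp(-2 * 50 / 100)), 0.3160603, tolerance = 1e-6)
  cfg2 <- sim_config(n_parents = 3, n_markers = 2, n_lgs = 1,
                     lg_length_cm = 50, seed = 5)
  f2 <- simulate_founder_haplotypes(cfg2)
  f2$map$cm <- c(0, 50)
  # make parent haplotypes distinguishable: h1 = 11, h2 = 00
  f2$h1[] <- 1L; f2$h2[] <- 0L
  ped2 <- make_circular_pedigree(rownames(f2$h1), 2000)
  gd2 <- gene_drop(ped2, f2, seed = 6)
  gam <- gd2$h1[ped2$id[!is.na(ped2$sire)], ]
  rec <- mean(gam[, 1] != gam[, 2])
  expect_equal(rec, 0.316, tolerance = 0.03)

  # allele frequencies conserved in expectation through meiosis
  cfg3 <- sim_config(n_parents = 60, n_markers = 300, n_lgs = 3, seed = 11)
  f3 <- simulate_founder_haplotypes(cfg3)
  ped3 <- make_circular_pedigree(rownames(f3$h1), 10)
  gd3 <- gene_drop(ped3, f3, seed = 12)
  founder_p <- colMeans(f3$h1 + f3$h2) / 2
  prog_p <- colMeans(gd3$markers$dosages[ped3$id[!is.na(ped3$sire)], ]) / 2
  expect_equal(mean(prog_p - founder_p), 0, tolerance = 0.01)
  expect_gt(cor(founder_p, prog_p), 0.9)
})

test_that("full sibs average genomic relationship near 0.5 with base frequencies", {
  cfg <- sim_config(n_parents = 150, n_markers = 2000, seed = 13)
  f <- simulate_founder_haplotypes(cfg)
  ped <- make_circular_pedigree(rownames(f$h1), 4)
  gd <- gene_drop(ped, f, seed = 14)
  pf <- colMeans(f$h1 + f$h2) / 2
  keep <- pf > 0.05 & pf < 0.95
  m <- marker_matrix(gd$markers$dosages[, keep])
  fam <- clonalGS:::.family_of(ped)
  prog <- ped$id[!is.na(ped$sire)]
  G <- grm_yang(marker_matrix(m$dosages[prog, ]), freqs = pf[keep])$values
  offd <- c()
  for (fm in unique(fam[prog])) {
    ids <- prog[fam[prog] == fm]
    g <- G[ids, ids]
    offd <- c(offd, g[upper.tri(g)])
  }
  expect_equal(mean(offd), 0.5, tolerance = 0.05)
})

test_that("simulated phenotypes carry the requested architecture", {
  # no noise, no design effects, single replicate: phenotype = genetic value
  cfg <- sim_config(n_parents = 10, progeny_per_cross = 6, n_markers = 300,
                    h2 = 0.6, family_frac = 0.2, clone_frac = 0.2,
                    bed_frac = 0, plot_frac = 0, n_reps = 1, seed = 17)
  sim <- simulate_breeding_trials(cfg)
  tr <- sim$truth
  gen <- sim$data$genotype
  total_genetic <- tr$tbv_by_trial$T1[gen] +
    tr$family_effects[tr$family_of[gen]] + tr$clone_effects[gen]
  expect_equal(unname(sim$data$trait), unname(total_genetic),
               tolerance = 1e-10)

  # empirical additive variance matches the target at larger n
  cfg2 <- sim_config(n_parents = 40, progeny_per_cross = 30,
                     n_markers = 800, h2 = 0.4, seed = 18)
  sim2 <- simulate_breeding_trials(cfg2)
  expect_equal(var(sim2$truth$tbv_by_trial$T1), 0.4, tolerance = 0.03)
  # shared part variance equals type_b * within-trial additive variance
  expect_equal(var(sim2$truth$tbv_shared), 0.4 * 1.0, tolerance = 0.03)

  # two-trial mode: overlap fraction and type-B variance split
  cfg3 <- sim_config(n_parents = 20, progeny_per_cross = 10,
                     n_markers = 400, h2 = 0.4, type_b = 0.6,
                     trial_overlap = 0.2, seed = 19)
  sim3 <- simulate_breeding_trials(cfg3, n_trials = 2)
  g1 <- unique(sim3$data$genotype[sim3$data$trial == "T1"])
  g2 <- unique(sim3$data$genotype[sim3$data$trial == "T2"])
  expect_equal(length(intersect(g1, g2)), round(0.2 * 200))
  expect_equal(var(sim3$truth$tbv_shared) /
                 var(sim3$truth$tbv_by_trial$T1), 0.6, tolerance = 0.15)

  expect_error(simulate_phenotypes(sim3$markers, sim3$ped,
                                   sim_config(n_qtl = 1e6)), "QTL")
})

test_that("the same seed reproduces an identical trial dataset", {
  cfg <- sim_config(n_parents = 8, progeny_per_cross = 4, n_markers = 100,
                    seed = 23)
  s1 <- simulate_breeding_trials(cfg)
  s2 <- simulate_breeding_trials(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$markers$dosages, s2$markers$dosages)
})
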