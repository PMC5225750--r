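map3 <- function() genetic_map(c("m1", "m2", "m3"), rep("LG1", 3),
                               c(0, 1, 11))

test_that("pairwise r2 is the squared dosage correlation", {
  d <- cbind(m1 = c(0, 1, 2, 0), m2 = c(0, 1, 2, 2), m3 = c(0, 1, 2, 0))
  rownames(d) <- paste0("i", 1:4)
  m <- marker_matrix(d)
  ld <- pairwise_r2(m, map3(), "LG1")
  expect_equal(nrow(ld), 3)
  # duplicated column -> r2 = 1
  expect_equal(ld$r2[ld$marker_i == "m1" & ld$marker_j == "m3"], 1)
  # hand Pearson computation
  expect_equal(ld$r2[ld$marker_i == "m1" & ld$marker_j == "m2"],
               cor(d[, 1], d[, 2])^2)
  expect_equal(ld$r2[ld$marker_i == "m1" & ld$marker_j == "m2"],
               0.2066116, tolerance = 1e-6)
  expect_equal(ld$dist_cm, c(1, 11, 10))

  # allele-flip invariance (x -> 2 - x) and order invariance
  mflip <- marker_matrix(cbind(d[, 1, drop = FALSE], 2 - d[, 2, drop = FALSE],
                               d[, 3, drop = FALSE]))
  ldf <- pairwise_r2(mflip, map3(), "LG1")
  expect_equal(ldf$r2, ld$r2, tolerance = 1e-12)

  # independent markers at large n have near-zero r2
  m0 <- rand_markers(10000, 2, seed = 3)
  ld0 <- pairwise_r2(m0, genetic_map(c("m1", "m2"), c("A", "A"), c(0, 5)), "A")
  expect_lt(ld0$r2, 0.001)
})

test_that("identity relatedness leaves rv2 equal to r2", {
  m <- rand_markers(80, 3, seed = 5)
  mapx <- genetic_map(colnames(m$dosages), rep("LG1", 3), c(0, 2, 7))
  v <- relationship_matrix(diag(80))
  rownames(v$values) <- colnames(v$values) <- rownames(m$dosages)
  v$labels <- rownames(m$dosages)
  ld <- corrected_r2(m, mapx, "LG1", v = v)
  expect_equal(ld$rv2, ld$r2, tolerance = 1e-10)
  # any positive multiple of the identity corrects nothing either
  v2 <- relationship_matrix(diag(80) * 3.7)
  rownames(v2$values) <- colnames(v2$values) <- rownames(m$dosages)
  v2$labels <- rownames(m$dosages)
  ld2 <- corrected_r2(m, mapx, "LG1", v = v2)
  expect_equal(ld2$rv2, ld$r2, tolerance = 1e-10)
})

test_that("duplicating every individual inflates r2 but not rv2", {
  set.seed(8)
  n <- 60
  base <- rand_markers(n, 6, seed = 21)
  d <- base$dosages[rep(seq_len(n), each = 2), ]
  rownames(d) <- paste0("i", seq_len(2 * n))
  m <- marker_matrix(d)
  mapx <- genetic_map(colnames(d), rep("LG1", 6), seq(0, 10, length.out = 6))
  # duplication kernel: block-diagonal of 2x2 ones (plus jitter for PSD)
  V <- kronecker(diag(n), matrix(1, 2, 2)) + diag(2 * n) * 1e-3
  dimnames(V) <- list(rownames(d), rownames(d))
  ld_dup <- corrected_r2(m, mapx, "LG1", v = relationship_matrix(V))
  ld_base <- pairwise_r2(base, mapx, "LG1")
  # corrected values recover the deduplicated panel's LD within 10%
  expect_equal(mean(ld_dup$rv2), mean(ld_base$r2), tolerance = 0.1)
})

test_that("family structure inflates r2 relative to rv2", {
  # two diverged families: between-family frequency drift creates
  # spurious LD which the kinship correction removes
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    p1 <- runif(8, 0.1, 0.45); p2 <- p1 + 0.45
    d <- rbind(
      matrix(rbinom(n * 8, 2, rep(p1, each = n)), n, 8),
      matrix(rbinom(n * 8, 2, rep(p2, each = n)), n, 8))
    rownames(d) <- paste0("i", 1:(2 * n))
    colnames(d) <- paste0("m", 1:8)
    m <- marker_matrix(d)
    mapx <- genetic_map(colnames(d), rep("LG1", 8),
                        seq(0, 14, length.out = 8))
    V <- kronecker(diag(2), matrix(0.5, n, n)) + diag(2 * n) * 0.5
    dimnames(V) <- list(rownames(d), rownames(d))
    ld <- corrected_r2(m, mapx, "LG1", v = relationship_matrix(V))
    if (mean(ld$rv2) < mean(ld$r2)) wins <- wins + 1
  }
  expect_gte(wins, 15)
})

test_that("decay profile bins distances and averages correctly", {
  ld <- data.frame(lg = "LG1", marker_i = c("a", "a"), marker_j = c("b", "c"),
                   dist_cm = c(1, 11), r2 = c(0.5, 0.1))
  prof <- ld_decay_profile(ld, bin_width = 10)
  expect_equal(prof$bins$n_pairs, c(1L, 1L))
  expect_equal(prof$bins$mean_r2, c(0.5, 0.1))
  expect_equal(unname(prof$overall["mean_r2"]), 0.3)

  # all pairs in one bin: bin mean equals the overall mean
  prof2 <- ld_decay_profile(ld, bin_width = 20)
  expect_equal(prof2$bins$mean_r2[1], 0.3)
})

test_that("block-structured founder LD decays over the first bins", {
  ok <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_parents = 80, n_markers = 300, n_lgs = 4,
                      lg_length_cm = 40, block_length_cm = 5, seed = s)
    f <- simulate_founder_haplotypes(cfg)
    m <- marker_matrix(f$h1 + f$h2)
    keep <- m$freqs > 0.05 & m$freqs < 0.95
    m <- marker_matrix(m$dosages[, keep])
    ld <- pairwise_r2(m, f$map, "LG1")
    prof <- ld_decay_profile(ld, bin_width = 5)
    mr <- prof$bins$mean_r2[1:3]
    if (all(diff(mr) <= 0)) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("published map density matches its printed value", {
  ms <- published_map_summary()
  dens <- ms[["n_mapped_snps"]] / ms[["total_map_length_cm"]]
  expect_equal(round(dens, 2), 2.86)
})
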