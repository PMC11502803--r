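test_that("internal distance profile is exact on rods and tiny hand-built cases", {
  rod <- generate_ensemble(ensemble_spec("rod", 50, 1, 0.55))
  prof <- internal_distance_profile(rod)
  expect_equal(prof$r, 0.55 * prof$s, tolerance = 1e-12)
  expect_equal(prof$n_pairs, 50 - prof$s)
  # single conformation of 3 collinear unit-spaced beads
  m <- cbind(0:2, 0, 0)
  p3 <- internal_distance_profile(m)
  expect_equal(p3$r, c(1, 2))
  # ideal chains follow sqrt(s) within sampling error
  id <- generate_ensemble(ensemble_spec("ideal", 100, 500, 0.55, seed = 4))
  pid <- internal_distance_profile(id)
  expect_equal(pid$r / (0.55 * sqrt(pid$s)), rep(1, 99), tolerance = 0.05)
})

test_that("flory fit is exact on noiseless power-law profiles", {
  s <- 1:365
  for (b in c(0.1, 0.55, 1.0)) for (nu in c(0.2, 0.42, 0.5, 1.0)) {
    prof <- data.frame(s = s, r = b * s^nu, n_pairs = 1)
    free <- fit_flory(prof, "free", min_sep = 0)
    expect_equal(free$nu, nu, tolerance = 1e-10)
    expect_equal(free$b, b, tolerance = 1e-10)
  }
  # paper mode recovers nu exactly when b matches the true prefactor
  prof <- data.frame(s = s, r = 0.55 * s^0.42, n_pairs = 1)
  pap <- fit_flory(prof, "paper", b_fixed = 0.55, min_sep = 200)
  expect_equal(pap$nu, 0.42, tolerance = 1e-10)
  expect_true(pap$b_fixed)
  expect_equal(pap$n_points, sum(s > 200))
  # rod limit
  rodp <- data.frame(s = s, r = 0.55 * s, n_pairs = 1)
  expect_equal(fit_flory(rodp, "paper", min_sep = 200)$nu, 1, tolerance = 1e-10)
})

test_that("flory fit refuses profiles without separations above min_sep", {
  prof <- data.frame(s = 1:50, r = sqrt(1:50), n_pairs = 1)
  expect_error(fit_flory(prof, "paper", min_sep = 200), "min_sep")
  expect_silent(fit_flory(prof, "free", min_sep = 10))
})

test_that("replica-level fit reports scatter across seeds", {
  profs <- lapply(1:3, function(sd)
    internal_distance_profile(
      generate_ensemble(ensemble_spec("ideal", 80, 200, seed = sd))))
  rep <- fit_flory_replicas(profs, mode = "free", min_sep = 0)
  expect_length(rep$fits, 3)
  expect_equal(rep$nu, 0.5, tolerance = 0.03)
  expect_gt(rep$nu_sd, 0)
})

test_that("radius of gyration matches its definition", {
  expect_equal(radius_of_gyration(matrix(1, 5, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  # mass weighting moves the centre of mass
  expect_equal(radius_of_gyration(two, masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
  set.seed(8)
  m <- matrix(rnorm(30), 10, 3)
  w <- runif(10, 0.5, 2)
  com <- colSums(m * w) / sum(w)
  brute <- sqrt(sum(w * rowSums((m - matrix(com, 10, 3, byrow = TRUE))^2)) / sum(w))
  expect_equal(radius_of_gyration(m, w), brute)
  # ensemble form returns a distribution with summary attributes
  e <- generate_ensemble(ensemble_spec("ideal", 30, 25, seed = 9))
  rg <- radius_of_gyration(e)
  expect_length(rg, 25)
  expect_equal(attr(rg, "mean"), mean(rg))
})

test_that("turn classification uses a strict 0.7 nm boundary", {
  cl <- turn_classification(c(0.7, 0.699999, 0.700001), cutoff = 0.7)
  expect_equal(cl$compact_fraction, 1 / 3) # exactly 0.7 is extended
  expect_equal(cl$auc_ratio, 0.5)
  all_compact <- turn_classification(rep(0.5, 10))
  expect_equal(all_compact$compact_fraction, 1)
  expect_identical(all_compact$auc_ratio, Inf)
  expect_true(all_compact$all_compact)
  # auc_ratio equals count-below / count-above for any sample
  set.seed(10)
  d <- runif(1000, 0.3, 1.2)
  cl2 <- turn_classification(d)
  expect_equal(cl2$auc_ratio, sum(d < 0.7) / sum(d >= 0.7))
  expect_equal(cl2$auc_ratio,
               cl2$compact_fraction / (1 - cl2$compact_fraction))
})

test_that("turn metrics extract motif bead distances from a trajectory", {
  # 10-bead chain, motifs at 0-based starts 2 and 5; distances constructed
  f1 <- cbind(seq(0, 2.7, by = 0.3), 0, 0)     # r(i, i+3) = 0.9 -> extended
  f2 <- f1; f2[6, ] <- f2[3, ] + c(0.5, 0, 0)  # motif1 r1-r4 = 0.5 -> compact
  tr <- make_traj(list(f1, f2))
  tm <- turn_metrics(tr, motifs = c(2L, 5L))
  expect_equal(dim(tm$distances), c(2, 2))
  expect_equal(tm$distances[1, ], c(0.9, 0.9))
  expect_equal(tm$distances[2, 1], 0.5)
  expect_equal(tm$per_motif$compact_fraction, c(0.5, 0))
  expect_equal(tm$pooled$compact_fraction, 0.25)
  expect_error(turn_metrics(tr, motifs = c(8L)), "exceed")
})

test_that("mixture recovery through the classifier is within binomial error", {
  d <- turn_distance_mixture(1e5, 0.3, seed = 12)
  expect_equal(turn_classification(d)$compact_fraction, 0.3,
               tolerance = 0.01 / 0.3)
})

test_that("energy map matches closed-form pair energies and stays symmetric", {
  p <- default_params()
  # static single frame: a 4-residue chain bent so residues 1 and 4 sit at
  # the 12-6 minimum distance
  seqs <- build_ctd("cons", 1)[1:4, ]
  class(seqs) <- c("ctd_sequence", "data.frame")
  attr(seqs, "variant_label") <- "cons"
  top <- build_topology(seqs, p)
  rmin <- p$sigma * 2^(1 / 6)
  fr <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.38, 0.38, 0), c(rmin, 0, 0))
  tr <- make_traj(list(fr))
  tr$topologies <- list(top)
  em <- residue_energy_map(tr, p)
  expect_identical(em$energy, t(em$energy))
  e14 <- pair_potential(top$type[1], top$type[4], r = rmin, params = p)
  expect_equal(em$energy[1, 4], e14, tolerance = 1e-10)
  # bonded neighbours are excluded, never-in-range pairs exactly zero
  expect_equal(em$energy[1, 2], 0)
  far <- make_traj(list(cbind((0:3) * 2, 0, 0)))
  far$topologies <- list(top)
  expect_true(all(residue_energy_map(far, p)$energy == 0))
})

test_that("energy map highlight threshold is inclusive and sums match total_energy", {
  p <- default_params()
  tr <- fixture_condensed_traj()
  one <- tr; one$frames <- tr$frames[, tr$chain_id == 1, , drop = FALSE]
  one$chain_id <- rep(1L, sum(tr$chain_id == 1))
  one$residue <- tr$residue[tr$chain_id == 1]
  one$is_backbone <- tr$is_backbone[tr$chain_id == 1]
  one$type <- tr$type[tr$chain_id == 1]
  one$topologies <- tr$topologies[1]
  one$box <- NULL # isolated-chain reading of the frames
  em <- residue_energy_map(one, p)
  # grand sum over i < j equals the trajectory-averaged nonbonded total
  tot <- sapply(seq_len(n_frames(one)), function(f) {
    e <- total_energy(get_frame(one, f), one$topologies, p)
    unname(e["nonbonded"] + e["electrostatic"])
  })
  expect_equal(sum(em$energy) / 2, mean(tot), tolerance = 1e-8)
  # inclusive highlight: an entry equal to the threshold is flagged
  nz <- which(em$energy < 0, arr.ind = TRUE)
  v <- em$energy[nz[1, 1], nz[1, 2]]
  em2 <- residue_energy_map(one, p, highlight_threshold = v)
  expect_true(em2$highlight[nz[1, 1], nz[1, 2]])
})

test_that("averaging energy maps weights by frame count", {
  m1 <- structure(list(energy = matrix(c(0, -2, -2, 0), 2),
                       highlight = matrix(FALSE, 2, 2),
                       highlight_threshold = -7, n_frames = 1),
                  class = "energy_map")
  m2 <- structure(list(energy = matrix(c(0, -8, -8, 0), 2),
                       highlight = matrix(FALSE, 2, 2),
                       highlight_threshold = -7, n_frames = 3),
                  class = "energy_map")
  avg <- average_energy_maps(list(m1, m2))
  expect_equal(avg$energy[1, 2], (1 * -2 + 3 * -8) / 4)
  expect_equal(avg$n_frames, 4)
  expect_false(avg$highlight[1, 2]) # -6.5 does not reach -7
})
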