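test_that("topology construction: beads, bonds, charges, phospho side beads", {
  top <- build_topology(build_ctd("cons", 52))
  expect_equal(top$n_beads, 366)
  expect_equal(nrow(top$bonds), 365)
  expect_true(all(top$charge == 0))
  expect_equal(nrow(top$turn_bias), 0)

  p <- default_params()
  ps5 <- build_topology(apply_phosphorylation(build_ctd("cons", 1), 5, -1), p)
  expect_equal(ps5$n_beads, 10)          # 9 residues + 1 side bead
  expect_equal(sum(!ps5$is_backbone), 1)
  side_bond <- ps5$bonds[nrow(ps5$bonds), ]
  expect_equal(ps5$bond_r0[nrow(ps5$bonds)], 0.319)
  expect_equal(ps5$charge[side_bond[2]], -1)
  expect_equal(ps5$residue[side_bond[2]], side_bond[1])
})

test_that("cis-flagged SPXX motifs carry turn-bias restraints", {
  di <- build_ctd("cons", 2)
  expect_equal(nrow(build_topology(assign_proline_isomers(di, "cis-cis"))$turn_bias), 3)
  expect_equal(nrow(build_topology(assign_proline_isomers(di, "cis-trans"))$turn_bias), 2)
  expect_equal(nrow(build_topology(assign_proline_isomers(di, "trans-cis"))$turn_bias), 1)
  expect_equal(nrow(build_topology(di)$turn_bias), 0)
  b <- build_topology(assign_proline_isomers(di, "cis-cis"))$turn_bias
  m <- spxx_motif_residues(di)
  expect_equal(unname(b[, 1]), unname(m[, 1]))
  expect_equal(unname(b[, 2]), unname(m[, 4]))
})

test_that("pair potential is shifted to zero at the cutoff and has the closed-form minimum", {
  p <- default_params()
  expect_equal(pair_potential("Y", "Y", r = p$cutoff, params = p), 0)
  expect_equal(pair_potential("S", "A", r = 2.5, params = p), 0)
  # continuity approaching the cutoff
  expect_lt(abs(pair_potential("Y", "Y", r = p$cutoff - 1e-7, params = p)), 1e-4)
  # analytic value at the 12-6 minimum
  rmin <- p$sigma * 2^(1 / 6)
  eps <- pair_eps_table(p)["Y", "Y"]
  sc6 <- (p$sigma / p$cutoff)^6
  expect_equal(pair_potential("Y", "Y", r = rmin, params = p),
               -eps - 4 * eps * (sc6^2 - sc6), tolerance = 1e-12)
  # sticker hierarchy and symmetry
  tab <- pair_eps_table(p)
  expect_true(tab["Y", "Y"] > tab["F", "F"])
  expect_true(tab["F", "F"] > tab["S", "S"])
  expect_identical(tab, t(tab))
  expect_true(all(tab >= 0))
})

test_that("screened electrostatics decays with the analytic Debye length", {
  p <- default_params()
  lam <- debye_length(p)
  expect_equal(lam, 0.78, tolerance = 0.01)
  # isolate the electrostatic term as the difference charged - neutral
  elec <- function(r)
    pair_potential("SP", "SP", -1, -1, r, p) - pair_potential("SP", "SP", 0, 0, r, p)
  kq <- 138.935458 / p$dielectric
  shift <- exp(-p$elec_cutoff / lam) / p$elec_cutoff
  for (r in c(0.5, 0.7, 0.9, 1.5))
    expect_equal(elec(r), kq * (exp(-r / lam) / r - shift), tolerance = 1e-10)
  expect_gt(elec(0.5), 0) # like charges repel
  # charged pairs vanish beyond the electrostatic cutoff, neutral beyond
  # the 12-6 cutoff
  expect_equal(pair_potential("SP", "SP", -1, -1, p$elec_cutoff, p), 0)
  expect_gt(abs(pair_potential("SP", "SP", -1, -1, 2.0, p)), 0)
})

test_that("zero steps returns the initial configuration unchanged", {
  top <- build_topology(build_ctd("cons", 1))
  x0 <- matrix(rnorm(top$n_beads * 3, sd = 0.1), ncol = 3) +
    matrix(c(0.38 * seq_len(top$n_beads), rep(0, 2 * top$n_beads)), ncol = 3)
  cfg <- sim_config(box = c(6, 6, 6), n_chains = 1, n_steps = 0,
                    init_mode = "preformed", init_coords = x0, seed = 3)
  tr <- run_dynamics(top, cfg)
  expect_equal(n_frames(tr), 1)
  expect_equal(get_frame(tr, 1), x0)
})

test_that("identical seed and config give bit-identical trajectories", {
  top <- build_topology(build_ctd("cons", 1))
  cfg <- sim_config(box = c(6, 6, 6), n_chains = 3, n_steps = 2000,
                    seed = 7, sample_every = 500)
  tr1 <- run_dynamics(top, cfg)
  tr2 <- run_dynamics(top, cfg)
  expect_identical(tr1$frames, tr2$frames)
  tr3 <- run_dynamics(top, sim_config(box = c(6, 6, 6), n_chains = 3,
                                      n_steps = 2000, seed = 8,
                                      sample_every = 500))
  expect_false(identical(tr1$frames, tr3$frames))
})

test_that("thermostat holds the kinetic temperature and bonds stay near equilibrium", {
  tr <- fixture_condensed_traj()
  kt <- tr$kinetic_temperature[-(1:3)]
  expect_lt(abs(mean(kt) - 300) / 300, 0.03)
  sys <- ctdphase:::.assemble_system(tr$topologies)
  for (f in seq_len(n_frames(tr))) {
    m <- get_frame(tr, f)
    d <- sqrt(rowSums((m[sys$bonds[, 1], ] - m[sys$bonds[, 2], ])^2))
    expect_lt(max(abs(d - sys$bond_r0) / sys$bond_r0), 0.20)
  }
})

test_that("total energy matches a brute-force double loop and decomposes", {
  set.seed(5)
  p <- default_params()
  seq <- apply_phosphorylation(build_ctd("cons", 2), 5, -1)
  top <- build_topology(seq, p)
  n <- top$n_beads
  frame <- matrix(runif(n * 3, 0, 3), ncol = 3)
  box <- c(5, 5, 5)
  e <- total_energy(frame, top, p, box)
  expect_equal(unname(e["total"]),
               unname(e["bonded"] + e["nonbonded"] + e["electrostatic"]))
  # independent R-level double loop
  bonded_keys <- paste(pmin(top$bonds[, 1], top$bonds[, 2]),
                       pmax(top$bonds[, 1], top$bonds[, 2]))
  enb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% bonded_keys) next
    r <- mi_dist(frame[i, ], frame[j, ], box)
    enb <- enb + pair_potential(top$type[i], top$type[j],
                                top$charge[i], top$charge[j], r, p)
  }
  expect_equal(unname(e["nonbonded"] + e["electrostatic"]), enb,
               tolerance = 1e-9)
  eb <- 0
  for (b in seq_len(nrow(top$bonds))) {
    r <- mi_dist(frame[top$bonds[b, 1], ], frame[top$bonds[b, 2], ], box)
    eb <- eb + 0.5 * p$k_bond * (r - top$bond_r0[b])^2
  }
  expect_equal(unname(e["bonded"]), eb, tolerance = 1e-9)
})

test_that("bonded energy is zero at equilibrium length and nonbonded zero beyond cutoff", {
  p <- default_params()
  top <- build_topology(build_ctd("cons", 1), p)
  # straight chain with every bond at its equilibrium length
  eq_frame <- cbind(p$bond_length * (seq_len(top$n_beads) - 1), 0, 0)
  e2 <- total_energy(eq_frame, top, p)
  expect_equal(unname(e2["bonded"]), 0, tolerance = 1e-10)
  # spread beads far apart: nonbonded exactly zero
  far <- cbind((seq_len(top$n_beads) - 1) * 2, 0, 0)
  e3 <- total_energy(far, top, p)
  expect_equal(unname(e3["nonbonded"]), 0)
  expect_equal(unname(e3["electrostatic"]), 0)
})

test_that("potential is invariant under whole-system translation by box vectors", {
  set.seed(6)
  p <- default_params()
  top <- build_topology(build_ctd("cons", 2), p)
  frame <- matrix(runif(top$n_beads * 3, 0, 4), ncol = 3)
  box <- c(6, 7, 8)
  e1 <- total_energy(frame, top, p, box)
  shift <- matrix(rep(box * c(2, -1, 3), each = top$n_beads), ncol = 3)
  e2 <- total_energy(frame + shift, top, p, box)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("single consensus chains are more compact than Y1A with stickers on", {
  pp <- default_params()
  nu1 <- function(variant, seed) {
    tr <- run_dynamics(build_topology(build_ctd(variant, 6), pp),
                       sim_config(box = NULL, n_chains = 1,
                                  n_steps = 150000, seed = seed,
                                  sample_every = 500), pp)
    fit_flory(internal_distance_profile(tr, discard_fraction = 0.25),
              "free", min_sep = 4)$nu
  }
  expect_lt(nu1("cons", 21), nu1("Y1A", 22))
})

test_that("ideal-chain limit: all attraction off gives nu near 1/2", {
  pp <- default_params(type_eps = c(Y = 0, F = 0, S = 0, P = 0, T = 0,
                                    A = 0, G = 0, O = 0, pS = 0, SP = 0))
  tr <- run_dynamics(build_topology(build_ctd("cons", 6), pp),
                     sim_config(box = NULL, n_chains = 1, n_steps = 150000,
                                seed = 23, sample_every = 500), pp)
  nu <- fit_flory(internal_distance_profile(tr, discard_fraction = 0.25),
                  "free", min_sep = 4)$nu
  # excluded volume pushes slightly above the ideal-chain value
  expect_gt(nu, 0.45)
  expect_lt(nu, 0.75)
})
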