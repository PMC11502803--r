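# Langevin dynamics driver: BAOAB splitting, Maxwell-Boltzmann velocities,
# random or preformed initial configurations, reproducible from the seed.

#' Simulation configuration
#'
#' @param box periodic box lengths in nm (3-vector), or `NULL` for open
#'   boundaries (single-chain mode). The condensed-phase reference setup is
#'   a 45 nm cube; the desk-scale default is a 12 nm cube.
#' @param n_chains number of chains (topology replicated if a single one is
#'   given)
#' @param n_steps number of integration steps
#' @param timestep ps
#' @param friction Langevin friction, 1/ps
#' @param temperature K
#' @param mass bead mass, g/mol (a reduced CG mass; only sets the time
#'   scale of the dynamics, not the sampled ensemble)
#' @param seed RNG seed; fully determines the run
#' @param init_mode `"random"` (random non-overlapping insertion) or
#'   `"preformed"` (start from `init_coords`, e.g. the final frame of a
#'   previous condensed run)
#' @param init_coords n_beads x 3 matrix for `init_mode = "preformed"`
#' @param sample_every store every this-many steps
#' @param relax_steps initial small-timestep steps to remove insertion
#'   strain (not sampled)
#' @return A `sim_config` list.
#' @export
sim_config <- function(box = c(12, 12, 12), n_chains = 10, n_steps = 200000,
                       timestep = 0.02, friction = 0.2, temperature = 300,
                       mass = 50, seed = 1,
                       init_mode = c("random", "preformed"),
                       init_coords = NULL, sample_every = 2000,
                       relax_steps = 2000) {
  init_mode <- match.arg(init_mode)
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    if (any(box <= 2 * default_params()$cutoff))
      stop("box lengths must exceed twice the nonbonded cutoff", call. = FALSE)
  }
  if (init_mode == "preformed" && is.null(init_coords))
    stop("init_mode = 'preformed' requires init_coords ",
         "(e.g. the final frame of a previous run)", call. = FALSE)
  structure(list(box = box, n_chains = n_chains, n_steps = n_steps,
                 timestep = timestep, friction = friction,
                 temperature = temperature, mass = mass, seed = seed,
                 init_mode = init_mode, init_coords = init_coords,
                 sample_every = sample_every, relax_steps = relax_steps),
            class = "sim_config")
}

# grow one chain as an off-lattice excluded-volume random walk
.grow_chain <- function(tp, params, origin) {
  n_res <- tp$n_residues
  x <- matrix(0, tp$n_beads, 3)
  x[1, ] <- origin
  min2 <- (0.8 * params$sigma)^2
  for (i in 2:n_res) {
    for (try in 1:500) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- x[i - 1, ] + params$bond_length * u
      d2 <- rowSums((x[seq_len(i - 1), , drop = FALSE] -
                     matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (all(d2 > min2 * 0.9)) { x[i, ] <- cand; break }
      if (try == 500) stop("failed to grow chain without overlap")
    }
  }
  side <- which(!tp$is_backbone)
  for (s in side) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    x[s, ] <- x[tp$residue[s], ] + params$phospho_bond_length * u
  }
  x
}

.init_random <- function(topologies, config, params) {
  box <- config$box
  placed <- NULL
  min2 <- (0.8 * params$sigma)^2
  coords <- vector("list", length(topologies))
  for (k in seq_along(topologies)) {
    ok <- FALSE
    for (try in 1:200) {
      origin <- if (is.null(box)) c(0, 0, 0) else runif(3) * box
      x <- .grow_chain(topologies[[k]], params, origin)
      if (is.null(placed) || is.null(box)) { ok <- TRUE }
      else {
        ok <- TRUE
        dx <- outer(x[, 1], placed[, 1], `-`)
        dy <- outer(x[, 2], placed[, 2], `-`)
        dz <- outer(x[, 3], placed[, 3], `-`)
        dx <- dx - box[1] * round(dx / box[1])
        dy <- dy - box[2] * round(dy / box[2])
        dz <- dz - box[3] * round(dz / box[3])
        if (any(dx^2 + dy^2 + dz^2 < min2)) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok) stop("could not insert chain ", k,
                  " without overlap after bounded retries; enlarge the box",
                  call. = FALSE)
    coords[[k]] <- x
    placed <- rbind(placed, x)
  }
  do.call(rbind, coords)
}

#' Run Langevin dynamics
#'
#' Underdamped Langevin dynamics (BAOAB splitting) of one or more CTD
#' chains. Nonbonded interactions are evaluated with a linked-cell search
#' under orthorhombic periodicity (or open boundaries when `config$box` is
#' `NULL`). The run is fully determined by `config$seed`. Coordinates are
#' stored unwrapped, so bonded neighbours remain contiguous across the box.
#'
#' @param topologies a `cg_topology` (replicated `config$n_chains` times) or
#'   a list of per-chain topologies
#' @param config a [sim_config()]
#' @param params an `interaction_params`
#' @return A `cg_trajectory`: list with `frames` (n_frames x n_beads x 3,
#'   nm), `chain_id`, `residue`, `is_backbone`, `type`, `box`,
#'   `sample_every`, `timestep`, `kinetic_temperature` (per frame, K),
#'   `topologies`, `config`, `params_version`.
#' @export
run_dynamics <- function(topologies, config = sim_config(),
                         params = default_params()) {
  if (inherits(topologies, "cg_topology"))
    topologies <- rep(list(topologies), config$n_chains)
  stopifnot(length(topologies) == config$n_chains)
  sys <- .assemble_system(topologies)
  set.seed(config$seed)
  x0 <- if (config$init_mode == "preformed") {
    ic <- as.matrix(config$init_coords)
    if (nrow(ic) != sys$n || ncol(ic) != 3)
      stop("init_coords must be ", sys$n, " x 3 for this system",
           call. = FALSE)
    ic
  } else .init_random(topologies, config, params)

  use_pbc <- !is.null(config$box)
  box <- if (use_pbc) config$box else c(0, 0, 0)
  eps <- pair_eps_table(params)
  kq <- .coulomb_k / params$dielectric
  lam <- debye_length(params)
  ty <- .type_index(sys$type)

  if (config$n_steps > 0 && config$relax_steps > 0) {
    rx <- cpp_run_dynamics(x0, ty, sys$charge, eps, params$sigma,
                           params$cutoff, params$elec_cutoff,
                           params$eps_min * params$solvation_scale, kq, lam,
                           sys$bonds, sys$bond_r0,
                           params$k_bond, sys$bias, use_pbc, box,
                           config$relax_steps, config$timestep / 10,
                           config$friction * 10, config$temperature,
                           config$mass, config$relax_steps, 1e4)
    nf <- dim(rx$frames)[1]
    x0 <- matrix(rx$frames[nf, , ], ncol = 3)
  }
  out <- cpp_run_dynamics(x0, ty, sys$charge, eps, params$sigma,
                          params$cutoff, params$elec_cutoff,
                          params$eps_min * params$solvation_scale, kq, lam,
                          sys$bonds, sys$bond_r0,
                          params$k_bond, sys$bias, use_pbc, box,
                          config$n_steps, config$timestep, config$friction,
                          config$temperature, config$mass,
                          config$sample_every, 0)
  structure(list(
    frames = out$frames, chain_id = sys$chain, residue = sys$residue,
    is_backbone = sys$is_backbone, type = sys$type,
    box = config$box, sample_every = config$sample_every,
    timestep = config$timestep,
    kinetic_temperature = out$kinetic_temperature,
    topologies = topologies, config = config,
    params_version = params$version
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat("CG trajectory: ", d[1], " frames, ", d[2], " beads, ",
      max(x$chain_id), " chain(s), ",
      if (is.null(x$box)) "open boundaries"
      else paste0("box ", paste(signif(x$box, 4), collapse = " x "), " nm"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as a coordinate matrix
#' @param traj a `cg_trajectory`
#' @param i frame index (1-based)
#' @return n_beads x 3 matrix, nm.
#' @export
get_frame <- function(traj, i) {
  d <- dim(traj$frames)
  stopifnot(i >= 1, i <= d[1])
  matrix(traj$frames[i, , ], ncol = 3)
}

#' Initial coordinates for a phospho run from a preformed condensate
#'
#' Maps the final frame of a condensed-phase run onto a new set of
#' topologies for the same chains (e.g. the phosphorylated variant):
#' backbone beads keep their positions, new side beads are placed at the
#' phospho bond length from their parent residue.
#'
#' @param traj a `cg_trajectory` of the source (e.g. unphosphorylated) run
#' @param topologies per-chain topologies of the target system (same chain
#'   count and residue counts)
#' @param params an `interaction_params`
#' @param frame source frame index (default: the final frame)
#' @return Coordinate matrix suitable for `sim_config(init_mode =
#'   "preformed", init_coords = ...)`.
#' @export
preformed_from <- function(traj, topologies, params = default_params(),
                           frame = n_frames(traj)) {
  if (inherits(topologies, "cg_topology"))
    topologies <- rep(list(topologies), max(traj$chain_id))
  last <- get_frame(traj, frame)
  out <- NULL
  for (k in seq_along(topologies)) {
    tp <- topologies[[k]]
    src <- last[traj$chain_id == k & traj$is_backbone, , drop = FALSE]
    if (nrow(src) != tp$n_residues)
      stop("residue count mismatch between source trajectory and topology",
           call. = FALSE)
    x <- matrix(0, tp$n_beads, 3)
    x[tp$is_backbone, ] <- src
    placed <- rbind(out, x[tp$is_backbone, , drop = FALSE])
    for (s in which(!tp$is_backbone)) {
      # best of several directions: maximize clearance from placed beads
      best <- NULL; best_d <- -Inf
      for (try in 1:24) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- x[tp$residue[s], ] + params$phospho_bond_length * u
        d2 <- rowSums((placed - matrix(cand, nrow(placed), 3,
                                       byrow = TRUE))^2)
        d2 <- d2[d2 > 1e-12] # exclude the parent bead itself
        dmin <- sqrt(min(d2))
        if (dmin > best_d) { best_d <- dmin; best <- cand }
      }
      x[s, ] <- best
      placed <- rbind(placed, best)
    }
    out <- rbind(out, x)
  }
  out
}
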