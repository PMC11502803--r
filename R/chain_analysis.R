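# Single-chain structural analyses: radius of gyration, per-residue
# interaction-energy maps, and SPXX beta-turn classification.

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance from the centre of mass. For a
#' single coordinate matrix returns a scalar; for an ensemble or trajectory
#' returns the per-frame distribution with `mean` and `sd` attributes.
#'
#' @param x coordinate matrix (beads x 3), `polymer_ensemble` or
#'   `cg_trajectory`
#' @param masses per-bead masses (equal by default)
#' @param discard_fraction leading fraction of frames to drop
#' @return Scalar or numeric vector (nm).
#' @export
radius_of_gyration <- function(x, masses = NULL, discard_fraction = 0) {
  rg1 <- function(m, w) {
    com <- colSums(m * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(m, 2, com)^2)) / sum(w))
  }
  if (is.matrix(x)) {
    w <- if (is.null(masses)) rep(1, nrow(x)) else masses
    stopifnot(length(w) == nrow(x), nrow(x) >= 1)
    return(rg1(x, w))
  }
  fr <- if (inherits(x, "cg_trajectory")) {
    if (discard_fraction > 0) {
      nf <- dim(x$frames)[1]
      x$frames[seq.int(floor(discard_fraction * nf) + 1L, nf), , ,
               drop = FALSE]
    } else x$frames
  } else .frames_array(x, discard_fraction)
  w <- if (is.null(masses)) rep(1, dim(fr)[2]) else masses
  out <- vapply(seq_len(dim(fr)[1]),
                function(f) rg1(matrix(fr[f, , ], ncol = 3), w), numeric(1))
  attr(out, "mean") <- mean(out)
  attr(out, "sd") <- sd(out)
  out
}

#' Per-residue interaction-energy map
#'
#' Residue-by-residue matrix of the time-averaged nonbonded pair energy
#' (shifted 12-6 plus screened electrostatics); phospho side beads are
#' aggregated onto their parent residue. Entries for pairs never within the
#' cutoff are exactly zero. The highlight mask flags entries at or below
#' -7.0 kJ/mol (strong, persistent contacts).
#'
#' @param traj a single-chain `cg_trajectory`
#' @param params an `interaction_params`
#' @param discard_fraction leading fraction of frames to drop
#' @param highlight_threshold kJ/mol; entries `<= threshold` are flagged
#' @return An `energy_map`: list with `energy` (symmetric matrix, kJ/mol),
#'   `highlight` (logical matrix), `highlight_threshold`, `n_frames`.
#' @export
residue_energy_map <- function(traj, params = default_params(),
                               discard_fraction = 0,
                               highlight_threshold = -7.0) {
  stopifnot(inherits(traj, "cg_trajectory"))
  sys <- .assemble_system(traj$topologies)
  nf <- n_frames(traj)
  keep <- seq.int(floor(discard_fraction * nf) + 1L, nf)
  use_pbc <- !is.null(traj$box)
  box <- if (use_pbc) traj$box else c(0, 0, 0)
  n_res <- sum(traj$is_backbone)
  acc <- matrix(0, n_res, n_res)
  eps <- pair_eps_table(params)
  for (f in keep) {
    acc <- acc + cpp_residue_energy_matrix(
      get_frame(traj, f), .type_index(sys$type), sys$charge,
      sys$residue, eps, params$sigma, params$cutoff, params$elec_cutoff,
      params$eps_min * params$solvation_scale,
      .coulomb_k / params$dielectric, debye_length(params), sys$bonds,
      use_pbc, box, n_res)
  }
  em <- acc / length(keep)
  structure(list(energy = em, highlight = em <= highlight_threshold,
                 highlight_threshold = highlight_threshold,
                 n_frames = length(keep)),
            class = "energy_map")
}

#' Average several energy maps
#'
#' Combines maps from replicas and/or different constructs (frame-count
#' weighted), the reduction used when maps are reported averaged over
#' replicas and all di-heptad constructs.
#'
#' @param maps list of `energy_map`s of identical dimension
#' @return An `energy_map`.
#' @export
average_energy_maps <- function(maps) {
  w <- vapply(maps, `[[`, numeric(1), "n_frames")
  em <- Reduce(`+`, Map(function(m, wi) m$energy * wi, maps, w)) / sum(w)
  structure(list(energy = em,
                 highlight = em <= maps[[1]]$highlight_threshold,
                 highlight_threshold = maps[[1]]$highlight_threshold,
                 n_frames = sum(w)),
            class = "energy_map")
}

#' Classify turn distances against the beta-turn cutoff
#'
#' A motif conformation is compact iff its Calpha1-Calpha4 distance is
#' strictly less than the cutoff (0.7 nm); a distance exactly at the cutoff
#' is extended. The AUC ratio is the empirical mass below the cutoff over
#' the mass above it (`Inf` when nothing lies above, flagged via
#' `all_compact`).
#'
#' @param distances numeric vector of distances, nm
#' @param cutoff nm
#' @return List with `compact_fraction`, `auc_ratio`, `n`, `all_compact`.
#' @export
turn_classification <- function(distances, cutoff = 0.7) {
  stopifnot(length(distances) >= 1)
  below <- sum(distances < cutoff)
  above <- length(distances) - below
  list(compact_fraction = below / length(distances),
       auc_ratio = if (above == 0) Inf else below / above,
       n = length(distances), all_compact = above == 0)
}

#' SPXX beta-turn metrics from a trajectory
#'
#' Distances between the backbone beads at motif positions 1 and 4 (the
#' single bead per residue stands in for the Calpha), per motif and frame,
#' classified against the 0.7 nm cutoff.
#'
#' @param traj a single-chain `cg_trajectory`
#' @param motifs motif residue matrix from [spxx_motif_residues()], or a
#'   vector of 0-based motif start indices as returned by
#'   [find_spxx_motifs()]
#' @param cutoff nm
#' @param discard_fraction leading fraction of frames to drop
#' @return A `turn_distribution`: list with `distances` (frames x motifs),
#'   `cutoff`, `per_motif` data frame (`motif`, `compact_fraction`,
#'   `auc_ratio`), `pooled` (as in [turn_classification()]).
#' @export
turn_metrics <- function(traj, motifs, cutoff = 0.7, discard_fraction = 0) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (!is.matrix(motifs)) {
    motifs <- outer(as.integer(motifs) + 1L, 0:3, `+`)
    colnames(motifs) <- paste0("r", 1:4)
  }
  bb <- which(traj$is_backbone & traj$chain_id == 1L)
  if (max(motifs) > length(bb))
    stop("motif residues exceed the chain length", call. = FALSE)
  nf <- n_frames(traj)
  keep <- seq.int(floor(discard_fraction * nf) + 1L, nf)
  d <- matrix(0, length(keep), nrow(motifs))
  for (k in seq_along(keep)) {
    fr <- get_frame(traj, keep[k])
    a <- fr[bb[motifs[, 1]], , drop = FALSE]
    z <- fr[bb[motifs[, 4]], , drop = FALSE]
    d[k, ] <- sqrt(rowSums((a - z)^2))
  }
  per <- do.call(rbind, lapply(seq_len(ncol(d)), function(m) {
    cl <- turn_classification(d[, m], cutoff)
    data.frame(motif = m, compact_fraction = cl$compact_fraction,
               auc_ratio = cl$auc_ratio)
  }))
  structure(list(distances = d, cutoff = cutoff, per_motif = per,
                 pooled = turn_classification(as.vector(d), cutoff)),
            class = "turn_distribution")
}

#' @export
print.turn_distribution <- function(x, ...) {
  cat(sprintf(
    "SPXX turn distances: %d frames x %d motifs, cutoff %.2f nm\n",
    nrow(x$distances), ncol(x$distances), x$cutoff))
  cat(sprintf("  pooled compact fraction %.3f, AUC ratio %s\n",
              x$pooled$compact_fraction,
              if (x$pooled$all_compact) "Inf (all compact)"
              else sprintf("%.3f", x$pooled$auc_ratio)))
  invisible(x)
}
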