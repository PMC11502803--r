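# Bead/bond topology of a single CTD chain: one backbone bead per residue,
# one charged side bead per phosphoserine, harmonic bonds, and turn-bias
# restraints on SPXX motifs whose proline is cis.

#' Build a chain topology
#'
#' One backbone bead per residue (bead index = residue index), plus one side
#' bead appended per phosphoserine, carrying the phospho charge and bonded
#' to its backbone bead at `phospho_bond_length` (0.319 nm, the lengthened
#' phosphoserine side-chain bond). SPXX motifs whose proline is flagged cis
#' carry a harmonic restraint between motif beads 1 and 4 at `turn_bias_r0`,
#' representing the compact beta-turn state the cis isomer stabilizes.
#'
#' @param seq a `ctd_sequence`
#' @param params an `interaction_params`
#' @return A `cg_topology`: list with `n_beads`, `type`, `charge`, `residue`
#'   (parent residue of each bead), `is_backbone`, `bonds` (2-column matrix),
#'   `bond_r0`, `turn_bias` (matrix with columns i, j, r0, k), `n_residues`,
#'   `variant_label`.
#' @export
build_topology <- function(seq, params = default_params()) {
  stopifnot(inherits(seq, "ctd_sequence"))
  n <- nrow(seq)
  type <- seq$code
  charge <- rep(0, n)
  residue <- seq_len(n)
  is_backbone <- rep(TRUE, n)
  bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  bond_r0 <- rep(params$bond_length, n - 1L)
  ph <- which(seq$is_phospho)
  type[ph] <- "pS" # phosphoserine backbone: hydrophilic, non-sticky
  for (i in ph) {
    type <- c(type, "SP")
    charge <- c(charge, seq$phospho_charge[i])
    residue <- c(residue, i)
    is_backbone <- c(is_backbone, FALSE)
    bonds <- rbind(bonds, c(i, length(type)))
    bond_r0 <- c(bond_r0, params$phospho_bond_length)
  }
  cis <- spxx_motif_is_cis(seq)
  bias <- matrix(numeric(), 0L, 4L)
  if (any(cis)) {
    m <- spxx_motif_residues(seq)[cis, , drop = FALSE]
    bias <- cbind(m[, 1L], m[, 4L], params$turn_bias_r0,
                  params$turn_bias_strength)
  }
  colnames(bias) <- c("i", "j", "r0", "k")
  structure(list(
    n_beads = length(type), type = type, charge = charge, residue = residue,
    is_backbone = is_backbone, bonds = bonds, bond_r0 = bond_r0,
    turn_bias = bias, n_residues = n,
    variant_label = attr(seq, "variant_label")
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology '", x$variant_label, "': ", x$n_beads, " beads (",
      x$n_residues, " residues, ", sum(!x$is_backbone), " phospho side), ",
      nrow(x$bonds), " bonds, ", nrow(x$turn_bias), " turn-bias restraints, ",
      "net charge ", sum(x$charge), "e\n", sep = "")
  invisible(x)
}

# concatenate per-chain topologies into system arrays for the C++ core
.assemble_system <- function(topologies) {
  offs <- 0L
  type <- character(); charge <- numeric(); residue <- integer()
  chain <- integer(); backbone <- logical()
  bonds <- matrix(integer(), 0L, 2L); bond_r0 <- numeric()
  bias <- matrix(numeric(), 0L, 4L)
  for (k in seq_along(topologies)) {
    tp <- topologies[[k]]
    type <- c(type, tp$type)
    charge <- c(charge, tp$charge)
    residue <- c(residue, tp$residue)
    chain <- c(chain, rep(k, tp$n_beads))
    backbone <- c(backbone, tp$is_backbone)
    bonds <- rbind(bonds, tp$bonds + offs)
    bond_r0 <- c(bond_r0, tp$bond_r0)
    if (nrow(tp$turn_bias)) {
      b <- tp$turn_bias
      b[, 1:2] <- b[, 1:2] + offs
      bias <- rbind(bias, b)
    }
    offs <- offs + tp$n_beads
  }
  list(n = offs, type = type, charge = charge, residue = residue,
       chain = chain, is_backbone = backbone, bonds = bonds,
       bond_r0 = bond_r0, bias = bias)
}

.type_index <- function(type) {
  i <- match(type, .bead_types)
  if (anyNA(i)) stop("unknown bead type(s): ",
                     paste(unique(type[is.na(i)]), collapse = ", "))
  i - 1L
}

#' Decomposed potential energy of one frame
#'
#' Bonded (harmonic bonds plus turn-bias restraints), nonbonded (shifted
#' 12-6) and electrostatic (shifted Debye-Hueckel) terms; directly bonded
#' pairs are excluded from the nonbonded sum. Agrees with a brute-force
#' double loop over all pairs.
#'
#' @param frame n_beads x 3 coordinate matrix, nm
#' @param topology a `cg_topology` or list of them (multi-chain system)
#' @param params an `interaction_params`
#' @param box periodic box lengths (3), or `NULL` for open boundaries
#' @return Named vector `bonded`, `nonbonded`, `electrostatic`, `total`.
#' @export
total_energy <- function(frame, topology, params = default_params(),
                         box = NULL) {
  if (inherits(topology, "cg_topology")) topology <- list(topology)
  sys <- .assemble_system(topology)
  stopifnot(nrow(frame) == sys$n, ncol(frame) == 3)
  e <- cpp_total_energy(
    frame, .type_index(sys$type), sys$charge, pair_eps_table(params),
    params$sigma, params$cutoff, params$elec_cutoff,
    params$eps_min * params$solvation_scale,
    .coulomb_k / params$dielectric,
    debye_length(params), sys$bonds, sys$bond_r0, params$k_bond,
    sys$bias, !is.null(box), if (is.null(box)) c(0, 0, 0) else box)
  c(e, total = sum(e))
}
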