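# Interaction parameter set for the sticker-and-spacer CTD model.
# Calibrated once against the qualitative phase behaviour of the default
# condensed-phase setup (consensus condenses, Y1A stays dispersed, phospho-S5
# dissolves a preformed condensate) and frozen; version string tracks edits.

.bead_types <- c("Y", "F", "S", "P", "T", "A", "G", "O", "pS", "SP")

#' Default interaction parameters
#'
#' One bead per residue interacting through a 12-6 potential shifted to zero
#' at the cutoff, with type-dependent well depths following the sticker
#' hierarchy Y > F > spacers > A, plus Debye-Hueckel screened electrostatics
#' for charged phospho side beads (type `SP`). Phosphorylation also turns
#' the serine backbone bead into the non-sticky hydrophilic type `pS`: in
#' an implicit-solvent model a strongly solvated residue appears as one
#' that has lost its protein-protein attraction. Pair well depths are the
#' geometric mean of per-type stickiness values, floored at `eps_min`, and
#' scaled by `solvation_scale` < 1 (enhanced solvation, i.e. weaker
#' effective protein-protein attraction). Pairs sitting at the floor -
#' anything involving alanine, a phosphoserine backbone or a phospho side
#' bead - interact purely repulsively (WCA form: the 12-6 core cut and
#' shifted to zero at its minimum), making those beads fully non-sticky
#' while every pair retains excluded volume.
#'
#' @param ... named overrides of any default field.
#' @return An `interaction_params` list with fields `type_eps` (kJ/mol per
#'   bead type), `eps_min`, `solvation_scale`, `sigma` (nm), `cutoff` (nm),
#'   `elec_cutoff` (nm, screened-Coulomb truncation, about three Debye
#'   lengths), `salt_molar`, `dielectric`, `temperature` (K),
#'   `bond_length` (nm),
#'   `phospho_bond_length` (nm), `k_bond` (kJ/mol/nm^2),
#'   `turn_bias_strength` (kJ/mol/nm^2), `turn_bias_r0` (nm), `version`.
#' @export
default_params <- function(...) {
  p <- list(
    type_eps = c(Y = 11.0, F = 8.8, S = 2.2, P = 2.2, T = 2.2,
                 A = 0.3, G = 1.76, O = 2.2, pS = 0.3, SP = 0.3),
    eps_min = 0.3,
    solvation_scale = 1 / 1.1,
    sigma = 0.47,
    cutoff = 1.1,
    elec_cutoff = 2.5,
    salt_molar = 0.150,
    dielectric = 78,
    temperature = 300,
    bond_length = 0.38,
    phospho_bond_length = 0.319,
    k_bond = 8000,
    turn_bias_strength = 1500,
    turn_bias_r0 = 0.45,
    version = "ctdphase-params-1"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  stopifnot(p$cutoff > p$sigma, p$sigma > 0, p$elec_cutoff >= p$cutoff,
            all(p$type_eps >= 0), p$eps_min >= 0)
  class(p) <- "interaction_params"
  p
}

#' Pairwise well-depth table
#'
#' Effective well depths in kJ/mol: `solvation_scale *
#' max(sqrt(eps_i * eps_j), eps_min)`, symmetric by construction.
#'
#' @param params an `interaction_params`
#' @return Named symmetric matrix over bead types.
#' @export
pair_eps_table <- function(params) {
  e <- params$type_eps[.bead_types]
  m <- sqrt(outer(e, e))
  m[m < params$eps_min] <- params$eps_min
  m <- m * params$solvation_scale
  dimnames(m) <- list(.bead_types, .bead_types)
  m
}

#' Debye screening length
#'
#' `sqrt(eps0 * eps_r * kB * T / (2 * NA * e^2 * I))` for a 1:1 salt of
#' ionic strength `I`; about 0.78 nm at 150 mM and 300 K.
#'
#' @param params an `interaction_params`
#' @return Debye length in nm.
#' @export
debye_length <- function(params) {
  # kappa^-2 = eps0 eps_r kB T / (2 NA e^2 I); with Coulomb constant
  # kc = 138.935 kJ mol^-1 nm e^-2 = 1/(4 pi eps0) this reduces to
  # 1 / (8 pi kc I / (eps_r kB T)) with I in nm^-3.
  I_nm3 <- params$salt_molar * 6.02214076e23 * 1e-24 # ions/nm^3 per species
  kT <- .kB * params$temperature
  kappa2 <- 8 * pi * .coulomb_k / (params$dielectric * kT) * I_nm3
  1 / sqrt(kappa2)
}

#' Nonbonded pair potential
#'
#' Shifted 12-6 potential plus (for charged pairs) shifted Debye-Hueckel
#' screened Coulomb. The 12-6 term is exactly zero for r >= cutoff; the
#' screened Coulomb term is shifted to zero at its own, longer cutoff
#' (`elec_cutoff`), so neutral pairs vanish beyond `cutoff` and charged
#' pairs beyond `elec_cutoff`. At the minimum r = sigma * 2^(1/6) a neutral
#' pair has energy `-eps_ij + shift` where
#' `shift = 4 eps_ij ((sigma/rc)^12 - (sigma/rc)^6)`.
#'
#' @param type_i,type_j bead type codes (see [default_params()])
#' @param charge_i,charge_j charges in elementary units
#' @param r distance(s), nm
#' @param params an `interaction_params`
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
pair_potential <- function(type_i, type_j, charge_i = 0, charge_j = 0, r,
                           params = default_params()) {
  stopifnot(all(r > 0))
  eps <- pair_eps_table(params)[type_i, type_j]
  s6 <- (params$sigma / r)^6
  sc6 <- (params$sigma / params$cutoff)^6
  if (eps <= params$eps_min * params$solvation_scale * (1 + 1e-9)) {
    # non-sticky pair: WCA (12-6 core cut and shifted at its minimum)
    u <- 4 * eps * (s6^2 - s6) + eps
    u[r >= params$sigma * 2^(1 / 6)] <- 0
  } else {
    u <- 4 * eps * (s6^2 - s6) - 4 * eps * (sc6^2 - sc6)
    u[r >= params$cutoff] <- 0
  }
  qq <- charge_i * charge_j
  if (qq != 0) {
    lam <- debye_length(params)
    kq <- .coulomb_k / params$dielectric
    ue <- kq * qq * (exp(-r / lam) / r -
                     exp(-params$elec_cutoff / lam) / params$elec_cutoff)
    ue[r >= params$elec_cutoff] <- 0
    u <- u + ue
  }
  u
}
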