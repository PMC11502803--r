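# CTD construct builder: heptad-repeat sequences, substitution variants,
# phospho-states, and proline isomer states.

.consensus_heptad <- c("Y", "S", "P", "T", "S", "P", "S")

#' Supported CTD variant labels
#'
#' The consensus heptad is Y1-S2-P3-T4-S5-P6-S7. Substitution variants are
#' named by the substituted consensus letter, the comma-separated heptad
#' positions, and the replacement letter (e.g. `"S2,5,7A"`). `"Hyp"` replaces
#' both prolines with hydroxyproline (code `O`); `"pS5"`/`"pS7"` are the
#' consensus phosphorylated on serine 5 or 7 (charge -1e by default).
#'
#' @return Character vector of recognised variant labels.
#' @export
ctd_variants <- function() {
  c("cons", "Y1F", "Y1A", "P3G", "T4G",
    "S2A", "S5A", "S7A", "S2,5A", "S2,7A", "S5,7A", "S2,5,7A",
    "Hyp", "pS5", "pS7", "P6G", "P3,6G")
}

.parse_variant <- function(label) {
  if (label == "cons") return(list(pos = integer(), to = character()))
  if (label == "Hyp")  return(list(pos = c(3L, 6L), to = c("O", "O")))
  m <- regmatches(label, regexec("^([YSPT])([0-9,]+)([A-Z])$", label))[[1]]
  if (length(m) == 0) {
    stop("unknown variant label '", label, "'; supported labels: ",
         paste(ctd_variants(), collapse = ", "), call. = FALSE)
  }
  from <- m[2]
  pos <- as.integer(strsplit(m[3], ",", fixed = TRUE)[[1]])
  if (any(is.na(pos)) || any(pos < 1L | pos > 7L))
    stop("variant positions must be heptad positions 1-7", call. = FALSE)
  bad <- pos[.consensus_heptad[pos] != from]
  if (length(bad))
    stop("consensus has no '", from, "' at heptad position ",
         paste(bad, collapse = ","), call. = FALSE)
  list(pos = pos, to = rep(m[4], length(pos)))
}

#' Build a CTD construct
#'
#' Constructs an annotated residue table for a CTD variant: a two-residue
#' `PS` N-terminal prefix followed by `n_repeats` heptads with the variant's
#' substitutions applied identically in every repeat. Residues start
#' unphosphorylated; prolines and hydroxyprolines start in the trans state.
#'
#' @param variant_label one of [ctd_variants()]. `"pS5"`/`"pS7"` build the
#'   consensus and then phosphorylate serine 5 or 7 at the default charge.
#' @param n_repeats number of heptad repeats (52 for the full-length human
#'   CTD).
#' @return A `ctd_sequence`: a data frame with one row per residue and
#'   columns `code`, `heptad_position` (0 for the prefix), `repeat_index`
#'   (0 for the prefix), `is_phospho`, `phospho_charge`, `isomer`
#'   (`"trans"`/`"cis"` for P/O, `NA` otherwise), plus attributes
#'   `variant_label` and `n_repeats`.
#' @examples
#' seq <- build_ctd("cons", 52)
#' nrow(seq)                 # 2 + 7*52 = 366
#' sum(seq$code == "Y")      # 52
#' @export
build_ctd <- function(variant_label, n_repeats) {
  stopifnot(length(variant_label) == 1L, length(n_repeats) == 1L)
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L)
    stop("n_repeats must be a positive integer", call. = FALSE)
  phospho_target <- NULL
  lab <- variant_label
  if (lab %in% c("pS5", "pS7")) {
    phospho_target <- as.integer(sub("pS", "", lab))
    lab <- "cons"
  }
  sub <- .parse_variant(lab)
  if (variant_label %in% c("P6G", "P3,6G"))
    warning("variant ", variant_label, " was experimentally insoluble ",
            "(amyloid-like cross-beta predictions); constructing anyway",
            call. = FALSE)
  heptad <- .consensus_heptad
  heptad[sub$pos] <- sub$to
  code <- c("P", "S", rep(heptad, n_repeats))
  hpos <- c(0L, 0L, rep(1:7, n_repeats))
  rpt  <- c(0L, 0L, rep(seq_len(n_repeats), each = 7L))
  seq <- data.frame(
    code = code,
    heptad_position = hpos,
    repeat_index = rpt,
    is_phospho = FALSE,
    phospho_charge = 0,
    isomer = ifelse(code %in% c("P", "O"), "trans", NA_character_),
    stringsAsFactors = FALSE
  )
  attr(seq, "variant_label") <- variant_label
  attr(seq, "n_repeats") <- n_repeats
  class(seq) <- c("ctd_sequence", "data.frame")
  if (!is.null(phospho_target))
    seq <- apply_phosphorylation(seq, phospho_target)
  seq
}

#' @export
print.ctd_sequence <- function(x, ...) {
  cat("CTD construct '", attr(x, "variant_label"), "': ",
      attr(x, "n_repeats"), " heptad repeat(s), ", nrow(x), " residues, ",
      "net charge ", ctd_net_charge(x), "e\n", sep = "")
  cat(paste(x$code, collapse = ""), "\n")
  invisible(x)
}

#' Net charge of a construct in elementary charge units
#' @param seq a `ctd_sequence`
#' @return Sum of phospho charges (0 for unphosphorylated constructs).
#' @export
ctd_net_charge <- function(seq) sum(seq$phospho_charge)

#' Phosphorylate serines at a heptad position
#'
#' Marks the serine at heptad position 5 or 7 of every repeat as
#' phosphorylated. In the coarse-grained topology each phosphoserine gains a
#' charged side bead (-1e or -1.5e, after the Martini bead types Q5 and D;
#' the stronger D parameterization is the default) and its backbone bead
#' becomes the non-sticky hydrophilic type `pS`.
#'
#' @param seq a `ctd_sequence`
#' @param target_position heptad position, 5 or 7
#' @param charge phospho charge in elementary units, -1 or -1.5
#' @return The phosphorylated `ctd_sequence`.
#' @export
apply_phosphorylation <- function(seq, target_position, charge = -1.5) {
  stopifnot(inherits(seq, "ctd_sequence"))
  if (!target_position %in% c(5L, 7L))
    stop("target_position must be 5 or 7", call. = FALSE)
  if (!charge %in% c(-1, -1.5))
    stop("phospho charge must be -1 or -1.5", call. = FALSE)
  idx <- which(seq$heptad_position == target_position)
  if (any(seq$code[idx] != "S"))
    stop("residue at heptad position ", target_position,
         " is not serine in variant '", attr(seq, "variant_label"),
         "'; cannot phosphorylate", call. = FALSE)
  seq$is_phospho[idx] <- TRUE
  seq$phospho_charge[idx] <- charge
  seq
}

#' Assign proline cis/trans isomer states
#'
#' Sets the isomer state of position-3 and position-6 prolines (or
#' hydroxyprolines) in every heptad. The pattern names the position-3 state
#' first, then position-6: `"trans-trans"` (the major state), `"cis-trans"`,
#' `"trans-cis"`, `"cis-cis"`. Variants lacking a proline at a position (e.g.
#' P3G) simply have nothing to flag there. Isomer states are fixed per run:
#' cis/trans interconversion is far slower than the simulated time scales.
#'
#' @param seq a `ctd_sequence`
#' @param pattern isomer pattern for heptad positions 3 and 6
#' @return The `ctd_sequence` with `isomer` updated.
#' @export
assign_proline_isomers <- function(seq,
    pattern = c("trans-trans", "cis-trans", "trans-cis", "cis-cis")) {
  stopifnot(inherits(seq, "ctd_sequence"))
  pattern <- match.arg(pattern)
  states <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  for (k in 1:2) {
    pos <- c(3L, 6L)[k]
    idx <- which(seq$heptad_position == pos & seq$code %in% c("P", "O"))
    seq$isomer[idx] <- states[k]
  }
  seq
}

#' Locate SPXX motifs
#'
#' Finds 0-based start indices i such that residue i is serine-like
#' (including phosphoserine), residue i+1 is proline-like (proline or
#' hydroxyproline), and residues i+2 and i+3 exist. A consensus construct of
#' n repeats carries 2n - 1 motifs: one S2-P3-T4-S5 per heptad plus the
#' bridging S5-P6-S7-Y1 between consecutive heptads.
#'
#' @param seq a `ctd_sequence`
#' @return Integer vector of 0-based motif start indices.
#' @export
find_spxx_motifs <- function(seq) {
  code <- seq$code
  n <- length(code)
  if (n < 4L) return(integer())
  i <- seq_len(n - 3L)
  hits <- code[i] == "S" & code[i + 1L] %in% c("P", "O")
  as.integer(i[hits] - 1L)
}

#' Residues of each SPXX motif
#'
#' @param seq a `ctd_sequence`
#' @return Integer matrix, one row per motif, columns `r1`..`r4` giving the
#'   1-based residue indices of motif positions 1-4.
#' @export
spxx_motif_residues <- function(seq) {
  starts <- find_spxx_motifs(seq)
  m <- outer(starts + 1L, 0:3, `+`)
  colnames(m) <- paste0("r", 1:4)
  m
}

#' Motifs whose proline is in the cis state
#'
#' @param seq a `ctd_sequence`
#' @return Logical vector over motifs (rows of [spxx_motif_residues()]);
#'   `TRUE` where the motif's position-2 proline/hydroxyproline is cis.
#' @export
spxx_motif_is_cis <- function(seq) {
  m <- spxx_motif_residues(seq)
  iso <- seq$isomer[m[, 2L]]
  !is.na(iso) & iso == "cis"
}
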