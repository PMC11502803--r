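# Trajectory, sequence and table I/O. Coordinates are always nm; image
# measurements are px with an explicit um^2 conversion column.

#' Write a trajectory as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the box and
#' frame index, then one line per bead with type, coordinates (nm, 4
#' decimals), chain index and residue index.
#'
#' @param traj a `cg_trajectory` (or compatible list)
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- if (length(dim(traj$frames))) dim(traj$frames)[1] else 0L
  nb <- if (nf) dim(traj$frames)[2] else 0L
  for (f in seq_len(nf)) {
    box <- if (is.null(traj$box)) "none"
           else paste(format(traj$box, trim = TRUE), collapse = ",")
    writeLines(c(as.character(nb), paste0("box=", box, " frame=", f)), con)
    m <- matrix(traj$frames[f, , ], ncol = 3)
    writeLines(sprintf("%s %.4f %.4f %.4f %d %d", traj$type,
                       m[, 1], m[, 2], m[, 3], traj$chain_id, traj$residue),
               con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path file written by [write_xyz()]
#' @return A `cg_trajectory` (without topologies) with `frames`,
#'   `chain_id`, `residue`, `type`, `is_backbone` (types other than `SP`),
#'   `box`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); meta <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed frame header at line ", i, call. = FALSE)
    cm <- lines[i + 1L]
    bx <- sub("^box=([^ ]+).*$", "\\1", cm)
    box <- if (bx == "none") NULL else as.numeric(strsplit(bx, ",")[[1]])
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i, call. = FALSE)
    rows <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(rows, " ", fixed = TRUE)
    if (any(lengths(parts) != 6L))
      stop("malformed atom record near line ",
           i + 1L + which(lengths(parts) != 6L)[1], call. = FALSE)
    pm <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
    fr <- list(type = pm[, 1],
               xyz = matrix(as.numeric(pm[, 2:4]), ncol = 3),
               chain = as.integer(pm[, 5]), residue = as.integer(pm[, 6]))
    if (is.null(meta)) meta <- fr
    else if (length(fr$type) != length(meta$type))
      stop("inconsistent atom count in frame starting at line ", i,
           call. = FALSE)
    frames[[length(frames) + 1L]] <- fr$xyz
    i <- i + 2L + n
  }
  nf <- length(frames)
  nb <- if (nf) nrow(frames[[1]]) else 0L
  arr <- array(0, dim = c(nf, nb, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  structure(list(frames = arr,
                 chain_id = if (nf) meta$chain else integer(),
                 residue = if (nf) meta$residue else integer(),
                 type = if (nf) meta$type else character(),
                 is_backbone = if (nf) meta$type != "SP" else logical(),
                 box = box, topologies = NULL),
            class = "cg_trajectory")
}

#' Write one frame as PDB
#'
#' Coordinates converted nm -> Angstrom; chains map to PDB chain letters.
#'
#' @param traj a `cg_trajectory`
#' @param path output file
#' @param frame frame index
#' @return `path`, invisibly.
#' @export
write_pdb_frame <- function(traj, path, frame = 1L) {
  m <- get_frame(traj, frame) * 10
  nb <- nrow(m)
  bio3d::write.pdb(file = path, xyz = as.vector(t(m)),
                   resno = traj$residue,
                   chain = LETTERS[(traj$chain_id - 1L) %% 26L + 1L],
                   resid = rep("BEA", nb),
                   elety = substr(traj$type, 1, 1))
  invisible(path)
}

#' Export a construct as FASTA plus an annotation sidecar
#'
#' FASTA carries the residue string (hydroxyproline as `O`); the sidecar
#' CSV carries what FASTA cannot: phospho states, charges and isomer
#' states.
#'
#' @param seq a `ctd_sequence`
#' @param fasta_path,csv_path output files (CSV defaults to the FASTA path
#'   with a `.annotations.csv` suffix)
#' @return `fasta_path`, invisibly.
#' @export
write_ctd_fasta <- function(seq, fasta_path,
                            csv_path = sub("\\.[^.]*$", ".annotations.csv",
                                           fasta_path)) {
  stopifnot(inherits(seq, "ctd_sequence"))
  name <- paste0("CTD_", attr(seq, "variant_label"), "_x",
                 attr(seq, "n_repeats"))
  seqinr::write.fasta(paste(seq$code, collapse = ""), name, fasta_path)
  ann <- as.data.frame(seq)
  ann$index <- seq_len(nrow(ann))
  write.csv(ann[, c("index", "code", "heptad_position", "repeat_index",
                    "is_phospho", "phospho_charge", "isomer")],
            csv_path, row.names = FALSE)
  invisible(fasta_path)
}

#' Export analysis tables as CSV
#'
#' `export_profile_csv`: scaling profile (s, r, n_pairs).
#' `export_energy_map_csv`: long-format energy map (i, j, energy,
#' highlighted). `export_turn_csv`: per-frame, per-motif turn distances.
#' `export_cluster_csv`: per-frame largest-cluster size.
#'
#' @param x the object to export
#' @param path output file
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile_csv
#' @export
export_energy_map_csv <- function(x, path) {
  n <- nrow(x$energy)
  idx <- which(upper.tri(x$energy, diag = TRUE), arr.ind = TRUE)
  write.csv(data.frame(i = idx[, 1], j = idx[, 2],
                       energy = x$energy[idx],
                       highlighted = x$highlight[idx]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile_csv
#' @export
export_turn_csv <- function(x, path) {
  d <- x$distances
  write.csv(data.frame(frame = rep(seq_len(nrow(d)), ncol(d)),
                       motif = rep(seq_len(ncol(d)), each = nrow(d)),
                       distance = as.vector(d)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile_csv
#' @export
export_cluster_csv <- function(x, path) {
  write.csv(data.frame(frame = x$frame, largest = x$largest,
                       fraction = x$largest / x$n_chains),
            path, row.names = FALSE)
  invisible(path)
}
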