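# Reference polymer ensembles with known Flory scaling exponents, used to
# validate the analysis stack without any simulation: ideal Gaussian chains
# (nu = 1/2), lattice self-avoiding walks (nu ~ 0.588), compact globules
# (nu = 1/3) and rigid rods (nu = 1).

#' Specify a reference ensemble
#'
#' @param kind `"ideal"`, `"saw"`, `"globule"` or `"rod"`
#' @param n_residues beads per chain (>= 2)
#' @param n_conformations independent conformations
#' @param segment_length step length in nm (default the 0.55 nm Kuhn length
#'   used throughout the scaling analysis)
#' @param seed RNG seed
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(kind = c("ideal", "saw", "globule", "rod"),
                          n_residues, n_conformations,
                          segment_length = 0.55, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 2, n_conformations >= 1, segment_length > 0)
  structure(list(kind = kind, n_residues = as.integer(n_residues),
                 n_conformations = as.integer(n_conformations),
                 segment_length = segment_length, seed = seed),
            class = "ensemble_spec")
}

#' Generate a reference ensemble
#'
#' * `ideal`: Gaussian-step chain; each step is isotropic normal with
#'   root-mean-square length `segment_length`, so the rms internal distance
#'   is exactly `b * sqrt(s)`.
#' * `saw`: cubic-lattice self-avoiding walks decorrelated by the pivot
#'   algorithm (octahedral lattice symmetries), scaled so the lattice step
#'   equals `segment_length`; configurations are strictly self-avoiding.
#' * `globule`: random contiguous windows of a 3-d Hilbert curve filling a
#'   cube of at least twice `n_residues` sites, so any `s` consecutive
#'   beads occupy a compact region of linear size ~ `s^(1/3)` at every
#'   scale; small uniform jitter breaks lattice degeneracy.
#' * `rod`: collinear beads spaced `segment_length` apart.
#'
#' @param spec an [ensemble_spec()]
#' @param warmup,stride accepted pivot counts for SAW equilibration and
#'   decorrelation (defaults scale with chain length)
#' @return Array `n_conformations x n_residues x 3` (nm) with attribute
#'   `spec`; class `polymer_ensemble`.
#' @export
generate_ensemble <- function(spec, warmup = NULL, stride = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  nc <- spec$n_conformations
  b <- spec$segment_length
  x <- switch(spec$kind,
    ideal = {
      steps <- array(rnorm(nc * (n - 1) * 3, sd = b / sqrt(3)),
                     dim = c(nc, n - 1, 3))
      a <- array(0, dim = c(nc, n, 3))
      for (d in 1:3)
        a[, -1, d] <- t(apply(steps[, , d, drop = FALSE], 1, cumsum))
      a
    },
    rod = {
      a <- array(0, dim = c(nc, n, 3))
      a[, , 1] <- matrix(b * (seq_len(n) - 1), nc, n, byrow = TRUE)
      a
    },
    saw = {
      if (is.null(warmup)) warmup <- max(20L * n, 2000L)
      if (is.null(stride)) stride <- max(n, 100L)
      cpp_saw_pivot(n, nc, as.integer(warmup), as.integer(stride), 200) * b
    },
    globule = {
      a <- array(0, dim = c(nc, n, 3))
      k <- max(1L, ceiling(log2((2 * n)^(1 / 3))))
      curve <- .hilbert_curve(k)
      for (cf in seq_len(nc)) {
        o <- sample.int(nrow(curve) - n + 1L, 1L)
        path <- curve[o:(o + n - 1L), , drop = FALSE]
        path <- path + matrix(runif(3 * n, -0.25, 0.25), n, 3)
        a[cf, , ] <- path * b
      }
      a
    })
  attr(x, "spec") <- spec
  class(x) <- "polymer_ensemble"
  x
}

# 3-d Hilbert curve through a cube of side 2^k (Skilling's bit-transpose
# algorithm), vectorized over the whole index range; cached per order.
.hilbert_cache <- new.env(parent = emptyenv())
.hilbert_curve <- function(k) {
  key <- as.character(k)
  if (!is.null(.hilbert_cache[[key]])) return(.hilbert_cache[[key]])
  n <- 8^k
  h <- 0:(n - 1)
  X <- matrix(0L, n, 3)
  for (p in 0:(3 * k - 1)) { # p = 0 is the most significant bit of h
    bit <- bitwAnd(h %/% 2^(3 * k - 1 - p), 1L)
    axis <- p %% 3 + 1L
    X[, axis] <- bitwOr(X[, axis], bit * 2^(k - 1 - p %/% 3))
  }
  t0 <- X[, 3] %/% 2L # Gray decode
  X[, 3] <- bitwXor(X[, 3], X[, 2])
  X[, 2] <- bitwXor(X[, 2], X[, 1])
  X[, 1] <- bitwXor(X[, 1], t0)
  Q <- 2L
  while (Q != 2^k) { # undo excess work
    P <- Q - 1L
    for (i in 3:1) {
      hasQ <- bitwAnd(X[, i], Q) > 0
      X[hasQ, 1] <- bitwXor(X[hasQ, 1], P)
      tt <- bitwAnd(bitwXor(X[!hasQ, 1], X[!hasQ, i]), P)
      X[!hasQ, 1] <- bitwXor(X[!hasQ, 1], tt)
      X[!hasQ, i] <- bitwXor(X[!hasQ, i], tt)
    }
    Q <- Q * 2L
  }
  .hilbert_cache[[key]] <- X
  X
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  s <- attr(x, "spec")
  cat("Reference ensemble '", s$kind, "': ", s$n_conformations,
      " conformations x ", s$n_residues, " beads, segment ",
      s$segment_length, " nm\n", sep = "")
  invisible(x)
}

#' Bimodal SPXX turn-distance samples
#'
#' Truncated-normal (positive support) mixture of a compact and an extended
#' Calpha1-Calpha4 distance population on opposite sides of the 0.7 nm
#' beta-turn cutoff. The empirical fraction below the cutoff converges to
#' `compact_fraction` as n grows (up to the truncated tail mass of each
#' component crossing the cutoff).
#'
#' @param n_samples number of distances to draw
#' @param compact_fraction mixture weight of the compact component in [0, 1]
#' @param compact_mean,compact_sd nm; mean must be < 0.7
#' @param extended_mean,extended_sd nm; mean must be > 0.7
#' @param seed RNG seed
#' @return Numeric vector of distances (nm) with attribute
#'   `compact_fraction`.
#' @export
turn_distance_mixture <- function(n_samples, compact_fraction,
                                  compact_mean = 0.52, compact_sd = 0.05,
                                  extended_mean = 0.95, extended_sd = 0.09,
                                  seed = 1) {
  stopifnot(compact_fraction >= 0, compact_fraction <= 1,
            compact_mean < 0.7, extended_mean > 0.7)
  set.seed(seed)
  comp <- runif(n_samples) < compact_fraction
  draw <- function(n, mu, sd) {
    x <- rnorm(n, mu, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mu, sd)
    x
  }
  d <- numeric(n_samples)
  if (any(comp)) d[comp] <- draw(sum(comp), compact_mean, compact_sd)
  if (any(!comp)) d[!comp] <- draw(sum(!comp), extended_mean, extended_sd)
  attr(d, "compact_fraction") <- compact_fraction
  d
}

#' View an ensemble as a single-chain trajectory
#'
#' Wraps a reference ensemble in the trajectory container so XYZ export and
#' every chain analysis consume simulator output and synthetic ensembles
#' identically.
#'
#' @param ens a `polymer_ensemble`
#' @return A `cg_trajectory` (open boundaries, no topologies).
#' @export
ensemble_as_trajectory <- function(ens) {
  stopifnot(inherits(ens, "polymer_ensemble"))
  n <- dim(ens)[2]
  structure(list(frames = unclass(ens), chain_id = rep(1L, n),
                 residue = seq_len(n), type = rep("S", n),
                 is_backbone = rep(TRUE, n), box = NULL, topologies = NULL),
            class = "cg_trajectory")
}
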