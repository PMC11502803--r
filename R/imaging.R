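# Fluorescence-micrograph droplet quantification: synthetic micrograph
# generation with ground truth, Otsu segmentation, diameter / shape /
# intensity filters, and per-droplet measurement with px -> um^2 conversion
# (0.010645 um^2 per pixel).

#' Generate a synthetic fluorescence micrograph
#'
#' Renders droplet-like objects with smooth (sigmoidal-edge) radial
#' intensity profiles on a constant background plus Gaussian noise, and
#' returns the rasterized ground truth alongside. Elliptical droplets keep
#' the area of the equivalent circle (`pi * radius^2`).
#'
#' @param droplets data frame with columns `x`, `y` (centre, px), `radius`
#'   (px), `intensity` (peak, arbitrary units in [0, 1]), and optionally
#'   `eccentricity` (default 0) and `angle` (radians, default 0)
#' @param dim image dimensions in px (the source-data convention is
#'   2048 x 2048)
#' @param background constant background level
#' @param noise_sd Gaussian noise SD
#' @param edge_width sigmoid edge width, px
#' @param pixel_area um^2 per pixel
#' @param seed RNG seed; the image is bit-identical on regeneration
#' @return A `micrograph`: list with `image` (matrix), `truth` (data frame
#'   with rasterized `area_px` per droplet), `pixel_area`, `channel`,
#'   `measurement`, `condition`.
#' @param channel,measurement,condition labels carried through to records
#' @export
generate_micrograph <- function(droplets, dim = c(2048, 2048),
                                background = 0.05, noise_sd = 0.01,
                                edge_width = 0.8, pixel_area = 0.010645,
                                seed = 1, channel = "GFP",
                                measurement = 1L, condition = "cond") {
  if (is.null(droplets))
    droplets <- data.frame(x = numeric(), y = numeric(),
                           radius = numeric(), intensity = numeric())
  stopifnot(is.data.frame(droplets))
  if (is.null(droplets$eccentricity))
    droplets$eccentricity <- rep(0, nrow(droplets))
  if (is.null(droplets$angle)) droplets$angle <- rep(0, nrow(droplets))
  set.seed(seed)
  img <- matrix(background, dim[1], dim[2])
  truth <- droplets
  truth$area_px <- rep(NA_real_, nrow(truth))
  for (k in seq_len(nrow(droplets))) {
    d <- droplets[k, ]
    if (d$x < 1 || d$x > dim[1] || d$y < 1 || d$y > dim[2])
      stop("droplet ", k, " centre outside the image", call. = FALSE)
    ecc <- d$eccentricity
    ax <- d$radius / (1 - ecc^2)^0.25   # major semi-axis
    bx <- d$radius * (1 - ecc^2)^0.25   # minor semi-axis
    w <- ceiling(ax + 6 * edge_width)
    xs <- max(1, floor(d$x - w)):min(dim[1], ceiling(d$x + w))
    ys <- max(1, floor(d$y - w)):min(dim[2], ceiling(d$y + w))
    dx <- outer(xs - d$x, rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - d$y)
    u <- cos(d$angle) * dx + sin(d$angle) * dy
    v <- -sin(d$angle) * dx + cos(d$angle) * dy
    re <- d$radius * sqrt((u / ax)^2 + (v / bx)^2) # elliptical radius
    prof <- d$intensity / (1 + exp((re - d$radius) / edge_width))
    inside <- re <= d$radius
    truth$area_px[k] <- sum(inside)
    if (any(img[xs, ys][inside] > background + 1e-12))
      warning("droplet ", k, " overlaps an earlier droplet; ",
              "ground-truth areas count shared pixels twice", call. = FALSE)
    img[xs, ys] <- img[xs, ys] + prof
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        dim[1], dim[2])
  structure(list(image = img, truth = truth, pixel_area = pixel_area,
                 channel = channel, measurement = measurement,
                 condition = condition),
            class = "micrograph")
}

#' Otsu threshold on a 256-bin histogram
#'
#' Classic formulation: pixel values (assumed in [0, 1]) are binned into
#' `levels` equal-width bins and the candidate cut `k / levels` maximizing
#' the between-class variance is returned (ties broken towards the lowest
#' cut). Returns `NA` with a warning for a constant image, where the
#' threshold is undefined.
#'
#' @param img numeric matrix with values in [0, 1]
#' @param levels number of histogram bins
#' @return Threshold in [0, 1], or `NA_real_`.
#' @export
otsu_threshold <- function(img, levels = 256L) {
  v <- as.vector(img)
  if (diff(range(v)) < .Machine$double.eps) {
    warning("constant image: Otsu threshold undefined", call. = FALSE)
    return(NA_real_)
  }
  bin <- pmin(pmax(ceiling(v * levels), 1L), levels)
  counts <- as.numeric(tabulate(bin, nbins = levels))
  centers <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(counts)[-levels]
  w1 <- length(v) - w0
  m0 <- cumsum(counts * centers)[-levels]
  mu0 <- m0 / w0
  mu1 <- (sum(counts * centers) - m0) / w1
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  which.max(sigma_b) / levels
}

#' Segment droplet-like objects
#'
#' Normalizes the image to [0, 1], applies the global Otsu threshold,
#' labels connected components (touching objects optionally split by a
#' distance-transform watershed), and discards components whose equivalent
#' diameter (`2 * sqrt(area / pi)`) lies outside `diameter_range`
#' (4-70 px, i.e. 0.413-7.5 um, in the reference pipeline).
#'
#' @param img a `micrograph` or numeric matrix
#' @param diameter_range px, inclusive
#' @param levels Otsu histogram bins
#' @param split_touching split touching objects by watershed
#' @return A `droplet_labels`: list with `labels` (integer matrix),
#'   `image` (normalized), `threshold`, `pixel_area`, `channel`,
#'   `measurement`, `condition`.
#' @export
segment_droplets <- function(img, diameter_range = c(4, 70), levels = 256L,
                             split_touching = TRUE) {
  meta <- list(pixel_area = 0.010645, channel = NA_character_,
               measurement = NA_integer_, condition = NA_character_)
  if (inherits(img, "micrograph")) {
    meta <- img[c("pixel_area", "channel", "measurement", "condition")]
    img <- img$image
  }
  rng <- range(img)
  norm <- if (diff(rng) > .Machine$double.eps)
    (img - rng[1]) / diff(rng) else img * 0
  thr <- otsu_threshold(norm, levels)
  if (is.na(thr)) {
    labels <- matrix(0L, nrow(img), ncol(img))
  } else {
    mask <- norm > thr
    labels <- if (split_touching)
      EBImage::watershed(EBImage::distmap(EBImage::Image(mask)), tolerance = 1)
    else EBImage::bwlabel(EBImage::Image(mask))
    labels <- EBImage::imageData(labels)
    storage.mode(labels) <- "integer"
    if (max(labels) > 0) {
      area <- tabulate(labels[labels > 0], nbins = max(labels))
      diam <- 2 * sqrt(area / pi)
      drop <- which(diam < diameter_range[1] | diam > diameter_range[2] |
                    area == 0)
      if (length(drop)) labels[labels %in% drop] <- 0L
      labels <- matrix(match(labels, sort(unique(labels[labels > 0])),
                             nomatch = 0L), nrow(labels), ncol(labels))
    }
  }
  structure(c(list(labels = labels, image = norm, threshold = thr), meta),
            class = "droplet_labels")
}

#' Measure segmented droplets
#'
#' Per-object area (px and um^2), equivalent diameter, eccentricity from
#' the second-central-moment ellipse (0 = circle, 1 = line segment), median
#' pixel intensity and integrated intensity (sum of pixel signal), on the
#' normalized image.
#'
#' @param objects a `droplet_labels`
#' @param pixel_area um^2 per pixel (default from the object metadata)
#' @return Data frame of `droplet_record`s, one row per object: `label`,
#'   `area_px`, `area_um2`, `diameter_px`, `eccentricity`,
#'   `median_intensity`, `integrated_intensity`, `measurement`,
#'   `condition`, `channel`.
#' @export
measure_droplets <- function(objects, pixel_area = NULL) {
  stopifnot(inherits(objects, "droplet_labels"))
  if (is.null(pixel_area)) pixel_area <- objects$pixel_area
  lab <- objects$labels
  n <- max(lab)
  empty <- data.frame(label = integer(), area_px = numeric(),
                      area_um2 = numeric(), diameter_px = numeric(),
                      eccentricity = numeric(), median_intensity = numeric(),
                      integrated_intensity = numeric())
  if (n == 0)
    return(cbind(empty, measurement = integer(), condition = character(),
                 channel = character()))
  mom <- EBImage::computeFeatures.moment(lab, objects$image)
  idx <- lab > 0
  px <- objects$image[idx]
  lv <- lab[idx]
  area <- tabulate(lv, nbins = n)
  med <- tapply(px, lv, median)
  tot <- tapply(px, lv, sum)
  data.frame(label = seq_len(n),
             area_px = area,
             area_um2 = area * pixel_area,
             diameter_px = 2 * sqrt(area / pi),
             eccentricity = unname(mom[, "m.eccentricity"]),
             median_intensity = as.numeric(med),
             integrated_intensity = as.numeric(tot),
             measurement = objects$measurement,
             condition = objects$condition,
             channel = objects$channel)
}

#' Filter measured droplets by shape and intensity
#'
#' Keeps objects with eccentricity at most `ecc_max` (elongated aggregates
#' discarded) and median pixel intensity within `intensity_range`
#' (inclusive). Idempotent, and commutes with the diameter filter applied
#' at segmentation.
#'
#' @param records droplet records from [measure_droplets()]
#' @param ecc_max eccentricity cap
#' @param intensity_range median-intensity range on the normalized image
#' @return Filtered records.
#' @export
filter_droplets <- function(records, ecc_max = 0.6,
                            intensity_range = c(0.1, 1)) {
  records[records$eccentricity <= ecc_max &
          records$median_intensity >= intensity_range[1] &
          records$median_intensity <= intensity_range[2], , drop = FALSE]
}

#' Full quantification pipeline for one micrograph
#'
#' Segment (Otsu + diameter 4-70 px), measure, then filter (eccentricity
#' <= 0.6, median intensity 0.1-1). Deterministic given the input image.
#'
#' @param img a `micrograph` or matrix
#' @param ... passed to [segment_droplets()]
#' @param ecc_max,intensity_range see [filter_droplets()]
#' @return Filtered droplet records.
#' @export
quantify_micrograph <- function(img, ..., ecc_max = 0.6,
                                intensity_range = c(0.1, 1)) {
  filter_droplets(measure_droplets(segment_droplets(img, ...)),
                  ecc_max, intensity_range)
}
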