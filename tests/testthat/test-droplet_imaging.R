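test_that("synthetic micrographs honour their spec and ground truth", {
  empty <- generate_micrograph(NULL, dim = c(64, 64), background = 0.05,
                               noise_sd = 0)
  expect_true(all(empty$image == 0.05))
  one <- generate_micrograph(
    data.frame(x = 100, y = 100, radius = 10, intensity = 0.8),
    dim = c(200, 200), noise_sd = 0, seed = 4)
  expect_equal(one$truth$area_px, pi * 100, tolerance = 0.04)
  # bit-identical regeneration from the same seed
  spec <- data.frame(x = c(40, 120), y = c(50, 130), radius = c(8, 12),
                     intensity = c(0.6, 0.9))
  a <- generate_micrograph(spec, dim = c(180, 180), seed = 9)
  b <- generate_micrograph(spec, dim = c(180, 180), seed = 9)
  expect_identical(a$image, b$image)
  expect_warning(
    generate_micrograph(data.frame(x = c(50, 54), y = c(50, 50),
                                   radius = c(6, 6),
                                   intensity = c(0.5, 0.5)),
                        dim = c(100, 100), noise_sd = 0),
    "overlap")
  expect_error(
    generate_micrograph(data.frame(x = 500, y = 50, radius = 5,
                                   intensity = 0.5), dim = c(100, 100)),
    "outside")
})

test_that("Otsu threshold equals the exhaustive between-class-variance maximizer", {
  # independent oracle: scan all 256 candidate cuts on the binned image
  brute_otsu <- function(img, levels = 256L) {
    v <- as.vector(img)
    bin <- pmin(pmax(ceiling(v * levels), 1L), levels)
    centers <- (bin - 0.5) / levels
    best <- -Inf; arg <- NA
    for (k in 1:(levels - 1)) {
      lo <- centers[bin <= k]; hi <- centers[bin > k]
      if (!length(lo) || !length(hi)) next
      sb <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
      if (sb > best) { best <- sb; arg <- k / levels }
    }
    arg
  }
  # perfect two-level image
  two <- matrix(c(rep(0.2, 700), rep(0.8, 300)), 20)
  expect_equal(otsu_threshold(two), brute_otsu(two))
  # quantized random images
  set.seed(30)
  for (rep in 1:3) {
    img <- matrix((sample(0:255, 400, TRUE, prob = runif(256)) + 0.5) / 256, 20)
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
  # cross-check against an independent implementation: both must achieve
  # the maximal between-class variance (the argmax can sit anywhere on a
  # flat plateau between well-separated modes)
  img <- matrix(c(rnorm(500, 0.3, 0.05), rnorm(500, 0.75, 0.05)), 25)
  img <- pmin(pmax(img, 0), 1)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  sb <- function(t) {
    lo <- img[img <= t]; hi <- img[img > t]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }
  expect_equal(sb(otsu_threshold(img)), sb(ref), tolerance = 1e-3)
  expect_warning(t0 <- otsu_threshold(matrix(0.5, 10, 10)), "undefined")
  expect_true(is.na(t0))
})

test_that("segmentation finds in-range objects and applies the diameter filter", {
  mg <- generate_micrograph(
    data.frame(x = 100, y = 100, radius = 10, intensity = 0.8),
    dim = c(200, 200), noise_sd = 0.01, seed = 5)
  seg <- segment_droplets(mg)
  expect_equal(max(seg$labels), 1)
  # a ~2 px diameter speck is below the 4 px lower bound
  tiny <- generate_micrograph(
    data.frame(x = 50, y = 50, radius = 1, intensity = 0.9),
    dim = c(100, 100), noise_sd = 0, edge_width = 0.3)
  expect_equal(max(segment_droplets(tiny)$labels), 0)
  # uniform image: zero objects, warning from the undefined threshold
  flat <- matrix(0.4, 64, 64)
  expect_warning(s0 <- segment_droplets(flat), "undefined")
  expect_equal(max(s0$labels), 0)
  expect_equal(nrow(measure_droplets(s0)), 0)
})

test_that("measurements convert px to um^2 and integrate intensity", {
  # hand-built label field: a 1-px object and a 10x10 square of value 0.5
  img <- matrix(0, 40, 40)
  lab <- matrix(0L, 40, 40)
  img[5, 5] <- 0.9; lab[5, 5] <- 1L
  img[20:29, 20:29] <- 0.5; lab[20:29, 20:29] <- 2L
  obj <- structure(list(labels = lab, image = img, threshold = 0.1,
                        pixel_area = 0.010645, channel = "GFP",
                        measurement = 1L, condition = "c"),
                   class = "droplet_labels")
  rec <- measure_droplets(obj)
  expect_equal(rec$area_px, c(1, 100))
  expect_equal(rec$area_um2[1], 0.010645)
  expect_equal(rec$area_um2[2], 1.0645)
  expect_equal(rec$integrated_intensity, c(0.9, 100 * 0.5))
  expect_equal(rec$median_intensity, c(0.9, 0.5))
  expect_equal(rec$diameter_px, 2 * sqrt(c(1, 100) / pi))
  expect_lt(rec$eccentricity[2], 0.2) # square is nearly isotropic
})

test_that("shape and intensity filters follow the stated bounds", {
  rec <- data.frame(label = 1:4,
                    eccentricity = c(0.05, 0.9, 0.6, 0.3),
                    median_intensity = c(0.5, 0.5, 0.5, 0.05))
  kept <- filter_droplets(rec)
  expect_equal(kept$label, c(1, 3)) # ecc 0.6 kept (boundary), 0.9 and dim removed
  # idempotent and order-independent with the intensity filter
  expect_identical(filter_droplets(kept), kept)
  a <- filter_droplets(filter_droplets(rec, ecc_max = 2), ecc_max = 0.6,
                       intensity_range = c(0, 1))
  b <- filter_droplets(filter_droplets(rec, intensity_range = c(0, 1)),
                       ecc_max = 0.6)
  expect_identical(a, b)
})

test_that("elongated objects are rejected end to end", {
  mg <- generate_micrograph(
    data.frame(x = c(60, 160), y = c(60, 160), radius = c(12, 12),
               intensity = c(0.8, 0.8), eccentricity = c(0, 0.95),
               angle = c(0, 0.5)),
    dim = c(220, 220), noise_sd = 0.005, seed = 6)
  rec <- measure_droplets(segment_droplets(mg))
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$eccentricity > 0.6), 1)
  expect_equal(nrow(filter_droplets(rec)), 1)
})

test_that("pipeline recovers count and areas on clean synthetic micrographs", {
  # realistic droplet density: a 6 x 5 grid of well-separated droplets
  set.seed(31)
  g <- expand.grid(x = seq(180, 1868, length.out = 6),
                   y = seq(180, 1868, length.out = 5))
  spec <- data.frame(x = g$x, y = g$y,
                     radius = runif(30, 8, 25),
                     intensity = runif(30, 0.5, 0.9))
  mg <- generate_micrograph(spec, dim = c(2048, 2048), noise_sd = 0.02,
                            seed = 7)
  rec <- quantify_micrograph(mg)
  expect_equal(nrow(rec), nrow(spec))
  # match each recovered droplet to ground truth by area rank
  expect_equal(sort(rec$area_px), sort(mg$truth$area_px), tolerance = 0.05)
  # determinism of the analysis given the image
  rec2 <- quantify_micrograph(mg)
  expect_identical(rec, rec2)
})

test_that("assay summary works from medians with pooled-variance t-tests", {
  mk <- function(cond, meas, vals)
    data.frame(condition = cond, measurement = meas, area_um2 = vals)
  recs <- rbind(mk("a", 1, c(1, 2, 9)), mk("a", 2, c(2, 2, 2)),
                mk("a", 3, c(3, 3, 3)),
                mk("b", 1, c(4, 4, 4)), mk("b", 2, c(5, 5, 5)),
                mk("b", 3, c(6, 6, 6)))
  s <- summarize_assay(recs)
  expect_equal(sort(s$medians$median[s$medians$condition == "a"]), c(2, 2, 3))
  expect_equal(s$summary$mean_of_medians[s$summary$condition == "b"], 5)
  # identical groups: t = 0, p = 1
  recs2 <- rbind(mk("a", 1, 1), mk("a", 2, 2), mk("a", 3, 3),
                 mk("b", 1, 1), mk("b", 2, 2), mk("b", 3, 3))
  s2 <- summarize_assay(recs2)
  expect_equal(s2$tests$t, 0)
  expect_equal(s2$tests$p, 1)
  expect_equal(s2$tests$tier, "ns")
  # (1,2,3) vs (4,5,6): closed-form pooled t
  recs3 <- rbind(mk("a", 1, 1), mk("a", 2, 2), mk("a", 3, 3),
                 mk("b", 1, 4), mk("b", 2, 5), mk("b", 3, 6))
  s3 <- summarize_assay(recs3)
  expect_equal(s3$tests$t, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-10)
  expect_equal(s3$tests$df, 4)
  expect_error(summarize_assay(rbind(mk("a", 1, 1), mk("b", 1, 2))),
               "at least 2")
})

test_that("significance tiers follow the stated p-value convention", {
  expect_equal(significance_tier(c(0.2, 0.03, 0.009, 0.0009, 0.00005)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significance_tier(0.05), "*")
})
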