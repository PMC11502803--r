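# Assay-level statistics: the unit of replication is the measurement, not
# the pooled droplet. Summaries are computed from per-measurement medians
# (mean +/- SD of the n = 3 medians in the reference design), and condition
# comparisons use an unpaired two-sided t-test on those medians.

#' Significance tier of a p-value
#'
#' `ns` for p > 0.05, then `*`, `**`, `***`, `****` at 0.05, 0.01, 0.001,
#' 0.0001.
#'
#' @param p p-value(s)
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Summarize a droplet assay
#'
#' Groups droplet records by condition and measurement, takes the median of
#' `value` per measurement, reports mean +/- SD of the medians and droplet
#' counts per condition, and compares conditions with an unpaired two-sided
#' t-test on the per-measurement medians (pooled variance by default,
#' Welch with `welch = TRUE`).
#'
#' @param records droplet records (rows from [measure_droplets()] /
#'   [filter_droplets()], possibly several images), with `condition` and
#'   `measurement` columns
#' @param value measured column to summarize (droplet size = area in um^2
#'   by default; `diameter_px` is also available)
#' @param welch use the Welch t-test instead of pooled variance
#' @return An `assay_summary`: list with `medians` (per condition x
#'   measurement), `summary` (per condition: mean, sd of medians, droplet
#'   and measurement counts), `tests` (pairwise: t, df, p, tier).
#' @export
summarize_assay <- function(records, value = "area_um2", welch = FALSE) {
  stopifnot(is.data.frame(records), value %in% names(records),
            all(c("condition", "measurement") %in% names(records)))
  if (nrow(records) == 0) stop("no droplet records to summarize",
                               call. = FALSE)
  grp <- interaction(records$condition, records$measurement, drop = TRUE)
  med <- data.frame(
    condition = tapply(as.character(records$condition), grp, `[`, 1),
    measurement = tapply(records$measurement, grp, `[`, 1),
    median = as.numeric(tapply(records[[value]], grp, median)),
    n_droplets = as.integer(tapply(records[[value]], grp, length)),
    row.names = NULL)
  med <- med[order(med$condition, med$measurement), ]
  conds <- unique(med$condition)
  summ <- do.call(rbind, lapply(conds, function(cn) {
    m <- med$median[med$condition == cn]
    data.frame(condition = cn, n_measurements = length(m),
               mean_of_medians = mean(m),
               sd_of_medians = if (length(m) > 1) sd(m) else NA_real_,
               n_droplets = sum(med$n_droplets[med$condition == cn]))
  }))
  tests <- NULL
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- med$median[med$condition == pairs[1, k]]
      b <- med$median[med$condition == pairs[2, k]]
      if (length(a) < 2 || length(b) < 2)
        stop("t-test requires at least 2 measurements per condition",
             call. = FALSE)
      df0 <- length(a) + length(b) - 2
      if (sd(c(a - mean(a), b - mean(b))) == 0) {
        # zero within-group variance: t is 0 for equal means, +/-Inf otherwise
        eq <- isTRUE(all.equal(mean(a), mean(b)))
        tt <- list(statistic = c(t = if (eq) 0 else Inf * sign(mean(a) - mean(b))),
                   parameter = c(df = df0), p.value = if (eq) 1 else 0)
      } else {
        tt <- t.test(a, b, var.equal = !welch)
      }
      data.frame(condition_a = pairs[1, k], condition_b = pairs[2, k],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, tier = significance_tier(tt$p.value))
    }))
  }
  structure(list(medians = med, summary = summ, tests = tests,
                 value = value, welch = welch),
            class = "assay_summary")
}

#' @export
print.assay_summary <- function(x, ...) {
  cat("Assay summary of", x$value, "(median per measurement)\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Unpaired two-sided t-tests",
        if (x$welch) "(Welch)" else "(pooled variance)", "on medians:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
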