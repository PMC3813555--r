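# Depot volume and fat-fraction quantification, cohort aggregation and
# group comparisons.

#' Per-depot volume and fat-fraction statistics
#'
#' Volume is voxel count times voxel volume (cc = mL); the fat-fraction mean
#' and SD are taken over the valid fat-fraction voxels inside the mask
#' without re-thresholding.
#'
#' @param mask a `region_mask`.
#' @param ff a `fat_fraction_map` on the same grid.
#' @param subject subject identifier carried into the output row.
#' @return one-row data frame: subject, region, volume_cc, mean_ff, sd_ff
#'   (fractions), n_voxels.
#' @export
depot_stats <- function(mask, ff, subject = NA) {
  stopifnot(inherits(mask, "region_mask"), inherits(ff, "fat_fraction_map"))
  check_congruent(mask$mask, ff$ff, "region mask and fat-fraction map")
  n <- sum(mask$mask)
  if (n == 0L) {
    stop("empty-ROI error: region '", mask$region, "' contains no voxels",
         call. = FALSE)
  }
  vals <- ff$ff[mask$mask & ff$valid]
  vals <- vals[!is.na(vals)]
  data.frame(subject = subject, region = mask$region,
             volume_cc = n * voxel_volume_cc(mask$spacing),
             mean_ff = mean(vals),
             sd_ff = if (length(vals) > 1) stats::sd(vals) else 0,
             n_voxels = n, stringsAsFactors = FALSE)
}

#' Cohort summary table
#'
#' Per-region mean, sample SD (n - 1), and min-max range of depot volume
#' (cc) and mean fat fraction (percent), across subjects. Subjects missing a
#' region are listed in the `"incomplete"` attribute and excluded from that
#' region's summary.
#'
#' @param stats data frame of [depot_stats()] rows (>= 2 subjects).
#' @return data frame with one row per region.
#' @export
cohort_summary <- function(stats) {
  stopifnot(length(unique(stats$subject)) >= 2)
  subjects <- unique(stats$subject)
  regions <- unique(stats$region)
  missing <- do.call(rbind, lapply(regions, function(r) {
    miss <- setdiff(subjects, stats$subject[stats$region == r])
    if (length(miss)) data.frame(region = r, subject = miss) else NULL
  }))
  out <- do.call(rbind, lapply(regions, function(r) {
    s <- stats[stats$region == r, ]
    data.frame(region = r, n = nrow(s),
               volume_mean_cc = mean(s$volume_cc),
               volume_sd_cc = stats::sd(s$volume_cc),
               volume_min_cc = min(s$volume_cc),
               volume_max_cc = max(s$volume_cc),
               ff_mean_pct = 100 * mean(s$mean_ff),
               ff_sd_pct = 100 * stats::sd(s$mean_ff),
               ff_min_pct = 100 * min(s$mean_ff),
               ff_max_pct = 100 * max(s$mean_ff),
               stringsAsFactors = FALSE)
  }))
  attr(out, "incomplete") <- missing
  out
}

#' Paired white-vs-brown fat-fraction comparison
#'
#' Computes the mean paired difference in mean fat fraction (white minus
#' brown, percentage points) across subjects, the difference of the two
#' means (identical when the layout is complete), and a two-sided paired
#' test.
#'
#' @param stats data frame of [depot_stats()] rows.
#' @param bat_region,wat_region region labels to compare.
#' @param method `"t"` (Student's paired t, default) or `"wilcoxon"`.
#' @return list with `delta_pct` (mean of paired differences),
#'   `delta_of_means_pct`, `statistic`, `p_value`, `n` and `degenerate`
#'   (TRUE when the differences have zero variance, making the test
#'   undefined).
#' @export
paired_wat_bat <- function(stats, bat_region = "union",
                           wat_region = "nuchal_wat",
                           method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  bat <- stats[stats$region == bat_region, c("subject", "mean_ff")]
  wat <- stats[stats$region == wat_region, c("subject", "mean_ff")]
  m <- merge(bat, wat, by = "subject", suffixes = c("_bat", "_wat"))
  if (nrow(m) < 2) {
    stop("insufficient-data error: paired comparison needs >= 2 subjects ",
         "with both regions", call. = FALSE)
  }
  d <- (m$mean_ff_wat - m$mean_ff_bat) * 100
  degenerate <- stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
  } else if (method == "t") {
    tt <- stats::t.test(m$mean_ff_wat, m$mean_ff_bat, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(m$mean_ff_wat, m$mean_ff_bat, paired = TRUE,
                             exact = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  list(delta_pct = mean(d),
       delta_of_means_pct = 100 * (mean(m$mean_ff_wat) - mean(m$mean_ff_bat)),
       statistic = stat, p_value = p, n = nrow(m), degenerate = degenerate,
       method = method)
}

#' Fat fraction versus depot volume correlation
#'
#' Pearson correlation across subjects between depot volume and mean fat
#' fraction for one region.
#'
#' @param stats data frame of [depot_stats()] rows.
#' @param region region label.
#' @return list with `r`, `p_value`, `n`.
#' @export
ff_volume_correlation <- function(stats, region) {
  s <- stats[stats$region == region, ]
  if (nrow(s) < 3) {
    stop("insufficient-data error: correlation needs >= 3 subjects",
         call. = FALSE)
  }
  if (stats::sd(s$volume_cc) == 0 || stats::sd(s$mean_ff) == 0) {
    stop("undefined-correlation error: zero variance in volume or fat ",
         "fraction", call. = FALSE)
  }
  ct <- stats::cor.test(s$volume_cc, s$mean_ff, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(s))
}
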