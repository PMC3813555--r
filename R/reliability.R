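# Reliability analysis: two-way random-effects variance decomposition
# (ICC / WSC / N), scan-rescan voxelwise agreement, and rater-table
# simulation.
#
# ICC is the ratio of between-subject variance to total variance; WSC
# (within-subject correlation coefficient) is the ratio of between-rater
# variance to total variance; N is the residual fraction. A full two-way
# random-effects decomposition estimates the three components from the ANOVA
# expected mean squares, truncates negative estimates at zero (standard
# practice) and renormalizes, so ICC + WSC + N = 1 by construction.

#' Two-way random-effects ICC/WSC/N decomposition
#'
#' For a complete subject x rater table of single measurements, estimates
#' the subject, rater and residual variance components from the two-way
#' ANOVA mean squares: with n subjects, k raters, sigma2_subject =
#' (MS_subject - MS_error) / k, sigma2_rater = (MS_rater - MS_error) / n,
#' sigma2_error = MS_error. Negative estimates are truncated to zero and the
#' three ratios renormalized to sum to one.
#'
#' @param table data frame with columns `subject`, `rater`, `value`; every
#'   subject must be rated by every rater exactly once (>= 2 subjects,
#'   >= 2 raters).
#' @param region,metric optional labels copied into the output row.
#' @return one-row data frame with `icc`, `wsc`, `noise`, the variance
#'   components, and `degenerate` (TRUE when total variance is zero, in
#'   which case the ratios are `NA`).
#' @export
icc_decompose <- function(table, region = NA_character_,
                          metric = NA_character_) {
  stopifnot(all(c("subject", "rater", "value") %in% names(table)))
  tab <- table
  tab$subject <- factor(tab$subject)
  tab$rater <- factor(tab$rater)
  n <- nlevels(tab$subject); k <- nlevels(tab$rater)
  if (n < 2 || k < 2) {
    stop("layout error: need >= 2 subjects and >= 2 raters", call. = FALSE)
  }
  counts <- table(tab$subject, tab$rater)
  if (any(counts != 1L)) {
    stop("layout error: table is not a complete subject x rater layout ",
         "with one measurement per cell", call. = FALSE)
  }
  if (stats::var(tab$value) == 0) {
    return(data.frame(region = region, metric = metric,
                      icc = NA_real_, wsc = NA_real_, noise = NA_real_,
                      sigma2_subject = 0, sigma2_rater = 0, sigma2_error = 0,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  fit <- stats::aov(value ~ subject + rater, data = tab)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  ms_s <- ms[["subject"]]; ms_r <- ms[["rater"]]
  ms_e <- if ("Residuals" %in% names(ms)) ms[["Residuals"]] else 0
  s2_s <- max((ms_s - ms_e) / k, 0)
  s2_r <- max((ms_r - ms_e) / n, 0)
  s2_e <- max(ms_e, 0)
  total <- s2_s + s2_r + s2_e
  if (total == 0) {
    icc <- NA_real_; wsc <- NA_real_; nse <- NA_real_; degenerate <- TRUE
  } else {
    icc <- s2_s / total; wsc <- s2_r / total; nse <- s2_e / total
    degenerate <- FALSE
  }
  data.frame(region = region, metric = metric, icc = icc, wsc = wsc,
             noise = nse, sigma2_subject = s2_s, sigma2_rater = s2_r,
             sigma2_error = s2_e, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Inter- and intra-rater reliability report
#'
#' Expects three ratings per subject: two by rater 1 separated in time
#' (`"1a"`, `"1b"`) and one by rater 2 (`"2"`). Inter-rater ICC/WSC/N per
#' region and metric is the average of the (1a vs 2) and (1b vs 2)
#' decompositions; intra-rater reliability is the (1a vs 1b) decomposition.
#'
#' @param rater_table data frame with columns `subject`, `rater` (levels
#'   `"1a"`, `"1b"`, `"2"`), `region`, `metric`, `value`.
#' @return data frame with one row per region x metric x comparison
#'   (inter/intra) carrying `icc`, `wsc`, `noise`.
#' @export
reliability_report <- function(rater_table) {
  needed <- c("subject", "rater", "region", "metric", "value")
  stopifnot(all(needed %in% names(rater_table)))
  pairs <- list(inter = list(c("1a", "2"), c("1b", "2")),
                intra = list(c("1a", "1b")))
  combos <- unique(rater_table[, c("region", "metric")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- rater_table[rater_table$region == combos$region[i] &
                         rater_table$metric == combos$metric[i], ]
    for (cmp in names(pairs)) {
      parts <- lapply(pairs[[cmp]], function(p) {
        icc_decompose(sub[sub$rater %in% p, ],
                      region = combos$region[i], metric = combos$metric[i])
      })
      avg <- colMeans(do.call(rbind, lapply(parts, function(d)
        d[, c("icc", "wsc", "noise")])))
      rows[[length(rows) + 1L]] <- data.frame(
        region = combos$region[i], metric = combos$metric[i],
        comparison = cmp, icc = avg[["icc"]], wsc = avg[["wsc"]],
        noise = avg[["noise"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a rater table with known variance components
#'
#' Additive two-way random-effects model: value_ij = mean + subject_i +
#' rater_j + error_ij with independent zero-mean Gaussian components. The
#' population ICC is sigma_subject^2 / (sigma_subject^2 + sigma_rater^2 +
#' sigma_error^2).
#'
#' @param n_subjects number of subjects.
#' @param raters character vector of rater/session labels.
#' @param sigma_subject,sigma_rater,sigma_error component SDs.
#' @param mean grand mean.
#' @param seed optional RNG seed.
#' @return data frame with columns `subject`, `rater`, `value`.
#' @export
simulate_rater_table <- function(n_subjects, raters = c("1a", "1b", "2"),
                                 sigma_subject = 1, sigma_rater = 0.2,
                                 sigma_error = 0.3, mean = 0, seed = NULL) {
  with_seed(seed, {
    s <- stats::rnorm(n_subjects, sd = sigma_subject)
    r <- stats::rnorm(length(raters), sd = sigma_rater)
    g <- expand.grid(subject = seq_len(n_subjects), rater = raters,
                     stringsAsFactors = FALSE)
    g$value <- mean + s[g$subject] + r[match(g$rater, raters)] +
      stats::rnorm(nrow(g), sd = sigma_error)
    g
  })
}

#' Scan-rescan voxelwise agreement
#'
#' For each compartment (e.g. the union of brown-adipose segmentations, the
#' nuchal white-adipose region, and all remaining appreciable-signal voxels)
#' computes the Pearson correlation of voxelwise fat fractions between the
#' two acquisitions and the mean absolute fat-fraction residual in
#' percentage points. No registration is applied.
#'
#' @param ff1,ff2 `fat_fraction_map` objects from the two acquisitions.
#' @param compartments named list of `region_mask` objects; a compartment
#'   named `all_other` is added automatically as signal minus the union of
#'   the given compartments.
#' @param signal a `signal_mask` restricting all comparisons.
#' @param min_voxels compartments with fewer jointly valid voxels are
#'   skipped with a warning.
#' @return data frame with one row per compartment: `n_voxels`, `r`,
#'   `mean_abs_residual_pct`.
#' @export
rescan_agreement <- function(ff1, ff2, compartments, signal,
                             min_voxels = 10L) {
  stopifnot(inherits(ff1, "fat_fraction_map"),
            inherits(ff2, "fat_fraction_map"))
  check_congruent(ff1$ff, ff2$ff, "fat-fraction maps")
  comp <- compartments
  used <- Reduce(`|`, lapply(comp, function(m) m$mask),
                 accumulate = FALSE) | array(FALSE, dim(ff1$ff))
  other <- structure(list(mask = signal$mask & !used, region = "all_other",
                          spacing = ff1$spacing,
                          provenance = list(source = "derived")),
                     class = "region_mask")
  comp$all_other <- other
  rows <- list()
  for (nm in names(comp)) {
    sel <- comp[[nm]]$mask & signal$mask & ff1$valid & ff2$valid
    a <- ff1$ff[sel]; b <- ff2$ff[sel]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < min_voxels) {
      warning("compartment '", nm, "' has fewer than ", min_voxels,
              " valid voxels; skipped", call. = FALSE)
      next
    }
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      compartment = nm, n_voxels = length(a), r = r,
      mean_abs_residual_pct = 100 * mean(abs(a - b)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
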