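# Independent oracles and small fixture builders used across the suite.

# Skew-normal CDF by numerical integration of the density, with the
# moment-inversion re-derived inline (independent of the package path).
oracle_sn_cdf <- function(x, mean, sd, skewness) {
  b <- sqrt(2 / pi)
  if (skewness == 0) {
    delta <- 0
  } else {
    g23 <- abs(skewness)^(2 / 3)
    delta <- sign(skewness) *
      sqrt((pi / 2) * g23 / (g23 + ((4 - pi) / 2)^(2 / 3)))
  }
  omega <- sd / sqrt(1 - b^2 * delta^2)
  xi <- mean - omega * b * delta
  alpha <- delta / sqrt(1 - delta^2)
  dens <- function(t) {
    z <- (t - xi) / omega
    2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
  }
  stats::integrate(dens, xi - 12 * omega, x, rel.tol = 1e-9)$value
}

# Two-way ANOVA variance components computed from sums of squares by hand.
oracle_two_way_components <- function(tab) {
  x <- stats::xtabs(value ~ subject + rater, data = tab)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ss_s <- k * sum((rm_ - grand)^2)
  ss_r <- n * sum((cm - grand)^2)
  resid <- sweep(sweep(x, 1, rm_), 2, cm) + grand
  ss_e <- sum(resid^2)
  ms_s <- ss_s / (n - 1); ms_r <- ss_r / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  c(sigma2_subject = max((ms_s - ms_e) / k, 0),
    sigma2_rater = max((ms_r - ms_e) / n, 0),
    sigma2_error = ms_e)
}

# AUC as the brute-force pairwise comparison probability P(bat < wat).
oracle_pairwise_auc <- function(bat, wat) {
  cmp <- outer(bat, wat, `<`) + 0.5 * outer(bat, wat, `==`)
  mean(cmp)
}

# Closed-form paired t statistic.
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# Single-ellipsoid phantom: one brown-adipose-like depot in air, small grid.
single_depot_phantom <- function(mean_ff = 0.40, sd_ff = 0.03,
                                 radii = c(8, 7, 6), noise_sd = 0.02,
                                 seed = 1L, region = "supraclavicular_L") {
  spec <- phantom_spec(
    grid = c(48L, 40L, 32L), spacing = c(1, 1, 1),
    depots = list(list(
      geometry = depot_geometry(region, c(24, 20, 16), radii),
      tissue = tissue_distribution(region, mean_ff, sd_ff))),
    noise_sd = noise_sd, seed = seed)
  make_phantom(spec)
}

# Two disjoint depots (same grid) for connectivity tests.
two_depot_phantom <- function(noise_sd = 0.02, seed = 1L) {
  dep <- function(region, ctr) list(
    geometry = depot_geometry(region, ctr, c(5, 5, 5)),
    tissue = tissue_distribution(region, 0.40, 0.02))
  spec <- phantom_spec(
    grid = c(48L, 40L, 32L), spacing = c(1, 1, 1),
    depots = list(dep("supraclavicular_L", c(13, 20, 16)),
                  dep("supraclavicular_R", c(35, 20, 16))),
    noise_sd = noise_sd, seed = seed)
  make_phantom(spec)
}

# Two depots joined by an in-band corridor of unlabelled tissue; the only
# regime in which seed placement can move the segmentation at all.
corridor_phantom <- function(seed = 1L) {
  dep <- function(region, ctr) list(
    geometry = depot_geometry(region, ctr, c(5, 5, 5)),
    tissue = tissue_distribution(region, 0.40, 0.02))
  corridor <- list(
    geometry = depot_geometry("other_soft_tissue", c(24, 19, 15),
                              c(9, 2.5, 2.5)),
    tissue = tissue_distribution("corridor", 0.40, 0.02))
  make_phantom(phantom_spec(
    grid = c(48L, 40L, 32L), spacing = c(1, 1, 1),
    depots = list(corridor, dep("supraclavicular_L", c(13, 19, 15)),
                  dep("axillary_L", c(35, 19, 15))),
    noise_sd = 0.02, seed = seed))
}

truth_mask <- function(truth, regions) {
  neobat:::region_mask_from_truth(truth, regions)
}

sample_skewness <- function(x) mean(((x - mean(x)) / stats::sd(x))^3)
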