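# Skew-normal tissue fat-fraction distributions.
#
# Ex vivo adipose FF histograms are reported as mean, SD and skewness only,
# so tissues are modelled by the three-parameter skew-normal family, the
# simplest unimodal law pinned down exactly by those three moments. The
# skew-normal can represent skewness only up to |g1| < 0.99527 (the limit as
# the shape parameter goes to infinity); distributions outside that range are
# rejected.

# maximum skewness attainable by a skew-normal (delta -> 1)
.sn_skew_max <- 0.9952717

#' Tissue fat-fraction distribution
#'
#' @param name label for the tissue (e.g. "bat", "wat").
#' @param mean_ff mean fat fraction, in (0, 1).
#' @param sd_ff standard deviation of the fat fraction (>= 0; 0 gives a
#'   degenerate point mass).
#' @param skewness moment skewness; must satisfy |skewness| < 0.99527, the
#'   representable range of the skew-normal family.
#' @param total_signal combined water + fat signal of the tissue (arbitrary
#'   units, constant within the tissue up to acquisition noise).
#' @return object of class `tissue_distribution`.
#' @export
tissue_distribution <- function(name, mean_ff, sd_ff, skewness = 0,
                                total_signal = 1) {
  stopifnot(length(mean_ff) == 1, length(sd_ff) == 1, length(skewness) == 1)
  if (!(mean_ff > 0 && mean_ff < 1)) {
    stop("mean_ff must lie strictly between 0 and 1", call. = FALSE)
  }
  if (sd_ff < 0) stop("sd_ff must be non-negative", call. = FALSE)
  if (abs(skewness) >= .sn_skew_max) {
    stop("unrepresentable distribution: |skewness| = ", abs(skewness),
         " exceeds the skew-normal limit ", .sn_skew_max, call. = FALSE)
  }
  structure(list(name = name, mean_ff = mean_ff, sd_ff = sd_ff,
                 skewness = skewness, total_signal = total_signal),
            class = "tissue_distribution")
}

#' Skew-normal parameters from moments
#'
#' Moment-matches a skew-normal SN(xi, omega, alpha) to a requested mean,
#' standard deviation and skewness. Writing b = sqrt(2/pi) and
#' delta = alpha / sqrt(1 + alpha^2), the skew-normal has
#' mean xi + omega * b * delta, variance omega^2 * (1 - b^2 * delta^2) and
#' skewness g1 = (4 - pi)/2 * (b * delta)^3 / (1 - b^2 * delta^2)^(3/2);
#' inverting g1 for delta gives the closed form used here.
#'
#' @param mean,sd,skewness target moments (sd > 0, |skewness| < 0.99527).
#' @return list with elements `xi`, `omega`, `alpha`, `delta`.
#' @export
skew_normal_params <- function(mean, sd, skewness = 0) {
  if (abs(skewness) >= .sn_skew_max) {
    stop("unrepresentable distribution: |skewness| >= ", .sn_skew_max,
         call. = FALSE)
  }
  stopifnot(sd > 0)
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
  alpha <- if (abs(delta) >= 1) Inf * sign(delta) else delta / sqrt(1 - delta^2)
  list(xi = xi, omega = omega, alpha = alpha, delta = delta)
}

#' Draw skew-normal variates
#'
#' Uses the representation X = xi + omega * (delta * |U0| +
#' sqrt(1 - delta^2) * U1) with independent standard normals U0, U1.
#'
#' @param n number of draws.
#' @param params list from [skew_normal_params()].
#' @return numeric vector of draws.
#' @export
rskewnorm <- function(n, params) {
  d <- params$delta
  params$xi + params$omega * (d * abs(stats::rnorm(n)) +
                                sqrt(1 - d^2) * stats::rnorm(n))
}

#' Sample voxel fat fractions for a tissue
#'
#' Draws `n` fat-fraction values from the moment-matched skew-normal for the
#' tissue and clips them to [0, 1]. The fraction of clipped draws is recorded
#' in the `"clip_fraction"` attribute; clipping perturbs the realised moments
#' only when the distribution has appreciable mass outside the unit interval.
#'
#' @param dist a [tissue_distribution()].
#' @param n number of voxels to sample.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return numeric vector in [0, 1] with attribute `clip_fraction`.
#' @export
sample_ff <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "tissue_distribution"))
  with_seed(seed, {
    if (dist$sd_ff == 0) {
      x <- rep(dist$mean_ff, n)
      clipped <- 0
    } else {
      p <- skew_normal_params(dist$mean_ff, dist$sd_ff, dist$skewness)
      x <- rskewnorm(n, p)
      clipped <- mean(x < 0 | x > 1)
      x <- pmin(pmax(x, 0), 1)
    }
    attr(x, "clip_fraction") <- clipped
    x
  })
}

# Analytic moments of a skew-normal given its parameter list; used for
# documentation/testing of the moment-matching round trip.
#' @keywords internal
skew_normal_moments <- function(params) {
  b <- sqrt(2 / pi)
  d <- params$delta
  m <- params$xi + params$omega * b * d
  v <- params$omega^2 * (1 - b^2 * d^2)
  g1 <- (4 - pi) / 2 * (b * d)^3 / (1 - b^2 * d^2)^(3 / 2)
  list(mean = m, sd = sqrt(v), skewness = g1)
}
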