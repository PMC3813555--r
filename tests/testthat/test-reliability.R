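# ICC/WSC/N decomposition, rescan agreement, ROC calibration.

test_that("all-subject variance gives ICC 1; rater offsets give WSC 1", {
  tab <- expand.grid(subject = 1:6, rater = c("a", "b"))
  tab$value <- c(1:6, 1:6) # identical across raters
  r1 <- icc_decompose(tab)
  expect_equal(r1$icc, 1)
  expect_equal(r1$wsc, 0)
  expect_equal(r1$noise, 0)
  tab$value <- ifelse(tab$rater == "a", 5, 7) # subjects identical
  r2 <- icc_decompose(tab)
  expect_equal(r2$icc, 0)
  expect_equal(r2$wsc, 1)
  expect_equal(r2$noise, 0)
})

test_that("components match a hand-computed mean-squares oracle", {
  set.seed(11)
  for (rep_i in 1:5) {
    tab <- expand.grid(subject = 1:6, rater = c("a", "b"))
    tab$value <- rnorm(12)
    est <- icc_decompose(tab)
    orc <- oracle_two_way_components(tab)
    expect_equal(est$sigma2_subject, orc[["sigma2_subject"]],
                 tolerance = 1e-10)
    expect_equal(est$sigma2_rater, orc[["sigma2_rater"]], tolerance = 1e-10)
    expect_equal(est$sigma2_error, orc[["sigma2_error"]], tolerance = 1e-10)
    expect_equal(est$icc + est$wsc + est$noise, 1, tolerance = 1e-12)
    expect_true(all(c(est$icc, est$wsc, est$noise) >= 0 &
                      c(est$icc, est$wsc, est$noise) <= 1))
  }
})

test_that("the decomposition is invariant to affine rescaling", {
  set.seed(12)
  tab <- expand.grid(subject = 1:8, rater = c("a", "b", "c"))
  tab$value <- rnorm(24)
  r1 <- icc_decompose(tab)
  tab$value <- 3.7 * tab$value + 42
  r2 <- icc_decompose(tab)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-10)
  expect_equal(r1$wsc, r2$wsc, tolerance = 1e-10)
})

test_that("layout violations and zero variance are reported", {
  tab <- expand.grid(subject = 1:6, rater = c("a", "b"))
  tab$value <- rnorm(12)
  expect_error(icc_decompose(tab[-1, ]), "layout error")
  expect_error(icc_decompose(tab[tab$rater == "a", ]), "layout error")
  tab$value <- 1
  deg <- icc_decompose(tab)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$icc))
})

test_that("simulated tables recover population ICC across the 0.41-0.97 regime", {
  set.seed(13)
  for (icc0 in c(0.41, 0.6, 0.8, 0.97)) {
    ss <- sqrt(icc0)
    sr <- sqrt((1 - icc0) * 0.3)
    se <- sqrt((1 - icc0) * 0.7)
    est <- replicate(25, {
      tab <- simulate_rater_table(100, raters = c("a", "b"),
                                  sigma_subject = ss, sigma_rater = sr,
                                  sigma_error = se)
      icc_decompose(tab)$icc
    })
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - icc0), 3 * mc_se + 0.01)
  }
})

test_that("the three-rating report averages the stated pairs", {
  set.seed(14)
  rt <- simulate_rater_table(10, raters = c("1a", "1b", "2"),
                             sigma_subject = 1, sigma_rater = 0.3,
                             sigma_error = 0.2)
  rt$region <- "union"; rt$metric <- "volume_cc"
  rep_ <- reliability_report(rt)
  expect_setequal(rep_$comparison, c("inter", "intra"))
  manual_inter <- mean(c(
    icc_decompose(rt[rt$rater %in% c("1a", "2"), ])$icc,
    icc_decompose(rt[rt$rater %in% c("1b", "2"), ])$icc))
  expect_equal(rep_$icc[rep_$comparison == "inter"], manual_inter,
               tolerance = 1e-12)
  manual_intra <- icc_decompose(rt[rt$rater %in% c("1a", "1b"), ])$icc
  expect_equal(rep_$icc[rep_$comparison == "intra"], manual_intra,
               tolerance = 1e-12)
})

test_that("identical acquisitions give r = 1 and zero residual", {
  ph <- single_depot_phantom(seed = 15)
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  comp <- list(depot = truth_mask(ph$truth, "supraclavicular_L"))
  ag <- suppressWarnings(rescan_agreement(ffm, ffm, comp, sm))
  expect_equal(ag$r, rep(1, nrow(ag)), tolerance = 1e-12)
  expect_true(all(ag$mean_abs_residual_pct == 0))
})

test_that("rescan agreement is symmetric and matches a Monte-Carlo oracle", {
  noise_sd <- 0.04
  ph <- single_depot_phantom(seed = 16, noise_sd = noise_sd)
  re <- make_rescan(ph, noise_sd = noise_sd, seed = 17)
  ff1 <- compute_fat_fraction(separate_water_fat(ph$echoes))
  ff2 <- compute_fat_fraction(separate_water_fat(re))
  sm <- signal_mask(separate_water_fat(ph$echoes))
  comp <- list(depot = truth_mask(ph$truth, "supraclavicular_L"))
  ag12 <- suppressWarnings(rescan_agreement(ff1, ff2, comp, sm))
  ag21 <- suppressWarnings(rescan_agreement(ff2, ff1, comp, sm))
  expect_equal(ag12$r, ag21$r, tolerance = 1e-12)
  expect_equal(ag12$mean_abs_residual_pct, ag21$mean_abs_residual_pct,
               tolerance = 1e-12)

  # brute-force two-realization oracle on the same true voxels
  set.seed(18)
  m <- truth_mask(ph$truth, "supraclavicular_L")$mask
  w <- ph$truth$water[m]; f <- ph$truth$fat[m]
  draw_ff <- function() {
    ip <- pmax(w + f + rnorm(length(w), sd = noise_sd), 0)
    op <- pmax(abs(w - f) + rnorm(length(w), sd = noise_sd), 0)
    a <- (ip + op) / 2
    b <- pmax((ip - op) / 2, 0)
    fat <- ifelse(f > w, a, b)
    fat / (a + b)
  }
  res <- replicate(40, mean(abs(draw_ff() - draw_ff())))
  oracle <- 100 * mean(res)
  got <- ag12$mean_abs_residual_pct[ag12$compartment == "depot"]
  expect_lt(abs(got - oracle), 0.15)
})

test_that("independent noise-only maps are uncorrelated", {
  set.seed(19)
  d <- c(12, 12, 12)
  f1 <- array(runif(prod(d)), d); f2 <- array(runif(prod(d)), d)
  mk <- function(x) structure(list(ff = x, valid = array(TRUE, d),
                                   spacing = c(1, 1, 1)),
                              class = "fat_fraction_map")
  smx <- structure(list(mask = array(TRUE, d), mean = 0, sd = 1,
                        threshold = 0, spacing = c(1, 1, 1)),
                   class = "signal_mask")
  m <- array(FALSE, d); m[1:800] <- TRUE
  comp <- list(x = structure(list(mask = m, region = "x",
                                  spacing = c(1, 1, 1),
                                  provenance = list()),
                             class = "region_mask"))
  ag <- rescan_agreement(mk(f1), mk(f2), comp, smx)
  expect_lt(abs(ag$r[ag$compartment == "x"]), 0.1)
})

test_that("tiny compartments are skipped with a warning", {
  ph <- single_depot_phantom(seed = 20)
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  tiny <- array(FALSE, dim(ffm$ff)); tiny[1:3] <- TRUE
  comp <- list(tiny = structure(list(mask = tiny, region = "tiny",
                                     spacing = ffm$spacing,
                                     provenance = list()),
                                class = "region_mask"))
  expect_warning(ag <- rescan_agreement(ffm, ffm, comp, sm),
                 "fewer than")
  expect_false("tiny" %in% ag$compartment)
})

test_that("ROC sweep separates, calibrates and matches the pairwise AUC", {
  # perfectly separated samples
  roc <- roc_calibrate(c(0.2, 0.3, 0.35), c(0.7, 0.8, 0.9))
  expect_equal(roc$auc, 1)
  expect_gte(roc$upper, 0.35)
  expect_lte(roc$upper, 0.7)
  # monotone rates
  sweep_tab <- roc$thresholds
  expect_true(all(diff(sweep_tab$bat_below) >= 0))
  expect_true(all(diff(sweep_tab$wat_below) >= 0))
  expect_true(all(diff(sweep_tab$bat_above) <= 0))
  # trapezoid AUC equals brute-force pairwise probability on small samples
  set.seed(21)
  for (i in 1:3) {
    bat <- pmin(pmax(round(rnorm(40, 0.4, 0.1), 3), 0), 1)
    wat <- pmin(pmax(round(rnorm(40, 0.7, 0.12), 3), 0), 1)
    roc2 <- roc_calibrate(bat, wat)
    expect_equal(roc2$auc, oracle_pairwise_auc(bat, wat), tolerance = 1e-9)
  }
  # degenerate identical constants
  expect_error(roc_calibrate(rep(0.5, 5), rep(0.5, 5)), "no-threshold")
})
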