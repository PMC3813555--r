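# Threshold-constrained seeded region growing.

setup_single <- function(seed = 1L, ...) {
  ph <- single_depot_phantom(seed = seed, ...)
  wf <- separate_water_fat(ph$echoes)
  list(ph = ph, wf = wf, ffm = compute_fat_fraction(wf),
       sm = signal_mask(wf))
}

test_that("zero iterations return the rasterized seed bubbles", {
  s <- setup_single()
  proto <- segmentation_protocol()
  seg <- segment_bat_region(s$ffm, s$ph$seeds, proto, iterations = 0)
  bubbles <- neobat:::rasterize_seed_bubbles(s$ph$seeds, dim(s$ffm$ff),
                                             s$ffm$spacing)
  eligible <- neobat:::bat_eligibility(s$ffm, proto)
  expect_identical(seg$mask, bubbles & eligible)
  # deep inside the depot the bubble is fully eligible
  expect_gt(sum(seg$mask) / sum(bubbles), 0.95)
})

test_that("growth is monotone in the iteration count", {
  s <- setup_single(seed = 2)
  proto <- segmentation_protocol()
  prev <- NULL
  for (k in c(0, 1, 3, 6, 12, 50)) {
    seg <- segment_bat_region(s$ffm, s$ph$seeds, proto, iterations = k)
    if (!is.null(prev)) expect_true(all(prev <= seg$mask))
    prev <- seg$mask
  }
})

test_that("the result is confined to the eligibility set and holds seeds", {
  for (sd_i in 1:3) {
    s <- setup_single(seed = sd_i, mean_ff = 0.30 + 0.05 * sd_i,
                      radii = c(6 + sd_i, 7, 5 + sd_i))
    proto <- segmentation_protocol()
    seg <- segment_bat_region(s$ffm, s$ph$seeds, proto, s$sm)
    eligible <- neobat:::bat_eligibility(s$ffm, proto, s$sm)
    expect_false(any(seg$mask & !eligible))
    idx <- neobat:::seed_center_index(s$ph$seeds, dim(s$ffm$ff),
                                      s$ffm$spacing)
    expect_true(all(seg$mask[idx]))
  }
})

test_that("a centroid-seeded in-band depot is recovered with Dice >= 0.9", {
  s <- setup_single(seed = 4, mean_ff = 0.40, sd_ff = 0.03)
  seg <- segment_bat_region(s$ffm, s$ph$seeds, segmentation_protocol(),
                            s$sm)
  depot <- truth_mask(s$ph$truth, "supraclavicular_L")$mask
  expect_gte(dice_coefficient(seg$mask, depot), 0.90)
})

test_that("only components touching a seed are labelled", {
  ph <- two_depot_phantom(seed = 5)
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  one <- ph$seeds[ph$seeds$region == "supraclavicular_L", ]
  seg <- segment_bat_region(ffm, one, segmentation_protocol(), sm)
  left <- truth_mask(ph$truth, "supraclavicular_L")$mask
  right <- truth_mask(ph$truth, "supraclavicular_R")$mask
  expect_gt(sum(seg$mask & left), 0)
  expect_identical(sum(seg$mask & right), 0L)
})

test_that("seed-placement and protocol violations raise named errors", {
  s <- setup_single(seed = 6)
  proto <- segmentation_protocol()
  bad <- s$ph$seeds
  bad$x_mm <- 2; bad$y_mm <- 2; bad$z_mm <- 2 # air corner
  expect_error(segment_bat_region(s$ffm, bad, proto, s$sm),
               "seed-placement error.*supraclavicular_L")
  five <- s$ph$seeds[rep(1, 5), ]
  expect_error(segment_bat_region(s$ffm, five, proto),
               "protocol error")
  spine_bad <- seed_spec("spine_T6_L", 24, 20, 16)
  expect_error(segment_bat_region(s$ffm, spine_bad, proto),
               "T1-T5")
  dup <- rbind(seed_spec("spine_T1_L", 24, 20, 16),
               seed_spec("spine_T1_L", 25, 20, 16))
  expect_error(segment_bat_region(s$ffm, dup, proto),
               "one spinal seed per side")
})

test_that("iteration counts follow the protocol and admit 40-60 for spine", {
  expect_error(segmentation_protocol(iterations_spine = 30), "iterations")
  p45 <- segmentation_protocol(iterations_spine = 45)
  expect_identical(p45$iterations_spine, 45L)
})

test_that("nuchal white adipose segmentation recovers the depot", {
  ph <- make_torso_phantom(torso_phantom_spec(seed = 41))
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  seed <- ph$seeds[ph$seeds$region == "nuchal_wat", ]
  seg <- segment_wat_nuchal(wf, seed, signal = sm)
  st <- depot_stats(seg, ffm)
  true_ff <- ph$truth$region_table$mean_ff[
    ph$truth$region_table$region == "nuchal_wat"]
  expect_lt(abs(st$mean_ff - true_ff), 0.02)
  # wrong seed radius violates the protocol
  seed3 <- seed; seed3$radius_mm <- 3
  expect_error(segment_wat_nuchal(wf, seed3, signal = sm),
               "protocol error")
  # a seed parked in water-rich tissue is sub-quartile
  bad <- seed; bad$x_mm <- 62; bad$y_mm <- 46; bad$z_mm <- 20
  expect_error(segment_wat_nuchal(wf, bad, signal = sm),
               "sub-quartile")
})

test_that("a uniform fat image degrades gracefully to the signal mask", {
  water <- array(0, c(12, 12, 12)); fat <- array(0, c(12, 12, 12))
  fat[5:8, 5:8, 5:8] <- 1
  wf <- structure(list(water = water, fat = fat, spacing = c(1, 1, 1)),
                  class = "water_fat_volumes")
  seed <- seed_spec("nuchal_wat", 5.5, 5.5, 5.5, radius_mm = 5)
  expect_warning(seg <- segment_wat_nuchal(wf, seed), "degenerate")
  expect_true(all(seg$mask <= (fat > 0)))
})

test_that("union is the voxel-set union with subadditive volume", {
  ph <- two_depot_phantom(seed = 8)
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  proto <- segmentation_protocol()
  a <- segment_bat_region(ffm, ph$seeds[1, ], proto, sm, label = "a")
  b <- segment_bat_region(ffm, ph$seeds[2, ], proto, sm, label = "b")
  u <- union_region(a, b)
  expect_identical(sum(u$mask), sum(a$mask | b$mask))
  expect_identical(sum(u$mask), sum(a$mask) + sum(b$mask) -
                     sum(a$mask & b$mask))
  # a subset union collapses
  expect_identical(sum(union_region(a, a)$mask), sum(a$mask))
})

test_that("under 1 mm seed jitter the union varies less than its parts", {
  ph <- corridor_phantom(seed = 1)
  wf <- separate_water_fat(ph$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  proto <- segmentation_protocol()
  vols <- t(vapply(1:8, function(j) {
    js <- jitter_seeds(ph$seeds, 1, ph$truth, seed = j)
    js <- snap_seeds(js, ffm, proto, sm)
    sup <- segment_bat_region(ffm, js[js$region == "supraclavicular_L", ],
                              proto, sm, label = "sup", iterations = 12)
    ax <- segment_bat_region(ffm, js[js$region == "axillary_L", ],
                             proto, sm, label = "ax", iterations = 12)
    c(sup = sum(sup$mask), ax = sum(ax$mask),
      uni = sum(union_region(sup, ax)$mask))
  }, numeric(3)))
  cv <- apply(vols, 2, function(x) sd(x) / mean(x))
  expect_lt(cv[["uni"]], max(cv[["sup"]], cv[["ax"]]))
})

test_that("seed snapping moves centres onto eligible voxels only", {
  s <- setup_single(seed = 9)
  proto <- segmentation_protocol()
  off <- s$ph$seeds
  off$x_mm <- off$x_mm + 9 # just outside the depot (radius 8 mm)
  snapped <- snap_seeds(off, s$ffm, proto, s$sm)
  idx <- neobat:::seed_center_index(snapped, dim(s$ffm$ff), s$ffm$spacing)
  eligible <- neobat:::bat_eligibility(s$ffm, proto, s$sm)
  expect_true(all(eligible[idx]))
  far <- s$ph$seeds
  far$x_mm <- 2; far$y_mm <- 2; far$z_mm <- 2
  expect_error(snap_seeds(far, s$ffm, proto, s$sm), "seed-placement error")
})
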