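# Threshold-constrained seeded segmentation of adipose depots.
#
# Reproduces the semi-automated protocol used for the neonate ROIs: seed
# bubbles are placed in depots, the evolution is confined to an intensity
# eligibility set (fat fraction between 20% and 60% for brown adipose;
# fat-image values above the lowest quartile for white adipose) and iterated
# a fixed number of times. The continuous active-contour evolution is
# modelled as morphological region growing at one voxel shell per iteration
# with a curvature-smoothing annexation rule, so the iteration count maps
# one-to-one onto growth shells and acts as the stopping rule exactly as in
# the interactive protocol.

#' Segmentation protocol parameters
#'
#' @param ff_band fat-fraction eligibility band for brown adipose
#'   (default `c(0.20, 0.60)`).
#' @param iterations_spine iterations for spinal depots; the protocol admits
#'   40-60, default 50.
#' @param iterations_supraclavicular,iterations_axillary fixed at 50 to
#'   avoid bleeding in these more heterogeneous regions.
#' @param iterations_wat iterations for the nuchal white-adipose region
#'   (default 100).
#' @param wat_quantile fat-image quantile defining white-adipose
#'   eligibility (values above the lowest quartile, default 0.25).
#' @param seed_radius_mm,wat_seed_radius_mm seed bubble radii (3 mm for
#'   brown adipose, 5 mm for the single nuchal seed).
#' @param max_seeds_per_side seed-count limits per side for the
#'   supraclavicular and axillary regions (4 each); spinal depots take one
#'   seed per side per vertebra, T1-T5 only.
#' @param min_neighbors curvature-smoothing parameter of [grow_region()].
#' @return object of class `segmentation_protocol`.
#' @export
segmentation_protocol <- function(ff_band = c(0.20, 0.60),
                                  iterations_spine = 50L,
                                  iterations_supraclavicular = 50L,
                                  iterations_axillary = 50L,
                                  iterations_wat = 100L,
                                  wat_quantile = 0.25,
                                  seed_radius_mm = 3,
                                  wat_seed_radius_mm = 5,
                                  max_seeds_per_side = c(supraclavicular = 4L,
                                                         axillary = 4L),
                                  min_neighbors = 3L) {
  stopifnot(length(ff_band) == 2, ff_band[1] >= 0, ff_band[2] <= 1,
            ff_band[1] < ff_band[2],
            iterations_spine >= 40L, iterations_spine <= 60L,
            iterations_supraclavicular > 0L, iterations_axillary > 0L,
            iterations_wat > 0L)
  structure(list(ff_band = ff_band,
                 iterations_spine = as.integer(iterations_spine),
                 iterations_supraclavicular =
                   as.integer(iterations_supraclavicular),
                 iterations_axillary = as.integer(iterations_axillary),
                 iterations_wat = as.integer(iterations_wat),
                 wat_quantile = wat_quantile,
                 seed_radius_mm = seed_radius_mm,
                 wat_seed_radius_mm = wat_seed_radius_mm,
                 max_seeds_per_side = max_seeds_per_side,
                 min_neighbors = as.integer(min_neighbors)),
            class = "segmentation_protocol")
}

#' Construct a seed table
#' @param region region label per seed.
#' @param x_mm,y_mm,z_mm seed centres in world mm.
#' @param radius_mm seed bubble radius in mm (> 0).
#' @return data frame with one row per seed.
#' @export
seed_spec <- function(region, x_mm, y_mm, z_mm, radius_mm = 3) {
  stopifnot(all(radius_mm > 0))
  data.frame(region = region, x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
             radius_mm = radius_mm, stringsAsFactors = FALSE)
}

region_group <- function(region) {
  ifelse(grepl("^supraclavicular", region), "supraclavicular",
  ifelse(grepl("^axillary", region), "axillary",
  ifelse(grepl("^spine", region), "spine",
  ifelse(grepl("wat", region), "wat", "other"))))
}

check_seed_limits <- function(seeds, protocol) {
  grp <- region_group(seeds$region)
  for (g in c("supraclavicular", "axillary")) {
    lim <- protocol$max_seeds_per_side[[g]]
    per_side <- table(seeds$region[grp == g])
    if (any(per_side > lim)) {
      stop("protocol error: more than ", lim, " ", g, " seeds on one side",
           call. = FALSE)
    }
  }
  sp <- seeds$region[grp == "spine"]
  if (length(sp)) {
    if (!all(grepl("^spine_T[1-5]_(L|R)$", sp))) {
      stop("protocol error: spinal seeds are limited to T1-T5, one per side",
           call. = FALSE)
    }
    if (any(table(sp) > 1L)) {
      stop("protocol error: more than one spinal seed per side per vertebra",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

rasterize_seed_bubbles <- function(seeds, grid, spacing) {
  m <- array(FALSE, grid)
  for (i in seq_len(nrow(seeds))) {
    geom <- depot_geometry(seeds$region[i],
                           c(seeds$x_mm[i], seeds$y_mm[i], seeds$z_mm[i]),
                           rep(seeds$radius_mm[i], 3))
    # seed bubbles may graze the grid edge; clip instead of erroring
    xs <- axis_mm(grid[1], spacing[1]); ys <- axis_mm(grid[2], spacing[2])
    zs <- axis_mm(grid[3], spacing[3])
    q <- outer(outer(((xs - geom$center_mm[1]) / geom$radii_mm[1])^2,
                     ((ys - geom$center_mm[2]) / geom$radii_mm[2])^2, `+`),
               ((zs - geom$center_mm[3]) / geom$radii_mm[3])^2, `+`)
    m <- m | (q <= 1)
  }
  m
}

seed_center_index <- function(seeds, grid, spacing) {
  idx <- world_to_index(as.matrix(seeds[, c("x_mm", "y_mm", "z_mm")]),
                        spacing)
  idx[] <- pmin(pmax(idx, 1L), matrix(grid, nrow(idx), 3, byrow = TRUE))
  idx
}

bat_eligibility <- function(ff, protocol, signal = NULL) {
  eligible <- ff$valid & !is.na(ff$ff) &
    ff$ff >= protocol$ff_band[1] & ff$ff <= protocol$ff_band[2]
  eligible[is.na(eligible)] <- FALSE
  if (!is.null(signal)) eligible <- eligible & signal$mask
  eligible
}

#' Segment a brown-adipose region from seeds
#'
#' Grows the rasterized seed bubbles inside the eligibility set (fat
#' fraction within the protocol band, intersected with the
#' appreciable-signal mask when supplied) for the protocol's iteration count
#' of the region group. Only components touching a seed can be produced, by
#' construction.
#'
#' @param ff a `fat_fraction_map`.
#' @param seeds seed table (see [seed_spec()]); seed centres must fall on
#'   eligible voxels and counts must respect the protocol limits.
#' @param protocol a [segmentation_protocol()].
#' @param signal optional `signal_mask` restricting eligibility.
#' @param label region label for the result; defaults to the seed group.
#' @param iterations overrides the protocol iteration count when given.
#' @return object of class `region_mask` with provenance (seeds, iterations
#'   requested and run, band).
#' @export
segment_bat_region <- function(ff, seeds, protocol = segmentation_protocol(),
                               signal = NULL, label = NULL,
                               iterations = NULL) {
  stopifnot(inherits(ff, "fat_fraction_map"), nrow(seeds) >= 1)
  check_seed_limits(seeds, protocol)
  grid <- dim(ff$ff)
  eligible <- bat_eligibility(ff, protocol, signal)
  idx <- seed_center_index(seeds, grid, ff$spacing)
  ok <- eligible[idx]
  if (!all(ok)) {
    bad <- seeds$region[!ok][1]
    stop("seed-placement error: seed '", bad, "' at (",
         paste(signif(unlist(seeds[!ok, c("x_mm", "y_mm", "z_mm")][1, ]), 4),
               collapse = ", "),
         ") mm is outside the eligibility set", call. = FALSE)
  }
  grp <- unique(region_group(seeds$region))
  if (is.null(iterations)) {
    iterations <- if (identical(grp, "spine")) protocol$iterations_spine
      else if (identical(grp, "axillary")) protocol$iterations_axillary
      else protocol$iterations_supraclavicular
  }
  bubbles <- rasterize_seed_bubbles(seeds, grid, ff$spacing)
  g <- grow_region(bubbles, eligible, iterations, protocol$min_neighbors)
  if (is.null(label)) label <- paste(sort(grp), collapse = "+")
  structure(list(mask = g$mask, region = label, spacing = ff$spacing,
                 provenance = list(seeds = seeds,
                                   iterations_requested = iterations,
                                   iterations_run = g$iterations_run,
                                   ff_band = protocol$ff_band)),
            class = "region_mask")
}

#' Segment nuchal white adipose from the fat image
#'
#' Eligibility is the set of voxels whose fat-image value exceeds the lowest
#' quartile of fat values within the appreciable-signal mask; a single 5 mm
#' seed is grown for the protocol's white-adipose iteration count and only
#' the connected component containing the seed is returned.
#'
#' @param wf a `water_fat_volumes` (the fat image is taken from it).
#' @param seed one-row seed table with a 5 mm radius.
#' @param protocol a [segmentation_protocol()].
#' @param signal `signal_mask`; computed from `wf` when omitted.
#' @return a `region_mask` labelled `"nuchal_wat"`.
#' @export
segment_wat_nuchal <- function(wf, seed, protocol = segmentation_protocol(),
                               signal = NULL) {
  stopifnot(inherits(wf, "water_fat_volumes"), nrow(seed) == 1)
  if (!isTRUE(all.equal(seed$radius_mm, protocol$wat_seed_radius_mm))) {
    stop("protocol error: the nuchal seed radius must be ",
         protocol$wat_seed_radius_mm, " mm", call. = FALSE)
  }
  if (is.null(signal)) signal <- signal_mask(wf)
  fat <- wf$fat
  vals <- fat[signal$mask]
  if (length(vals) == 0L || max(vals) == min(vals)) {
    warning("degenerate fat image: quartile threshold undefined, ",
            "eligibility falls back to the signal mask", call. = FALSE)
    eligible <- signal$mask
    q <- NA_real_
  } else {
    q <- stats::quantile(vals, protocol$wat_quantile, names = FALSE)
    eligible <- signal$mask & (fat > q)
  }
  grid <- dim(fat)
  idx <- seed_center_index(seed, grid, wf$spacing)
  if (!eligible[idx]) {
    stop("seed-placement error: nuchal seed lies in a sub-quartile voxel",
         call. = FALSE)
  }
  bubbles <- rasterize_seed_bubbles(seed, grid, wf$spacing)
  g <- grow_region(bubbles, eligible, protocol$iterations_wat,
                   protocol$min_neighbors)
  structure(list(mask = g$mask, region = "nuchal_wat", spacing = wf$spacing,
                 provenance = list(seeds = seed,
                                   iterations_requested =
                                     protocol$iterations_wat,
                                   iterations_run = g$iterations_run,
                                   fat_quantile_threshold = q)),
            class = "region_mask")
}

#' Union of two region masks
#'
#' Voxel-set union; overlapping voxels are counted once. Used for the
#' supraclavicular + axillary union ROI that absorbs the occasionally
#' ambiguous border between the two regions.
#'
#' @param a,b `region_mask` objects on congruent grids.
#' @param label label for the union (default `"union"`).
#' @return a `region_mask`.
#' @export
union_region <- function(a, b, label = "union") {
  stopifnot(inherits(a, "region_mask"), inherits(b, "region_mask"))
  check_congruent(a$mask, b$mask, "region masks")
  structure(list(mask = a$mask | b$mask, region = label,
                 spacing = a$spacing,
                 provenance = list(parts = c(a$region, b$region))),
            class = "region_mask")
}

#' Snap seed centres onto eligible voxels
#'
#' Raters place seeds on voxels they can see are inside the fat-fraction
#' band; canonical centroid seeds generated from ground truth may land on a
#' voxel pushed out of the band by noise. This helper moves each seed centre
#' to the nearest eligible voxel within `max_shift_mm`.
#'
#' @param seeds seed table.
#' @param ff a `fat_fraction_map`.
#' @param protocol a [segmentation_protocol()].
#' @param signal optional `signal_mask`.
#' @param eligible optional precomputed eligibility array (overrides
#'   `ff`/`protocol`/`signal`).
#' @param max_shift_mm search radius (default 4 mm).
#' @return the seed table with adjusted centres.
#' @export
snap_seeds <- function(seeds, ff, protocol = segmentation_protocol(),
                       signal = NULL, eligible = NULL, max_shift_mm = 4) {
  if (is.null(eligible)) eligible <- bat_eligibility(ff, protocol, signal)
  grid <- dim(eligible)
  spacing <- ff$spacing
  idx <- seed_center_index(seeds, grid, spacing)
  rvox <- ceiling(max_shift_mm / spacing)
  for (i in seq_len(nrow(seeds))) {
    if (eligible[idx[i, , drop = FALSE]]) next
    lo <- pmax(idx[i, ] - rvox, 1L)
    hi <- pmin(idx[i, ] + rvox, grid)
    sub <- eligible[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cand <- which(sub, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      stop("seed-placement error: no eligible voxel within ", max_shift_mm,
           " mm of seed '", seeds$region[i], "'", call. = FALSE)
    }
    cand_full <- sweep(cand, 2, lo - 1L, `+`)
    w <- index_to_world(cand_full, spacing)
    ctr <- c(seeds$x_mm[i], seeds$y_mm[i], seeds$z_mm[i])
    d2 <- colSums((t(w) - ctr)^2)
    best <- w[which.min(d2), ]
    seeds$x_mm[i] <- best[1]; seeds$y_mm[i] <- best[2]
    seeds$z_mm[i] <- best[3]
  }
  seeds
}
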