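# Synthetic phantom generator.
#
# All inputs of the quantification pipeline can be simulated: ex vivo vial
# phantoms (excised adipose samples in glass tubes), a neonate torso with
# bilateral supraclavicular, axillary and spinal (T1-T5) brown-adipose
# depots plus a subcutaneous nuchal white-adipose depot, whole cohorts with
# between-subject variation, scan-rescan noise replicates and rater seed
# jitter. Depots are axis-aligned ellipsoids (vials are cylinders) so every
# true volume has a closed form, and voxel fat fractions inside a depot are
# drawn from the tissue's moment-matched skew-normal distribution.
#
# Forward model (magnitude dual-echo Dixon): with per-voxel water signal W
# and fat signal F,
#   in-phase      IP = W + F + noise
#   opposed-phase OP = |W - F| + noise
# with independent additive Gaussian noise on each echo (Rician behaviour is
# negligible at the simulated SNR) and magnitudes clipped at zero. Because
# the opposed-phase magnitude discards the sign of W - F, the phantom also
# emits the vendor-style dominance field (which compartment is larger per
# voxel), emulating the scanner's phase-based resolution; declared swap
# regions corrupt that field, which is how fat/water swap artifacts enter
# the simulation.

#' Ellipsoidal or cylindrical depot geometry
#'
#' @param region region label, e.g. `"supraclavicular_L"`, `"spine_T3_R"`,
#'   `"nuchal_wat"`, `"other_soft_tissue"`.
#' @param center_mm centre of the shape in world mm (length 3).
#' @param radii_mm principal semi-axes in mm (length 3). For cylinders the
#'   first two entries are the cross-section semi-axes and the third the
#'   half-length along z.
#' @param shape `"ellipsoid"` or `"cylinder"` (axis along z).
#' @return object of class `depot_geometry` with an `analytic_volume_cc`
#'   field.
#' @export
depot_geometry <- function(region, center_mm, radii_mm,
                           shape = c("ellipsoid", "cylinder")) {
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 3, length(radii_mm) == 3, all(radii_mm > 0))
  vol_mm3 <- switch(shape,
    ellipsoid = 4 / 3 * pi * prod(radii_mm),
    cylinder = pi * radii_mm[1] * radii_mm[2] * 2 * radii_mm[3]
  )
  structure(list(region = region, center_mm = center_mm, radii_mm = radii_mm,
                 shape = shape, analytic_volume_cc = vol_mm3 / 1000),
            class = "depot_geometry")
}

scale_geometry <- function(geom, volume_cc) {
  s <- (volume_cc / geom$analytic_volume_cc)^(1 / 3)
  depot_geometry(geom$region, geom$center_mm, geom$radii_mm * s, geom$shape)
}

#' Phantom specification
#'
#' @param grid integer length-3 grid shape in voxels.
#' @param spacing voxel spacing in mm (default 0.97 x 0.97 x 1, the
#'   acquisition voxel size; keeping it makes all volume arithmetic match).
#' @param depots list of elements, each a list with fields `geometry`
#'   (a [depot_geometry()]) and `tissue` (a [tissue_distribution()]).
#' @param noise_sd additive Gaussian noise SD on each magnitude echo, as a
#'   fraction of unit tissue signal (>= 0).
#' @param swap_regions optional list of [depot_geometry()] objects inside
#'   which the emitted water/fat dominance labels are exchanged, emulating a
#'   phase-ambiguity swap artifact.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 96L, 64L), spacing = c(0.97, 0.97, 1),
                         depots = list(), noise_sd = 0.04,
                         swap_regions = list(), seed = 1L) {
  stopifnot(length(grid) == 3, all(grid >= 4), all(spacing > 0),
            noise_sd >= 0)
  structure(list(grid = as.integer(grid), spacing = spacing, depots = depots,
                 noise_sd = noise_sd, swap_regions = swap_regions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize one shape: logical array, voxel centres inside the shape.
rasterize_shape <- function(geom, grid, spacing) {
  xs <- axis_mm(grid[1], spacing[1])
  ys <- axis_mm(grid[2], spacing[2])
  zs <- axis_mm(grid[3], spacing[3])
  u <- (xs - geom$center_mm[1]) / geom$radii_mm[1]
  v <- (ys - geom$center_mm[2]) / geom$radii_mm[2]
  w <- (zs - geom$center_mm[3]) / geom$radii_mm[3]
  if (geom$shape == "ellipsoid") {
    q <- outer(outer(u^2, v^2, `+`), w^2, `+`)
    q <= 1
  } else {
    disc <- outer(u^2, v^2, `+`) <= 1
    outer(disc, abs(w) <= 1, `&`)
  }
}

geometry_in_grid <- function(geom, grid, spacing) {
  extent_mm <- (grid - 1) * spacing
  all(geom$center_mm - geom$radii_mm >= 0) &&
    all(geom$center_mm + geom$radii_mm <= extent_mm)
}

#' Build a phantom from a specification
#'
#' Rasterizes every depot, draws per-voxel fat fractions from the depot's
#' tissue distribution, applies the dual-echo forward model and packages the
#' ground truth. Region labels are assigned in depot order; a region named
#' `"other_soft_tissue"` is treated as a body background that other depots
#' may overwrite, while genuine depots must not overlap (geometry error).
#'
#' @param spec a [phantom_spec()].
#' @return list with `echoes` (class `dual_echo_volume`), `truth` (class
#'   `ground_truth`) and `seeds` (a seed table, one canonical seed per depot
#'   centroid; empty for specs without adipose depots).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid; spacing <- spec$spacing
  with_seed(spec$seed, {
    labels <- array(0L, grid)
    water <- array(0, grid)
    fat <- array(0, grid)
    ffg <- array(NA_real_, grid)
    soft <- vapply(spec$depots, function(d)
      identical(d$geometry$region, "other_soft_tissue"), logical(1))
    ord <- order(!soft) # soft tissue first so depots overwrite it
    next_id <- 0L
    ids <- integer(length(spec$depots))
    soft_ids <- integer(0)
    for (i in ord) {
      dep <- spec$depots[[i]]
      geom <- dep$geometry
      if (!geometry_in_grid(geom, grid, spacing)) {
        stop("geometry error: depot '", geom$region,
             "' extends outside the grid", call. = FALSE)
      }
      m <- rasterize_shape(geom, grid, spacing)
      if (!soft[i] && any(!(labels[m] %in% c(0L, soft_ids)))) {
        stop("geometry error: depot '", geom$region,
             "' overlaps another depot", call. = FALSE)
      }
      next_id <- next_id + 1L
      ids[i] <- next_id
      if (soft[i]) soft_ids <- c(soft_ids, next_id)
      idx <- which(m)
      labels[idx] <- next_id
      ff <- sample_ff(dep$tissue, length(idx))
      tot <- dep$tissue$total_signal
      fat[idx] <- tot * ff
      water[idx] <- tot * (1 - ff)
      ffg[idx] <- ff
    }
    # truth table from the final label field (soft tissue may have been
    # partially overwritten by depots)
    rows <- lapply(ord, function(i) {
      id <- ids[i]
      geom <- spec$depots[[i]]$geometry
      idx <- which(labels == id)
      data.frame(
        id = id, region = geom$region, n_voxels = length(idx),
        volume_cc = length(idx) * voxel_volume_cc(spacing),
        analytic_volume_cc = geom$analytic_volume_cc,
        mean_ff = if (length(idx)) mean(ffg[idx]) else NA_real_,
        stringsAsFactors = FALSE)
    })
    region_table <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = integer(), region = character(), n_voxels = integer(),
                 volume_cc = numeric(), analytic_volume_cc = numeric(),
                 mean_ff = numeric())
    region_table <- region_table[order(region_table$id), , drop = FALSE]
    rownames(region_table) <- NULL

    fat_dominant <- fat > water
    vendor_dom <- fat_dominant
    for (sw in spec$swap_regions) {
      m <- rasterize_shape(sw, grid, spacing)
      vendor_dom[m] <- !vendor_dom[m]
    }

    sdn <- spec$noise_sd
    ip <- water + fat
    op <- abs(water - fat)
    if (sdn > 0) {
      ip <- pmax(ip + stats::rnorm(length(ip), sd = sdn), 0)
      op <- pmax(op + stats::rnorm(length(op), sd = sdn), 0)
    }

    echoes <- structure(list(
      in_phase = ip, opposed_phase = op, spacing = spacing,
      te_ms = c(2.45, 3.675), fat_dominant = vendor_dom),
      class = "dual_echo_volume")
    truth <- structure(list(
      labels = labels, region_table = region_table, water = water, fat = fat,
      ff = ffg, fat_dominant = fat_dominant, spacing = spacing),
      class = "ground_truth")
    seeds <- canonical_seeds(truth)
    list(echoes = echoes, truth = truth, seeds = seeds)
  })
}

#' @keywords internal
region_mask_from_truth <- function(truth, regions) {
  ids <- truth$region_table$id[truth$region_table$region %in% regions]
  m <- array(truth$labels %in% ids, dim(truth$labels))
  structure(list(mask = m, region = paste(regions, collapse = "+"),
                 spacing = truth$spacing,
                 provenance = list(source = "ground_truth")),
            class = "region_mask")
}

# Canonical "rater 0" seed table: one seed at each adipose depot centroid.
canonical_seeds <- function(truth) {
  rt <- truth$region_table
  rt <- rt[!(rt$region %in% c("other_soft_tissue", "background")), ,
           drop = FALSE]
  if (nrow(rt) == 0L) return(empty_seed_table())
  out <- lapply(seq_len(nrow(rt)), function(i) {
    idx <- which(truth$labels == rt$id[i], arr.ind = TRUE)
    ctr <- colMeans(index_to_world(idx, truth$spacing))
    radius <- if (rt$region[i] == "nuchal_wat") 5 else 3
    data.frame(region = rt$region[i], x_mm = ctr[1], y_mm = ctr[2],
               z_mm = ctr[3], radius_mm = radius, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

empty_seed_table <- function() {
  data.frame(region = character(), x_mm = numeric(), y_mm = numeric(),
             z_mm = numeric(), radius_mm = numeric())
}

#' Ex vivo vial phantom specification
#'
#' Two cylindrical vials in air, one filled with brown-adipose material and
#' one with white-adipose material, with per-voxel fat fractions drawn from
#' the printed ex vivo moments by default.
#'
#' @param bat,wat [tissue_distribution()] objects for the two vials.
#' @param grid,spacing,noise_sd,seed as in [phantom_spec()].
#' @return a [phantom_spec()] with two vial depots.
#' @export
vial_phantom_spec <- function(bat = tissue_distribution("bat", 0.437, 0.078,
                                                        -0.27),
                              wat = tissue_distribution("wat", 0.733, 0.104,
                                                        -0.85),
                              grid = c(48L, 28L, 28L),
                              spacing = c(0.97, 0.97, 1),
                              noise_sd = 0.04, seed = 1L) {
  depots <- list(
    list(geometry = depot_geometry("bat_vial", c(13, 13, 13.5), c(6, 6, 8),
                                   shape = "cylinder"), tissue = bat),
    list(geometry = depot_geometry("wat_vial", c(32, 13, 13.5), c(6, 6, 8),
                                   shape = "cylinder"), tissue = wat))
  phantom_spec(grid = grid, spacing = spacing, depots = depots,
               noise_sd = noise_sd, seed = seed)
}

#' Build the ex vivo vial phantom
#'
#' @param spec a [phantom_spec()] containing exactly two non-overlapping
#'   vials (one brown-adipose, one white-adipose distribution).
#' @return list with `echoes` and `truth` (see [make_phantom()]).
#' @export
make_vial_phantom <- function(spec = vial_phantom_spec()) {
  adipose <- Filter(function(d)
    !identical(d$geometry$region, "other_soft_tissue"), spec$depots)
  if (length(adipose) != 2L) {
    stop("vial phantom requires exactly two vials", call. = FALSE)
  }
  make_phantom(spec)
}

# Depot placement for the neonate torso (world mm on the default grid).
# Base radii set the aspect ratio of each depot; they are rescaled to the
# requested true volume. Positions keep every depot inside the grid and
# pairwise disjoint over the plausible cohort volume range.
torso_layout <- function() {
  list(
    supraclavicular_L = list(center = c(44, 58, 52), radii = c(7.0, 6.0, 5.3)),
    supraclavicular_R = list(center = c(80, 58, 52), radii = c(7.0, 6.0, 5.3)),
    axillary_L = list(center = c(30, 40, 28), radii = c(8.0, 6.5, 5.5)),
    axillary_R = list(center = c(94, 40, 28), radii = c(8.0, 6.5, 5.5)),
    spine_T1_L = list(center = c(54, 34, 50), radii = c(5.2, 4.6, 3.4)),
    spine_T1_R = list(center = c(70, 34, 50), radii = c(5.2, 4.6, 3.4)),
    spine_T2_L = list(center = c(54, 34, 40), radii = c(5.2, 4.6, 3.4)),
    spine_T2_R = list(center = c(70, 34, 40), radii = c(5.2, 4.6, 3.4)),
    spine_T3_L = list(center = c(54, 34, 30), radii = c(5.2, 4.6, 3.4)),
    spine_T3_R = list(center = c(70, 34, 30), radii = c(5.2, 4.6, 3.4)),
    spine_T4_L = list(center = c(54, 34, 20), radii = c(5.2, 4.6, 3.4)),
    spine_T4_R = list(center = c(70, 34, 20), radii = c(5.2, 4.6, 3.4)),
    spine_T5_L = list(center = c(54, 34, 10), radii = c(5.2, 4.6, 3.4)),
    spine_T5_R = list(center = c(70, 34, 10), radii = c(5.2, 4.6, 3.4)),
    nuchal_wat = list(center = c(62, 14, 50), radii = c(13.0, 9.0, 8.5))
  )
}

#' Neonate torso phantom specification
#'
#' A torso of water-rich soft tissue (low fat fraction, low total signal)
#' containing bilateral supraclavicular and axillary depots, bilateral
#' spinal depots at T1-T5, and one subcutaneous nuchal white-adipose depot.
#' Supraclavicular + axillary volumes are controlled jointly through the
#' union volume, split in the ratio of the printed component means
#' (2.95 : 3.76); the spinal volume is divided equally over the ten
#' vertebral blobs.
#'
#' @param union_volume_cc true supraclavicular + axillary volume (cc).
#' @param union_ff true mean fat fraction of the union depots.
#' @param spine_volume_cc true total T1-T5 spinal volume (cc).
#' @param spine_ff true mean fat fraction of spinal depots.
#' @param wat_volume_cc true nuchal white-adipose volume (cc).
#' @param wat_ff true mean fat fraction of nuchal white adipose.
#' @param within_sd voxelwise fat-fraction SD inside each depot.
#' @param soft_ff,soft_total fat fraction and total signal of background
#'   soft tissue (water-rich, darker than adipose on gradient-echo).
#' @param grid,spacing,noise_sd,swap_regions,seed as in [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
torso_phantom_spec <- function(union_volume_cc = 6.50, union_ff = 0.295,
                               spine_volume_cc = 3.65, spine_ff = 0.322,
                               wat_volume_cc = 5.0, wat_ff = 0.677,
                               within_sd = 0.03, soft_ff = 0.08,
                               soft_total = 0.30,
                               grid = c(128L, 96L, 64L),
                               spacing = c(0.97, 0.97, 1),
                               noise_sd = 0.04, swap_regions = list(),
                               seed = 1L) {
  lay <- torso_layout()
  sup_frac <- 2.95 / (2.95 + 3.76)
  vols <- c(
    supraclavicular_L = union_volume_cc * sup_frac / 2,
    supraclavicular_R = union_volume_cc * sup_frac / 2,
    axillary_L = union_volume_cc * (1 - sup_frac) / 2,
    axillary_R = union_volume_cc * (1 - sup_frac) / 2,
    stats::setNames(rep(spine_volume_cc / 10, 10),
                    grep("^spine", names(lay), value = TRUE)),
    nuchal_wat = wat_volume_cc)
  ffs <- c(
    stats::setNames(rep(union_ff, 4),
                    grep("^(supra|axil)", names(lay), value = TRUE)),
    stats::setNames(rep(spine_ff, 10),
                    grep("^spine", names(lay), value = TRUE)),
    nuchal_wat = wat_ff)
  depots <- list(list(
    geometry = depot_geometry("other_soft_tissue", c(62, 46, 30),
                              c(36, 26, 28)),
    tissue = tissue_distribution("soft", soft_ff, 0.01,
                                 total_signal = soft_total)))
  for (nm in names(lay)) {
    geom <- scale_geometry(
      depot_geometry(nm, lay[[nm]]$center, lay[[nm]]$radii), vols[[nm]])
    depots[[length(depots) + 1L]] <- list(
      geometry = geom,
      tissue = tissue_distribution(nm, ffs[[nm]], within_sd))
  }
  phantom_spec(grid = grid, spacing = spacing, depots = depots,
               noise_sd = noise_sd, swap_regions = swap_regions, seed = seed)
}

#' Build a neonate torso phantom
#'
#' @param spec a [phantom_spec()], typically from [torso_phantom_spec()].
#' @return list with `echoes`, `truth` and `seeds` (canonical centroid
#'   seeds: one per depot side, within the protocol seed-count limits).
#' @export
make_torso_phantom <- function(spec = torso_phantom_spec()) {
  make_phantom(spec)
}

#' Re-acquire a phantom with a fresh noise realization
#'
#' Keeps the noiseless signal (the ground truth) fixed and draws new echo
#' noise, emulating a scan-rescan pair separated only by a re-shim. An
#' optional smooth multiplicative bias field emulates the shim difference.
#'
#' @param phantom output of [make_phantom()] (or the vial/torso wrappers).
#' @param noise_sd echo noise SD for the repeat acquisition; the first
#'   scan's noise level is not recoverable from the phantom object, so pass
#'   the value used to generate it (default 0.04).
#' @param seed integer seed for the new noise realization.
#' @param bias_amplitude peak fractional amplitude of the multiplicative
#'   bias field (0 disables it).
#' @return a new `dual_echo_volume`.
#' @export
make_rescan <- function(phantom, noise_sd = 0.04, seed = 2L,
                        bias_amplitude = 0) {
  truth <- phantom$truth
  grid <- dim(truth$water)
  with_seed(seed, {
    ip <- truth$water + truth$fat
    op <- abs(truth$water - truth$fat)
    if (bias_amplitude > 0) {
      xs <- seq(-1, 1, length.out = grid[1])
      ys <- seq(-1, 1, length.out = grid[2])
      zs <- seq(-1, 1, length.out = grid[3])
      cf <- stats::rnorm(6)
      field <- outer(outer(cf[1] * xs + cf[4] * xs^2,
                           cf[2] * ys + cf[5] * ys^2, `+`),
                     cf[3] * zs + cf[6] * zs^2, `+`)
      field <- 1 + bias_amplitude * field / max(abs(field))
      ip <- ip * field
      op <- op * field
    }
    if (noise_sd > 0) {
      ip <- pmax(ip + stats::rnorm(length(ip), sd = noise_sd), 0)
      op <- pmax(op + stats::rnorm(length(op), sd = noise_sd), 0)
    }
    structure(list(in_phase = ip, opposed_phase = op,
                   spacing = truth$spacing, te_ms = c(2.45, 3.675),
                   fat_dominant = phantom$echoes$fat_dominant),
              class = "dual_echo_volume")
  })
}

#' Jitter seed points to emulate rater variability
#'
#' Displaces each seed centre by an isotropic Gaussian vector whose expected
#' norm equals `magnitude_mm` (for an isotropic 3-D Gaussian with axis SD
#' sigma the expected norm is sigma * sqrt(8 / pi), so sigma =
#' magnitude_mm / sqrt(8 / pi)). Displaced seeds must land inside their
#' source depot; failing draws are retried up to 100 times.
#'
#' @param seeds seed table (columns region, x_mm, y_mm, z_mm, radius_mm).
#' @param magnitude_mm expected displacement norm in mm (>= 0).
#' @param truth a `ground_truth` (supplies depot labels for containment).
#' @param seed optional RNG seed.
#' @return a jittered seed table.
#' @export
jitter_seeds <- function(seeds, magnitude_mm, truth, seed = NULL) {
  stopifnot(magnitude_mm >= 0)
  if (magnitude_mm == 0 || nrow(seeds) == 0L) return(seeds)
  sigma <- magnitude_mm / sqrt(8 / pi)
  rt <- truth$region_table
  grid <- dim(truth$labels)
  with_seed(seed, {
    for (i in seq_len(nrow(seeds))) {
      id <- rt$id[rt$region == seeds$region[i]]
      ok <- FALSE
      for (attempt in 1:100) {
        ctr <- c(seeds$x_mm[i], seeds$y_mm[i], seeds$z_mm[i]) +
          stats::rnorm(3, sd = sigma)
        vox <- world_to_index(matrix(ctr, 1), truth$spacing)
        if (any(vox < 1L) || any(vox > grid)) next
        if (length(id) && truth$labels[vox] == id) {
          seeds$x_mm[i] <- ctr[1]; seeds$y_mm[i] <- ctr[2]
          seeds$z_mm[i] <- ctr[3]
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("seed-placement error: could not keep jittered seed inside ",
             "depot '", seeds$region[i], "'", call. = FALSE)
      }
    }
    seeds
  })
}
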