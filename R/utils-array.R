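# Low-level 3-D array helpers shared by the phantom generator and the
# segmentation engine. Volumes are plain numeric/logical arrays; physical
# coordinates follow the convention world_mm = (index - 1) * spacing, i.e.
# the first voxel is centred at the origin and grids are axis-aligned.

#' Voxel volume in cubic centimetres
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Volume of one voxel in cc (= mL).
#' @export
voxel_volume_cc <- function(spacing) prod(spacing) / 1000

#' Convert voxel indices to world coordinates (mm)
#'
#' Indices are 1-based; the centre of voxel (1,1,1) is at 0 mm on every axis.
#' @param idx integer matrix (n x 3) of voxel indices.
#' @param spacing voxel spacing in mm.
#' @return numeric matrix (n x 3) of world coordinates in mm.
#' @export
index_to_world <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}

#' Convert world coordinates (mm) to the nearest voxel index
#' @param xyz numeric matrix (n x 3) of world coordinates in mm.
#' @param spacing voxel spacing in mm.
#' @return integer matrix of 1-based voxel indices.
#' @export
world_to_index <- function(xyz, spacing) {
  round(sweep(xyz, 2, spacing, `/`)) + 1L
}

axis_mm <- function(n, dx) (seq_len(n) - 1) * dx

#' @keywords internal
mask_bbox <- function(m) {
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

bbox_expand <- function(bb, margin, dim) {
  rbind(lo = pmax(bb["lo", ] - margin, 1L),
        hi = pmin(bb["hi", ] + margin, dim))
}

crop_array <- function(a, bb) {
  a[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3],
    drop = FALSE]
}

embed_array <- function(sub, bb, dim, fill = FALSE) {
  out <- array(fill, dim)
  out[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2],
      bb["lo", 3]:bb["hi", 3]] <- sub
  out
}

#' Count 26-connected TRUE neighbours of every voxel
#' @param m logical 3-D array.
#' @return integer array of the same shape.
#' @keywords internal
neighbor_count <- function(m) {
  d <- dim(m)
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  cnt <- array(0L, d)
  i1 <- 2:(d[1] + 1L); i2 <- 2:(d[2] + 1L); i3 <- 2:(d[3] + 1L)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    cnt <- cnt + p[i1 + dx, i2 + dy, i3 + dz]
  }
  cnt
}

# TRUE if the region touches a crop face that is not also a grid face,
# i.e. growth might need voxels outside the current crop.
touches_interior_face <- function(reg, bb, dim) {
  d <- dim(reg)
  (bb["lo", 1] > 1L     && any(reg[1, , ])) ||
  (bb["hi", 1] < dim[1] && any(reg[d[1], , ])) ||
  (bb["lo", 2] > 1L     && any(reg[, 1, ])) ||
  (bb["hi", 2] < dim[2] && any(reg[, d[2], ])) ||
  (bb["lo", 3] > 1L     && any(reg[, , 1])) ||
  (bb["hi", 3] < dim[3] && any(reg[, , d[3]]))
}

#' Monotone morphological region growth
#'
#' Grows a seed region inside an eligibility set by at most one 26-connected
#' voxel shell per iteration. A voxel is added only when at least
#' `min_neighbors` of its 26 neighbours already belong to the region, which
#' acts as a curvature-smoothing step (spikes one voxel wide do not
#' propagate). Growth is monotone: the result after k iterations is a subset
#' of the result after k + 1. Iterating past the fixed point is a no-op, so
#' the loop stops early once no voxel can be added.
#'
#' @param seed_mask logical array of starting voxels.
#' @param eligible logical array; the region never leaves this set.
#' @param iterations maximum number of one-shell growth steps.
#' @param min_neighbors minimum number of region neighbours (out of 26)
#'   required to annex a voxel; 1 disables smoothing.
#' @return list with `mask` (logical array) and `iterations_run`.
#' @export
grow_region <- function(seed_mask, eligible, iterations, min_neighbors = 3L) {
  stopifnot(identical(dim(seed_mask), dim(eligible)))
  d <- dim(eligible)
  start <- seed_mask & eligible
  if (!any(start)) {
    return(list(mask = start, iterations_run = 0L))
  }
  if (iterations == 0L) {
    return(list(mask = start, iterations_run = 0L))
  }
  margin <- 8L
  bb <- bbox_expand(mask_bbox(start), margin, d)
  reg <- crop_array(start, bb)
  eli <- crop_array(eligible, bb)
  full_reg <- NULL
  run <- 0L
  for (k in seq_len(iterations)) {
    if (touches_interior_face(reg, bb, d)) {
      full_reg <- embed_array(reg, bb, d)
      bb <- bbox_expand(bbox_expand(mask_bbox(full_reg), 0L, d), margin, d)
      reg <- crop_array(full_reg, bb)
      eli <- crop_array(eligible, bb)
    }
    cnt <- neighbor_count(reg)
    add <- eli & !reg & (cnt >= min_neighbors)
    if (!any(add)) break
    reg <- reg | add
    run <- k
  }
  list(mask = embed_array(reg, bb, d), iterations_run = run)
}

#' Label 26-connected components of a logical array
#' @param m logical array.
#' @param min_voxels drop components smaller than this.
#' @return list of logical arrays, one per retained component.
#' @keywords internal
connected_components <- function(m, min_voxels = 1L) {
  comps <- list()
  remaining <- m
  while (any(remaining)) {
    seed <- array(FALSE, dim(m))
    seed[which(remaining)[1L]] <- TRUE
    comp <- grow_region(seed, remaining, iterations = .Machine$integer.max,
                        min_neighbors = 1L)$mask
    if (sum(comp) >= min_voxels) comps[[length(comps) + 1L]] <- comp
    remaining <- remaining & !comp
  }
  comps
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

check_congruent <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b))) {
    stop("congruence error: ", what, " have different shapes", call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
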