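# Two-point Dixon water-fat separation and fat-fraction mapping.
#
# With in-phase IP = W + F and opposed-phase OP = |W - F| magnitudes, the
# algebraic separation (IP + OP) / 2 and (IP - OP) / 2 recovers the larger
# and smaller of the two compartments; assigning them to water and fat
# requires a dominance decision, because magnitude images discard the sign
# of W - F (this is exactly the fat/water swap ambiguity, which vendor
# reconstructions resolve with phase information). `separate_water_fat()`
# therefore accepts a global dominance assumption or a per-voxel dominance
# field such as the one the phantom emits.

#' Separate water and fat from dual-echo magnitudes
#'
#' Computes A = (IP + OP) / 2 and B = (IP - OP) / 2, clips negative B to zero
#' (bookkeeping the clipped mass), and assigns A/B to water/fat according to
#' `dominance`. Under water dominance W = A, F = B; under fat dominance the
#' roles are exchanged. A logical array gives per-voxel dominance (TRUE =
#' fat-dominant), emulating a vendor phase-resolved reconstruction.
#'
#' @param echoes a `dual_echo_volume`.
#' @param dominance `"water"`, `"fat"`, a logical array congruent with the
#'   echoes, or `NULL` to use the `fat_dominant` field carried by the echoes
#'   (falling back to `"water"`).
#' @return object of class `water_fat_volumes` with fields `water`, `fat`,
#'   `spacing`, `clipped_mass_fraction` (clipped negative mass relative to
#'   total in-phase signal) and `clipped_mass_fraction_signal` (same ratio
#'   restricted to appreciable-signal voxels). A warning is raised when the
#'   latter exceeds 1%, indicating noise too high for magnitude-based
#'   separation: in background air half the difference signal is negative
#'   noise by construction, so only in-tissue clipping is diagnostic.
#' @export
separate_water_fat <- function(echoes, dominance = NULL) {
  stopifnot(inherits(echoes, "dual_echo_volume"))
  ip <- echoes$in_phase; op <- echoes$opposed_phase
  check_congruent(ip, op, "in-phase and opposed-phase grids")
  if (is.null(dominance)) {
    dominance <- if (!is.null(echoes$fat_dominant)) echoes$fat_dominant
                 else "water"
  }
  a <- (ip + op) / 2
  b <- (ip - op) / 2
  neg <- pmax(-b, 0)
  total <- sum(ip)
  clip_frac <- if (total > 0) sum(neg) / total else 0
  # background air is half negative-difference noise by construction, so the
  # "noise too high" diagnostic is assessed inside appreciable-signal voxels
  appreciable <- ip > mean(ip) + 2 * stats::sd(ip)
  tot_sig <- sum(ip[appreciable])
  clip_frac_signal <- if (tot_sig > 0) sum(neg[appreciable]) / tot_sig else 0
  b[b < 0] <- 0
  if (is.character(dominance)) {
    dominance <- match.arg(dominance, c("water", "fat"))
    fatdom <- array(dominance == "fat", dim(ip))
  } else {
    check_congruent(ip, dominance, "echoes and dominance field")
    fatdom <- dominance
  }
  water <- ifelse(fatdom, b, a)
  fat <- ifelse(fatdom, a, b)
  dim(water) <- dim(ip); dim(fat) <- dim(ip)
  if (clip_frac_signal > 0.01) {
    warning("clipped negative mass is ",
            signif(100 * clip_frac_signal, 3),
            "% of appreciable-voxel signal; noise may be too high for ",
            "magnitude Dixon", call. = FALSE)
  }
  structure(list(water = water, fat = fat, spacing = echoes$spacing,
                 clipped_mass_fraction = clip_frac,
                 clipped_mass_fraction_signal = clip_frac_signal),
            class = "water_fat_volumes")
}

#' Fat signal fraction map
#'
#' The fat signal fraction is the ratio of fat signal to the combined signal
#' from fat and water, FF = F / (F + W), defined only where the combined
#' signal exceeds a small fraction of the image maximum (avoiding 0/0 in
#' background air).
#'
#' @param wf a `water_fat_volumes`.
#' @param eps_frac voxels with F + W <= `eps_frac` * max(F + W) are marked
#'   invalid.
#' @return object of class `fat_fraction_map` with fields `ff` (fraction in
#'   `[0, 1]` where valid, `NA` elsewhere), `valid` (logical) and `spacing`.
#' @export
compute_fat_fraction <- function(wf, eps_frac = 1e-6) {
  stopifnot(inherits(wf, "water_fat_volumes"))
  total <- wf$water + wf$fat
  eps <- eps_frac * max(total)
  valid <- total > eps
  ff <- array(NA_real_, dim(total))
  ff[valid] <- wf$fat[valid] / total[valid]
  ff[valid] <- pmin(pmax(ff[valid], 0), 1)
  structure(list(ff = ff, valid = valid, spacing = wf$spacing),
            class = "fat_fraction_map")
}

#' Appreciable-signal mask
#'
#' Voxels whose combined signal exceeds the entire-image mean (background
#' noise included) by more than two standard deviations.
#'
#' @param wf a `water_fat_volumes`.
#' @return object of class `signal_mask` with the mask and the mean/SD/
#'   threshold it was derived from (so the mask is reproducible from its own
#'   record).
#' @export
signal_mask <- function(wf) {
  stopifnot(inherits(wf, "water_fat_volumes"))
  total <- wf$water + wf$fat
  m <- mean(total)
  s <- stats::sd(total)
  if (!is.finite(s) || s == 0) {
    warning("constant image: appreciable-signal mask is empty",
            call. = FALSE)
    s <- 0
  }
  thr <- m + 2 * s
  mask <- if (s == 0) array(FALSE, dim(total)) else total > thr
  structure(list(mask = mask, mean = m, sd = s, threshold = thr,
                 spacing = wf$spacing),
            class = "signal_mask")
}

#' Flag suspected fat/water swap components
#'
#' Advisory detector for phase-ambiguity swap artifacts; it never modifies
#' the data. Two complementary heuristics are combined: (1) connected
#' components of appreciable-signal voxels with near-pure fat fraction
#' (FF >= `ff_pure`), which is physiologically implausible in a neonatal
#' torso and is the complement of water-rich tissue; and (2) when region
#' masks are supplied, connected in-region components whose FF is close to
#' the complement of the region's median FF. Both work on fat fractions, so
#' the flags are invariant to global intensity scaling of the echoes.
#'
#' @param ff a `fat_fraction_map`.
#' @param wf the matching `water_fat_volumes`.
#' @param regions optional named list of `region_mask` objects providing
#'   context for complementarity testing.
#' @param ff_pure absolute fat-fraction cut for heuristic (1).
#' @param tol complementarity tolerance for heuristic (2).
#' @param min_voxels minimum component size to report.
#' @return data frame with one row per suspect component (context, voxel
#'   count, mean FF); the component masks are attached as the `"components"`
#'   attribute (list of logical arrays).
#' @export
flag_swaps <- function(ff, wf, regions = NULL, ff_pure = 0.85, tol = 0.10,
                       min_voxels = 20L) {
  stopifnot(inherits(ff, "fat_fraction_map"))
  sm <- signal_mask(wf)
  suspect <- sm$mask & ff$valid & !is.na(ff$ff) & (ff$ff >= ff_pure)
  suspect[is.na(suspect)] <- FALSE
  contexts <- list(global = suspect)
  for (nm in names(regions)) {
    rm_ <- regions[[nm]]
    med <- stats::median(ff$ff[rm_$mask & ff$valid], na.rm = TRUE)
    if (!is.finite(med) || abs(2 * med - 1) <= 2 * tol) next # ambiguous near 0.5
    comp_ff <- 1 - med
    s <- rm_$mask & ff$valid & !is.na(ff$ff) &
      (abs(ff$ff - comp_ff) < tol)
    s[is.na(s)] <- FALSE
    contexts[[nm]] <- s
  }
  rows <- list(); comps <- list()
  for (nm in names(contexts)) {
    for (comp in connected_components(contexts[[nm]], min_voxels)) {
      dup <- any(vapply(comps, function(c0) any(c0 & comp), logical(1)))
      if (dup) next
      comps[[length(comps) + 1L]] <- comp
      rows[[length(rows) + 1L]] <- data.frame(
        context = nm, n_voxels = sum(comp),
        mean_ff = mean(ff$ff[comp], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(context = character(), n_voxels = integer(),
               mean_ff = numeric())
  attr(out, "components") <- comps
  out
}
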