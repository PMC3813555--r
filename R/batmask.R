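# Rule-based brown-adipose candidate mask, used for visualization and
# seed-placement quality control (the analysis ROIs come from the seeded
# segmentation, not from this mask).

#' Three-criterion BAT candidate mask
#'
#' A voxel is a BAT candidate when (1) its combined signal exceeds the
#' entire-image mean (background included) by more than two SD, (2) its fat
#' signal clears a one-SD offset from the entire-image fat mean, and (3) its
#' fat fraction exceeds `ff_cut` (no upper bound).
#'
#' Criterion (2) is grammatically ambiguous in its source protocol ("fat
#' signal greater than one SD below the mean"). The default reading is the
#' lower bound `fat > mean - 1 SD`, which excludes water-only and noise
#' voxels; the alternative upper-bound reading `fat < mean - 1 SD` is
#' available via `fat_direction = "below"`, but on any image dominated by
#' background air the fat mean minus one SD is negative and an upper bound
#' excludes everything (whereas the lower bound is then vacuous and the mask
#' is carried by criteria 1 and 3).
#'
#' @param wf a `water_fat_volumes`.
#' @param ff the matching `fat_fraction_map`.
#' @param ff_cut lower fat-fraction bound (criterion 3), default 0.20.
#' @param fat_direction `"above"` (default; fat > mean - SD) or `"below"`
#'   (fat < mean - SD).
#' @return object of class `bat_mask`: the logical mask plus the three
#'   thresholds actually used.
#' @export
bat_candidate_mask <- function(wf, ff, ff_cut = 0.20,
                               fat_direction = c("above", "below")) {
  stopifnot(inherits(wf, "water_fat_volumes"),
            inherits(ff, "fat_fraction_map"))
  check_congruent(wf$fat, ff$ff, "water-fat volumes and fat-fraction map")
  fat_direction <- match.arg(fat_direction)
  total <- wf$water + wf$fat
  total_cut <- mean(total) + 2 * stats::sd(total)
  fat_cut <- mean(wf$fat) - stats::sd(wf$fat)
  crit1 <- total > total_cut
  crit2 <- if (fat_direction == "above") wf$fat > fat_cut else wf$fat < fat_cut
  crit3 <- ff$valid & !is.na(ff$ff) & ff$ff > ff_cut
  crit3[is.na(crit3)] <- FALSE
  mask <- crit1 & crit2 & crit3
  structure(list(mask = mask,
                 thresholds = list(total_cut = total_cut, fat_cut = fat_cut,
                                   ff_cut = ff_cut,
                                   fat_direction = fat_direction),
                 spacing = wf$spacing),
            class = "bat_mask")
}
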