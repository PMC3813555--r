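# Synthetic neonate cohorts.
#
# Between-subject structure follows the printed cohort statistics: the
# supraclavicular + axillary union volume (6.50 +/- 3.10 cc) and fat
# fraction (29.5 +/- 3.7 %), the T1-T5 spinal volume (3.65 +/- 1.40 cc) and
# fat fraction (32.2 +/- 3.2 %), and the nuchal white-adipose fat fraction
# (67.7 +/- 4.6 %). Nuchal volume is not printed and defaults to
# 5.0 +/- 1.5 cc. Fat fraction and volume are positively coupled through a
# Gaussian copula with the printed correlations (union 0.56, spine 0.84).

#' Cohort specification
#'
#' @param n_subjects number of subjects (>= 2, default 22).
#' @param union_volume,union_ff,spine_volume,spine_ff,wat_volume,wat_ff
#'   length-2 vectors `c(mean, sd)` of the between-subject distributions.
#'   Volumes in cc, fat fractions as fractions.
#' @param ff_volume_rho named vector of volume-FF correlations for the union
#'   and spine compartments.
#' @param within_sd voxelwise fat-fraction SD inside a depot.
#' @param noise_sd echo noise SD.
#' @param grid,spacing phantom grid (passed to [torso_phantom_spec()]).
#' @param stratified logical; draw subject-level truths by stratified
#'   (Latin-hypercube style) sampling so that a small cohort is
#'   representative of the requested distribution. Marginals are unchanged;
#'   set `FALSE` for plain iid draws.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22L,
                        union_volume = c(6.50, 3.10),
                        union_ff = c(0.295, 0.037),
                        spine_volume = c(3.65, 1.40),
                        spine_ff = c(0.322, 0.032),
                        wat_volume = c(5.0, 1.5),
                        wat_ff = c(0.677, 0.046),
                        ff_volume_rho = c(union = 0.56, spine = 0.84),
                        within_sd = 0.03, noise_sd = 0.04,
                        grid = c(128L, 96L, 64L),
                        spacing = c(0.97, 0.97, 1),
                        stratified = TRUE, seed = 1L) {
  stopifnot(n_subjects >= 2,
            union_volume[2] >= 0, union_ff[2] >= 0, spine_volume[2] >= 0,
            spine_ff[2] >= 0, wat_volume[2] >= 0, wat_ff[2] >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 union_volume = union_volume, union_ff = union_ff,
                 spine_volume = spine_volume, spine_ff = spine_ff,
                 wat_volume = wat_volume, wat_ff = wat_ff,
                 ff_volume_rho = ff_volume_rho, within_sd = within_sd,
                 noise_sd = noise_sd, grid = as.integer(grid),
                 spacing = spacing, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Stratified standard-normal draws: one draw per equiprobable stratum, in
# random order. Marginally each draw is N(0, 1); jointly the empirical
# distribution hugs the population one far more tightly than iid draws.
stratified_normal <- function(n) {
  u <- (sample.int(n) - stats::runif(n)) / n
  stats::qnorm(u)
}

#' Draw the subject-level ground truths of a cohort
#'
#' @param cspec a [cohort_spec()].
#' @return data frame with one row per subject: true union/spine/nuchal
#'   volumes (cc, truncated positive) and mean fat fractions (clipped to
#'   `[0.02, 0.98]`), plus the per-subject phantom seed.
#' @export
draw_cohort_subjects <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  n <- cspec$n_subjects
  with_seed(cspec$seed, {
    zdraw <- if (cspec$stratified) stratified_normal else stats::rnorm
    couple <- function(zv, rho) {
      rho * zv + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    z_uv <- zdraw(n); z_sv <- zdraw(n); z_wv <- zdraw(n)
    z_uf <- couple(z_uv, cspec$ff_volume_rho[["union"]])
    z_sf <- couple(z_sv, cspec$ff_volume_rho[["spine"]])
    z_wf <- zdraw(n)
    trunc_pos <- function(z, ms) pmax(ms[1] + ms[2] * z, 0.05 * ms[1])
    clip_ff <- function(z, ms) pmin(pmax(ms[1] + ms[2] * z, 0.02), 0.98)
    data.frame(
      subject = seq_len(n),
      union_volume_cc = trunc_pos(z_uv, cspec$union_volume),
      union_ff = clip_ff(z_uf, cspec$union_ff),
      spine_volume_cc = trunc_pos(z_sv, cspec$spine_volume),
      spine_ff = clip_ff(z_sf, cspec$spine_ff),
      wat_volume_cc = trunc_pos(z_wv, cspec$wat_volume),
      wat_ff = clip_ff(z_wf, cspec$wat_ff),
      phantom_seed = vapply(seq_len(n), function(i)
        derive_seed(cspec$seed, i), integer(1)))
  })
}

#' Phantom for one cohort subject
#'
#' @param cspec a [cohort_spec()].
#' @param subject_row one row of [draw_cohort_subjects()].
#' @param swap_regions optional swap geometries for this subject.
#' @return list with `echoes`, `truth`, `seeds` (see [make_phantom()]).
#' @export
cohort_subject_phantom <- function(cspec, subject_row, swap_regions = list()) {
  spec <- torso_phantom_spec(
    union_volume_cc = subject_row$union_volume_cc,
    union_ff = subject_row$union_ff,
    spine_volume_cc = subject_row$spine_volume_cc,
    spine_ff = subject_row$spine_ff,
    wat_volume_cc = subject_row$wat_volume_cc,
    wat_ff = subject_row$wat_ff,
    within_sd = cspec$within_sd, noise_sd = cspec$noise_sd,
    grid = cspec$grid, spacing = cspec$spacing,
    swap_regions = swap_regions,
    seed = subject_row$phantom_seed)
  make_torso_phantom(spec)
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject's phantom. For large grids this holds all
#' volumes in memory at once; streaming consumers should instead iterate
#' [cohort_subject_phantom()] over [draw_cohort_subjects()] rows, which is
#' what [run_cohort_pipeline()] does.
#'
#' @param cspec a [cohort_spec()].
#' @return list of per-subject phantoms (each with `echoes`, `truth`,
#'   `seeds`), with the subject truth table in attribute `"subjects"`.
#' @export
make_cohort <- function(cspec) {
  subjects <- draw_cohort_subjects(cspec)
  out <- lapply(seq_len(nrow(subjects)), function(i)
    cohort_subject_phantom(cspec, subjects[i, ]))
  attr(out, "subjects") <- subjects
  out
}
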