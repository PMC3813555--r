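# End-to-end pipeline: simulate -> separate -> mask -> segment -> quantify
# (-> reliability), with streaming cohort execution, swap-based subject
# exclusion and a reproducible run manifest.

bat_region_names <- function() {
  c("supraclavicular_L", "supraclavicular_R", "axillary_L", "axillary_R",
    paste0("spine_T", rep(1:5, each = 2), c("_L", "_R")))
}

# eligibility used for white-adipose segmentation (fat above the lowest
# quartile within the appreciable-signal mask)
wat_eligibility <- function(wf, protocol, signal) {
  vals <- wf$fat[signal$mask]
  if (length(vals) == 0L || max(vals) == min(vals)) return(signal$mask)
  q <- stats::quantile(vals, protocol$wat_quantile, names = FALSE)
  signal$mask & (wf$fat > q)
}

#' Quantify one subject phantom
#'
#' Runs separation, fat-fraction mapping, appreciable-signal masking, swap
#' flagging, seeded segmentation of the supraclavicular, axillary (and their
#' union), spinal and nuchal white-adipose regions, and per-region
#' quantification. Canonical seeds are snapped onto eligible voxels first,
#' emulating a rater who places seeds on visibly in-band voxels. Subjects
#' with a suspected swap component overlapping a brown-adipose analysis
#' region are marked excluded.
#'
#' @param phantom output of [make_torso_phantom()] /
#'   [cohort_subject_phantom()].
#' @param protocol a [segmentation_protocol()].
#' @param subject subject identifier for the stats rows.
#' @param seeds optional seed table overriding the phantom's canonical
#'   seeds (e.g. jittered rater seeds).
#' @param keep_masks return the segmentation masks and intermediate maps
#'   (memory-heavy for large grids).
#' @return list with `stats` (depot statistics rows), `excluded`, `flags`
#'   (swap report), and when `keep_masks` is TRUE also `masks`, `wf`, `ffm`,
#'   `sm`.
#' @export
process_subject <- function(phantom, protocol = segmentation_protocol(),
                            subject = 1L, seeds = NULL,
                            keep_masks = FALSE) {
  wf <- separate_water_fat(phantom$echoes)
  ffm <- compute_fat_fraction(wf)
  sm <- signal_mask(wf)
  truth <- phantom$truth
  if (is.null(seeds)) seeds <- phantom$seeds

  bat_regions <- intersect(bat_region_names(), truth$region_table$region)
  context <- list(
    bat = region_mask_from_truth(truth, bat_regions),
    wat = region_mask_from_truth(truth, "nuchal_wat"))
  flags <- flag_swaps(ffm, wf, regions = context)
  excluded <- FALSE
  if (nrow(flags) > 0) {
    bat_mask_arr <- context$bat$mask
    comps <- attr(flags, "components")
    excluded <- any(vapply(comps, function(cmp) any(cmp & bat_mask_arr),
                           logical(1)))
  }
  if (excluded) {
    return(list(stats = NULL, excluded = TRUE, flags = flags))
  }

  grp <- region_group(seeds$region)
  bat_seeds <- seeds[grp %in% c("supraclavicular", "axillary", "spine"), ]
  bat_seeds <- snap_seeds(bat_seeds, ffm, protocol, sm)
  wat_seed <- seeds[grp == "wat", ]
  wat_elig <- wat_eligibility(wf, protocol, sm)
  wat_seed <- snap_seeds(wat_seed, ffm, protocol, eligible = wat_elig)

  sgrp <- region_group(bat_seeds$region)
  sup <- segment_bat_region(ffm, bat_seeds[sgrp == "supraclavicular", ],
                            protocol, sm, label = "supraclavicular")
  ax <- segment_bat_region(ffm, bat_seeds[sgrp == "axillary", ],
                           protocol, sm, label = "axillary")
  uni <- union_region(sup, ax)
  spine <- segment_bat_region(ffm, bat_seeds[sgrp == "spine", ],
                              protocol, sm, label = "spine")
  wat <- segment_wat_nuchal(wf, wat_seed, protocol, sm)

  masks <- list(supraclavicular = sup, axillary = ax, union = uni,
                spine = spine, nuchal_wat = wat)
  stats <- do.call(rbind, lapply(masks, depot_stats, ff = ffm,
                                 subject = subject))
  rownames(stats) <- NULL
  out <- list(stats = stats, excluded = FALSE, flags = flags)
  if (keep_masks) {
    out$masks <- masks; out$wf <- wf; out$ffm <- ffm; out$sm <- sm
  }
  out
}

#' Run the full pipeline over a synthetic cohort
#'
#' Streams subjects one at a time (phantoms are generated, quantified and
#' discarded), mirroring the study analysis: per-subject segmentation and
#' quantification, cohort summary, the paired white-vs-brown fat-fraction
#' comparison, and fat-fraction/volume correlations.
#'
#' @param cspec a [cohort_spec()].
#' @param protocol a [segmentation_protocol()].
#' @param swaps optional named list mapping subject index (as character) to
#'   a list of swap-region geometries injected into that subject's phantom.
#' @param progress print per-subject progress to stderr.
#' @return list with `subjects` (true parameters), `stats`, `summary`,
#'   `paired`, `correlations`, `exclusions`.
#' @export
run_cohort_pipeline <- function(cspec, protocol = segmentation_protocol(),
                                swaps = NULL, progress = FALSE) {
  subjects <- draw_cohort_subjects(cspec)
  all_stats <- list()
  exclusions <- list()
  for (i in seq_len(nrow(subjects))) {
    sw <- if (!is.null(swaps)) swaps[[as.character(i)]] else NULL
    phantom <- cohort_subject_phantom(cspec, subjects[i, ],
                                      swap_regions = if (is.null(sw)) list()
                                                     else sw)
    res <- process_subject(phantom, protocol, subject = i)
    if (res$excluded) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        subject = i, reason = "fat/water swap in analysis region",
        n_flagged_components = nrow(res$flags))
      if (progress) message("subject ", i, ": excluded (swap)")
      next
    }
    all_stats[[length(all_stats) + 1L]] <- res$stats
    if (progress) message("subject ", i, ": ok")
  }
  stats <- do.call(rbind, all_stats)
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(subject = integer(), reason = character(),
               n_flagged_components = integer())
  summary <- cohort_summary(stats)
  paired <- paired_wat_bat(stats, bat_region = "union",
                           wat_region = "nuchal_wat")
  correlations <- lapply(
    stats::setNames(nm = c("supraclavicular", "axillary", "union", "spine")),
    function(r) tryCatch(ff_volume_correlation(stats, r),
                         error = function(e) NULL))
  list(subjects = subjects, stats = stats, summary = summary,
       paired = paired, correlations = correlations,
       exclusions = exclusions)
}

#' Simulate a multi-rater segmentation study
#'
#' Each subject is segmented three times: twice by "rater 1" (sessions 1a
#' and 1b) and once by "rater 2", each rating using independently jittered
#' seed points (expected displacement `jitter_mm`). Returns the long rater
#' table consumed by [reliability_report()].
#'
#' @param cspec a [cohort_spec()].
#' @param protocol a [segmentation_protocol()].
#' @param jitter_mm expected seed displacement per rating, in mm.
#' @param raters rating labels (default `c("1a", "1b", "2")`).
#' @param seed RNG seed for the jitter draws.
#' @return data frame with columns subject, rater, region, metric, value.
#' @export
run_rater_study <- function(cspec, protocol = segmentation_protocol(),
                            jitter_mm = 1, raters = c("1a", "1b", "2"),
                            seed = 1L) {
  subjects <- draw_cohort_subjects(cspec)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    phantom <- cohort_subject_phantom(cspec, subjects[i, ])
    for (j in seq_along(raters)) {
      jseeds <- jitter_seeds(phantom$seeds, jitter_mm, phantom$truth,
                             seed = derive_seed(seed, i * 100 + j))
      res <- process_subject(phantom, protocol, subject = i, seeds = jseeds)
      if (res$excluded) next
      s <- res$stats
      for (m in c("volume_cc", "mean_ff")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, rater = raters[j], region = s$region, metric = m,
          value = s[[m]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

default_pipeline_config <- function() {
  list(n_subjects = 4L, noise_sd = 0.04, within_sd = 0.03, seed = 1L,
       iterations_spine = 50L, ff_band = c(0.20, 0.60),
       out_dir = tempfile("neobat_run_"), write_volumes = FALSE,
       rescan = TRUE, stratified = TRUE, swap = NULL)
}

#' Run the configured end-to-end pipeline
#'
#' Executes simulate -> separate -> mask -> segment -> quantify (and
#' optionally a scan-rescan agreement stage) as configured, writes all
#' tables (and volumes when requested) under the output directory, and
#' returns a manifest recording the configuration, package version and an
#' MD5 checksum of every written file. A stage failure aborts with the
#' failing stage named.
#'
#' @param config a named list or the path of a YAML file. Recognized fields
#'   (all optional): `n_subjects`, `noise_sd`, `within_sd`, `seed`,
#'   `iterations_spine`, `ff_band`, `out_dir`, `write_volumes`, `rescan`,
#'   `stratified`, and `swap` (list with `subject` and `region`: injects a
#'   6 mm spherical fat/water swap at that depot's centre, which excludes
#'   the subject, mirroring the exclusion of swap-affected scans).
#' @return the manifest (also written as `manifest.json`), invisibly
#'   containing `config`, `version`, `files` and `exclusions`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  swaps <- NULL
  if (!is.null(cfg$swap)) {
    lay <- torso_layout()
    reg <- cfg$swap$region
    if (!reg %in% names(lay)) {
      stop("pipeline stage 'configure' failed: unknown swap region '",
           reg, "'", call. = FALSE)
    }
    geom <- depot_geometry("swap", lay[[reg]]$center, c(6, 6, 6))
    swaps <- stats::setNames(list(list(geom)), as.character(cfg$swap$subject))
  }

  cspec <- stage("configure", cohort_spec(
    n_subjects = cfg$n_subjects, noise_sd = cfg$noise_sd,
    within_sd = cfg$within_sd, stratified = cfg$stratified,
    seed = cfg$seed))
  protocol <- stage("configure", segmentation_protocol(
    ff_band = cfg$ff_band, iterations_spine = cfg$iterations_spine))

  run <- stage("quantify", run_cohort_pipeline(cspec, protocol,
                                               swaps = swaps))

  files <- character()
  wr <- function(obj, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  stage("write-tables", {
    wr(run$stats, "cohort_stats.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(run$summary, "cohort_summary.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(run$exclusions, "exclusions.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(list(paired = run$paired, correlations = run$correlations),
       "comparisons.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA))
  })

  if (isTRUE(cfg$rescan)) {
    stage("rescan", {
      subj <- run$subjects[1, ]
      phantom <- cohort_subject_phantom(cspec, subj)
      res <- process_subject(phantom, protocol, subject = 1L,
                             keep_masks = TRUE)
      echo2 <- make_rescan(phantom, noise_sd = cfg$noise_sd,
                           seed = derive_seed(cfg$seed, 991))
      wf2 <- separate_water_fat(echo2)
      ff2 <- compute_fat_fraction(wf2)
      agree <- rescan_agreement(
        res$ffm, ff2,
        compartments = list(bat_union = res$masks$union,
                            nuchal_wat = res$masks$nuchal_wat),
        signal = res$sm)
      wr(agree, "rescan_agreement.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    })
  }

  if (isTRUE(cfg$write_volumes)) {
    stage("write-volumes", {
      subj <- run$subjects[1, ]
      phantom <- cohort_subject_phantom(cspec, subj)
      files <<- c(files, write_phantom(phantom, cfg$out_dir, "subject1"))
    })
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    version = as.character(utils::packageVersion("neobat")),
    n_analyzed = length(unique(run$stats$subject)),
    exclusions = run$exclusions,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
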