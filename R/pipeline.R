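#' Pipeline configuration
#'
#' Bundles the generator configuration with the segmentation, tracking,
#' classification and survival parameters of the end-to-end pipeline.
#' Every run is a pure function of this configuration: all randomness
#' flows from the generator seed through named substreams.
#'
#' @param generator A [generator_config()].
#' @param threshold CV threshold applied when classifying (default 1.0).
#' @param n_labeled_per_class Size per class of the labelled calibration
#'   set (default 50).
#' @param min_area,max_area Segmentation area filter (pixels).
#' @param max_displacement Tracking displacement gate (pixels).
#' @param death_fraction Death-calling intensity fraction.
#' @param reference Reference group for the Cox group model (default: the
#'   first configured group).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            threshold = 1.0,
                            n_labeled_per_class = 50,
                            min_area = 30, max_area = 400,
                            max_displacement = 15,
                            death_fraction = 0.2,
                            reference = NULL) {
  stopifnot(inherits(generator, "generator_config"),
            threshold > 0, n_labeled_per_class >= 1,
            min_area >= 1, max_area > min_area,
            max_displacement > 0, death_fraction > 0, death_fraction < 1)
  groups <- vapply(generator$groups, `[[`, character(1), "name")
  reference <- reference %||% groups[1]
  if (!reference %in% groups) stop("unknown reference group: ", reference)
  structure(list(generator = generator, threshold = threshold,
                 n_labeled_per_class = as.integer(n_labeled_per_class),
                 min_area = min_area, max_area = max_area,
                 max_displacement = max_displacement,
                 death_fraction = death_fraction,
                 reference = reference),
            class = "pipeline_config")
}

#' Run the full synthetic imaging and survival pipeline
#'
#' Executes, deterministically for a given configuration: cohort sampling,
#' per-field movie rendering, segmentation, track linking, death calling,
#' per-ROI CV measurement, classifier calibration on a labelled ROI set,
#' per-neuron aggregate classification, survival record construction,
#' Kaplan-Meier estimation per group, a Cox group model (when more than
#' one group is configured) and per-group aggregate-stratified Cox models
#' (skipped, with a logged reason, when a group lacks either aggregate
#' class or any event). Fields are processed one at a time so pixel data
#' never accumulates.
#'
#' @param config A [pipeline_config()].
#' @param keep_tracks If `TRUE`, also return the concatenated track-level
#'   and call-level tables (larger output).
#' @return A list of class `run_report`; see the package vignette for the
#'   report schema.
#' @export
run_pipeline <- function(config, keep_tracks = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  calib <- calibrate_classifier(
    generate_labeled_roiset(gen, config$n_labeled_per_class,
                            min_area = config$min_area,
                            max_area = config$max_area),
    threshold = config$threshold)
  truth <- sample_cohort(gen)
  fields <- unique(truth$neurons$field)
  all_records <- list(); all_excl <- list()
  all_tracks <- list(); all_calls <- list()
  counts <- list()
  offset <- 0L
  for (f in fields) {
    grp <- truth$neurons$group[truth$neurons$field == f][1]
    movie <- render_movie(truth, gen, f)
    rois <- segment_movie(movie, min_area = config$min_area,
                          max_area = config$max_area)
    tracks <- link_tracks(rois, config$max_displacement)
    n_field <- sum(truth$neurons$field == f)
    if (nrow(tracks) == 0L) {
      counts[[f]] <- data.frame(field = f, group = grp, n_truth = n_field,
                                n_tracked = 0L)
      next
    }
    deaths <- call_death(tracks, gen$n_timepoints, config$death_fraction)
    calls <- classify_neurons(tracks, deaths, config$threshold)
    rec <- build_records(deaths, calls, grp, gen$n_timepoints,
                         gen$interval_hours)
    # field-local track ids are made globally unique
    rec$records$track_id <- rec$records$track_id + offset
    if (nrow(rec$exclusions)) {
      rec$exclusions$track_id <- rec$exclusions$track_id + offset
      rec$exclusions$field <- f
      all_excl[[f]] <- rec$exclusions
    }
    counts[[f]] <- data.frame(field = f, group = grp, n_truth = n_field,
                              n_tracked = nrow(deaths))
    all_records[[f]] <- rec$records
    if (keep_tracks) {
      tracks$track_id <- tracks$track_id + offset
      tracks$field <- f
      calls$track_id <- calls$track_id + offset
      calls$field <- f
      all_tracks[[f]] <- tracks
      all_calls[[f]] <- calls
    }
    offset <- offset + max(deaths$track_id)
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  exclusions <- if (length(all_excl)) do.call(rbind, all_excl) else
    data.frame(track_id = integer(0), reason = character(0),
               field = character(0))
  rownames(exclusions) <- NULL
  group_names <- vapply(gen$groups, `[[`, character(1), "name")
  groups <- list()
  cox_aggregate <- list()
  for (g in group_names) {
    rg <- records[records$group == g, ]
    km <- if (nrow(rg)) kaplan_meier(rg$time, rg$event) else NULL
    groups[[g]] <- list(
      n_analyzed = nrow(rg),
      n_events = sum(rg$event),
      aggregate_fraction_pct = if (nrow(rg))
        100 * mean(rg$aggregated) else NA_real_,
      km = if (!is.null(km)) km$table else NULL)
    cox_aggregate[[g]] <- if (nrow(rg) == 0L) {
      list(fit = NULL, skipped = "no analyzable neurons")
    } else if (length(unique(rg$aggregated)) < 2L) {
      list(fit = NULL,
           skipped = "aggregate and diffuse classes not both present")
    } else if (!any(rg$event)) {
      list(fit = NULL, skipped = "no observed deaths")
    } else {
      list(fit = cox_fit(rg, covariates = "aggregated"), skipped = NULL)
    }
  }
  cox_group <- if (length(unique(records$group)) >= 2L && any(records$event)) {
    cox_fit(records, covariates = "group",
            reference = c(group = config$reference))
  } else {
    NULL
  }
  report <- list(
    seed = gen$seed,
    config = config,
    calibration = list(auc = calib$auc,
                       threshold_selected = calib$threshold_selected,
                       threshold_applied = calib$threshold_applied,
                       sensitivity = calib$sensitivity,
                       specificity = calib$specificity,
                       n_labeled = calib$n),
    counts = {cd <- do.call(rbind, counts); rownames(cd) <- NULL; cd},
    groups = groups,
    cox_group = cox_group,
    cox_aggregate = cox_aggregate,
    records = records,
    exclusions = exclusions)
  if (keep_tracks) {
    report$tracks <- do.call(rbind, all_tracks)
    report$calls <- do.call(rbind, all_calls)
    rownames(report$tracks) <- rownames(report$calls) <- NULL
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Longitudinal survival pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf(
    "Calibration: AUC %.3f, Youden threshold %.3f, applied %.2f, sens %.1f%%, spec %.1f%%\n",
    x$calibration$auc, x$calibration$threshold_selected,
    x$calibration$threshold_applied, 100 * x$calibration$sensitivity,
    100 * x$calibration$specificity))
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf(
      "Group %-10s n = %4d, deaths = %4d, aggregate-bearing = %5.1f%%\n",
      g, gr$n_analyzed, gr$n_events, gr$aggregate_fraction_pct))
  }
  if (!is.null(x$cox_group)) {
    cat("\nCox group model:\n")
    print(x$cox_group)
  }
  for (g in names(x$cox_aggregate)) {
    ca <- x$cox_aggregate[[g]]
    if (!is.null(ca$fit)) {
      cat("\nAggregate-stratified Cox model,", g, ":\n")
      print(ca$fit)
    } else {
      cat("\nAggregate-stratified Cox model,", g, ": skipped (",
          ca$skipped, ")\n", sep = "")
    }
  }
  cat("\nExcluded neurons:", nrow(x$exclusions), "\n")
  invisible(x)
}
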