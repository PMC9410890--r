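#' Describe one construct group for the synthetic cohort
#'
#' A group corresponds to one transfected construct imaged longitudinally
#' (for example a diffuse-only control, or an aggregation-prone reporter).
#' Death is generated as a discrete-time geometric process on the 24 h
#' imaging grid: at every interval an alive neuron dies with probability
#' `baseline_hazard`, multiplied by `aggregate_hazard_multiplier` if the
#' neuron carries an aggregate.
#'
#' @param name Group label (character scalar).
#' @param aggregate_probability Probability in `[0, 1]` that a neuron of this
#'   group carries a reporter aggregate (planted as a static property,
#'   present from the first timepoint).
#' @param baseline_hazard Per-interval death probability in `[0, 1)` for
#'   aggregate-free neurons.
#' @param aggregate_hazard_multiplier Positive multiplier applied to the
#'   baseline hazard for aggregate-bearing neurons. The product
#'   `baseline_hazard * aggregate_hazard_multiplier` must stay below 1.
#' @return A list of class `cohort_group`.
#' @export
cohort_group <- function(name, aggregate_probability = 0,
                         baseline_hazard = 0.03,
                         aggregate_hazard_multiplier = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(aggregate_probability) || aggregate_probability < 0 ||
      aggregate_probability > 1) {
    stop("aggregate_probability must lie in [0, 1]")
  }
  if (!is.numeric(baseline_hazard) || baseline_hazard < 0 ||
      baseline_hazard >= 1) {
    stop("baseline_hazard must lie in [0, 1)")
  }
  if (!is.numeric(aggregate_hazard_multiplier) ||
      aggregate_hazard_multiplier <= 0) {
    stop("aggregate_hazard_multiplier must be positive")
  }
  if (baseline_hazard * aggregate_hazard_multiplier >= 1) {
    stop("baseline_hazard * aggregate_hazard_multiplier must stay below 1: ",
         "a per-interval death probability cannot reach 1")
  }
  structure(list(name = name,
                 aggregate_probability = aggregate_probability,
                 baseline_hazard = baseline_hazard,
                 aggregate_hazard_multiplier = aggregate_hazard_multiplier),
            class = "cohort_group")
}

#' Configuration of the synthetic two-channel movie generator
#'
#' The generator emulates the longitudinal imaging design the analysis
#' assumes: sparsely plated transfected neurons imaged once every 24 h for
#' 10 timepoints in two channels. The tracking channel carries a
#' constitutively expressed cell fill (a roughly uniform disc per live
#' soma); the reporter channel carries the GFP-tagged construct, rendered
#' either diffusely (uniform over the soma) or with `aggregate_flux_fraction`
#' of the same total reporter flux concentrated into 1-3 Gaussian puncta.
#' Total reporter flux is conserved between the two phenotypes, so the
#' coefficient of variation - not brightness - is what separates them.
#' Dead neurons emit no signal from their death interval onward. Pixel
#' noise is Poisson shot noise (scaled by `photon_scale`) plus Gaussian
#' read noise on top of a constant background.
#'
#' The default group set mirrors a three-arm experiment: a diffuse-only
#' control plus two aggregation-prone constructs with planted
#' aggregate-bearing fractions of 48.5% and 25%.
#'
#' @param groups List of [cohort_group()] descriptors.
#' @param n_neurons_per_group Neurons simulated per group.
#' @param n_timepoints Number of imaging timepoints (default 10).
#' @param interval_hours Hours between timepoints (default 24).
#' @param frame_shape Integer `c(height, width)` of each frame in pixels.
#' @param neurons_per_field Maximum neurons placed in one field of view;
#'   larger cohorts are split across several movies.
#' @param soma_radius_mean,soma_radius_sd,soma_radius_min Soma radius draw
#'   (pixels): Normal(mean, sd) truncated below at `soma_radius_min`.
#' @param n_puncta_range Integer range (inclusive) of puncta per aggregated
#'   neuron; drawn uniformly.
#' @param punctum_radius_fraction Gaussian sigma of each punctum as a
#'   fraction of the soma radius. Together with `aggregate_flux_fraction`
#'   this sets the CV contrast between phenotypes (see the methods
#'   vignette); the default places the aggregated/diffuse CV crossover
#'   near 1.0.
#' @param aggregate_flux_fraction Fraction of total reporter flux moved
#'   into puncta for aggregated neurons (default 0.6).
#' @param tracking_intensity,reporter_intensity Mean per-pixel signal
#'   (intensity units) of the tracking fill and of a diffuse reporter soma.
#' @param background_level Constant background (intensity units).
#' @param read_noise_sd Gaussian read noise standard deviation (intensity
#'   units); 0 disables read noise.
#' @param photon_scale Expected photon counts per intensity unit for the
#'   Poisson shot-noise model; `Inf` disables shot noise.
#' @param drift_sd Per-interval centroid drift standard deviation (pixels).
#' @param min_separation_radii Minimum pairwise centre separation at
#'   placement, in units of `soma_radius_mean` (default 4, which avoids
#'   merged ROIs by construction).
#' @param seed Root seed; identical config + seed gives bit-identical
#'   movies and tables.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(groups = list(
                               cohort_group("control", 0, 0.02, 1),
                               cohort_group("CGG", 0.485, 0.04, 2.5),
                               cohort_group("GGN", 0.25, 0.035, 1)),
                             n_neurons_per_group = 200,
                             n_timepoints = 10,
                             interval_hours = 24,
                             frame_shape = c(256, 256),
                             neurons_per_field = 20,
                             soma_radius_mean = 6,
                             soma_radius_sd = 0.8,
                             soma_radius_min = 4,
                             n_puncta_range = c(1, 3),
                             punctum_radius_fraction = 0.145,
                             aggregate_flux_fraction = 0.6,
                             tracking_intensity = 60,
                             reporter_intensity = 40,
                             background_level = 10,
                             read_noise_sd = 2,
                             photon_scale = 1,
                             drift_sd = 2,
                             min_separation_radii = 4,
                             seed = 1) {
  if (inherits(groups, "cohort_group")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "cohort_group")))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("group names must be unique")
  stopifnot(n_neurons_per_group >= 1, n_timepoints >= 1,
            interval_hours > 0, length(frame_shape) == 2L,
            all(frame_shape >= 32), neurons_per_field >= 1,
            soma_radius_mean > 0, soma_radius_sd >= 0, soma_radius_min > 0,
            length(n_puncta_range) == 2L, n_puncta_range[1] >= 1,
            n_puncta_range[2] >= n_puncta_range[1],
            punctum_radius_fraction > 0, punctum_radius_fraction <= 0.2,
            aggregate_flux_fraction > 0, aggregate_flux_fraction < 1,
            tracking_intensity > 0, reporter_intensity > 0,
            background_level >= 0, read_noise_sd >= 0, photon_scale > 0,
            drift_sd >= 0, min_separation_radii > 0)
  cfg <- list(groups = groups,
              n_neurons_per_group = as.integer(n_neurons_per_group),
              n_timepoints = as.integer(n_timepoints),
              interval_hours = interval_hours,
              frame_shape = as.integer(frame_shape),
              neurons_per_field = as.integer(neurons_per_field),
              soma_radius_mean = soma_radius_mean,
              soma_radius_sd = soma_radius_sd,
              soma_radius_min = soma_radius_min,
              n_puncta_range = as.integer(n_puncta_range),
              punctum_radius_fraction = punctum_radius_fraction,
              aggregate_flux_fraction = aggregate_flux_fraction,
              tracking_intensity = tracking_intensity,
              reporter_intensity = reporter_intensity,
              background_level = background_level,
              read_noise_sd = read_noise_sd,
              photon_scale = photon_scale,
              drift_sd = drift_sd,
              min_separation_radii = min_separation_radii,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# Dart-throwing placement with a minimum pairwise separation; errors out if
# the field cannot accommodate the requested density.
place_somata <- function(n, frame_shape, radius, min_sep) {
  h <- frame_shape[1]; w <- frame_shape[2]
  margin <- max(radius) + 2
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(5000L)) {
      x <- runif(1, margin, w - 1 - margin)
      y <- runif(1, margin, h - 1 - margin)
      if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " somata with separation ", min_sep,
           " px in a ", h, "x", w, " frame; reduce neurons_per_field")
    }
  }
  cbind(x = xs, y = ys)
}

#' Sample a ground-truthed synthetic cohort
#'
#' Draws, for every neuron, its group, field-of-view assignment, soma
#' geometry, aggregate status (Bernoulli with the group's
#' `aggregate_probability`), punctum geometry, centroid drift path, and a
#' death interval from a discrete-time geometric process with per-interval
#' hazard `baseline_hazard * aggregate_hazard_multiplier^aggregate`.
#' A neuron surviving all `n_timepoints` draws is censored
#' (`death_interval = NA`). `death_interval = k` means the neuron is first
#' seen dead at timepoint `k`; neurons already dead at the first imaging
#' timepoint are present in the ground truth but never enter image-based
#' tracking (they are logged as exclusions by the pipeline).
#'
#' @param config A [generator_config()].
#' @return A list of class `ground_truth` with data frames `neurons`
#'   (one row per neuron: `neuron_id`, `group`, `field`, `soma_radius`,
#'   `aggregate`, `n_puncta`, `death_interval`), `paths` (per neuron and
#'   timepoint: centroid `x`, `y` in 0-based pixel coordinates and an
#'   `alive` flag) and `puncta` (per punctum: offsets `dx`, `dy` from the
#'   soma centre, Gaussian `sigma`, and `flux_share`), plus the `config`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  tp <- config$n_timepoints
  neurons <- list(); paths <- list(); puncta <- list()
  nid <- 0L
  for (g in config$groups) {
    n <- config$n_neurons_per_group
    n_fields <- ceiling(n / config$neurons_per_field)
    field_of <- rep(seq_len(n_fields), each = config$neurons_per_field,
                    length.out = n)
    for (f in seq_len(n_fields)) {
      idx <- which(field_of == f)
      nf <- length(idx)
      radius <- pmax(config$soma_radius_min,
                     rnorm(nf, config$soma_radius_mean, config$soma_radius_sd))
      pos <- place_somata(nf, config$frame_shape, radius,
                          config$min_separation_radii * config$soma_radius_mean)
      agg <- runif(nf) < g$aggregate_probability
      hazard <- g$baseline_hazard *
        ifelse(agg, g$aggregate_hazard_multiplier, 1)
      field_name <- sprintf("%s_f%03d", g$name, f)
      for (k in seq_len(nf)) {
        nid <- nid + 1L
        # geometric death draw on the imaging grid, censored after tp draws
        u <- runif(tp)
        hit <- which(u < hazard[k])
        death <- if (length(hit)) hit[1] else NA_integer_
        npun <- 0L
        if (agg[k]) {
          npun <- sample(seq(config$n_puncta_range[1],
                             config$n_puncta_range[2]), 1L)
          sigma <- config$punctum_radius_fraction * radius[k]
          # puncta centres uniform in the disc, kept >= 2 sigma from the rim
          rmax <- max(radius[k] - 2 * sigma, 0.5)
          rr <- rmax * sqrt(runif(npun))
          th <- runif(npun, 0, 2 * pi)
          puncta[[length(puncta) + 1L]] <- data.frame(
            neuron_id = nid, punctum = seq_len(npun),
            dx = rr * cos(th), dy = rr * sin(th),
            sigma = sigma, flux_share = 1 / npun)
        }
        # per-interval random-walk drift, clamped so the soma stays in frame
        margin <- radius[k] + 1
        dx <- cumsum(c(0, rnorm(tp - 1, 0, config$drift_sd)))
        dy <- cumsum(c(0, rnorm(tp - 1, 0, config$drift_sd)))
        px <- pmin(pmax(pos[k, "x"] + dx, margin),
                   config$frame_shape[2] - 1 - margin)
        py <- pmin(pmax(pos[k, "y"] + dy, margin),
                   config$frame_shape[1] - 1 - margin)
        alive <- if (is.na(death)) rep(TRUE, tp) else seq_len(tp) < death
        neurons[[nid]] <- data.frame(
          neuron_id = nid, group = g$name, field = field_name,
          soma_radius = radius[k], aggregate = agg[k], n_puncta = npun,
          death_interval = death)
        paths[[nid]] <- data.frame(
          neuron_id = nid, timepoint = seq_len(tp), x = px, y = py,
          alive = alive)
      }
    }
  }
  out <- list(neurons = do.call(rbind, neurons),
              paths = do.call(rbind, paths),
              puncta = if (length(puncta)) do.call(rbind, puncta) else
                data.frame(neuron_id = integer(0), punctum = integer(0),
                           dx = numeric(0), dy = numeric(0),
                           sigma = numeric(0), flux_share = numeric(0)),
              config = config)
  rownames(out$neurons) <- NULL
  rownames(out$paths) <- NULL
  class(out) <- "ground_truth"
  out
}

# Render the noiseless signal of one channel for one timepoint.
# Coordinates are 0-based: pixel (row i, col j) sits at (x = j-1, y = i-1).
render_signal <- function(neurons, paths, puncta, config, timepoint, channel) {
  h <- config$frame_shape[1]; w <- config$frame_shape[2]
  img <- matrix(0, h, w)
  for (k in seq_len(nrow(neurons))) {
    nr <- neurons[k, ]
    p <- paths[paths$neuron_id == nr$neuron_id &
                 paths$timepoint == timepoint, ]
    if (nrow(p) != 1L || !p$alive) next
    r <- nr$soma_radius
    cx <- p$x; cy <- p$y
    if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1) {
      stop("soma of neuron ", nr$neuron_id, " does not fit in the frame")
    }
    rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r) + 2L)
    cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r) + 2L)
    d2 <- outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`)
    mask <- d2 <= r^2
    npix <- sum(mask)
    if (npix == 0L) next
    if (channel == "tracking") {
      img[rows, cols][mask] <- img[rows, cols][mask] + config$tracking_intensity
    } else {
      total_flux <- config$reporter_intensity * npix
      if (!nr$aggregate) {
        img[rows, cols][mask] <- img[rows, cols][mask] +
          config$reporter_intensity
      } else {
        base <- (1 - config$aggregate_flux_fraction) * config$reporter_intensity
        add <- matrix(base, nrow(d2), ncol(d2))
        pu <- puncta[puncta$neuron_id == nr$neuron_id, , drop = FALSE]
        for (q in seq_len(nrow(pu))) {
          gx <- cx + pu$dx[q]; gy <- cy + pu$dy[q]
          g2 <- outer((rows - 1 - gy)^2, (cols - 1 - gx)^2, `+`)
          g <- exp(-g2 / (2 * pu$sigma[q]^2))
          g[!mask] <- 0
          sg <- sum(g)
          if (sg <= 0) next
          # normalised within the soma so total reporter flux is conserved
          # exactly between diffuse and aggregated phenotypes
          flux <- config$aggregate_flux_fraction * total_flux *
            pu$flux_share[q]
          add <- add + flux * g / sg
        }
        add[!mask] <- 0
        img[rows, cols] <- img[rows, cols] + add
      }
    }
  }
  img
}

add_noise <- function(signal, config) {
  out <- signal + config$background_level
  if (is.finite(config$photon_scale)) {
    out <- rpois(length(out), config$photon_scale * out) / config$photon_scale
    out <- matrix(out, nrow(signal), ncol(signal))
  }
  if (config$read_noise_sd > 0) {
    out <- out + matrix(rnorm(length(out), 0, config$read_noise_sd),
                        nrow(signal), ncol(signal))
  }
  pmax(out, 0)
}

#' Render the movie of one field of view
#'
#' Produces the two-channel time-lapse stack for all neurons of one field:
#' live somata as filled discs on the tracking channel, diffuse or punctate
#' reporter signal on the reporter channel, no signal from a neuron's death
#' interval onward, then constant background, Poisson shot noise and
#' Gaussian read noise per pixel. Noise is drawn from a per-field substream
#' of the root seed, so any field re-renders bit-identically.
#'
#' @param truth A `ground_truth` object from [sample_cohort()].
#' @param config The matching [generator_config()].
#' @param field Field name (an entry of `truth$neurons$field`).
#' @return A `movie` object: list with `pixels` (array
#'   `height x width x 2 x n_timepoints`, channels ordered tracking then
#'   reporter), `times` (hours) and `channels`.
#' @export
render_movie <- function(truth, config, field) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "generator_config"))
  neurons <- truth$neurons[truth$neurons$field == field, , drop = FALSE]
  if (nrow(neurons) == 0L) stop("unknown field: ", field)
  paths <- truth$paths[truth$paths$neuron_id %in% neurons$neuron_id, ,
                       drop = FALSE]
  set.seed(derive_seed(config$seed, paste0("render/", field)))
  tp <- config$n_timepoints
  px <- array(0, dim = c(config$frame_shape[1], config$frame_shape[2], 2, tp))
  for (t in seq_len(tp)) {
    for (ci in 1:2) {
      ch <- c("tracking", "reporter")[ci]
      sig <- render_signal(neurons, paths, truth$puncta, config, t, ch)
      px[, , ci, t] <- add_noise(sig, config)
    }
  }
  structure(list(pixels = px,
                 times = config$interval_hours * seq_len(tp),
                 channels = c("tracking", "reporter")),
            class = "movie")
}

#' Generate a labelled ROI validation set
#'
#' Emulates the manual annotation step used to calibrate the CV classifier:
#' `n_per_class` aggregated and `n_per_class` diffuse ROIs are rendered by
#' the same engine as [render_movie()] (one neuron per miniature frame, one
#' timepoint), segmented on the tracking channel, and their
#' background-subtracted reporter CV computed, with the true phenotype
#' attached.
#'
#' @param config A [generator_config()].
#' @param n_per_class Number of ROIs per class (the calibration design uses
#'   50 per group).
#' @param min_area,max_area Area filter passed to [segment_frame()].
#' @return A data frame of class `labeled_roiset` with columns `roi_id`,
#'   `true_label` (factor: aggregated/diffuse), `cv`, `area`, `mean`, `sd`.
#' @export
generate_labeled_roiset <- function(config, n_per_class = 50,
                                    min_area = 30, max_area = 400) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("n_per_class must be at least 1")
  }
  n_per_class <- as.integer(n_per_class)
  set.seed(derive_seed(config$seed, "labeled_roiset"))
  side <- ceiling(6 * config$soma_radius_mean)
  mini <- config
  mini$frame_shape <- c(side, side)
  mini$n_timepoints <- 1L
  out <- vector("list", 2L * n_per_class)
  labels <- rep(c("aggregated", "diffuse"), each = n_per_class)
  for (i in seq_along(labels)) {
    agg <- labels[i] == "aggregated"
    radius <- max(config$soma_radius_min,
                  rnorm(1, config$soma_radius_mean, config$soma_radius_sd))
    npun <- 0L
    pu <- data.frame(neuron_id = integer(0), punctum = integer(0),
                     dx = numeric(0), dy = numeric(0), sigma = numeric(0),
                     flux_share = numeric(0))
    if (agg) {
      npun <- sample(seq(config$n_puncta_range[1], config$n_puncta_range[2]),
                     1L)
      sigma <- config$punctum_radius_fraction * radius
      rmax <- max(radius - 2 * sigma, 0.5)
      rr <- rmax * sqrt(runif(npun))
      th <- runif(npun, 0, 2 * pi)
      pu <- data.frame(neuron_id = 1L, punctum = seq_len(npun),
                       dx = rr * cos(th), dy = rr * sin(th),
                       sigma = sigma, flux_share = 1 / npun)
    }
    ctr <- (side - 1) / 2
    neurons <- data.frame(neuron_id = 1L, group = labels[i], field = "roi",
                          soma_radius = radius, aggregate = agg,
                          n_puncta = npun, death_interval = NA_integer_)
    paths <- data.frame(neuron_id = 1L, timepoint = 1L, x = ctr, y = ctr,
                        alive = TRUE)
    track <- add_noise(render_signal(neurons, paths, pu, mini, 1L,
                                     "tracking"), mini)
    rep_ <- add_noise(render_signal(neurons, paths, pu, mini, 1L,
                                    "reporter"), mini)
    rois <- segment_frame(track, rep_, min_area = min_area,
                          max_area = max_area)
    if (nrow(rois) == 0L) {
      out[[i]] <- data.frame(roi_id = i, true_label = labels[i],
                             cv = NA_real_, area = NA_real_,
                             mean = NA_real_, sd = NA_real_)
    } else {
      best <- rois[which.max(rois$area), ]
      out[[i]] <- data.frame(roi_id = i, true_label = labels[i],
                             cv = best$cv, area = best$area,
                             mean = best$mean, sd = best$sd)
    }
  }
  res <- do.call(rbind, out)
  res$true_label <- factor(res$true_label, levels = c("diffuse", "aggregated"))
  rownames(res) <- NULL
  class(res) <- c("labeled_roiset", "data.frame")
  res
}
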