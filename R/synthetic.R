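#' Psychophysical observer model
#'
#' Cumulative-Gaussian observer used by the staircase simulator: a stimulus of
#' attenuation `L` dB is seen with probability
#' `fp + (1 - fp - lapse) * pnorm((T - L) / slope)` where `T` is the true
#' threshold. `psychometric_slope = 0` gives the deterministic step observer
#' (sees exactly the levels at or below threshold). The false-positive rate
#' also drives blind-spot catch-trial presses (fixation losses).
#'
#' @param psychometric_slope Slope of the psychometric function in dB (>= 0).
#' @param false_positive_rate,lapse_rate Probabilities in \[0, 0.5\].
#' @return An object of class `sm_observer`.
#' @export
observer_model <- function(psychometric_slope = 1.5,
                           false_positive_rate = 0.04, lapse_rate = 0.02) {
  stopifnot(psychometric_slope >= 0,
            false_positive_rate >= 0, false_positive_rate <= 0.5,
            lapse_rate >= 0, lapse_rate <= 0.5)
  structure(list(psychometric_slope = psychometric_slope,
                 false_positive_rate = false_positive_rate,
                 lapse_rate = lapse_rate), class = "sm_observer")
}

#' Ground-truth retinal sensitivity field
#'
#' Parametric hill-of-vision model behind the synthetic cohorts. Healthy
#' profile: sensitivity `peak - radial_slope * r` (clamped to \[0, 36\] dB)
#' with, for cyan stimuli, the rod-free fovea replaced by a low cone-driven
#' residual inside `rod_free_radius`. Choroideremia profile: the same surface
#' minus a color-specific deficit inside a residual central island ellipse
#' (offset temporally, reflecting the typical temporal sparing), and non-seen
#' outside the island. Cyan and red dB scales are taken as calibrated so that
#' equal dB means equal scotopic visibility (the ~20 dB radiance offset
#' between colors is absorbed into the per-color dB definition), so a healthy
#' off-fovea cyan-red difference is 0.0 dB by construction.
#'
#' @param profile `"healthy"` or `"choroideremia"`.
#' @param peak_cyan,peak_red Peak sensitivities at fixation, dB.
#' @param radial_slope Fall-off, dB per degree of eccentricity.
#' @param rod_free_radius Radius of the rod-free fovea, degrees.
#' @param central_cyan_residual Cyan sensitivity inside the rod-free zone, dB
#'   (cone-driven response to bright cyan; healthy median 4.0 dB).
#' @param island_semi_axes Length-2 semi-axes (a, b) in degrees of the
#'   residual island ellipse (choroideremia only).
#' @param island_center_offset Temporal (+x) shift of the island center, deg.
#' @param cyan_deficit,red_deficit Sensitivity loss inside the island, dB.
#' @return An object of class `sm_field`.
#' @export
sensitivity_field <- function(profile = c("healthy", "choroideremia"),
                              peak_cyan = 23, peak_red = 23,
                              radial_slope = 0.5, rod_free_radius = 0.5,
                              central_cyan_residual = 4,
                              island_semi_axes = NULL,
                              island_center_offset = 1.5,
                              cyan_deficit = 0, red_deficit = 0) {
  profile <- match.arg(profile)
  stopifnot(rod_free_radius >= 0, cyan_deficit >= 0, red_deficit >= 0)
  if (profile == "choroideremia") {
    if (is.null(island_semi_axes) || length(island_semi_axes) != 2L ||
        any(island_semi_axes <= 0)) {
      stop("choroideremia profile requires positive island_semi_axes (a, b)",
           call. = FALSE)
    }
  }
  structure(list(profile = profile, peak_cyan = peak_cyan, peak_red = peak_red,
                 radial_slope = radial_slope, rod_free_radius = rod_free_radius,
                 central_cyan_residual = central_cyan_residual,
                 island_semi_axes = island_semi_axes,
                 island_center_offset = island_center_offset,
                 cyan_deficit = cyan_deficit, red_deficit = red_deficit),
            class = "sm_field")
}

#' True threshold of a sensitivity field at a retinal location
#'
#' Vectorized over `x`, `y`. Returns the noiseless threshold in dB, or the
#' non-seen sentinel `-1.0` outside a choroideremia residual island.
#'
#' @param field A [sensitivity_field()].
#' @param color `"cyan_505nm"`, `"red_627nm"` or `"white"` (white behaves as
#'   red: no rod-free scotoma).
#' @param x,y Retinal coordinates in degrees (OD convention).
#' @return Numeric vector of dB values (or `-1.0`).
#' @export
true_threshold <- function(field, color, x, y) {
  stopifnot(inherits(field, "sm_field"), length(x) == length(y))
  r <- sqrt(x^2 + y^2)
  peak <- if (color == "cyan_505nm") field$peak_cyan else field$peak_red
  t <- peak - field$radial_slope * r
  if (color == "cyan_505nm") {
    t[r <= field$rod_free_radius] <- field$central_cyan_residual
  }
  if (field$profile == "choroideremia") {
    a <- field$island_semi_axes[1]; b <- field$island_semi_axes[2]
    inside <- ((x - field$island_center_offset) / a)^2 + (y / b)^2 <= 1
    deficit <- if (color == "cyan_505nm") field$cyan_deficit else field$red_deficit
    t[inside] <- t[inside] - deficit
    t[!inside] <- SENTINEL_NONSEEN
  }
  seen <- t != SENTINEL_NONSEEN
  t[seen] <- pmin(pmax(t[seen], DB_RANGE[1]), DB_RANGE[2])
  t
}

#' Simulate a 4-2 bracketing threshold staircase
#'
#' Emulates the device's 4.0-2.0 dB bracketing strategy at one locus. Starting
#' from `start_level`, the level steps 4 dB brighter (lower dB) after each
#' not-seen response and 4 dB dimmer after each seen response; at the first
#' response reversal the step drops to 2 dB; one further presentation is made
#' after the second reversal and the staircase terminates, returning the last
#' level seen. A not-seen response at 0 dB (the brightest stimulus) terminates
#' with the non-seen sentinel `-1.0`; a seen response at 36 dB (the dimmest)
#' terminates at the ceiling.
#'
#' @param true_db True threshold in dB, or `-1.0` / `-Inf` for a non-seeing
#'   locus.
#' @param observer An [observer_model()].
#' @param start_level Initial attenuation level, dB.
#' @param return_trace If `TRUE`, attach the presentation levels and responses
#'   as attribute `"trace"`.
#' @param max_presentations Hard cap on the presentation loop.
#' @return Measured threshold in dB (on the 4/2-step lattice), or `-1.0`.
#' @examples
#' det <- observer_model(psychometric_slope = 0, false_positive_rate = 0,
#'                       lapse_rate = 0)
#' run_staircase(10, det)  # 18x, 14x, 10+, 12x, 10+ -> 10 dB
#' @export
run_staircase <- function(true_db, observer, start_level = 18,
                          return_trace = FALSE, max_presentations = 60L) {
  stopifnot(inherits(observer, "sm_observer"))
  t <- if (true_db == SENTINEL_NONSEEN) -Inf else true_db
  level <- start_level
  step <- 4
  last_seen <- NA_real_
  prev <- NA
  reversals <- 0L
  final_presentation <- FALSE
  levels <- numeric(0); responses <- logical(0)
  result <- SENTINEL_NONSEEN
  for (i in seq_len(max_presentations)) {
    seen <- stats::runif(1) < seen_probability(t, level, observer)
    levels <- c(levels, level); responses <- c(responses, seen)
    if (seen) last_seen <- level
    if (!is.na(prev) && seen != prev) {
      reversals <- reversals + 1L
      if (reversals == 1L) step <- 2
    }
    if (!seen && level <= DB_RANGE[1]) break # brightest stimulus not seen
    if (seen && level >= DB_RANGE[2]) { result <- DB_RANGE[2]; break }
    if (final_presentation) { result <- last_seen; break }
    if (reversals >= 2L) final_presentation <- TRUE # one more presentation
    prev <- seen
    level <- min(max(level + if (seen) step else -step,
                     DB_RANGE[1]), DB_RANGE[2])
    if (i == max_presentations && !is.na(last_seen)) result <- last_seen
  }
  if (return_trace) attr(result, "trace") <-
      data.frame(level = levels, seen = responses)
  result
}

seen_probability <- function(true_db, level, observer) {
  detect <- if (observer$psychometric_slope == 0) {
    as.numeric(level <= true_db)
  } else {
    stats::pnorm((true_db - level) / observer$psychometric_slope)
  }
  observer$false_positive_rate +
    (1 - observer$false_positive_rate - observer$lapse_rate) * detect
}

#' Simulate one exam
#'
#' Runs [run_staircase()] at every grid locus of a ground-truth field, draws
#' the fixation trace from a bivariate normal (jitter around the preferred
#' retinal locus at fixation) and catch-trial presses as Bernoulli draws with
#' the observer's false-positive rate. Uses the current RNG stream; seed at
#' the caller for reproducibility.
#'
#' @param field A [sensitivity_field()].
#' @param grid An [build_grid()] object.
#' @param observer An [observer_model()].
#' @param subject_id,eye,color,session Exam identity fields.
#' @param fixation_sigma Length-2 SDs (x, y) of fixation jitter, degrees.
#' @param fixation_rho Correlation of the fixation jitter.
#' @param n_fixation_samples,n_catch_trials Sample counts.
#' @param retest_offsets Optional per-locus additive perturbation of the true
#'   thresholds (biological/criterion drift between sessions), dB.
#' @param fixation_target_intensity,duration_s Metadata passed through.
#' @return An [new_exam()] object (condition `"scotopic"`).
#' @export
simulate_exam <- function(field, grid, observer, subject_id = "S1",
                          eye = "OD", color = "cyan_505nm",
                          session = "test1",
                          fixation_sigma = c(0.25, 0.25), fixation_rho = 0,
                          n_fixation_samples = 500L, n_catch_trials = 10L,
                          retest_offsets = NULL,
                          fixation_target_intensity = NA_real_,
                          duration_s = NA_real_) {
  truth <- true_threshold(field, color, grid$loci$x, grid$loci$y)
  if (!is.null(retest_offsets)) {
    seen <- truth != SENTINEL_NONSEEN
    truth[seen] <- pmin(pmax(truth[seen] + retest_offsets[seen], DB_RANGE[1]),
                        DB_RANGE[2])
  }
  thresholds <- vapply(truth, run_staircase, numeric(1), observer = observer)
  z1 <- stats::rnorm(n_fixation_samples)
  z2 <- stats::rnorm(n_fixation_samples)
  fx <- fixation_sigma[1] * z1
  fy <- fixation_sigma[2] * (fixation_rho * z1 +
                               sqrt(1 - fixation_rho^2) * z2)
  presses <- stats::runif(n_catch_trials) < observer$false_positive_rate
  new_exam(subject_id = subject_id, eye = eye, condition = "scotopic",
           color = color, grid = grid, thresholds = thresholds,
           fixation_trace = cbind(fx, fy), catch_trials = presses,
           fixation_target_intensity = fixation_target_intensity,
           duration_s = duration_s, session = session)
}
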