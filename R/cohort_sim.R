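#' Configuration for a synthetic scotopic microperimetry cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: group sizes,
#' grid, observer, between-subject distributions of the ground-truth field
#' parameters, fixation behavior, retest design and noise. Defaults emulate a
#' two-color scotopic study of choroideremia patients and healthy controls on
#' the 37-locus radial grid: healthy hill-of-vision peaks ~23 dB with a
#' shallow 0.5 dB/deg fall-off and a 4 dB cone-driven cyan residual at the
#' rod-free fovea; choroideremia residual central islands (lognormal
#' semi-axes, temporally offset) with rod (cyan) deficits exceeding cone
#' (red) deficits, non-seen outside the island; a 4% false-positive rate over
#' 10 blind-spot catch trials; an 8% structural rate of unreliable rod-free
#' mapping (spuriously high central cyan thresholds) which, combined with
#' single-press false positives at the solitary central locus, produces a
#' total failed-mapping rate near 15%; and 3.5 dB within-subject retest
#' drift.
#'
#' @param n_healthy,n_choroideremia Subjects per group.
#' @param n_retest_healthy,n_retest_choroideremia Number of subjects (the
#'   first of each group) who repeat both color exams as session `test2`.
#' @param grid An [build_grid()] object.
#' @param observer An [observer_model()].
#' @param retest_sd_within SD (dB) of the per-locus additive perturbation of
#'   the true thresholds at retest (biological/criterion drift; staircase
#'   measurement noise comes on top).
#' @param session_offset Systematic test2 - test1 offset in dB (learning /
#'   fatigue hook; default 0).
#' @param fixation_sigma,fixation_rho Bivariate-normal fixation jitter SDs
#'   (degrees) and correlation; per-subject SDs are scaled by a lognormal
#'   factor (`sdlog = 0.3`) to spread fixation quality across the cohort.
#' @param n_fixation_samples,n_catch_trials Per-exam sample counts.
#' @param rodfree_absent_rate Probability that a subject's central cyan
#'   responses are structurally high (12-24 dB), i.e. the rod-free zone fails
#'   to map -- the reliability failure mode the gate screens for. False
#'   positives during the central staircase add a further spurious-failure
#'   pathway on top of this rate.
#' @param healthy_field,chm_field Named lists of distribution parameters for
#'   the per-subject field draws (see defaults in the function signature).
#' @param mm_per_deg Emmetropic retinal scale used to convert island ellipse
#'   axes (deg) to the traced island area (mm^2); 1 deg = 0.288 mm.
#' @param seed Integer seed; cohorts are fully reproducible from it.
#' @return A list of class `sm_cohort_config`.
#' @export
cohort_config <- function(n_healthy = 21L, n_choroideremia = 20L,
                          n_retest_healthy = 0L,
                          n_retest_choroideremia = min(10L, n_choroideremia),
                          grid = build_grid(), observer = observer_model(),
                          retest_sd_within = 3.5, session_offset = 0,
                          fixation_sigma = c(0.25, 0.25), fixation_rho = 0,
                          n_fixation_samples = 500L, n_catch_trials = 10L,
                          rodfree_absent_rate = 0.08,
                          healthy_field = list(
                            peak_mean = 23, peak_sd = 1.2, color_jitter_sd = 0.6,
                            slope_mean = 0.5, slope_sd = 0.08,
                            residual_mean = 4, residual_sd = 1.5,
                            residual_max = 7, rod_free_radius = 0.5),
                          chm_field = list(
                            island_a_meanlog = log(4.5), island_b_meanlog = log(3.2),
                            island_sdlog = 0.40, offset_mean = 2.5,
                            offset_sd = 0.7, cyan_deficit_mean = 16,
                            cyan_deficit_sd = 3, red_deficit_mean = 7,
                            red_deficit_sd = 2.5),
                          mm_per_deg = 0.288, seed = 1L) {
  stopifnot(n_healthy >= 0, n_choroideremia >= 0, retest_sd_within >= 0,
            n_retest_healthy <= n_healthy,
            n_retest_choroideremia <= n_choroideremia,
            rodfree_absent_rate >= 0, rodfree_absent_rate <= 1)
  structure(as.list(environment()), class = "sm_cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

draw_field <- function(config) {
  hf <- config$healthy_field
  peak <- stats::rnorm(1, hf$peak_mean, hf$peak_sd)
  peak_cyan <- peak + stats::rnorm(1, 0, hf$color_jitter_sd)
  peak_red <- peak + stats::rnorm(1, 0, hf$color_jitter_sd)
  slope <- rtrunc_norm(1, hf$slope_mean, hf$slope_sd, lo = 0.05)
  residual <- rtrunc_norm(1, hf$residual_mean, hf$residual_sd,
                          lo = 0, hi = hf$residual_max)
  list(peak_cyan = peak_cyan, peak_red = peak_red, radial_slope = slope,
       central_cyan_residual = residual, rod_free_radius = hf$rod_free_radius)
}

draw_subject_field <- function(group, config) {
  base <- draw_field(config)
  rodfree_absent <- stats::runif(1) < config$rodfree_absent_rate
  if (group == "healthy") {
    if (rodfree_absent) base$central_cyan_residual <- stats::runif(1, 12, 24)
    return(do.call(sensitivity_field, c(list(profile = "healthy"), base)))
  }
  cf <- config$chm_field
  a <- stats::rlnorm(1, cf$island_a_meanlog, cf$island_sdlog)
  b <- stats::rlnorm(1, cf$island_b_meanlog, cf$island_sdlog)
  offset <- stats::rnorm(1, cf$offset_mean, cf$offset_sd)
  cyan_def <- rtrunc_norm(1, cf$cyan_deficit_mean, cf$cyan_deficit_sd, lo = 0)
  red_def <- rtrunc_norm(1, cf$red_deficit_mean, cf$red_deficit_sd, lo = 0)
  if (rodfree_absent) {
    # unreliable rod-free mapping: center maps 12-24 dB after the deficit
    base$central_cyan_residual <- stats::runif(1, 12, 24) + cyan_def
  }
  do.call(sensitivity_field,
          c(list(profile = "choroideremia", island_semi_axes = c(a, b),
                 island_center_offset = offset, cyan_deficit = cyan_def,
                 red_deficit = red_def), base))
}

#' Simulate a two-color scotopic cohort
#'
#' Draws a ground-truth [sensitivity_field()] per subject, measures cyan and
#' red exams through the [run_staircase()] observer, and for retest subjects
#' re-measures the same true field with independent staircase noise plus an
#' additive per-locus within-subject perturbation of SD
#' `retest_sd_within`. Choroideremia island areas are computed from the drawn
#' ellipse axes (`pi * a * b * mm_per_deg^2`). Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of [new_subject_record()] objects (healthy then
#'   choroideremia), each holding scotopic cyan and red exams for `test1` and,
#'   for retest subjects, `test2`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sm_cohort_config"))
  set.seed(config$seed)
  records <- list()
  groups <- list(
    list(name = "healthy", n = config$n_healthy,
         n_retest = config$n_retest_healthy, prefix = "H"),
    list(name = "choroideremia", n = config$n_choroideremia,
         n_retest = config$n_retest_choroideremia, prefix = "C"))
  for (grp in groups) {
    for (i in seq_len(grp$n)) {
      sid <- sprintf("%s%02d", grp$prefix, i)
      field <- draw_subject_field(grp$name, config)
      fix_scale <- stats::rlnorm(1, 0, 0.3)
      sigma <- config$fixation_sigma * fix_scale
      fti <- if (grp$name == "healthy") 5 else
        round(exp(stats::rnorm(1, log(35), 0.5)))
      exams <- list()
      sessions <- if (i <= grp$n_retest) c("test1", "test2") else "test1"
      for (session in sessions) {
        for (color in c("cyan_505nm", "red_627nm")) {
          # drift is drawn per color so cyan/red retest noise is separable
          offsets <- if (session == "test2") {
            config$session_offset +
              stats::rnorm(nrow(config$grid$loci), 0, config$retest_sd_within)
          } else NULL
          ex <- simulate_exam(
            field, config$grid, config$observer, subject_id = sid,
            eye = "OD", color = color, session = session,
            fixation_sigma = sigma, fixation_rho = config$fixation_rho,
            n_fixation_samples = config$n_fixation_samples,
            n_catch_trials = config$n_catch_trials,
            retest_offsets = offsets,
            fixation_target_intensity = fti,
            duration_s = round(stats::rnorm(1, 308, 45)))
          exams[[exam_key("scotopic", color, session)]] <- ex
        }
      }
      island <- if (grp$name == "choroideremia") {
        pi * prod(field$island_semi_axes) * config$mm_per_deg^2
      } else NA_real_
      rec <- new_subject_record(sid, grp$name, island_area_mm2 = island,
                                exams = exams)
      attr(rec, "true_field") <- field # generator ground truth, for tests
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}
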