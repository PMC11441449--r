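#' @keywords internal
"_PACKAGE"

# Export convention for loci where the brightest stimulus was not seen.
SENTINEL_NONSEEN <- -1.0
DB_RANGE <- c(0, 36)

#' Construct a microperimetry exam
#'
#' One stimulus-color threshold test on one eye: per-locus threshold
#' sensitivities in dB over a test grid, plus the fixation trace and blind-spot
#' catch-trial stream used for reliability assessment. Thresholds lie in
#' \[0, 36\] dB; loci where the brightest stimulus was not detected carry the
#' export sentinel `-1.0`.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param eye `"OD"` or `"OS"`.
#' @param condition `"scotopic"` or `"mesopic"`.
#' @param color Stimulus color: `"cyan_505nm"`, `"red_627nm"` or `"white"`.
#' @param grid An [build_grid()] object.
#' @param thresholds Numeric vector, one value per grid locus (grid order);
#'   each in \[0, 36\] or exactly `-1.0` (non-seen).
#' @param fixation_trace Two-column matrix or data frame of (x, y) fixation
#'   samples in degrees.
#' @param catch_trials Logical vector: `TRUE` where a blind-spot suprathreshold
#'   presentation was responded to (a fixation loss / false positive).
#' @param fixation_target_intensity Fixation-target brightness (device log
#'   units); metadata.
#' @param duration_s Test duration in seconds; metadata.
#' @param session `"test1"` or `"test2"` (repeat testing).
#' @return An object of class `sm_exam`.
#' @export
new_exam <- function(subject_id, eye = c("OD", "OS"),
                     condition = c("scotopic", "mesopic"),
                     color = c("cyan_505nm", "red_627nm", "white"),
                     grid, thresholds, fixation_trace,
                     catch_trials = logical(),
                     fixation_target_intensity = NA_real_,
                     duration_s = NA_real_,
                     session = c("test1", "test2")) {
  eye <- match.arg(eye)
  condition <- match.arg(condition)
  color <- match.arg(color)
  session <- match.arg(session)
  stopifnot(inherits(grid, "sm_grid"), is.character(subject_id),
            length(subject_id) == 1L)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != nrow(grid$loci)) {
    stop(sprintf("exam has %d thresholds but grid has %d loci",
                 length(thresholds), nrow(grid$loci)), call. = FALSE)
  }
  bad <- which(!(thresholds == SENTINEL_NONSEEN |
                   (thresholds >= DB_RANGE[1] & thresholds <= DB_RANGE[2])))
  if (length(bad)) {
    stop(sprintf("threshold out of range {-1} U [0,36] at locus index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fixation_trace <- as.matrix(fixation_trace)
  if (ncol(fixation_trace) != 2L) {
    stop("fixation_trace must have two columns (x, y)", call. = FALSE)
  }
  colnames(fixation_trace) <- c("x", "y")
  structure(list(subject_id = subject_id, eye = eye, condition = condition,
                 color = color, grid = grid, thresholds = thresholds,
                 fixation_trace = fixation_trace,
                 catch_trials = as.logical(catch_trials),
                 fixation_target_intensity = fixation_target_intensity,
                 duration_s = duration_s, session = session,
                 eye_normalized = FALSE),
            class = "sm_exam")
}

#' @export
print.sm_exam <- function(x, ...) {
  cat(sprintf(
    "<sm_exam> %s %s %s %s %s: %d loci (%d non-seen), %d fixation samples\n",
    x$subject_id, x$eye, x$condition, x$color, x$session,
    length(x$thresholds), n_nonseen(x), nrow(x$fixation_trace)))
  invisible(x)
}

#' Number of non-seen loci in an exam
#'
#' Counts loci carrying the `-1.0` dB non-seen sentinel.
#' @param exam An [new_exam()] object.
#' @return Integer count.
#' @export
n_nonseen <- function(exam) {
  stopifnot(inherits(exam, "sm_exam"))
  sum(exam$thresholds == SENTINEL_NONSEEN)
}

#' Mirror a left-eye exam into right-eye convention
#'
#' Hemifield analyses (temporal vs nasal) require a common retinal coordinate
#' convention. In right-eye (OD) convention +x is temporal retina; for a
#' left-eye (OS) exam the temporal retina is at -x, so OS exams are mirrored
#' `x -> -x` (grid loci and fixation trace) and flagged as eye-normalized. OD
#' exams are returned unchanged. Applying the function twice mirrors exactly
#' once: an already normalized exam is returned as-is.
#'
#' @param exam An [new_exam()] object.
#' @return The exam in OD convention with `eye_normalized = TRUE` for OS input.
#' @export
normalize_eye <- function(exam) {
  stopifnot(inherits(exam, "sm_exam"))
  if (exam$eye == "OD" || isTRUE(exam$eye_normalized)) {
    exam$eye_normalized <- TRUE
    return(exam)
  }
  exam$grid$loci$x <- -exam$grid$loci$x
  exam$fixation_trace[, "x"] <- -exam$fixation_trace[, "x"]
  exam$eye_normalized <- TRUE
  exam
}
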