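#' Fixation loss rate
#'
#' Percentage of blind-spot catch trials responded to. Responses to
#' suprathreshold stimuli presented inside the physiological blind spot are
#' false positives ("fixation losses").
#'
#' @param catch_trials Logical vector, `TRUE` = pressed.
#' @return Percentage in \[0, 100\].
#' @export
fixation_loss_rate <- function(catch_trials) {
  catch_trials <- as.logical(catch_trials)
  if (length(catch_trials) == 0L) {
    stop("fixation loss rate undefined with zero catch trials", call. = FALSE)
  }
  100 * mean(catch_trials)
}

#' P1/P2 fixation concentration
#'
#' Percentage of fixation samples within 1 and 2 degrees of the preferred
#' retinal locus (PRL). The PRL is estimated as the coordinate-wise median of
#' the trace (robust to saccade outliers); `center = "mean"` is available as
#' an alternative since device estimators differ.
#'
#' @param fixation_trace Two-column (x, y) matrix in degrees.
#' @param radii Radii in degrees for the two concentration percentages.
#' @param center PRL estimator: `"median"` (default) or `"mean"`.
#' @return Named numeric vector `c(P1 = , P2 = )` in percent.
#' @export
p1_p2 <- function(fixation_trace, radii = c(1, 2),
                  center = c("median", "mean")) {
  center <- match.arg(center)
  tr <- as.matrix(fixation_trace)
  if (nrow(tr) == 0L) stop("empty fixation trace", call. = FALSE)
  prl <- apply(tr, 2, center)
  r <- sqrt((tr[, 1] - prl[1])^2 + (tr[, 2] - prl[2])^2)
  stats::setNames(100 * c(mean(r <= radii[1]), mean(r <= radii[2])),
                  c("P1", "P2"))
}

#' Fujii fixation stability classification
#'
#' `stable` if P1 > 75% of fixation samples fall within 1 degree of the PRL;
#' `relatively_unstable` if P1 <= 75% but P2 > 75%; `unstable` if P2 <= 75%.
#'
#' @param P1,P2 Percentages from [p1_p2()].
#' @return `"stable"`, `"relatively_unstable"` or `"unstable"`.
#' @export
classify_fujii <- function(P1, P2) {
  stopifnot(P1 >= 0, P2 >= 0, P1 <= 100, P2 <= 100, P1 <= P2)
  if (P1 > 75) "stable" else if (P2 > 75) "relatively_unstable" else "unstable"
}

#' Bivariate contour ellipse area (BCEA)
#'
#' Area of the ellipse containing a given proportion of fixation samples
#' under a bivariate-normal model:
#' `BCEA(P) = 2 * k * pi * sx * sy * sqrt(1 - rho^2)` with `k = -log(1 - P)`,
#' where `sx`, `sy`, `rho` are the sample SDs and correlation of the trace.
#' The conventional "63%" output uses the exact `P = 1 - exp(-1) = 0.632`
#' (`k = 1`); 95% gives `k = 2.996`.
#'
#' @param fixation_trace Two-column (x, y) matrix in degrees.
#' @param coverage Ellipse coverage proportion in (0, 1); `0.632` or `0.95`
#'   for the standard outputs.
#' @return Area in deg^2.
#' @export
bcea <- function(fixation_trace, coverage = 1 - exp(-1)) {
  stopifnot(coverage > 0, coverage < 1)
  tr <- as.matrix(fixation_trace)
  if (nrow(tr) < 3L) {
    stop("BCEA requires at least 3 fixation samples", call. = FALSE)
  }
  sx <- stats::sd(tr[, 1]); sy <- stats::sd(tr[, 2])
  if (sx == 0 || sy == 0) return(0)
  rho <- stats::cor(tr[, 1], tr[, 2])
  k <- -log(1 - coverage)
  2 * k * pi * sx * sy * sqrt(max(0, 1 - rho^2))
}

#' Detect the rod-free zone in a scotopic cyan exam
#'
#' The fovea physiologically lacks rods, so under dark-adapted cyan testing
#' the central locus should show a scotoma: 0.0 dB, very low, or non-seen.
#' A high central cyan threshold indicates the rod-free zone failed to map
#' and the test is likely unreliable. Detection: central-locus threshold
#' `<= cutoff` (the non-seen sentinel counts as detected).
#'
#' @param exam A scotopic cyan [new_exam()] with a locus at (0, 0).
#' @param cutoff Detection cutoff in dB (default 8.0).
#' @return `TRUE` if the rod-free zone was mapped.
#' @export
detect_rod_free_zone <- function(exam, cutoff = 8) {
  stopifnot(inherits(exam, "sm_exam"))
  if (exam$condition != "scotopic" || exam$color != "cyan_505nm") {
    stop("rod-free zone detection applies to scotopic cyan exams",
         call. = FALSE)
  }
  ic <- which(exam$grid$loci$x == 0 & exam$grid$loci$y == 0)
  if (length(ic) != 1L) {
    stop("grid has no central (0, 0) locus; rod-free detection not applicable",
         call. = FALSE)
  }
  central <- exam$thresholds[ic]
  central == SENTINEL_NONSEEN || central <= cutoff
}

#' Reliability gate for one exam
#'
#' Applies the study exclusion rules: fixation losses at or above the cutoff
#' (default 30%), and -- for scotopic cyan exams -- failure to detect the
#' central rod-free zone (central cyan above `rodfree_cutoff`, default
#' 8.0 dB). All failing reasons are reported, not just the first.
#'
#' @param exam An [new_exam()] object.
#' @param fl_cutoff Fixation-loss exclusion cutoff in percent; the gate fails
#'   when the rate is `>= fl_cutoff`.
#' @param rodfree_cutoff Central cyan detection cutoff in dB.
#' @return An object of class `sm_reliability`: list with
#'   `fixation_loss_pct`, `P1`, `P2`, `BCEA63`, `BCEA95`, `fujii_class`,
#'   `rod_free_detected` (`NA` unless scotopic cyan), `passed`, and `reasons`
#'   (character vector among `"high_fixation_losses"`, `"rod_free_absent"`;
#'   empty iff `passed`).
#' @export
gate_exam <- function(exam, fl_cutoff = 30, rodfree_cutoff = 8) {
  stopifnot(inherits(exam, "sm_exam"))
  fl <- fixation_loss_rate(exam$catch_trials)
  pp <- p1_p2(exam$fixation_trace)
  b63 <- bcea(exam$fixation_trace, 1 - exp(-1))
  b95 <- bcea(exam$fixation_trace, 0.95)
  reasons <- character(0)
  if (fl >= fl_cutoff) reasons <- c(reasons, "high_fixation_losses")
  rodfree <- NA
  if (exam$condition == "scotopic" && exam$color == "cyan_505nm") {
    rodfree <- detect_rod_free_zone(exam, cutoff = rodfree_cutoff)
    if (!rodfree) reasons <- c(reasons, "rod_free_absent")
  }
  structure(list(subject_id = exam$subject_id, color = exam$color,
                 session = exam$session, fixation_loss_pct = fl,
                 P1 = unname(pp["P1"]), P2 = unname(pp["P2"]),
                 BCEA63 = b63, BCEA95 = b95,
                 fujii_class = classify_fujii(pp["P1"], pp["P2"]),
                 rod_free_detected = rodfree,
                 passed = length(reasons) == 0L, reasons = reasons),
            class = "sm_reliability")
}

#' @export
print.sm_reliability <- function(x, ...) {
  cat(sprintf(
    "<sm_reliability> %s %s %s: FL %.1f%%, P1 %.0f%%, P2 %.0f%%, BCEA63 %.2f, %s -> %s\n",
    x$subject_id, x$color, x$session, x$fixation_loss_pct, x$P1, x$P2,
    x$BCEA63, x$fujii_class,
    if (x$passed) "PASS" else paste("FAIL:", paste(x$reasons, collapse = ","))))
  invisible(x)
}
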