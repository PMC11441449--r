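# Sentinel-aware value extraction: -1.0 (non-seen) maps to 0.0 dB for the
# global indices (consistent with patients whose mean sensitivity reads
# 0.0 dB while pointwise exports carry -1.0); raw pointwise values keep it.
index_values <- function(thresholds) {
  ifelse(thresholds == SENTINEL_NONSEEN, 0, thresholds)
}

#' Mean sensitivity
#'
#' Arithmetic mean of the pointwise thresholds, with the non-seen sentinel
#' `-1.0` mapped to 0.0 dB. On a radial grid this is a spatially weighted
#' average (the denser center contributes more per unit area); see
#' [volume_sensitivity()] for the spatially unbiased index.
#'
#' @param exam An [new_exam()] object.
#' @param central_excluded Drop the (0, 0) locus? The central locus lies in
#'   the rod-free zone and biases global cyan-red comparisons towards
#'   apparent rod dysfunction.
#' @param nonseen Sentinel policy: `"zero"` (default, map to 0 dB) or
#'   `"exclude"` (drop those loci).
#' @return Mean sensitivity in dB.
#' @export
mean_sensitivity <- function(exam, central_excluded = FALSE,
                             nonseen = c("zero", "exclude")) {
  stopifnot(inherits(exam, "sm_exam"))
  nonseen <- match.arg(nonseen)
  keep <- rep(TRUE, length(exam$thresholds))
  if (central_excluded) {
    keep <- keep & !(exam$grid$loci$x == 0 & exam$grid$loci$y == 0)
  }
  if (nonseen == "exclude") keep <- keep & exam$thresholds != SENTINEL_NONSEEN
  v <- index_values(exam$thresholds[keep])
  if (length(v) == 0L) stop("no loci left to average", call. = FALSE)
  mean(v)
}

# Delaunay triangulation of grid loci via deldir; returns a data frame of
# vertex indices (i1, i2, i3) into the loci table.
grid_triangulation <- function(grid) {
  loci <- grid$loci
  d <- deldir::deldir(loci$x, loci$y, suppressMsge = TRUE)
  tl <- deldir::triang.list(d)
  tri <- do.call(rbind, lapply(tl, function(t) t$ptNum))
  colnames(tri) <- c("i1", "i2", "i3")
  as.data.frame(tri)
}

triangle_areas <- function(loci, tri) {
  x1 <- loci$x[tri$i1]; y1 <- loci$y[tri$i1]
  x2 <- loci$x[tri$i2]; y2 <- loci$y[tri$i2]
  x3 <- loci$x[tri$i3]; y3 <- loci$y[tri$i3]
  abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Volume sensitivity (hill of vision)
#'
#' Integral of the sensitivity surface over the grid footprint, in dB*deg^2:
#' the piecewise-linear interpolant over the Delaunay triangulation of the
#' loci is integrated exactly over the convex hull (each triangle contributes
#' its area times the mean of its vertex values; this rule is exact for
#' linear functions). Non-seen loci enter as 0.0 dB. Unlike mean sensitivity
#' the result is a true spatial product of sensitivity and area, immune to
#' sampling-density weighting and to averaging floor effects.
#'
#' @param exam An [new_exam()] object with >= 3 non-collinear loci.
#' @return Volume in dB*deg^2 (between 0 and 36 times the hull area).
#' @export
volume_sensitivity <- function(exam) {
  stopifnot(inherits(exam, "sm_exam"))
  loci <- exam$grid$loci
  if (nrow(loci) < 3L) stop("volume needs >= 3 loci", call. = FALSE)
  tri <- grid_triangulation(exam$grid)
  if (nrow(tri) == 0L) stop("degenerate grid geometry", call. = FALSE)
  v <- index_values(exam$thresholds)
  areas <- triangle_areas(loci, tri)
  sum(areas * (v[tri$i1] + v[tri$i2] + v[tri$i3]) / 3)
}

#' Temporal and nasal hemifield mean sensitivities
#'
#' Means (non-seen as 0 dB) over loci with x > 0 (temporal retina, OD
#' convention) and x < 0 (nasal); loci on the vertical midline (x = 0) are
#' excluded from both. The exam must be eye-normalized so that +x is
#' temporal (see [normalize_eye()]).
#'
#' @param exam An eye-normalized [new_exam()] object.
#' @return Named vector `c(temporal_mean = , nasal_mean = )` in dB.
#' @export
hemifield_means <- function(exam) {
  stopifnot(inherits(exam, "sm_exam"))
  if (!isTRUE(exam$eye_normalized) && exam$eye == "OS") {
    stop("normalize_eye() the exam before hemifield analysis", call. = FALSE)
  }
  v <- index_values(exam$thresholds)
  x <- exam$grid$loci$x
  c(temporal_mean = mean(v[x > 0]), nasal_mean = mean(v[x < 0]))
}

#' Combined sensitivity indices for one exam
#'
#' @param exam An [new_exam()] object.
#' @param central_excluded Exclude the central locus from the mean (the
#'   volume always integrates the full surface).
#' @return An `sm_indices` list: `pointwise` (sentinel preserved),
#'   `mean_sensitivity`, `volume_sensitivity`, `temporal_mean`, `nasal_mean`,
#'   `central_excluded`.
#' @export
sensitivity_indices <- function(exam, central_excluded = FALSE) {
  hm <- hemifield_means(exam)
  structure(list(subject_id = exam$subject_id, color = exam$color,
                 session = exam$session,
                 pointwise = exam$thresholds,
                 mean_sensitivity = mean_sensitivity(exam, central_excluded),
                 volume_sensitivity = volume_sensitivity(exam),
                 temporal_mean = unname(hm["temporal_mean"]),
                 nasal_mean = unname(hm["nasal_mean"]),
                 central_excluded = central_excluded),
            class = "sm_indices")
}

#' Pointwise cyan-red difference map
#'
#' Per-locus `cyan - red` threshold differences for a matched pair of exams
#' (same grid, subject and session). Negative differences outside the
#' rod-free fovea indicate rod dysfunction relative to cone function;
#' positive differences indicate relative cone dysfunction. The difference is
#' undefined (`NA`) where either input is non-seen, unless
#' `both_nonseen_zero = TRUE` (default) in which case loci non-seen in both
#' colors get difference 0 (equally impaired; they classify as
#' `equal_reduced`).
#'
#' @param cyan_exam,red_exam Matched [new_exam()] objects.
#' @param both_nonseen_zero Treat loci non-seen in both colors as difference
#'   0 rather than undefined.
#' @return An `sm_diffmap` data frame with columns `locus_id`, `x`, `y`,
#'   `cyan`, `red`, `diff`, plus attribute `both_nonseen` marking the loci
#'   affected by the policy.
#' @export
pointwise_difference <- function(cyan_exam, red_exam,
                                 both_nonseen_zero = TRUE) {
  stopifnot(inherits(cyan_exam, "sm_exam"), inherits(red_exam, "sm_exam"))
  if (!isTRUE(all.equal(cyan_exam$grid$loci[, c("x", "y")],
                        red_exam$grid$loci[, c("x", "y")]))) {
    stop("cyan and red exams are on different grids", call. = FALSE)
  }
  cy <- cyan_exam$thresholds; rd <- red_exam$thresholds
  cy_ns <- cy == SENTINEL_NONSEEN; rd_ns <- rd == SENTINEL_NONSEEN
  d <- cy - rd
  d[cy_ns | rd_ns] <- NA_real_
  both <- cy_ns & rd_ns
  if (both_nonseen_zero) d[both] <- 0
  out <- data.frame(locus_id = cyan_exam$grid$loci$id,
                    x = cyan_exam$grid$loci$x, y = cyan_exam$grid$loci$y,
                    cyan = cy, red = rd, diff = d)
  attr(out, "both_nonseen") <- both
  class(out) <- c("sm_diffmap", "data.frame")
  out
}

#' Classify a cyan-red difference map
#'
#' Assigns each locus with a defined difference to one of four classes, given
#' a symmetric variability threshold: `|diff| <= threshold` is an "equal"
#' class -- `equal_normal` (gray) when both thresholds are within normative
#' bounds, `equal_reduced` (black) otherwise; `diff < -threshold` is
#' `rod_dysfunction` (red); `diff > threshold` is `cone_dysfunction` (blue).
#' Thresholds of 0, 4 and 13 dB correspond to no test-retest allowance, the
#' device's arbitrary cutoff, and the combined cyan-red pointwise
#' test-retest variability, respectively.
#'
#' @param diffmap An [pointwise_difference()] result.
#' @param threshold Non-negative dB limit.
#' @param normative Per-locus lower normative bounds in dB (e.g. healthy
#'   mean - 2 SD from [normative_pointwise()]); a threshold below its bound
#'   is "reduced". `NULL` treats every seen locus as normal.
#' @return The diff map with an added `class` factor column.
#' @export
classify_difference <- function(diffmap, threshold = 4, normative = NULL) {
  stopifnot(inherits(diffmap, "sm_diffmap"), threshold >= 0)
  lower <- if (is.null(normative)) rep(-Inf, nrow(diffmap)) else normative
  stopifnot(length(lower) == nrow(diffmap))
  reduced <- index_values(diffmap$cyan) < lower |
    index_values(diffmap$red) < lower
  reduced[attr(diffmap, "both_nonseen")] <- TRUE
  cls <- rep(NA_character_, nrow(diffmap))
  defined <- !is.na(diffmap$diff)
  cls[defined & diffmap$diff < -threshold] <- "rod_dysfunction"
  cls[defined & diffmap$diff > threshold] <- "cone_dysfunction"
  eq <- defined & abs(diffmap$diff) <= threshold
  cls[eq & !reduced] <- "equal_normal"
  cls[eq & reduced] <- "equal_reduced"
  diffmap$class <- factor(cls, levels = c("equal_normal", "equal_reduced",
                                          "rod_dysfunction",
                                          "cone_dysfunction"))
  attr(diffmap, "threshold_used") <- threshold
  diffmap
}

#' Normative per-locus lower bounds from a healthy reference
#'
#' Per-locus `mean - 2 * SD` of healthy thresholds (non-seen as 0 dB),
#' defining "reduced" for the equal-difference classes of
#' [classify_difference()].
#'
#' @param exams List of healthy [new_exam()] objects on a common grid.
#' @return Numeric vector of lower bounds, one per locus.
#' @export
normative_pointwise <- function(exams) {
  stopifnot(length(exams) >= 2L)
  m <- vapply(exams, function(e) index_values(e$thresholds),
              numeric(length(exams[[1]]$thresholds)))
  apply(m, 1, mean) - 2 * apply(m, 1, stats::sd)
}

#' Summary cyan-red difference indices
#'
#' Differences of the global indices (cyan minus red) for a matched pair of
#' exams: mean sensitivity difference in dB and volume difference in
#' dB*deg^2.
#'
#' @param cyan_exam,red_exam Matched [new_exam()] objects.
#' @param central_excluded Exclude the rod-free central locus from the mean
#'   difference (recommended: including it biases the summary towards cyan
#'   dysfunction).
#' @return Named vector `c(mean_diff_db = , volume_diff = )`.
#' @export
summary_difference_indices <- function(cyan_exam, red_exam,
                                       central_excluded = TRUE) {
  c(mean_diff_db = mean_sensitivity(cyan_exam, central_excluded) -
      mean_sensitivity(red_exam, central_excluded),
    volume_diff = volume_sensitivity(cyan_exam) -
      volume_sensitivity(red_exam))
}
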