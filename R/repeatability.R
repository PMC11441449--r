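#' Paired test-retest measurements
#'
#' Validates a long table of paired measurements: one row per measurement
#' unit (a locus, or a whole-exam index) with its test1 and test2 values in
#' homogeneous units.
#'
#' @param subject_id,unit_id Identifiers (recycled to common length).
#' @param value_test1,value_test2 Numeric values, no missing entries.
#' @return A `data.frame` of class `sm_pairs`.
#' @export
paired_measurements <- function(subject_id, unit_id, value_test1,
                                value_test2) {
  d <- data.frame(subject_id = as.character(subject_id),
                  unit_id = as.character(unit_id),
                  value_test1 = as.numeric(value_test1),
                  value_test2 = as.numeric(value_test2))
  if (anyNA(d)) stop("paired measurements must be complete", call. = FALSE)
  class(d) <- c("sm_pairs", "data.frame")
  d
}

# One-way random-intercept variance components of the differences,
# d_ij = mu + u_i + e_ij. engine "reml" fits lme4::lmer (REML); "anova" is
# the closed-form moment estimator (Searle's unbalanced one-way ANOVA),
# identical to REML for balanced data and used for fast bootstrap refits.
fit_difference_model <- function(d, subject, engine = c("reml", "anova")) {
  engine <- match.arg(engine)
  if (stats::var(d) == 0) {
    return(list(mu = mean(d), sd_within = 0, sd_between = 0))
  }
  if (engine == "reml") {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(d ~ 1 + (1 | subject),
                 data = data.frame(d = d, subject = subject),
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(mu = unname(lme4::fixef(fit)[1]),
         sd_within = vc$sdcor[vc$grp == "Residual"],
         sd_between = vc$sdcor[vc$grp == "subject"])
  } else {
    subject <- as.character(subject)
    ni <- table(subject)
    k <- length(ni); N <- length(d)
    mi <- tapply(d, subject, mean)
    ssw <- sum((d - mi[subject])^2)
    ssb <- sum(ni * (mi - mean(d))^2)
    msw <- ssw / (N - k)
    if (k < 2L) return(list(mu = mean(d), sd_within = sqrt(msw),
                            sd_between = 0))
    msb <- ssb / (k - 1)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    vb <- max(0, (msb - msw) / n0)
    vw <- if (vb == 0) (ssw + ssb) / (N - 1) else msw
    list(mu = mean(mi), sd_within = sqrt(vw), sd_between = sqrt(vb))
  }
}

make_result <- function(bias, sd_within, sd_between, n_subjects, n_pairs,
                        cor_formula) {
  cor_mult <- if (cor_formula == "2x1.96") 2 * 1.96 else 1.96 * sqrt(2)
  sd_total <- sqrt(sd_between^2 + sd_within^2)
  structure(list(bias = bias, sd_within = sd_within, sd_between = sd_between,
                 cor = cor_mult * sd_within,
                 loa_low = bias - 1.96 * sd_total,
                 loa_high = bias + 1.96 * sd_total,
                 n_subjects = n_subjects, n_pairs = n_pairs,
                 cor_formula = cor_formula,
                 boot_ci = NULL, cor_pooled = NA_real_),
            class = "sm_repeatability")
}

#' Repeated-measures Bland-Altman analysis
#'
#' Test-retest agreement when each subject contributes many paired units
#' (e.g. 37 loci). Differences `d = test2 - test1` are modelled with a
#' linear mixed-effects model `d_ij = mu + u_i + e_ij` (subject random
#' intercepts, REML), separating the between-subject SD of `u` from the
#' within-subject SD of `e`. The coefficient of repeatability uses the
#' within-subject SD only (`CoR = 2 * 1.96 * SD_within` by default), while
#' the limits of agreement use the total SD
#' `sqrt(SD_between^2 + SD_within^2)`. Using the overall pooled SD instead of
#' the model's within-subject SD inflates the CoR whenever subjects differ
#' systematically (`cor_pooled` reports that naive value for comparison).
#' Confidence intervals come from a cluster bootstrap: subjects are resampled
#' with replacement and the model refitted (percentile intervals).
#'
#' @param data An [paired_measurements()] table (>= 2 subjects).
#' @param n_boot Bootstrap resamples (0 to skip CIs).
#' @param seed Integer seed for the bootstrap.
#' @param engine Variance-component estimator: `"reml"` (lme4) or `"anova"`
#'   (closed-form moment estimator, REML-equivalent for balanced data).
#' @param boot_engine Estimator used inside the bootstrap (default
#'   `"anova"` for speed).
#' @param cor_formula `"2x1.96"` (CoR = 3.92 * SD_within, the reporting
#'   convention implemented here) or `"1.96xsqrt2"`.
#' @param conf Confidence level for the bootstrap intervals.
#' @return An `sm_repeatability` object: `bias`, `sd_within`, `sd_between`,
#'   `cor`, `loa_low`/`loa_high`, `cor_pooled`, sample sizes, and `boot_ci`
#'   (rows `bias`, `loa_low`, `loa_high`, `cor`).
#' @export
rm_bland_altman <- function(data, n_boot = 1000L, seed = 1L,
                            engine = c("reml", "anova"),
                            boot_engine = "anova",
                            cor_formula = c("2x1.96", "1.96xsqrt2"),
                            conf = 0.95) {
  stopifnot(inherits(data, "sm_pairs"))
  engine <- match.arg(engine)
  cor_formula <- match.arg(cor_formula)
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2L) {
    stop("repeated-measures Bland-Altman needs >= 2 subjects", call. = FALSE)
  }
  d <- data$value_test2 - data$value_test1
  fit <- fit_difference_model(d, data$subject_id, engine)
  res <- make_result(fit$mu, fit$sd_within, fit$sd_between,
                     length(subjects), nrow(data), cor_formula)
  res$cor_pooled <- (if (cor_formula == "2x1.96") 2 * 1.96 else 1.96 * sqrt(2)) *
    stats::sd(d)
  if (n_boot > 0L) {
    set.seed(seed)
    idx_by_subject <- split(seq_len(nrow(data)), data$subject_id)
    stats_mat <- matrix(NA_real_, n_boot, 4,
                        dimnames = list(NULL, c("bias", "loa_low", "loa_high",
                                                "cor")))
    cor_mult <- if (cor_formula == "2x1.96") 2 * 1.96 else 1.96 * sqrt(2)
    for (b in seq_len(n_boot)) {
      pick <- sample(names(idx_by_subject), length(idx_by_subject),
                     replace = TRUE)
      rows <- unlist(idx_by_subject[pick], use.names = FALSE)
      subj <- rep(seq_along(pick), lengths(idx_by_subject[pick]))
      f <- fit_difference_model(d[rows], subj, boot_engine)
      st <- sqrt(f$sd_between^2 + f$sd_within^2)
      stats_mat[b, ] <- c(f$mu, f$mu - 1.96 * st, f$mu + 1.96 * st,
                          cor_mult * f$sd_within)
    }
    a <- (1 - conf) / 2
    res$boot_ci <- t(apply(stats_mat, 2, stats::quantile,
                           probs = c(a, 1 - a), names = FALSE))
    colnames(res$boot_ci) <- c("lower", "upper")
  }
  res
}

#' @export
print.sm_repeatability <- function(x, ...) {
  cat(sprintf(
    paste0("<sm_repeatability> bias %.3f, SD_within %.3f, SD_between %.3f,",
           " CoR +/-%.3f, LoA [%.3f, %.3f] (%d subjects, %d pairs)\n"),
    x$bias, x$sd_within, x$sd_between, x$cor, x$loa_low, x$loa_high,
    x$n_subjects, x$n_pairs))
  if (!is.null(x$boot_ci)) {
    cat(sprintf("  bootstrap %s CI for bias: [%.3f, %.3f]\n", "95%",
                x$boot_ci["bias", "lower"], x$boot_ci["bias", "upper"]))
  }
  invisible(x)
}

#' Standard Bland-Altman analysis (one pair per subject)
#'
#' For whole-exam indices (mean or volume sensitivity) each subject
#' contributes a single difference `d = test2 - test1`. Bias is the mean
#' difference and the limits of agreement are `bias +/- 1.96 * SD(d)`. The
#' within-subject SD is `SD(d) / sqrt(2)` (each difference carries the
#' measurement error of two tests), and the CoR applies the same
#' `2 * 1.96 * SD_within` convention as [rm_bland_altman()].
#'
#' @param pairs An [paired_measurements()] table with one row per subject.
#' @inheritParams rm_bland_altman
#' @return An `sm_repeatability` object (no between-subject component).
#' @export
standard_bland_altman <- function(pairs,
                                  cor_formula = c("2x1.96", "1.96xsqrt2")) {
  stopifnot(inherits(pairs, "sm_pairs"))
  cor_formula <- match.arg(cor_formula)
  if (anyDuplicated(pairs$subject_id)) {
    stop("standard Bland-Altman expects one pair per subject", call. = FALSE)
  }
  if (nrow(pairs) < 2L) stop("need >= 2 subjects", call. = FALSE)
  d <- pairs$value_test2 - pairs$value_test1
  sd_d <- stats::sd(d)
  res <- make_result(mean(d), sd_d / sqrt(2), 0, nrow(pairs), nrow(pairs),
                     cor_formula)
  # LoA for a single-pair design use SD(d) directly
  res$loa_low <- mean(d) - 1.96 * sd_d
  res$loa_high <- mean(d) + 1.96 * sd_d
  res
}

#' Combined cyan-red pointwise repeatability
#'
#' Repeatability of the cyan-red difference index: per locus and session the
#' cyan-red difference is formed, loci non-seen (below 0 dB) at either
#' session in either color are excluded, and the session-wise differences of
#' the index are analysed with [rm_bland_altman()].
#'
#' @param cyan_pairs,red_pairs [paired_measurements()] tables on matched
#'   (subject, unit) keys; values in dB with `-1.0` marking non-seen loci.
#' @param exclusion `"nonseen_any"` (default: drop loci with a value below
#'   0 dB in any of the four measurements) or `"zero_any"` (also drop loci at
#'   exactly 0.0 dB, the variant sometimes used in reporting).
#' @param ... Passed to [rm_bland_altman()].
#' @return An `sm_repeatability` object for the cyan-red index.
#' @export
cyan_red_combined_cor <- function(cyan_pairs, red_pairs,
                                  exclusion = c("nonseen_any", "zero_any"),
                                  ...) {
  stopifnot(inherits(cyan_pairs, "sm_pairs"), inherits(red_pairs, "sm_pairs"))
  exclusion <- match.arg(exclusion)
  key_c <- paste(cyan_pairs$subject_id, cyan_pairs$unit_id)
  key_r <- paste(red_pairs$subject_id, red_pairs$unit_id)
  m <- match(key_c, key_r)
  if (anyNA(m)) stop("cyan and red pairs do not share (subject, unit) keys",
                     call. = FALSE)
  red_pairs <- red_pairs[m, ]
  vals <- cbind(cyan_pairs$value_test1, cyan_pairs$value_test2,
                red_pairs$value_test1, red_pairs$value_test2)
  drop <- if (exclusion == "nonseen_any") {
    apply(vals < 0, 1, any)
  } else {
    apply(vals <= 0, 1, any)
  }
  if (all(drop)) stop("no loci left after the non-seen exclusion rule",
                      call. = FALSE)
  keep <- !drop
  idx <- paired_measurements(
    cyan_pairs$subject_id[keep], cyan_pairs$unit_id[keep],
    cyan_pairs$value_test1[keep] - red_pairs$value_test1[keep],
    cyan_pairs$value_test2[keep] - red_pairs$value_test2[keep])
  rm_bland_altman(idx, ...)
}

#' Pointwise test-retest agreement rates
#'
#' Percentage of loci measuring exactly the same at test1 and test2 (the
#' non-seen sentinel compares equal to itself) and within +/- 2.0 dB.
#'
#' @param pairs An [paired_measurements()] table of pointwise values.
#' @return Named vector `c(exact_pct = , within_2db_pct = )`.
#' @export
agreement_rates <- function(pairs) {
  stopifnot(inherits(pairs, "sm_pairs"))
  d <- pairs$value_test2 - pairs$value_test1
  c(exact_pct = 100 * mean(d == 0),
    within_2db_pct = 100 * mean(abs(d) <= 2))
}
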