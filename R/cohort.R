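med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

all_exams <- function(records) {
  out <- list()
  for (rec in records) {
    for (ex in rec$exams) {
      out[[length(out) + 1L]] <- list(record = rec, exam = ex)
    }
  }
  out
}

#' Reliability and cohort summary statistics
#'
#' Reproduces the standard reliability summary rows per (group, color,
#' session) stratum of scotopic exams: counts and percentages of tests with
#' zero, intermediate (0-30%) and high (>= 30%) fixation losses; median (IQR)
#' of the 63%/95% BCEA, P1 and P2; counts of stable Fujii fixation; rod-free
#' zone detection counts (cyan only); and median (IQR) fixation target
#' intensity and test duration.
#'
#' @param records List of [new_subject_record()] objects.
#' @param fl_cutoff,rodfree_cutoff Gate cutoffs passed to [gate_exam()].
#' @return A data frame with one row per (group, color, session) stratum.
#' @export
summarize_cohort <- function(records, fl_cutoff = 30, rodfree_cutoff = 8) {
  pairs <- all_exams(records)
  pairs <- Filter(function(p) p$exam$condition == "scotopic", pairs)
  if (length(pairs) == 0L) stop("empty cohort", call. = FALSE)
  df <- do.call(rbind, lapply(pairs, function(p) {
    rep <- gate_exam(p$exam, fl_cutoff, rodfree_cutoff)
    data.frame(group = p$record$group, color = p$exam$color,
               session = p$exam$session, fl = rep$fixation_loss_pct,
               P1 = rep$P1, P2 = rep$P2, BCEA63 = rep$BCEA63,
               BCEA95 = rep$BCEA95, stable = rep$fujii_class == "stable",
               rodfree = rep$rod_free_detected, passed = rep$passed,
               fti = p$exam$fixation_target_intensity,
               duration_s = p$exam$duration_s)
  }))
  strata <- unique(df[, c("group", "color", "session")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- df[df$group == strata$group[i] & df$color == strata$color[i] &
              df$session == strata$session[i], ]
    n <- nrow(s)
    b63 <- med_iqr(s$BCEA63); b95 <- med_iqr(s$BCEA95)
    p1 <- med_iqr(s$P1); p2 <- med_iqr(s$P2)
    data.frame(
      group = strata$group[i], color = strata$color[i],
      session = strata$session[i], n = n,
      zero_fl_n = sum(s$fl == 0), zero_fl_pct = 100 * mean(s$fl == 0),
      low_fl_n = sum(s$fl > 0 & s$fl < fl_cutoff),
      low_fl_pct = 100 * mean(s$fl > 0 & s$fl < fl_cutoff),
      high_fl_n = sum(s$fl >= fl_cutoff),
      high_fl_pct = 100 * mean(s$fl >= fl_cutoff),
      bcea63_median = b63["median"], bcea63_q25 = b63["q25"],
      bcea63_q75 = b63["q75"],
      bcea95_median = b95["median"], bcea95_q25 = b95["q25"],
      bcea95_q75 = b95["q75"],
      p1_median = p1["median"], p1_q25 = p1["q25"], p1_q75 = p1["q75"],
      p2_median = p2["median"], p2_q25 = p2["q25"], p2_q75 = p2["q75"],
      stable_n = sum(s$stable), stable_pct = 100 * mean(s$stable),
      rodfree_n = sum(s$rodfree, na.rm = TRUE),
      rodfree_pct = if (all(is.na(s$rodfree))) NA_real_ else
        100 * mean(s$rodfree, na.rm = TRUE),
      passed_n = sum(s$passed),
      fti_median = stats::median(s$fti),
      duration_median_s = stats::median(s$duration_s),
      row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Percentages for a published reliability-count table
#'
#' Takes a table of reliability counts per test stratum (as printed in study
#' summary tables: tests with zero / intermediate / high fixation losses and
#' rod-free detections out of `n`) and adds the derived percentages.
#'
#' @param counts Data frame with columns `n`, `zero_fl`, `low_fl`, `high_fl`
#'   and optionally `rodfree_detected`, `rodfree_n`.
#' @return The table with `zero_fl_pct`, `low_fl_pct`, `high_fl_pct` and
#'   `rodfree_pct` columns appended.
#' @export
summarize_reliability_counts <- function(counts) {
  stopifnot(all(c("n", "zero_fl", "low_fl", "high_fl") %in% names(counts)))
  if (any(counts$zero_fl + counts$low_fl + counts$high_fl != counts$n)) {
    stop("fixation-loss bins must sum to n", call. = FALSE)
  }
  counts$zero_fl_pct <- 100 * counts$zero_fl / counts$n
  counts$low_fl_pct <- 100 * counts$low_fl / counts$n
  counts$high_fl_pct <- 100 * counts$high_fl / counts$n
  if (all(c("rodfree_detected", "rodfree_n") %in% names(counts))) {
    counts$rodfree_pct <- 100 * counts$rodfree_detected / counts$rodfree_n
  }
  counts
}

#' Group and paired non-parametric comparisons
#'
#' Thin wrappers over the standard routines: `compare_groups` performs a
#' two-sided Mann-Whitney U test (`wilcox.test`), `paired_comparison` a
#' two-sided Wilcoxon signed-rank test. Exact vs normal-approximation
#' p-values follow the standard sample-size rules of `wilcox.test`. All-zero
#' paired differences (no effect, no variability) return p = 1 by policy.
#'
#' @param values_a,values_b,x,y Numeric samples (>= 2 observations; paired
#'   and equal-length for `paired_comparison`).
#' @return A list with `statistic`, `p_value` and medians.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(values_a), median_b = stats::median(values_b))
}

#' @rdname compare_groups
#' @export
paired_comparison <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (all(x == y)) {
    return(list(statistic = 0, p_value = 1,
                median_a = stats::median(x), median_b = stats::median(y)))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(x), median_b = stats::median(y))
}

#' Structure-function correlation
#'
#' Spearman rank correlations of residual island areas (the structural
#' disease-severity marker, mm^2) against cyan volume sensitivity, red volume
#' sensitivity, and the cyan-red volume difference.
#'
#' @param island_areas Numeric vector of areas in mm^2 (n >= 4).
#' @param cyan_volume,red_volume Matching volume sensitivities in dB*deg^2.
#' @return Data frame with one row per index: `index`, `rho`, `p_value`, `n`.
#' @export
structure_function <- function(island_areas, cyan_volume, red_volume) {
  n <- length(island_areas)
  stopifnot(n >= 4L, length(cyan_volume) == n, length(red_volume) == n)
  if (length(unique(island_areas)) == 1L) {
    stop("island areas are all tied; rank correlation undefined",
         call. = FALSE)
  }
  one <- function(index, y) {
    ct <- suppressWarnings(
      stats::cor.test(island_areas, y, method = "spearman"))
    data.frame(index = index, rho = unname(ct$estimate),
               p_value = ct$p.value, n = n)
  }
  rbind(one("cyan_volume", cyan_volume),
        one("red_volume", red_volume),
        one("cyan_red_volume_diff", cyan_volume - red_volume))
}

#' Run the full analysis pipeline on a cohort
#'
#' Chains the stages on a set of subject records: reliability gating with an
#' exclusion log, per-exam sensitivity indices, cohort summary, group and
#' color comparisons, test-retest repeatability (when test2 sessions are
#' present), and structure-function correlation (when island areas are
#' present). Deterministic given the records and `seed` (used only by the
#' repeatability bootstrap).
#'
#' @param records List of [new_subject_record()] objects.
#' @param fl_cutoff,rodfree_cutoff Gate configuration.
#' @param diff_threshold Cyan-red classification threshold in dB.
#' @param n_boot,seed Bootstrap configuration for the repeatability stage.
#' @param out_dir Optional directory; when given, every table is also written
#'   as a CSV.
#' @return A list of data frames: `reliability`, `exclusions`, `indices`,
#'   `pointwise`, `summary`, `comparisons`, `repeatability` (possibly empty),
#'   `structure_function` (possibly `NULL`).
#' @export
run_pipeline <- function(records, fl_cutoff = 30, rodfree_cutoff = 8,
                         diff_threshold = 4, n_boot = 200L, seed = 1L,
                         out_dir = NULL) {
  pairs <- all_exams(records)
  pairs <- Filter(function(p) p$exam$condition == "scotopic", pairs)
  reliability <- do.call(rbind, lapply(pairs, function(p) {
    rep <- gate_exam(p$exam, fl_cutoff, rodfree_cutoff)
    data.frame(subject_id = p$record$subject_id, group = p$record$group,
               color = p$exam$color, session = p$exam$session,
               fixation_loss_pct = rep$fixation_loss_pct, P1 = rep$P1,
               P2 = rep$P2, BCEA63 = rep$BCEA63, BCEA95 = rep$BCEA95,
               fujii_class = rep$fujii_class,
               rod_free_detected = rep$rod_free_detected,
               passed = rep$passed,
               reasons = paste(rep$reasons, collapse = ";"))
  }))
  exclusions <- reliability[!reliability$passed,
                            c("subject_id", "group", "color", "session",
                              "reasons")]
  # exclusion is per subject-session: a failed cyan gate voids both colors
  excluded_key <- unique(paste(exclusions$subject_id, exclusions$session))
  included <- list()
  idx_rows <- list(); pw_rows <- list()
  for (p in pairs) {
    key <- paste(p$record$subject_id, p$exam$session)
    if (key %in% excluded_key) next
    ex <- normalize_eye(p$exam)
    si <- sensitivity_indices(ex, central_excluded = FALSE)
    idx_rows[[length(idx_rows) + 1L]] <- data.frame(
      subject_id = p$record$subject_id, group = p$record$group,
      color = ex$color, session = ex$session,
      mean_sensitivity = si$mean_sensitivity,
      mean_sensitivity_excl_center = mean_sensitivity(ex, TRUE),
      volume_sensitivity = si$volume_sensitivity,
      temporal_mean = si$temporal_mean, nasal_mean = si$nasal_mean,
      island_area_mm2 = p$record$island_area_mm2)
    pw_rows[[length(pw_rows) + 1L]] <- data.frame(
      subject_id = p$record$subject_id, group = p$record$group,
      color = ex$color, session = ex$session,
      locus_id = ex$grid$loci$id, x = ex$grid$loci$x, y = ex$grid$loci$y,
      threshold_db = ex$thresholds)
    included[[length(included) + 1L]] <- p
  }
  indices <- do.call(rbind, idx_rows)
  pointwise <- do.call(rbind, pw_rows)
  comparisons <- cohort_comparisons(indices)
  repeatability <- repeatability_tables(indices, pointwise, n_boot, seed)
  sf <- NULL
  chm <- indices[indices$group == "choroideremia" &
                   indices$session == "test1" &
                   !is.na(indices$island_area_mm2), ]
  if (nrow(chm) > 0) {
    cy <- chm[chm$color == "cyan_505nm", ]
    rd <- chm[chm$color == "red_627nm", ]
    rd <- rd[match(cy$subject_id, rd$subject_id), ]
    if (nrow(cy) >= 4) {
      sf <- structure_function(cy$island_area_mm2, cy$volume_sensitivity,
                               rd$volume_sensitivity)
    }
  }
  summary <- summarize_cohort(records, fl_cutoff, rodfree_cutoff)
  out <- list(reliability = reliability, exclusions = exclusions,
              indices = indices, pointwise = pointwise, summary = summary,
              comparisons = comparisons, repeatability = repeatability,
              structure_function = sf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out
}

cohort_comparisons <- function(indices) {
  t1 <- indices[indices$session == "test1", ]
  rows <- list()
  for (col in unique(t1$color)) {
    for (metric in c("mean_sensitivity", "volume_sensitivity")) {
      a <- t1[t1$color == col & t1$group == "healthy", metric]
      b <- t1[t1$color == col & t1$group == "choroideremia", metric]
      if (length(a) >= 2 && length(b) >= 2) {
        cg <- compare_groups(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = "healthy_vs_choroideremia", color = col,
          metric = metric, statistic = cg$statistic, p_value = cg$p_value,
          median_a = cg$median_a, median_b = cg$median_b)
      }
    }
  }
  for (grp in unique(t1$group)) {
    for (metric in c("mean_sensitivity_excl_center", "volume_sensitivity")) {
      cy <- t1[t1$group == grp & t1$color == "cyan_505nm", ]
      rd <- t1[t1$group == grp & t1$color == "red_627nm", ]
      rd <- rd[match(cy$subject_id, rd$subject_id), ]
      ok <- !is.na(rd$subject_id)
      if (sum(ok) >= 2) {
        pc <- paired_comparison(cy[ok, metric], rd[ok, metric])
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = "cyan_vs_red", color = grp, metric = metric,
          statistic = pc$statistic, p_value = pc$p_value,
          median_a = pc$median_a, median_b = pc$median_b)
      }
    }
  }
  do.call(rbind, rows)
}

repeatability_tables <- function(indices, pointwise, n_boot, seed) {
  rows <- list()
  for (col in unique(pointwise$color)) {
    pw <- pointwise[pointwise$color == col, ]
    wide1 <- pw[pw$session == "test1", ]
    wide2 <- pw[pw$session == "test2", ]
    key1 <- paste(wide1$subject_id, wide1$locus_id)
    key2 <- paste(wide2$subject_id, wide2$locus_id)
    common <- intersect(key1, key2)
    if (length(common) == 0) next
    w1 <- wide1[match(common, key1), ]
    w2 <- wide2[match(common, key2), ]
    pm <- paired_measurements(w1$subject_id, w1$locus_id,
                              index_values(w1$threshold_db),
                              index_values(w2$threshold_db))
    if (length(unique(pm$subject_id)) < 2) next
    ba <- rm_bland_altman(pm, n_boot = n_boot, seed = seed)
    ar <- agreement_rates(paired_measurements(w1$subject_id, w1$locus_id,
                                              w1$threshold_db,
                                              w2$threshold_db))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "pointwise", color = col, bias = ba$bias,
      sd_within = ba$sd_within, sd_between = ba$sd_between, cor = ba$cor,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      n_subjects = ba$n_subjects, n_pairs = ba$n_pairs,
      exact_pct = ar["exact_pct"], within_2db_pct = ar["within_2db_pct"],
      row.names = NULL)
    for (metric in c("mean_sensitivity", "volume_sensitivity")) {
      i1 <- indices[indices$color == col & indices$session == "test1", ]
      i2 <- indices[indices$color == col & indices$session == "test2", ]
      common_s <- intersect(i1$subject_id, i2$subject_id)
      if (length(common_s) < 2) next
      pm2 <- paired_measurements(
        common_s, "exam",
        i1[match(common_s, i1$subject_id), metric],
        i2[match(common_s, i2$subject_id), metric])
      ba2 <- standard_bland_altman(pm2)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, color = col, bias = ba2$bias,
        sd_within = ba2$sd_within, sd_between = 0, cor = ba2$cor,
        loa_low = ba2$loa_low, loa_high = ba2$loa_high,
        n_subjects = ba2$n_subjects, n_pairs = ba2$n_pairs,
        exact_pct = NA_real_, within_2db_pct = NA_real_, row.names = NULL)
    }
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
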