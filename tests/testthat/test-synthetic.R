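test_that("true thresholds encode the rod-free fovea and island geometry", {
  f <- sensitivity_field("healthy", central_cyan_residual = 4.0)
  expect_equal(true_threshold(f, "cyan_505nm", 0, 0), 4.0)
  # equal peaks, zero deficits: cyan - red exactly 0 off-fovea
  g <- build_grid()
  off <- g$loci$x != 0 | g$loci$y != 0
  cy <- true_threshold(f, "cyan_505nm", g$loci$x, g$loci$y)
  rd <- true_threshold(f, "red_627nm", g$loci$x, g$loci$y)
  expect_equal(cy[off], rd[off])
  expect_lt(cy[!off], rd[!off]) # foveal cyan scotoma
  # choroideremia: non-seen outside the residual island
  fc <- sensitivity_field("choroideremia", island_semi_axes = c(3, 2),
                          island_center_offset = 1, cyan_deficit = 10)
  expect_equal(true_threshold(fc, "cyan_505nm", 6.5, 0), -1.0)
  expect_gte(true_threshold(fc, "cyan_505nm", 1, 0), 0)
  expect_error(sensitivity_field("choroideremia"), "island_semi_axes")
})

test_that("staircase follows the 4-2 bracketing rules exactly", {
  det <- det_observer()
  r <- run_staircase(10, det, return_trace = TRUE)
  tr <- attr(r, "trace")
  expect_equal(tr$level, c(18, 14, 10, 12, 10))
  expect_equal(tr$seen, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(as.numeric(r), 10)
  expect_equal(run_staircase(-1, det), -1.0)  # total non-seer
  expect_equal(run_staircase(36, det), 36)    # ceiling
  expect_equal(run_staircase(0, det), 0)      # floor, seen at brightest
})

test_that("staircase matches the independent oracle for all integer thresholds", {
  det <- det_observer()
  for (T in 0:36) {
    expect_equal(run_staircase(T, det), staircase_oracle_deterministic(T),
                 info = paste("threshold", T))
  }
})

test_that("deterministic staircase resolves any threshold to within 2 dB", {
  det <- det_observer()
  set.seed(8)
  for (T in runif(50, 0, 36)) {
    m <- run_staircase(T, det)
    expect_lte(abs(m - T), 2)
  }
})

test_that("measured thresholds lie on the reachable 4/2-step lattice", {
  obs <- observer_model(psychometric_slope = 2, false_positive_rate = 0.05,
                        lapse_rate = 0.05)
  # lattice reachable from 18 by +/-4 then +/-2 steps within [0, 36]
  reachable <- sort(unique(c(-1, seq(0, 36, by = 2))))
  set.seed(21)
  for (i in 1:200) {
    m <- run_staircase(runif(1, -5, 40), obs)
    expect_true(m %in% reachable)
  }
})

test_that("simulated exams honor degenerate observer and fixation settings", {
  g <- build_grid()
  f <- sensitivity_field()
  set.seed(2)
  ex <- simulate_exam(f, g, det_observer(), fixation_sigma = c(0, 0))
  expect_equal(fixation_loss_rate(ex$catch_trials), 0)
  expect_equal(bcea(ex$fixation_trace), 0)
  expect_equal(unname(p1_p2(ex$fixation_trace)), c(100, 100))
  # healthy field, noisy observer: valid range, central cyan low
  set.seed(3)
  ex2 <- simulate_exam(f, g, observer_model())
  expect_true(all(ex2$thresholds >= -1 & ex2$thresholds <= 36))
  expect_lte(ex2$thresholds[1], 8)
})

test_that("cohorts are reproducible and sized as configured", {
  cfg <- cohort_config(n_healthy = 2, n_choroideremia = 3,
                       n_retest_choroideremia = 2, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(length(c1), 5L)
  expect_equal(sum(vapply(c1, function(r) r$group == "choroideremia",
                          logical(1))), 3L)
  # retest subjects carry 4 exams, others 2
  n_exams <- vapply(c1, function(r) length(r$exams), integer(1))
  expect_equal(sort(n_exams), c(2L, 2L, 2L, 4L, 4L))
  # island areas present and positive for patients only
  isl <- vapply(c1, function(r) r$island_area_mm2, numeric(1))
  grp <- vapply(c1, function(r) r$group, character(1))
  expect_true(all(is.na(isl[grp == "healthy"])))
  expect_true(all(isl[grp == "choroideremia"] > 0))
})

test_that("zero retest noise with a deterministic observer reproduces test1", {
  cfg <- cohort_config(n_healthy = 2, n_choroideremia = 2,
                       n_retest_healthy = 2, n_retest_choroideremia = 2,
                       observer = det_observer(), retest_sd_within = 0,
                       rodfree_absent_rate = 0, seed = 9)
  rec <- simulate_cohort(cfg)
  for (r in rec) {
    for (color in c("cyan_505nm", "red_627nm")) {
      t1 <- r$exams[[exam_key("scotopic", color, "test1")]]$thresholds
      t2 <- r$exams[[exam_key("scotopic", color, "test2")]]$thresholds
      expect_identical(t1, t2)
    }
  }
})

test_that("retest difference spread grows with the configured drift SD", {
  sd_of_diffs <- function(retest_sd, seed = 13) {
    cfg <- cohort_config(n_healthy = 8, n_choroideremia = 0,
                         n_retest_healthy = 8, retest_sd_within = retest_sd,
                         rodfree_absent_rate = 0, seed = seed)
    rec <- simulate_cohort(cfg)
    d <- unlist(lapply(rec, function(r) {
      r$exams[["scotopic.cyan_505nm.test2"]]$thresholds -
        r$exams[["scotopic.cyan_505nm.test1"]]$thresholds
    }))
    sd(d)
  }
  s0 <- sd_of_diffs(0)
  s2 <- sd_of_diffs(2)
  s5 <- sd_of_diffs(5)
  expect_lt(s0, s2)
  expect_lt(s2, s5)
  # with zero drift the spread is pure staircase noise; adding drift should
  # push the total towards sqrt(2*sigma_stair^2 + sd^2)
  expect_gt(s5, sqrt(s0^2 + 5^2) * 0.8)
})

test_that("cohort pointwise distributions match the disease phenotype", {
  cfg <- cohort_config(n_healthy = 8, n_choroideremia = 8,
                       n_retest_choroideremia = 0, seed = 31)
  rec <- simulate_cohort(cfg)
  chm <- Filter(function(r) r$group == "choroideremia", rec)
  hea <- Filter(function(r) r$group == "healthy", rec)
  chm_cy <- unlist(lapply(chm, function(r)
    r$exams[["scotopic.cyan_505nm.test1"]]$thresholds))
  hea_cy <- unlist(lapply(hea, function(r)
    r$exams[["scotopic.cyan_505nm.test1"]]$thresholds))
  # patients: heavy mass at the non-seen sentinel; healthy: none off-fovea
  expect_gt(mean(chm_cy == -1), 0.2)
  expect_lt(mean(hea_cy == -1), 0.05)
  expect_gt(median(hea_cy), 15)
  expect_lt(median(chm_cy), 10)
})
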