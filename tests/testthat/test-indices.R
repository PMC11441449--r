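test_that("mean sensitivity averages with the sentinel mapped to 0 dB", {
  expect_equal(mean_sensitivity(quick_exam(20)), 20)
  expect_equal(mean_sensitivity(quick_exam(-1)), 0)
  expect_equal(mean_sensitivity(quick_exam(c(36, rep(0, 36)))), 36 / 37)
  # central exclusion drops the (0,0) locus only
  th <- c(0, rep(20, 36))
  expect_equal(mean_sensitivity(quick_exam(th), central_excluded = TRUE), 20)
  expect_equal(mean_sensitivity(quick_exam(th)), 36 * 20 / 37)
  # alternative policy: drop non-seen loci instead of zeroing them
  th2 <- c(rep(-1, 17), rep(10, 20))
  expect_equal(mean_sensitivity(quick_exam(th2), nonseen = "exclude"), 10)
  expect_equal(mean_sensitivity(quick_exam(th2)), 200 / 37)
})

test_that("volume of a flat field is sensitivity times hull area", {
  ex <- quick_exam(20.6)
  expect_equal(volume_sensitivity(ex), 20.6 * 147, tolerance = 1e-10)
  expect_equal(volume_sensitivity(ex), 3028.2, tolerance = 1e-10)
  expect_equal(volume_sensitivity(quick_exam(-1)), 0)
  expect_equal(volume_sensitivity(quick_exam(36)), 36 * 147,
               tolerance = 1e-10)
})

test_that("volume integration matches the dense quadrature oracle", {
  # radial cone field on the default grid
  ex <- field_exam(function(x, y) 30 - 3 * sqrt(x^2 + y^2))
  v <- volume_sensitivity(ex)
  expect_equal(v, volume_quadrature_oracle(ex, m = 20),
               tolerance = 1e-6)
  # and on an irregular grid with a random field
  set.seed(23)
  g <- random_grid(20, seed = 23)
  ex2 <- quick_exam(runif(20, 0, 36), grid = g)
  expect_equal(volume_sensitivity(ex2), volume_quadrature_oracle(ex2, m = 20),
               tolerance = 1e-6)
})

test_that("volume is additive, bounded, and invariant to rigid motion", {
  g <- random_grid(18, seed = 3)
  set.seed(3)
  f1 <- runif(18, 0, 15); f2 <- runif(18, 0, 15)
  v1 <- volume_sensitivity(quick_exam(f1, grid = g))
  v2 <- volume_sensitivity(quick_exam(f2, grid = g))
  v12 <- volume_sensitivity(quick_exam(f1 + f2, grid = g))
  expect_equal(v12, v1 + v2, tolerance = 1e-9)
  expect_gte(v1, 0)
  expect_lte(v1, 36 * polygon_area_oracle(g$loci$x, g$loci$y))
  # rotating every locus leaves the integral unchanged
  th <- 0.31
  gr <- g
  gr$loci$x <- cos(th) * g$loci$x - sin(th) * g$loci$y
  gr$loci$y <- sin(th) * g$loci$x + cos(th) * g$loci$y
  expect_equal(volume_sensitivity(quick_exam(f1, grid = gr)), v1,
               tolerance = 1e-9)
})

test_that("radial-grid mean is spatially weighted, volume is not", {
  # for the field S(r) = r the locus average over-weights the dense center
  ex <- field_exam(function(x, y) sqrt(x^2 + y^2))
  locus_mean <- mean_sensitivity(ex)
  area_mean <- volume_sensitivity(ex) / grid_hull_area(ex$grid)
  expect_equal(locus_mean, mean(sqrt(ex$grid$loci$x^2 + ex$grid$loci$y^2)))
  expect_gt(area_mean - locus_mean, 0.5) # materially different summaries
})

test_that("pointwise differences subtract red from cyan per locus", {
  cy <- quick_exam(10); rd <- quick_exam(15, color = "red_627nm")
  d <- pointwise_difference(cy, rd)
  expect_equal(d$diff, rep(-5, 37))
  d0 <- pointwise_difference(cy, quick_exam(10, color = "red_627nm"))
  expect_equal(d0$diff, rep(0, 37))
  # undefined where exactly one color is non-seen; 0 where both are
  thc <- rep(10, 37); thr <- rep(12, 37)
  thc[2] <- -1
  thc[3] <- -1; thr[3] <- -1
  dm <- pointwise_difference(quick_exam(thc),
                             quick_exam(thr, color = "red_627nm"))
  expect_true(is.na(dm$diff[2]))
  expect_equal(dm$diff[3], 0)
  dm2 <- pointwise_difference(quick_exam(thc),
                              quick_exam(thr, color = "red_627nm"),
                              both_nonseen_zero = FALSE)
  expect_true(is.na(dm2$diff[3]))
  g2 <- build_grid("custom", ring_radii = 3, points_per_ring = 12)
  expect_error(pointwise_difference(cy, quick_exam(1, grid = g2,
                                                   color = "red_627nm")),
               "different grids")
})

test_that("difference classification follows the four-class color code", {
  cy <- quick_exam(10); rd <- quick_exam(15, color = "red_627nm")
  dm <- pointwise_difference(cy, rd) # diff -5 everywhere
  cl4 <- classify_difference(dm, threshold = 4)
  expect_true(all(cl4$class == "rod_dysfunction"))
  cl13 <- classify_difference(dm, threshold = 13)
  expect_true(all(cl13$class == "equal_normal"))
  # equal but below the normative floor: equally impaired (black)
  norm <- rep(12, 37) # lower bound above both 10-dB maps
  cl0 <- classify_difference(pointwise_difference(
    cy, quick_exam(10, color = "red_627nm")), threshold = 0,
    normative = norm)
  expect_true(all(cl0$class == "equal_reduced"))
  # positive differences flag cone dysfunction
  dcone <- pointwise_difference(quick_exam(20),
                                quick_exam(10, color = "red_627nm"))
  expect_true(all(classify_difference(dcone, 4)$class == "cone_dysfunction"))
  # both-non-seen loci land in equal_reduced
  thc <- rep(10, 37); thr <- rep(10, 37); thc[5] <- thr[5] <- -1
  clb <- classify_difference(pointwise_difference(
    quick_exam(thc), quick_exam(thr, color = "red_627nm")), 4)
  expect_equal(as.character(clb$class[5]), "equal_reduced")
})

test_that("threshold 0 partitions by sign and raising it is monotone", {
  set.seed(33)
  cy <- quick_exam(sample(0:36, 37, TRUE))
  rd <- quick_exam(sample(0:36, 37, TRUE), color = "red_627nm")
  dm <- pointwise_difference(cy, rd)
  cl0 <- classify_difference(dm, 0)
  expect_equal(cl0$class %in% c("rod_dysfunction", "cone_dysfunction"),
               dm$diff != 0)
  n_dys <- function(thr) sum(classify_difference(dm, thr)$class %in%
                               c("rod_dysfunction", "cone_dysfunction"))
  counts <- vapply(c(0, 2, 4, 8, 13), n_dys, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hemifield means split on the vertical midline", {
  sym <- field_exam(function(x, y) 20 - abs(y)) # left-right symmetric
  hm <- hemifield_means(sym)
  expect_equal(hm[["temporal_mean"]], hm[["nasal_mean"]])
  right_only <- field_exam(function(x, y) ifelse(x > 0, 12, 0))
  hm2 <- hemifield_means(right_only)
  expect_equal(hm2[["nasal_mean"]], 0)
  expect_equal(hm2[["temporal_mean"]], 12)
  ex_os <- quick_exam(20, eye = "OS")
  expect_error(hemifield_means(ex_os), "normalize_eye")
})

test_that("temporal island sparing drives temporal > nasal in most patients", {
  cfg <- cohort_config(n_healthy = 0, n_choroideremia = 40,
                       n_retest_choroideremia = 0, seed = 3)
  rec <- simulate_cohort(cfg)
  frac <- mean(vapply(rec, function(r) {
    hm <- hemifield_means(normalize_eye(
      r$exams[["scotopic.red_627nm.test1"]]))
    hm[["temporal_mean"]] > hm[["nasal_mean"]]
  }, logical(1)))
  expect_gte(frac, 0.9)
})

test_that("summary difference indices subtract matched global indices", {
  cy <- quick_exam(20)
  rd0 <- quick_exam(20, color = "red_627nm")
  expect_equal(unname(summary_difference_indices(cy, rd0)), c(0, 0))
  # printed-style worked example: mean sensitivities 2.3 vs 4.9
  th_c <- rep(2.3, 37); th_r <- rep(4.9, 37)
  sdi <- summary_difference_indices(quick_exam(th_c),
                                    quick_exam(th_r, color = "red_627nm"),
                                    central_excluded = FALSE)
  expect_equal(sdi[["mean_diff_db"]], -2.6)
})

test_that("healthy simulated exams show the foveal cyan-red signature", {
  cfg <- cohort_config(n_healthy = 6, n_choroideremia = 0,
                       rodfree_absent_rate = 0, seed = 5)
  rec <- simulate_cohort(cfg)
  central <- vapply(rec, function(r) {
    d <- pointwise_difference(r$exams[["scotopic.cyan_505nm.test1"]],
                              r$exams[["scotopic.red_627nm.test1"]])
    d$diff[d$x == 0 & d$y == 0]
  }, numeric(1))
  expect_true(all(central < 0)) # rod-free fovea: cyan below red centrally
  # and the global summary with the center excluded sits near zero
  sdi <- vapply(rec, function(r) summary_difference_indices(
    r$exams[["scotopic.cyan_505nm.test1"]],
    r$exams[["scotopic.red_627nm.test1"]],
    central_excluded = TRUE)[["mean_diff_db"]], numeric(1))
  expect_lt(abs(median(sdi)), 1.5)
})

test_that("normative bounds are healthy mean minus two SDs per locus", {
  exams <- list(quick_exam(c(10, rep(20, 36))),
                quick_exam(c(14, rep(24, 36))))
  nb <- normative_pointwise(exams)
  expect_equal(nb[1], 12 - 2 * sd(c(10, 14)))
  expect_equal(nb[2], 22 - 2 * sd(c(20, 24)))
})
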