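test_that("identical sessions give zero bias, zero SDs and zero CoR", {
  pm <- paired_measurements(rep(c("A", "B"), each = 5), rep(1:5, 2),
                            rep(1:10), rep(1:10))
  res <- rm_bland_altman(pm, n_boot = 0)
  expect_equal(res$bias, 0)
  expect_equal(res$sd_within, 0)
  expect_equal(res$sd_between, 0)
  expect_equal(res$cor, 0)
  expect_equal(res$loa_low, 0)
  expect_equal(res$loa_high, 0)
})

test_that("mixed-model CoR recovers the simulated within-subject SD", {
  set.seed(71)
  pm1 <- simulate_pairs(20, 37, mu = 0, sd_between = 0, sd_within = 1)
  res1 <- rm_bland_altman(pm1, n_boot = 0)
  expect_equal(res1$cor, 2 * 1.96 * 1.0, tolerance = 0.15 / 3.92)
  expect_equal(res1$cor, 2 * 1.96 * res1$sd_within, tolerance = 1e-12)
  pm3 <- simulate_pairs(20, 37, mu = 0, sd_between = 0, sd_within = 3)
  res3 <- rm_bland_altman(pm3, n_boot = 0)
  expect_equal(res3$cor, 11.76, tolerance = 0.45 / 11.76)
})

test_that("REML and closed-form engines agree on balanced data", {
  set.seed(72)
  pm <- simulate_pairs(12, 10, mu = 0.4, sd_between = 0.8, sd_within = 1.2)
  r_reml <- rm_bland_altman(pm, n_boot = 0, engine = "reml")
  r_anov <- rm_bland_altman(pm, n_boot = 0, engine = "anova")
  expect_equal(r_anov$bias, r_reml$bias, tolerance = 1e-6)
  expect_equal(r_anov$sd_within, r_reml$sd_within, tolerance = 1e-5)
  expect_equal(r_anov$sd_between, r_reml$sd_between, tolerance = 1e-4)
  # also when the between-subject variance hits the zero boundary
  set.seed(73)
  pm0 <- simulate_pairs(8, 12, sd_between = 0, sd_within = 1)
  r0_reml <- rm_bland_altman(pm0, n_boot = 0, engine = "reml")
  r0_anov <- rm_bland_altman(pm0, n_boot = 0, engine = "anova")
  expect_equal(r0_anov$sd_within, r0_reml$sd_within, tolerance = 1e-3)
})

test_that("LoA use the total SD while CoR uses the within-subject SD only", {
  set.seed(74)
  pm <- simulate_pairs(25, 30, mu = 0.5, sd_between = 1.5, sd_within = 1)
  res <- rm_bland_altman(pm, n_boot = 0)
  expect_equal(res$loa_high - res$bias,
               1.96 * sqrt(res$sd_between^2 + res$sd_within^2),
               tolerance = 1e-10)
  expect_lt(res$cor, 2 * 1.96 * sqrt(res$sd_between^2 + res$sd_within^2))
  # naive pooled-SD CoR inflates whenever subjects differ systematically
  expect_gt(res$cor_pooled, res$cor)
})

test_that("the analysis is invariant to subject and unit ordering and scale", {
  set.seed(75)
  pm <- simulate_pairs(10, 8, mu = 0.2, sd_between = 0.5, sd_within = 1)
  perm <- sample(nrow(pm))
  pmp <- pm[perm, ]
  class(pmp) <- class(pm)
  r1 <- rm_bland_altman(pm, n_boot = 0)
  r2 <- rm_bland_altman(pmp, n_boot = 0)
  expect_equal(r1$bias, r2$bias, tolerance = 1e-9)
  expect_equal(r1$sd_within, r2$sd_within, tolerance = 1e-9)
  # scale equivariance: multiplying values by c scales CoR by |c|
  pms <- paired_measurements(pm$subject_id, pm$unit_id,
                             3 * pm$value_test1, 3 * pm$value_test2)
  rs <- rm_bland_altman(pms, n_boot = 0)
  expect_equal(rs$cor, 3 * r1$cor, tolerance = 1e-6)
})

test_that("cluster bootstrap CIs bracket the point estimates", {
  set.seed(76)
  pm <- simulate_pairs(15, 20, mu = 0.3, sd_between = 0.5, sd_within = 1)
  res <- rm_bland_altman(pm, n_boot = 200, seed = 99)
  expect_true(res$boot_ci["bias", "lower"] <= res$bias)
  expect_true(res$boot_ci["bias", "upper"] >= res$bias)
  expect_true(res$boot_ci["cor", "lower"] <= res$boot_ci["cor", "upper"])
  # seeded: identical across reruns
  res2 <- rm_bland_altman(pm, n_boot = 200, seed = 99)
  expect_identical(res$boot_ci, res2$boot_ci)
})

test_that("standard Bland-Altman follows the single-pair conventions", {
  pm0 <- paired_measurements(letters[1:5], "exam", 1:5, 1:5)
  r0 <- standard_bland_altman(pm0)
  expect_equal(r0$bias, 0)
  expect_equal(r0$cor, 0)
  # two subjects with differences +1 and -1: SD(d) = sqrt(2),
  # sd_within = 1, CoR = 2 * 1.96 * 1
  pm2 <- paired_measurements(c("a", "b"), "exam", c(10, 10), c(11, 9))
  r2 <- standard_bland_altman(pm2)
  expect_equal(r2$bias, 0)
  expect_equal(r2$sd_within, 1)
  expect_equal(r2$cor, 3.92)
  expect_equal(r2$loa_high, 1.96 * sqrt(2))
  set.seed(77)
  d <- rnorm(1e4)
  pmn <- paired_measurements(sprintf("s%05d", 1:1e4), "exam",
                             rep(0, 1e4), d)
  rn <- standard_bland_altman(pmn)
  expect_equal(rn$cor, 2 * 1.96 / sqrt(2), tolerance = 0.03)
  expect_error(standard_bland_altman(
    paired_measurements(c("a", "a"), c(1, 2), c(1, 2), c(2, 3))),
    "one pair per subject")
})

test_that("combined cyan-red repeatability applies the non-seen exclusion", {
  # identical sessions -> zero CoR after exclusion
  set.seed(78)
  subj <- rep(c("A", "B", "C"), each = 37)
  unit <- rep(1:37, 3)
  cy <- pmax(round(runif(111, -1, 30)), -1)
  rd <- pmax(round(runif(111, -1, 30)), -1)
  cyp <- paired_measurements(subj, unit, cy, cy)
  rdp <- paired_measurements(subj, unit, rd, rd)
  res <- cyan_red_combined_cor(cyp, rdp, n_boot = 0)
  expect_equal(res$cor, 0)
  expect_lt(res$n_pairs, 111) # sentinels were dropped
  # all cyan non-seen at test1 saturates the exclusion
  cy_ns <- paired_measurements(subj, unit, rep(-1, 111), cy)
  expect_error(cyan_red_combined_cor(cy_ns, rdp, n_boot = 0), "no loci left")
})

test_that("independent per-color noise adds in the combined variance", {
  set.seed(79)
  sigma <- 1.5
  subj <- rep(sprintf("S%02d", 1:20), each = 37)
  unit <- rep(1:37, 20)
  n <- length(subj)
  base_c <- runif(n, 10, 25); base_r <- runif(n, 10, 25)
  # each color's session-wise difference has within-SD sigma; the combined
  # cyan-red index difference therefore has SD sigma * sqrt(2)
  cyp <- paired_measurements(subj, unit, base_c,
                             base_c + rnorm(n, 0, sigma))
  rdp <- paired_measurements(subj, unit, base_r,
                             base_r + rnorm(n, 0, sigma))
  res <- cyan_red_combined_cor(cyp, rdp, n_boot = 0)
  expect_equal(res$cor, 2 * 1.96 * sigma * sqrt(2), tolerance = 0.06)
})

test_that("agreement rates count exact and within-2dB matches", {
  pm <- paired_measurements("A", 1:10,
                            c(5, 5, 5, 5, 5, 10, 10, 10, 20, 20),
                            c(5, 5, 5, 5, 5, 12, 11, 8, 26, 27))
  ar <- agreement_rates(pm)
  expect_equal(ar[["exact_pct"]], 50)
  expect_equal(ar[["within_2db_pct"]], 80)
  ident <- paired_measurements("A", 1:5, c(-1, 0, 3, 3, 9), c(-1, 0, 3, 3, 9))
  expect_equal(unname(agreement_rates(ident)), c(100, 100))
})
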