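# Shared fixture builders: everything is generated in code at test time.

det_observer <- function() {
  observer_model(psychometric_slope = 0, false_positive_rate = 0,
                 lapse_rate = 0)
}

# Minimal exam with caller-chosen thresholds on the default grid.
quick_exam <- function(thresholds, grid = build_grid(), color = "cyan_505nm",
                       eye = "OD", session = "test1", subject_id = "S1",
                       catch_trials = rep(FALSE, 10),
                       fixation_trace = cbind(rnorm(50, 0, 0.2),
                                              rnorm(50, 0, 0.2))) {
  if (length(thresholds) == 1L) {
    thresholds <- rep(thresholds, nrow(grid$loci))
  }
  new_exam(subject_id = subject_id, eye = eye, condition = "scotopic",
           color = color, grid = grid, thresholds = thresholds,
           fixation_trace = fixation_trace, catch_trials = catch_trials,
           session = session)
}

# Exam whose thresholds are a function f(x, y), clamped to the valid range.
field_exam <- function(f, grid = build_grid(), ...) {
  v <- pmin(pmax(f(grid$loci$x, grid$loci$y), 0), 36)
  quick_exam(v, grid = grid, ...)
}

# A random irregular grid (no cocircular ties) for geometry properties.
random_grid <- function(n = 25, seed = 1) {
  set.seed(seed)
  loci <- data.frame(id = seq_len(n) - 1L,
                     x = runif(n, -7, 7), y = runif(n, -7, 7),
                     ring_index = NA_integer_)
  structure(list(kind = "custom", ring_radii = NULL, points_per_ring = NULL,
                 loci = loci), class = "sm_grid")
}

# Paired measurements drawn from the one-way random-effects model.
simulate_pairs <- function(n_subjects, n_units, mu = 0, sd_between = 0,
                           sd_within = 1) {
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_units)
  u <- rep(rnorm(n_subjects, 0, sd_between), each = n_units)
  d <- mu + u + rnorm(n_subjects * n_units, 0, sd_within)
  base <- rnorm(n_subjects * n_units, 15, 4)
  paired_measurements(subj, rep(seq_len(n_units), n_subjects),
                      base, base + d)
}

# Two-subject two-color record set for I/O round trips.
make_records <- function(seed = 42) {
  set.seed(seed)
  g <- build_grid()
  recs <- list()
  for (i in 1:2) {
    sid <- sprintf("P%02d", i)
    exams <- list()
    for (color in c("cyan_505nm", "red_627nm")) {
      th <- sample(c(-1, round(runif(20, 0, 36), 1)), nrow(g$loci),
                   replace = TRUE)
      ex <- new_exam(sid, eye = sample(c("OD", "OS"), 1),
                     condition = "scotopic", color = color, grid = g,
                     thresholds = th,
                     fixation_trace = cbind(rnorm(30, 0, .3), rnorm(30, 0, .3)),
                     catch_trials = runif(10) < 0.2,
                     fixation_target_intensity = 35, duration_s = 300,
                     session = "test1")
      exams[[exam_key("scotopic", color, "test1")]] <- ex
    }
    recs[[i]] <- new_subject_record(
      sid, group = if (i == 1) "healthy" else "choroideremia",
      island_area_mm2 = if (i == 2) 12.5 else NA_real_, exams = exams)
  }
  recs
}
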