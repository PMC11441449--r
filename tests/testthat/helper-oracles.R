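# Independent oracles used to cross-check package computations.

# Independent re-implementation of the 4-2 bracketing staircase for a
# deterministic observer (sees exactly the levels at or below threshold).
# Builds the full presentation list first, then derives the result, so it
# shares no control flow with the package's sequential implementation.
staircase_oracle_deterministic <- function(true_db, start = 18,
                                           lo = 0, hi = 36) {
  if (true_db < lo) {
    # descend to the brightest level and fail there
    return(-1.0)
  }
  sees <- function(l) l <= true_db
  levels <- start
  responses <- sees(start)
  repeat {
    n <- length(levels)
    resp <- responses[n]
    # termination conditions observed so far
    changes <- which(diff(responses) != 0)
    n_reversals <- length(changes)
    if (!resp && levels[n] <= lo) return(-1.0)
    if (resp && levels[n] >= hi) return(hi)
    if (n_reversals >= 2 && n >= changes[2] + 2) break
    step <- if (n_reversals >= 1) 2 else 4
    nxt <- levels[n] + if (resp) step else -step
    nxt <- min(max(nxt, lo), hi)
    levels <- c(levels, nxt)
    responses <- c(responses, sees(nxt))
  }
  utils::tail(levels[responses], 1)
}

# Evaluate the piecewise-linear interpolant defined by a triangulation at
# arbitrary points via global point location + barycentric coordinates.
# Independent of the closed-form area * mean-vertex integration rule.
pl_interp_eval <- function(loci, tri, values, px, py) {
  out <- rep(NA_real_, length(px))
  eps <- 1e-9
  for (t in seq_len(nrow(tri))) {
    i1 <- tri$i1[t]; i2 <- tri$i2[t]; i3 <- tri$i3[t]
    x1 <- loci$x[i1]; y1 <- loci$y[i1]
    x2 <- loci$x[i2]; y2 <- loci$y[i2]
    x3 <- loci$x[i3]; y3 <- loci$y[i3]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) /
      ((y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3))
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) /
      ((y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3))
    l3 <- 1 - l1 - l2
    inside <- is.na(out) & l1 >= -eps & l2 >= -eps & l3 >= -eps
    out[inside] <- l1[inside] * values[i1] + l2[inside] * values[i2] +
      l3[inside] * values[i3]
  }
  out
}

# Quadrature oracle for the hill-of-vision volume: subdivide every Delaunay
# triangle into m^2 congruent subtriangles and apply the centroid rule
# (exact for a linear function on each piece), evaluating the interpolant
# through the independent point-location path above.
volume_quadrature_oracle <- function(exam, m = 20L) {
  grid <- exam$grid
  tri <- scotoperim:::grid_triangulation(grid)
  v <- ifelse(exam$thresholds == -1, 0, exam$thresholds)
  total <- 0
  for (t in seq_len(nrow(tri))) {
    P <- rbind(c(grid$loci$x[tri$i1[t]], grid$loci$y[tri$i1[t]]),
               c(grid$loci$x[tri$i2[t]], grid$loci$y[tri$i2[t]]),
               c(grid$loci$x[tri$i3[t]], grid$loci$y[tri$i3[t]]))
    area <- abs((P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
                  (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])) / 2
    sub_area <- area / m^2
    # centroids of the upward and downward subtriangles in barycentric coords
    cx <- c(); cy <- c()
    for (i in 0:(m - 1)) {
      for (j in 0:(m - 1 - i)) {
        b <- c(i + 1 / 3, j + 1 / 3, m - i - j - 2 / 3) / m
        cx <- c(cx, sum(b * P[, 1])); cy <- c(cy, sum(b * P[, 2]))
        if (j < m - 1 - i) {
          b2 <- c(i + 2 / 3, j + 2 / 3, m - i - j - 4 / 3) / m
          cx <- c(cx, sum(b2 * P[, 1])); cy <- c(cy, sum(b2 * P[, 2]))
        }
      }
    }
    vals <- pl_interp_eval(grid$loci, tri, v, cx, cy)
    total <- total + sub_area * sum(vals)
  }
  total
}

# Shoelace hull area, independent of the package's helper.
polygon_area_oracle <- function(x, y) {
  h <- grDevices::chull(x, y)
  xh <- x[h]; yh <- y[h]
  abs(sum(xh * c(yh[-1], yh[1]) - c(xh[-1], xh[1]) * yh)) / 2
}

# Exact probability that a staircase measurement exceeds a cutoff, by
# probability propagation over the full staircase state space (independent
# of the package's sequential sampler).
staircase_exceed_prob <- function(true_db, observer, cutoff = 8,
                                  start = 18, max_pres = 60) {
  p_seen <- function(level) {
    det <- if (observer$psychometric_slope == 0) as.numeric(level <= true_db)
    else pnorm((true_db - level) / observer$psychometric_slope)
    observer$false_positive_rate +
      (1 - observer$false_positive_rate - observer$lapse_rate) * det
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(level, step, prev, reversals, final, last_seen, depth) {
    key <- paste(level, step, prev, reversals, final, last_seen, depth)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- p_seen(level)
    out <- 0
    for (seen in c(TRUE, FALSE)) {
      pb <- if (seen) p else 1 - p
      if (pb == 0) next
      ls <- if (seen) level else last_seen
      rev <- reversals + (!is.na(prev) && seen != prev)
      st <- if (rev >= 1) 2 else step
      exceed <- NULL
      if (!seen && level <= 0) {
        exceed <- 0 # sentinel result
      } else if (seen && level >= 36) {
        exceed <- as.numeric(36 > cutoff)
      } else if (final) {
        exceed <- as.numeric(!is.na(ls) && ls > cutoff)
      } else if (depth >= max_pres) {
        exceed <- as.numeric(!is.na(ls) && ls > cutoff)
      }
      if (is.null(exceed)) {
        nxt <- min(max(level + if (seen) st else -st, 0), 36)
        exceed <- rec(nxt, st, seen, rev, rev >= 2, ls, depth + 1)
      }
      out <- out + pb * exceed
    }
    memo[[key]] <- out
    out
  }
  rec(start, 4, NA, 0, FALSE, NA, 1)
}
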