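#' Build a microperimetry test grid
#'
#' Constructs the locus layout of a fundus-controlled perimetry test pattern
#' in retinal degrees. The default scotopic pattern is a 37-locus radial grid:
#' one locus at the anatomical fovea (0, 0) plus three concentric rings of 12
#' equally spaced loci. Ring loci are placed at angles `2*pi*k/points_per_ring`
#' starting at 0 rad on the +x axis (temporal retina in right-eye convention)
#' and proceeding counter-clockwise.
#'
#' Coordinates follow the right-eye (OD) convention throughout: +x is temporal
#' retina, +y superior. Left-eye exams are mirrored into this convention by
#' [normalize_eye()].
#'
#' @param kind One of `"scotopic_radial_37"` (the default dark-adapted
#'   pattern), `"mesopic_10_2"` (68-locus rectilinear 10-2 variant), or
#'   `"custom"` (radial grid with caller-supplied geometry).
#' @param ring_radii Strictly increasing positive ring radii in degrees.
#'   Defaults to `c(1, 3, 7)` for the radial grids; ignored for
#'   `"mesopic_10_2"`.
#' @param points_per_ring Number of equally spaced loci per ring (>= 3).
#' @return An object of class `sm_grid`: a list with `kind`, `ring_radii`,
#'   `points_per_ring`, and `loci`, a data frame with columns `id`, `x`, `y`,
#'   `ring_index` (0 for the central locus). Locus ids are unique and the
#'   layout is deterministic.
#' @examples
#' g <- build_grid()
#' nrow(g$loci)           # 37
#' grid_hull_area(g)      # 147 deg^2 for radii 1/3/7, 12 per ring
#' @export
build_grid <- function(kind = c("scotopic_radial_37", "mesopic_10_2", "custom"),
                       ring_radii = c(1, 3, 7), points_per_ring = 12L) {
  kind <- match.arg(kind)
  if (kind == "mesopic_10_2") {
    loci <- grid_10_2_loci()
    g <- structure(list(kind = kind, ring_radii = NULL, points_per_ring = NULL,
                        loci = loci), class = "sm_grid")
    return(g)
  }
  if (any(!is.finite(ring_radii)) || any(ring_radii <= 0)) {
    stop("invalid grid geometry: ring radii must be finite and positive",
         call. = FALSE)
  }
  if (is.unsorted(ring_radii, strictly = TRUE)) {
    stop("invalid grid geometry: ring radii must be strictly increasing",
         call. = FALSE)
  }
  points_per_ring <- as.integer(points_per_ring)
  if (points_per_ring < 3L) {
    stop("invalid grid geometry: points_per_ring must be >= 3", call. = FALSE)
  }
  if (kind == "scotopic_radial_37" &&
      (length(ring_radii) != 3L || points_per_ring != 12L)) {
    stop("scotopic_radial_37 requires 3 rings of 12 loci; use kind = \"custom\"",
         call. = FALSE)
  }
  ang <- 2 * pi * (seq_len(points_per_ring) - 1L) / points_per_ring
  xs <- c(0, unlist(lapply(ring_radii, function(r) r * cos(ang))))
  ys <- c(0, unlist(lapply(ring_radii, function(r) r * sin(ang))))
  ring <- c(0L, rep(seq_along(ring_radii), each = points_per_ring))
  loci <- data.frame(id = seq_along(xs) - 1L, x = xs, y = ys, ring_index = ring)
  structure(list(kind = kind, ring_radii = ring_radii,
                 points_per_ring = points_per_ring, loci = loci),
            class = "sm_grid")
}

# 68-locus 10-2 rectilinear pattern: odd-degree coordinates within 10 degrees
# of fixation (|.|^2 <= 85 keeps the standard 17 loci per quadrant).
grid_10_2_loci <- function() {
  v <- c(-9, -7, -5, -3, -1, 1, 3, 5, 7, 9)
  pts <- expand.grid(x = v, y = v)
  pts <- pts[pts$x^2 + pts$y^2 <= 85, , drop = FALSE]
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  data.frame(id = seq_len(nrow(pts)) - 1L, x = pts$x, y = pts$y,
             ring_index = NA_integer_)
}

#' @export
print.sm_grid <- function(x, ...) {
  cat(sprintf("<sm_grid> kind=%s, %d loci, hull area %.1f deg^2\n",
              x$kind, nrow(x$loci), grid_hull_area(x)))
  invisible(x)
}

#' Area of the convex hull of a grid
#'
#' @param grid An [build_grid()] object.
#' @return Hull area in square degrees (shoelace formula on the convex hull).
#' @export
grid_hull_area <- function(grid) {
  stopifnot(inherits(grid, "sm_grid"))
  polygon_area(grid$loci$x, grid$loci$y)
}

# Shoelace area of the convex hull of a point set.
polygon_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  xh <- x[h]; yh <- y[h]
  abs(sum(xh * c(yh[-1], yh[1]) - c(xh[-1], xh[1]) * yh)) / 2
}

#' Stimulus dynamic range in decibels
#'
#' The attenuation range spanned by a perimeter's stimulus luminances,
#' `10 * log10(max / min)`. The S-MAIA scotopic stimuli span 0.00064 to
#' 2.545 cd/m^2, a 36.0 dB range.
#'
#' @param max_luminance,min_luminance Luminances in cd/m^2 (same units).
#' @return Dynamic range in dB.
#' @examples
#' dynamic_range_db(2.545, 0.00064) # ~36.0
#' @export
dynamic_range_db <- function(max_luminance, min_luminance) {
  stopifnot(max_luminance > 0, min_luminance > 0)
  10 * log10(max_luminance / min_luminance)
}
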