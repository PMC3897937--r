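# Planar geometry primitives shared by the image generator and the
# morphometry engine. All coordinates are micrometres unless stated
# otherwise; polygons are n x 2 matrices (x, y), open (no repeated
# first vertex), y increasing upward from the canvas bottom.

#' Length of an open polyline
#'
#' @param xy numeric matrix with two columns (x, y); at least two rows.
#' @return total arc length in the units of `xy`.
#' @export
polyline_length <- function(xy) {
  xy <- as_xy(xy, min_rows = 2)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Shoelace area of a simple polygon
#'
#' @param xy polygon vertex matrix (open; the closing edge is implicit).
#' @return enclosed area (always nonnegative).
#' @export
polygon_area <- function(xy) {
  xy <- as_xy(xy, min_rows = 3)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Closed perimeter of a simple polygon
#' @inheritParams polygon_area
#' @return boundary length including the closing edge.
#' @export
polygon_perimeter <- function(xy) {
  xy <- as_xy(xy, min_rows = 3)
  polyline_length(rbind(xy, xy[1, , drop = FALSE]))
}

as_xy <- function(xy, min_rows = 2) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < min_rows || anyNA(xy)) {
    abort(sprintf("expected a numeric %d+ x 2 coordinate matrix", min_rows))
  }
  storage.mode(xy) <- "double"
  xy
}

# Closed-form perimeter (base excluded) and area of the supported villus
# profiles. `h` is the total height from base chord to tip, `w` the width.
#   rect:   VP = 2h + w,            VA = w h
#   capped: rectangle of straight height h - w/2 topped by a semicircular
#           cap of radius w/2: VP = 2(h - w/2) + pi w / 2,
#           VA = w (h - w/2) + pi w^2 / 8
villus_truth <- function(profile, h, w) {
  switch(profile,
    rect = list(perimeter = 2 * h + w, area = w * h),
    capped = {
      if (h < w / 2) abort("capped profile needs height >= width/2")
      hs <- h - w / 2
      list(perimeter = 2 * hs + pi * w / 2, area = w * hs + pi * w^2 / 8)
    },
    abort(sprintf("unknown villus profile '%s'", profile))
  )
}

# Analytic outline of a villus in local coordinates (u across, v along the
# axis, v = 0 at the base chord), then placed at base centre (cx, y0) with
# tilt `theta` radians from the vertical. Returned counter-clockwise
# starting at the base-left vertex; the base chord is the closing edge.
villus_outline <- function(profile, cx, y0, h, w, theta = 0, n_arc = 64) {
  r <- w / 2
  if (profile == "rect") {
    u <- c(-r, -r, r, r)
    v <- c(0, h, h, 0)
  } else {
    hs <- h - r
    ang <- seq(pi, 0, length.out = n_arc + 1)
    u <- c(-r, r * cos(ang), r)
    v <- c(0, hs + r * sin(ang), 0)
  }
  # rotate about the base centre, then translate
  ct <- cos(theta); st <- sin(theta)
  x <- cx + u * ct + v * st
  y <- y0 + v * ct - u * st
  cbind(x = x, y = y)
}

# angle (degrees, in [0, 90]) between a villus axis and the normal of the
# muscularis direction
axis_tilt_deg <- function(axis_vec, muscularis_vec) {
  normal <- c(-muscularis_vec[2], muscularis_vec[1])
  na <- sqrt(sum(axis_vec^2)); nn <- sqrt(sum(normal^2))
  if (na == 0 || nn == 0) abort("degenerate axis or muscularis direction")
  cosang <- abs(sum(axis_vec * normal)) / (na * nn)
  acos(pmin(1, cosang)) * 180 / pi
}
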