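# Measurement engine: orientation screen, automatic threshold segmentation,
# sub-pixel villous contour extraction, perimeter/area with base exclusion,
# per-100-um muscularis normalisation, and landmark-based VH/CD/VW.

#' Orientation-adequacy screen
#'
#' A section is adequate for morphometry when both villi and crypts are seen
#' in longitudinal section: at least one villus and one crypt must be
#' present, and every villus axis must lie within `tilt_tol_deg` of the
#' muscularis normal. Inadequate sections are excluded from analysis.
#'
#' @param annotation a `mucosa_annotation`, or any list carrying
#'   `villus_polygons` + `villus_base_segments` + `crypt_polylines` +
#'   `muscularis_polyline`, or a landmark set with `vh_polylines` and
#'   `cd_polylines`.
#' @param tilt_tol_deg maximal villus-axis tilt from the muscularis normal
#'   (degrees) still counted as longitudinal; default 30.
#' @return `TRUE` (adequate) or `FALSE`.
#' @export
assess_orientation <- function(annotation, tilt_tol_deg = 30) {
  if (is.null(annotation)) abort("unassessable: no annotation provided")
  lm <- annotation$landmarks %||% annotation
  polys <- annotation$villus_polygons
  crypts <- annotation$crypt_polylines %||% lm$cd_polylines
  musc <- annotation$muscularis_polyline %||% lm$muscularis_polyline
  if (is.null(musc)) abort("unassessable: no muscularis polyline")
  mvec <- musc[nrow(musc), ] - musc[1, ]

  if (!is.null(polys)) {
    bases <- annotation$villus_base_segments
    if (length(polys) < 1 || length(crypts) < 1) return(FALSE)
    tilts <- vapply(seq_along(polys), function(i) {
      base_mid <- colMeans(bases[[i]])
      d2 <- (polys[[i]][, 1] - base_mid[1])^2 + (polys[[i]][, 2] - base_mid[2])^2
      tip <- polys[[i]][which.max(d2), ]
      axis_tilt_deg(tip - base_mid, mvec)
    }, numeric(1))
    return(all(tilts <= tilt_tol_deg))
  }
  vh <- lm$vh_polylines %||% (if (!is.null(lm$vh_polyline)) list(lm$vh_polyline))
  if (is.null(vh)) abort("unassessable: annotation carries neither villus polygons nor landmarks")
  if (length(vh) < 1 || length(crypts) < 1) return(FALSE)
  tilts <- vapply(vh, function(p) {
    axis_tilt_deg(p[nrow(p), ] - p[1, ], mvec)
  }, numeric(1))
  all(tilts <= tilt_tol_deg)
}

#' Automatic global threshold (maximum between-class variance)
#'
#' Chooses the grey level that maximises the between-class intensity
#' variance over the 0-255 histogram (Otsu's criterion) and returns the
#' tissue mask. Tissue is taken as the darker class unless
#' `polarity = "light"`.
#'
#' @param image a `calibrated_image` (or plain numeric matrix, 0-255).
#' @param polarity `"dark"` if tissue is darker than lumen (default).
#' @return list with `threshold` (grey level) and `mask` (logical matrix,
#'   `TRUE` = tissue).
#' @export
auto_threshold <- function(image, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  px <- if (inherits(image, "calibrated_image")) image$pixels else as.matrix(image)
  if (length(px) == 0) abort("empty image")
  v <- as.vector(px)
  if (polarity == "light") v <- 255 - v
  if (max(v) - min(v) < .Machine$double.eps^0.5) {
    abort("no threshold separable: constant image")
  }
  thr <- otsu_threshold(v)
  mask <- matrix(v < thr, nrow = nrow(px))
  list(threshold = if (polarity == "light") 255 - thr else thr, mask = mask)
}

# between-class variance maximisation on the integer 0-255 histogram;
# returns a cut level midway between the optimal bin and the next
otsu_threshold <- function(v) {
  b <- pmin(255L, pmax(0L, as.integer(round(v))))
  counts <- tabulate(b + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[256]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  ks <- which(sigma_b == max(sigma_b))
  mean(lev[ks]) + 0.5
}

#' Extract villous contours from a tissue mask
#'
#' Villi are the connected tissue protrusions rising above the inter-villous
#' plateau. The plateau elevation is estimated as the median top-of-tissue
#' elevation over non-villus columns; each protrusion is cut at plateau
#' level (yielding its base chord) and traced row by row with
#' linearly-interpolated threshold crossings, giving a sub-pixel polygonal
#' contour rather than a pixel staircase.
#'
#' @param image the `calibrated_image` the mask came from (used for
#'   sub-pixel interpolation).
#' @param mask logical tissue mask from [auto_threshold()].
#' @param threshold the grey level used to build the mask.
#' @param min_prominence_um minimal elevation above the plateau for a
#'   protrusion to count as a villus (um).
#' @param min_width_px minimal base width of a protrusion, in pixels.
#' @return list of contours ordered left to right; each is a list with
#'   `polygon` (n x 2 um matrix; base chord is the closing edge) and
#'   `base_segment` (2 x 2 um matrix). Empty list for flat mucosa.
#' @export
extract_villous_contours <- function(image, mask, threshold = NULL,
                                     min_prominence_um = 20,
                                     min_width_px = 3) {
  stopifnot(inherits(image, "calibrated_image"))
  upp <- image$um_per_pixel
  px <- image$pixels
  ny <- nrow(mask); nx <- ncol(mask)
  if (is.null(threshold)) threshold <- otsu_threshold(as.vector(px))

  # top-of-tissue elevation per column (um, y up)
  r_top <- apply(mask, 2, function(col) match(TRUE, col))
  y_top <- (ny - r_top + 0.5) * upp
  if (all(is.na(y_top))) return(list())

  p0 <- quantile(y_top, 0.25, na.rm = TRUE, names = FALSE)
  villus_col <- !is.na(y_top) & y_top > p0 + min_prominence_um
  if (all(villus_col)) return(list())  # no resolvable plateau
  plateau <- median(y_top[!villus_col], na.rm = TRUE)

  # cut row: last row whose centre lies strictly above the plateau
  r_cut <- floor(ny + 0.5 - (plateau + 0.5 * upp) / upp)
  if (r_cut < 1) return(list())
  r_cut <- min(r_cut, ny)
  y_base <- (ny - r_cut + 0.5) * upp

  occ <- mask[r_cut, ]
  runs <- rle(occ)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_width_px
  c1 <- starts[keep]; c2 <- ends[keep]
  # require genuine prominence above the plateau
  prom <- vapply(seq_along(c1), function(i) {
    max(y_top[c1[i]:c2[i]], na.rm = TRUE)
  }, numeric(1))
  sel <- prom >= plateau + min_prominence_um
  c1 <- c1[sel]; c2 <- c2[sel]
  if (!length(c1)) return(list())

  # column windows, not crossing the midline toward a neighbouring villus
  lo <- c(1, floor((c2[-length(c2)] + c1[-1]) / 2) + 1)
  hi <- c(floor((c2[-length(c2)] + c1[-1]) / 2), nx)

  contours <- lapply(seq_along(c1), function(i) {
    w1 <- max(lo[i], c1[i] - 3L); w2 <- min(hi[i], c2[i] + 3L)
    left <- NULL; right <- NULL
    for (r in seq(r_cut, 1)) {
      seg <- mask[r, w1:w2]
      if (!any(seg)) break
      cl <- w1 - 1L + match(TRUE, seg)
      cr <- w1 - 1L + max(which(seg))
      y <- (ny - r + 0.5) * upp
      left <- rbind(left, c(edge_cross(px, r, cl, threshold, "left") * upp, y))
      right <- rbind(right, c(edge_cross(px, r, cr, threshold, "right") * upp, y))
    }
    if (is.null(left) || nrow(left) < 2) return(NULL)
    # extend the lowest traced crossings straight down to the base level
    base_l <- c(left[1, 1], y_base)
    base_r <- c(right[1, 1], y_base)
    polygon <- rbind(base_l, left, right[rev(seq_len(nrow(right))), ], base_r)
    list(polygon = unname(polygon),
         base_segment = unname(rbind(base_l, base_r)))
  })
  contours[!vapply(contours, is.null, logical(1))]
}

# sub-pixel boundary position (in pixel-centre units where column c has its
# centre at c - 0.5) by linear interpolation of intensity at the threshold
edge_cross <- function(px, r, c, threshold, side) {
  nb <- if (side == "left") c - 1L else c + 1L
  if (nb < 1 || nb > ncol(px)) return(c - 0.5)
  i_in <- px[r, c]; i_out <- px[r, nb]
  if (!is.finite(i_in) || !is.finite(i_out) || i_out == i_in) return(c - 0.5)
  frac <- (i_out - threshold) / (i_out - i_in)
  frac <- min(1, max(0, frac))
  if (side == "left") (nb - 0.5) + frac else (nb - 0.5) - frac
}

#' Area and base-excluded perimeter of a villous contour
#'
#' @param contour list with `polygon` (um coordinates; the base chord is the
#'   implicit closing edge) and `base_segment`.
#' @param um_per_pixel scale applied to the coordinates (1 when the contour
#'   is already in um, as produced by [extract_villous_contours()]).
#' @return named numeric: `area_um2` (shoelace) and `perimeter_um`
#'   (closed boundary length minus the base chord).
#' @export
measure_villus <- function(contour, um_per_pixel = 1) {
  poly <- as_xy(contour$polygon, min_rows = 3) * um_per_pixel
  base <- as_xy(contour$base_segment, min_rows = 2) * um_per_pixel
  base_len <- polyline_length(base)
  c(area_um2 = polygon_area(poly),
    perimeter_um = polygon_perimeter(poly) - base_len)
}

#' Express a summed quantity per 100 um of muscularis mucosae
#'
#' @param total quantity summed over all adequate villi in the section.
#' @param muscularis_length_um length of the muscularis mucosae (um, > 0).
#' @export
normalize_per_muscularis <- function(total, muscularis_length_um) {
  if (!is.numeric(muscularis_length_um) || muscularis_length_um <= 0) {
    abort("muscularis_length_um must be positive")
  }
  total / muscularis_length_um * 100
}

#' Landmark-based measurements: VH, CD, VW and muscularis length
#'
#' Computes arc lengths of analyst-drawn polylines. Villous height is by
#' default the maximum over the villi of the section and crypt depth the
#' mean over measured crypts; both rules are switchable.
#'
#' @param landmarks list with `vh_polylines` (or a single `vh_polyline`),
#'   `cd_polylines` (or `cd_polyline`), `vw_segment`, `muscularis_polyline`.
#' @param um_per_pixel scale factor from landmark coordinates to um (1 if
#'   the landmarks are already in um).
#' @param vh_rule `"max"` (default) or `"mean"` across villi.
#' @param cd_rule `"mean"` (default) or `"max"` across crypts.
#' @return one-row tibble with `VH`, `CD`, `VW`, `muscularis_um`.
#' @export
measure_landmarks <- function(landmarks, um_per_pixel = 1,
                              vh_rule = c("max", "mean"),
                              cd_rule = c("mean", "max")) {
  vh_rule <- match.arg(vh_rule); cd_rule <- match.arg(cd_rule)
  as_list <- function(x) if (is.list(x) && !is.matrix(x)) x else list(x)
  need <- function(x, nm) {
    if (is.null(x)) abort(sprintf("missing landmark field '%s'", nm))
    x
  }
  vh <- as_list(need(landmarks$vh_polylines %||% landmarks$vh_polyline, "vh_polyline"))
  cd <- as_list(need(landmarks$cd_polylines %||% landmarks$cd_polyline, "cd_polyline"))
  vw <- need(landmarks$vw_segment, "vw_segment")
  mm <- need(landmarks$muscularis_polyline, "muscularis_polyline")
  vh_len <- vapply(vh, polyline_length, numeric(1)) * um_per_pixel
  cd_len <- vapply(cd, polyline_length, numeric(1)) * um_per_pixel
  tibble::tibble(
    VH = if (vh_rule == "max") max(vh_len) else mean(vh_len),
    CD = if (cd_rule == "mean") mean(cd_len) else max(cd_len),
    VW = polyline_length(vw) * um_per_pixel,
    muscularis_um = polyline_length(mm) * um_per_pixel
  )
}

#' Full morphometry of one biopsy section
#'
#' Composes the automatic path (threshold, contour extraction, per-villus
#' area/perimeter, per-100-um normalisation) with the landmark path
#' (VH/CD/VW) into a single morphometry record. Sections failing the
#' orientation screen are returned flagged inadequate with missing
#' measurements, mirroring their exclusion from analysis.
#'
#' @param image a `calibrated_image`.
#' @param annotation annotation carrying the muscularis polyline and
#'   landmarks (um coordinates), e.g. from [generate_mucosa_image()] or
#'   [read_annotation()].
#' @param tilt_tol_deg orientation tolerance passed to [assess_orientation()].
#' @param polarity tissue polarity for [auto_threshold()].
#' @inheritParams measure_landmarks
#' @return one-row tibble: `VH`, `CD`, `VW`, `VP_per100`, `VA_per100`,
#'   `muscularis_um`, `n_villi`, `threshold`, `adequate`.
#' @export
summarize_biopsy <- function(image, annotation, tilt_tol_deg = 30,
                             polarity = "dark",
                             vh_rule = "max", cd_rule = "mean") {
  adequate <- assess_orientation(annotation, tilt_tol_deg = tilt_tol_deg)
  if (!adequate) {
    return(tibble::tibble(VH = NA_real_, CD = NA_real_, VW = NA_real_,
                          VP_per100 = NA_real_, VA_per100 = NA_real_,
                          muscularis_um = NA_real_, n_villi = NA_integer_,
                          threshold = NA_real_, adequate = FALSE))
  }
  th <- auto_threshold(image, polarity = polarity)
  contours <- extract_villous_contours(image, th$mask, threshold = th$threshold)
  meas <- vapply(contours, measure_villus, numeric(2))
  total_area <- if (length(contours)) sum(meas["area_um2", ]) else 0
  total_perim <- if (length(contours)) sum(meas["perimeter_um", ]) else 0
  lmk <- measure_landmarks(annotation$landmarks, um_per_pixel = 1,
                           vh_rule = vh_rule, cd_rule = cd_rule)
  musc <- lmk$muscularis_um
  tibble::tibble(
    VH = lmk$VH, CD = lmk$CD, VW = lmk$VW,
    VP_per100 = normalize_per_muscularis(total_perim, musc),
    VA_per100 = normalize_per_muscularis(total_area, musc),
    muscularis_um = musc,
    n_villi = length(contours),
    threshold = th$threshold,
    adequate = TRUE
  )
}

#' Measure every section in a directory
#'
#' Reads each PNG/TIFF with its JSON sidecar and runs [summarize_biopsy()].
#'
#' @param dir directory of images + sidecars as written by [render_batch()].
#' @param ... passed to [summarize_biopsy()].
#' @return tibble with one row per section (`biopsy_id` plus the
#'   [summarize_biopsy()] columns), also written by the pipeline as
#'   `morphometry.csv`.
#' @export
measure_batch <- function(dir, ...) {
  imgs <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE))
  rows <- purrr::map(imgs, function(p) {
    sc <- sub("\\.[^.]+$", ".json", p)
    if (!file.exists(sc)) abort(sprintf("missing sidecar for '%s'", p))
    ann <- read_annotation(sc)
    img <- read_calibrated_image(p, um_per_pixel = ann$um_per_pixel)
    dplyr::bind_cols(tibble::tibble(biopsy_id = basename(p)),
                     summarize_biopsy(img, ann, ...))
  })
  dplyr::bind_rows(rows)
}
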