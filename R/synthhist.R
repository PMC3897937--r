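# Synthetic jejunal mucosa generator. Renders finger-like villi standing on
# a mucosal plateau above the muscularis mucosae, with narrow crypt lumens
# opening between villi, as an 8-bit grayscale image (tissue dark, lumen
# bright) plus an exact geometric ground-truth annotation in micrometres.
#
# Coordinate conventions: geometry lives in micrometres with the origin at
# the bottom-left of the canvas and y increasing upward; image matrices are
# row-major with row 1 at the top, so pixel (r, c) has its centre at
# x = (c - 0.5) * um_per_pixel, y = (nrow - r + 0.5) * um_per_pixel.

#' Specification of a synthetic mucosa section
#'
#' Describes the geometry, calibration and noise of one synthetic
#' haematoxylin-and-eosin-like cross section. The defaults draw a mildly
#' blunted jejunal mucosa of the magnitude reported in environmental
#' enteropathy (villous height around 300 um, crypt depth around 160 um).
#'
#' @param n_villi number of villi (>= 1).
#' @param villus_height_um true villous height, base chord to tip (um).
#' @param villus_width_um true maximal villous width (um).
#' @param crypt_depth_um true crypt depth, mouth to base (um).
#' @param muscularis_length_um extent of the muscularis mucosae baseline (um);
#'   the denominator for per-100-um normalisation.
#' @param um_per_pixel pixel calibration (um per pixel, > 0).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (0-255 units).
#' @param orientation_adequate if `FALSE` the villi are rendered tilted
#'   beyond the longitudinal-section tolerance and the ground-truth record is
#'   flagged inadequate.
#' @param profile villus profile family: `"capped"` (rectangle with
#'   semicircular tip; the default) or `"rect"`.
#' @param tilt_deg tilt of each villus axis from the muscularis normal,
#'   degrees. Defaults to 0 when adequate, 45 when not.
#' @param seed integer seed controlling the noise stream.
#' @param tissue_intensity,lumen_intensity the two base intensities (0-255).
#' @param margin_um blank margin around the tissue (um).
#' @param crypt_width_um width of the crypt lumen slot (um).
#' @return an object of class `mucosa_spec` (a validated list).
#' @export
mucosa_spec <- function(n_villi = 3,
                        villus_height_um = 300,
                        villus_width_um = 110,
                        crypt_depth_um = 160,
                        muscularis_length_um = 600,
                        um_per_pixel = 1,
                        noise_sd = 0,
                        orientation_adequate = TRUE,
                        profile = c("capped", "rect"),
                        tilt_deg = if (orientation_adequate) 0 else 45,
                        seed = 1L,
                        tissue_intensity = 60,
                        lumen_intensity = 200,
                        margin_um = 20,
                        crypt_width_um = 10) {
  profile <- match.arg(profile)
  spec <- list(
    n_villi = as.integer(n_villi),
    villus_height_um = villus_height_um,
    villus_width_um = villus_width_um,
    crypt_depth_um = crypt_depth_um,
    muscularis_length_um = muscularis_length_um,
    um_per_pixel = um_per_pixel,
    noise_sd = noise_sd,
    orientation_adequate = isTRUE(orientation_adequate),
    profile = profile,
    tilt_deg = tilt_deg,
    seed = as.integer(seed),
    tissue_intensity = tissue_intensity,
    lumen_intensity = lumen_intensity,
    margin_um = margin_um,
    crypt_width_um = crypt_width_um
  )
  class(spec) <- "mucosa_spec"
  validate_mucosa_spec(spec)
  spec
}

validate_mucosa_spec <- function(spec) {
  lens <- c("villus_height_um", "villus_width_um", "crypt_depth_um",
            "muscularis_length_um", "um_per_pixel")
  for (f in lens) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1 || spec[[f]] <= 0) {
      abort(sprintf("mucosa_spec: '%s' must be a single positive number", f))
    }
  }
  if (spec$n_villi < 1) abort("mucosa_spec: n_villi must be >= 1")
  if (spec$noise_sd < 0) abort("mucosa_spec: noise_sd must be nonnegative")
  if (spec$profile == "capped" &&
      spec$villus_height_um < spec$villus_width_um / 2) {
    abort("mucosa_spec: capped profile needs villus_height_um >= villus_width_um / 2")
  }
  # fit check: villi must sit on the muscularis span without touching,
  # and tilted villi must not leave the canvas
  spacing <- spec$muscularis_length_um / spec$n_villi
  if (spacing < spec$villus_width_um + 2 * spec$crypt_width_um) {
    abort(sprintf(
      "mucosa_spec: geometry cannot fit: %d villi of width %.1f um need more than %.1f um of muscularis",
      spec$n_villi, spec$villus_width_um, spec$muscularis_length_um))
  }
  invisible(spec)
}

# canvas layout shared by the renderer and the annotation builder; the
# canvas is widened on the tilt side so oblique villi are never clipped
mucosa_layout <- function(spec) {
  margin <- spec$margin_um
  L <- spec$muscularis_length_um
  st <- sin(spec$tilt_deg * pi / 180)
  over_l <- spec$villus_height_um * max(0, -st)
  over_r <- spec$villus_height_um * max(0, st)
  x0 <- margin + over_l              # left end of the muscularis span
  y_band0 <- 4                       # bottom of the tissue band
  y_musc <- 10                       # muscularis mucosae line
  y_plateau <- y_musc + spec$crypt_depth_um + 6   # inter-villous surface
  width_um <- L + 2 * margin + over_l + over_r
  height_um <- y_plateau + spec$villus_height_um + margin
  centres <- x0 + (seq_len(spec$n_villi) - 0.5) * L / spec$n_villi
  crypt_x <- if (spec$n_villi > 1) {
    x0 + seq_len(spec$n_villi - 1) * L / spec$n_villi
  } else {
    x0 + L / 4
  }
  list(margin = x0, L = L, y_band0 = y_band0, y_musc = y_musc,
       y_plateau = y_plateau, width_um = width_um, height_um = height_um,
       centres = centres, crypt_x = crypt_x)
}

#' Generate one synthetic mucosa image with ground truth
#'
#' Deterministic for a fixed spec (the seed drives the noise stream). In the
#' noise-free limit the image takes exactly two intensity values, so a global
#' threshold separates tissue from lumen perfectly.
#'
#' @param spec a [mucosa_spec()].
#' @return a list with elements `image` (a `calibrated_image`: `pixels`
#'   matrix, 0-255, row 1 at the top, plus `um_per_pixel`) and `annotation`
#'   (ground truth: villus polygons and base segments, crypt polylines,
#'   muscularis polyline, landmark polylines, and the analytically computed
#'   `true_record` morphometry row).
#' @export
generate_mucosa_image <- function(spec) {
  validate_mucosa_spec(spec)
  lay <- mucosa_layout(spec)
  upp <- spec$um_per_pixel
  nx <- as.integer(ceiling(lay$width_um / upp))
  ny <- as.integer(ceiling(lay$height_um / upp))
  theta <- spec$tilt_deg * pi / 180
  h <- spec$villus_height_um
  w <- spec$villus_width_um
  r <- w / 2
  hs <- if (spec$profile == "capped") h - r else h

  # pixel-centre coordinates, y increasing upward
  xs <- (seq_len(nx) - 0.5) * upp
  ys <- (seq_len(ny) - 0.5) * upp

  inside <- matrix(FALSE, nrow = ny, ncol = nx)   # row iy ~ ys[iy]
  band_rows <- which(ys >= lay$y_band0 & ys <= lay$y_plateau)
  inside[band_rows, ] <- TRUE

  # crypt lumens: slots cut from the plateau down to the crypt base
  for (xc in lay$crypt_x) {
    cols <- which(abs(xs - xc) <= spec$crypt_width_um / 2)
    rows <- which(ys > lay$y_plateau - spec$crypt_depth_um & ys <= lay$y_plateau)
    inside[rows, cols] <- FALSE
  }

  # villi: membership in local (u across, v along axis) coordinates
  ct <- cos(theta); st <- sin(theta)
  for (cx in lay$centres) {
    reach <- h * abs(st) + r + 2 * upp
    cols <- which(abs(xs - cx) <= reach)
    rows <- which(ys > lay$y_plateau - upp & ys <= lay$y_plateau + h * ct + r + upp)
    if (!length(cols) || !length(rows)) next
    du <- xs[cols] - cx
    dv <- ys[rows] - lay$y_plateau
    # v along the axis, u across; inverse rotation of the placement
    U <- outer(dv, du, function(v, u) u * ct - v * st)
    V <- outer(dv, du, function(v, u) u * st + v * ct)
    memb <- if (spec$profile == "rect") {
      V >= 0 & V <= h & abs(U) <= r
    } else {
      (V >= 0 & V <= hs & abs(U) <= r) |
        (V > hs & (U^2 + (V - hs)^2) <= r^2)
    }
    inside[rows, cols] <- inside[rows, cols] | memb
  }

  px <- matrix(spec$lumen_intensity, nrow = ny, ncol = nx)
  px[inside] <- spec$tissue_intensity
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    px <- px + rnorm(length(px), sd = spec$noise_sd)
    px <- matrix(pmin(pmax(px, 0), 255), nrow = ny)
  }
  px <- round(px)
  # flip so row 1 is the top of the image
  px <- px[rev(seq_len(ny)), , drop = FALSE]

  image <- calibrated_image(px, upp)
  annotation <- mucosa_annotation(spec, lay, theta)
  list(image = image, annotation = annotation)
}

#' Construct a calibrated image
#'
#' @param pixels numeric matrix of intensities in 0-255, row 1 at the top.
#' @param um_per_pixel positive scale (identical for both axes).
#' @export
calibrated_image <- function(pixels, um_per_pixel) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels)) abort("pixels must be a numeric matrix")
  if (!is.numeric(um_per_pixel) || um_per_pixel <= 0) {
    abort("um_per_pixel must be a single positive number")
  }
  structure(list(pixels = pixels, um_per_pixel = um_per_pixel),
            class = "calibrated_image")
}

# ground truth: polygons, landmarks and the analytic morphometry record
mucosa_annotation <- function(spec, lay, theta) {
  h <- spec$villus_height_um
  w <- spec$villus_width_um
  ct <- cos(theta); st <- sin(theta)
  polys <- lapply(lay$centres, function(cx) {
    villus_outline(spec$profile, cx, lay$y_plateau, h, w, theta)
  })
  bases <- lapply(lay$centres, function(cx) {
    rbind(c(cx - w / 2 * ct, lay$y_plateau + w / 2 * st),
          c(cx + w / 2 * ct, lay$y_plateau - w / 2 * st))
  })
  crypts <- lapply(lay$crypt_x, function(xc) {
    rbind(c(xc, lay$y_plateau), c(xc, lay$y_plateau - spec$crypt_depth_um))
  })
  muscularis <- rbind(c(lay$margin, lay$y_musc),
                      c(lay$margin + lay$L, lay$y_musc))
  # landmark polylines, as an analyst would draw them on an adequate section
  vh_polylines <- lapply(lay$centres, function(cx) {
    tip <- c(cx + h * st, lay$y_plateau + h * ct)
    rbind(tip, c(cx, lay$y_plateau))
  })
  vw_y <- lay$y_plateau + min(h / 2, h - w / 2) # widest level of the profile
  vw_segment <- rbind(c(lay$centres[1] - w / 2, vw_y),
                      c(lay$centres[1] + w / 2, vw_y))

  tr <- villus_truth(spec$profile, h, w)
  L <- spec$muscularis_length_um
  true_record <- tibble::tibble(
    VH = h, CD = spec$crypt_depth_um, VW = w,
    VP_per100 = spec$n_villi * tr$perimeter / L * 100,
    VA_per100 = spec$n_villi * tr$area / L * 100,
    muscularis_um = L,
    adequate = spec$orientation_adequate
  )

  structure(list(
    um_per_pixel = spec$um_per_pixel,
    villus_polygons = polys,
    villus_base_segments = bases,
    crypt_polylines = crypts,
    muscularis_polyline = muscularis,
    landmarks = list(vh_polylines = vh_polylines,
                     cd_polylines = crypts,
                     vw_segment = vw_segment,
                     muscularis_polyline = muscularis),
    true_record = true_record,
    orientation_adequate = spec$orientation_adequate,
    canvas_um = c(width = lay$width_um, height = lay$height_um)
  ), class = "mucosa_annotation")
}

#' Render a batch of synthetic sections to disk
#'
#' Writes one 8-bit grayscale PNG and one JSON annotation sidecar per spec
#' and returns a manifest. All specs are validated before anything is
#' written, so an invalid spec never leaves partial output behind.
#'
#' @param specs list of [mucosa_spec()] objects (may be empty).
#' @param out_dir output directory (created if needed).
#' @return a tibble manifest with one row per image: `image_path`,
#'   `sidecar_path`, `seed`, `VH`, `CD`, `VW`, `VP_per100`, `VA_per100`,
#'   `adequate`. Also written to `manifest.csv` in `out_dir`.
#' @export
render_batch <- function(specs, out_dir) {
  stopifnot(is.list(specs))
  for (i in seq_along(specs)) {
    tryCatch(validate_mucosa_spec(specs[[i]]),
             error = function(e) abort(sprintf("spec %d is invalid: %s", i,
                                               conditionMessage(e))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))
  rows <- purrr::imap(specs, function(spec, i) {
    img_name <- sprintf("section_%03d.png", i)
    sc_name <- sprintf("section_%03d.json", i)
    gen <- generate_mucosa_image(spec)
    write_calibrated_image(gen$image, file.path(out_dir, img_name))
    write_annotation(gen$annotation, file.path(out_dir, sc_name))
    # paths are stored relative to the manifest so runs are relocatable
    dplyr::bind_cols(
      tibble::tibble(image_path = img_name, sidecar_path = sc_name,
                     seed = spec$seed),
      gen$annotation$true_record
    )
  })
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0) {
    manifest <- tibble::tibble(image_path = character(), sidecar_path = character(),
                               seed = integer(), VH = double(), CD = double(),
                               VW = double(), VP_per100 = double(),
                               VA_per100 = double(), muscularis_um = double(),
                               adequate = logical())
  }
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Write a calibrated image as 8-bit grayscale PNG (or TIFF)
#'
#' The pixel scale is stored in the JSON sidecar, not the image file.
#' @param image a `calibrated_image`.
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  m <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("the 'tiff' package is needed to write TIFF files")
    }
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}

#' Read a calibrated image written by [write_calibrated_image()]
#' @param path image path.
#' @param um_per_pixel pixel calibration; if `NULL`, taken from a JSON
#'   sidecar with the same stem.
#' @export
read_calibrated_image <- function(path, um_per_pixel = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("the 'tiff' package is needed to read TIFF files")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(m)) == 3) {         # RGB -> luminance grayscale
    m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
  }
  if (is.null(um_per_pixel)) {
    sc <- sub("\\.[^.]+$", ".json", path)
    if (!file.exists(sc)) abort(sprintf("no um_per_pixel given and no sidecar at '%s'", sc))
    um_per_pixel <- jsonlite::read_json(sc)$um_per_pixel[[1]]
  }
  calibrated_image(round(m * 255), um_per_pixel)
}

#' Write a ground-truth annotation sidecar as JSON
#' @param annotation a `mucosa_annotation`.
#' @param path output .json path.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "mucosa_annotation"))
  payload <- list(
    um_per_pixel = annotation$um_per_pixel,
    villus_polygons = lapply(annotation$villus_polygons, unname),
    villus_base_segments = lapply(annotation$villus_base_segments, unname),
    crypt_polylines = lapply(annotation$crypt_polylines, unname),
    muscularis_polyline = unname(annotation$muscularis_polyline),
    landmarks = list(
      vh_polylines = lapply(annotation$landmarks$vh_polylines, unname),
      cd_polylines = lapply(annotation$landmarks$cd_polylines, unname),
      vw_segment = unname(annotation$landmarks$vw_segment),
      muscularis_polyline = unname(annotation$landmarks$muscularis_polyline)
    ),
    true_record = as.list(annotation$true_record),
    orientation_adequate = annotation$orientation_adequate,
    canvas_um = as.list(annotation$canvas_um)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation sidecar
#' @param path .json path written by [write_annotation()].
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  one_mat <- function(m) {
    as_xy(do.call(rbind, lapply(m, function(row) unlist(row, use.names = FALSE))))
  }
  to_mats <- function(x) lapply(x, one_mat)
  structure(list(
    um_per_pixel = j$um_per_pixel,
    villus_polygons = to_mats(j$villus_polygons),
    villus_base_segments = to_mats(j$villus_base_segments),
    crypt_polylines = to_mats(j$crypt_polylines),
    muscularis_polyline = one_mat(j$muscularis_polyline),
    landmarks = list(
      vh_polylines = to_mats(j$landmarks$vh_polylines),
      cd_polylines = to_mats(j$landmarks$cd_polylines),
      vw_segment = one_mat(j$landmarks$vw_segment),
      muscularis_polyline = one_mat(j$landmarks$muscularis_polyline)
    ),
    true_record = tibble::as_tibble(lapply(j$true_record, unlist)),
    orientation_adequate = isTRUE(j$orientation_adequate),
    canvas_um = unlist(j$canvas_um)
  ), class = "mucosa_annotation")
}
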