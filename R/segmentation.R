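#' Colour-classification thresholds for stained-slice segmentation
#'
#' Fixed hue/saturation/value thresholds tuned to the default render palette
#' (see [render_params()]); all exposed so that real photographs with other
#' lighting can be accommodated. Hue is on the 0..1 circle (red wraps around
#' 0). Morphological cleanup uses a disc of `morph_radius` pixels — 0.3 mm at
#' the default 10 px/mm, below the resolution of any area claim.
#'
#' @param white_s_max,white_v_min White (TTC-unstained) class: saturation
#'   below / value above.
#' @param red_hue_lo,red_hue_hi Red hue band: hue above `red_hue_lo` or below
#'   `red_hue_hi`.
#' @param red_s_min,red_v_min,red_v_max Deep-red class saturation/value gates.
#' @param melanin_v_max Melanin class: value below this (dark pixels).
#' @param morph_radius Disc radius in px for opening-then-closing.
#' @param red_adjacency_px Dilation radius within which red pixels must touch
#'   the white component.
#' @param min_component_px,component_frac Connected components smaller than
#'   `min_component_px` or than `component_frac` of the largest are dropped
#'   as speckle.
#' @export
seg_thresholds <- function(white_s_max = 0.16, white_v_min = 0.88,
                           red_hue_lo = 0.92, red_hue_hi = 0.06,
                           red_s_min = 0.45, red_v_min = 0.25,
                           red_v_max = 0.85, melanin_v_max = 0.60,
                           morph_radius = 3, red_adjacency_px = 5,
                           min_component_px = 64, component_frac = 0.05) {
  structure(as.list(environment()), class = "seg_thresholds")
}

#' Calibrate the image scale from the rendered ruler
#'
#' Estimates pixels-per-mm from the periodicity of the ruler tick marks: rows
#' containing many short dark runs are identified, tick centres are taken
#' from the run midpoints of the best such row, and the tick pitch is
#' estimated robustly from the centre spacings (gaps are rounded to integer
#' multiples of the median pitch so missing ticks do not bias the estimate).
#' A user-supplied scale bypasses detection.
#'
#' @param image Numeric RGB array (`[rows, cols, 3]`, values in 0..1) or a
#'   `stain_bundle`.
#' @param ruler A [ruler_spec()] giving the tick pitch in mm.
#' @param pixels_per_mm Optional user override; returned verbatim with
#'   `source = "user-supplied"`.
#' @return An object of class `scale_calibration` with `pixels_per_mm` and
#'   `source` (`"ruler-detected"` or `"user-supplied"`).
#' @export
calibrate_scale <- function(image, ruler = ruler_spec(),
                            pixels_per_mm = NULL) {
  if (!is.null(pixels_per_mm)) {
    stopifnot(pixels_per_mm > 0)
    return(structure(list(pixels_per_mm = pixels_per_mm,
                          source = "user-supplied"),
                     class = "scale_calibration"))
  }
  img <- if (inherits(image, "stain_bundle")) image$image else image
  stopifnot(is.array(img), length(dim(img)) == 3L)
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  dark <- gray < 0.35

  best <- NULL; best_n <- 0L
  for (i in seq_len(nrow(dark))) {
    r <- rle(dark[i, ])
    short <- r$values & r$lengths <= 5L
    n <- sum(short)
    if (n >= 15L && n > best_n) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      best <- (starts[short] + ends[short]) / 2
      best_n <- n
    }
  }
  if (is.null(best))
    stop("no ruler found in the image and no pixels_per_mm override supplied")
  d <- diff(sort(best))
  pitch0 <- stats::median(d)
  units <- pmax(1, round(d / pitch0))
  pitch <- sum(d) / sum(units)
  structure(list(pixels_per_mm = pitch / ruler$tick_mm,
                 source = "ruler-detected"),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale: %.3f px/mm (%s)\n", x$pixels_per_mm, x$source))
  invisible(x)
}

#' Convert a mask pixel count to an area
#'
#' `count / pixels_per_mm^2 / 100`, in cm^2. Pixels belong to a class by
#' their centre value; counts are unweighted.
#'
#' @param mask Logical matrix.
#' @param calib A `scale_calibration`.
#' @return Area in cm^2.
#' @export
measure_area <- function(mask, calib) {
  stopifnot(inherits(calib, "scale_calibration"))
  sum(mask) / calib$pixels_per_mm^2 / 100
}

hsv_planes <- function(img) {
  m <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
             as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  d <- dim(img)[1:2]
  list(h = matrix(hsv[1L, ], d[1L], d[2L]),
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ], d[1L], d[2L]))
}

morph_clean <- function(mask, radius) {
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)
  m > 0.5
}

# drop speckle components; keep every component at least `frac` of the
# largest and at least `min_px` pixels
keep_main_components <- function(mask, min_px, frac) {
  if (!any(mask)) return(list(mask = mask, n_kept = 0L, sizes = integer(0)))
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  keep <- which(sizes >= max(min_px, frac * max(sizes)))
  list(mask = matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask)),
       n_kept = length(keep), sizes = sizes[keep])
}

touches_border <- function(mask) {
  any(mask[1L, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1L]) || any(mask[, ncol(mask)])
}

#' Segment a TTC-stained slice photograph
#'
#' Classifies pixels in hue/saturation/value space: the TTC-unstained white
#' class is low saturation and high value; the deep-red class is red-band
#' hue with saturation above the background. Each class is cleaned by
#' morphological opening then closing, speckle components are dropped (the
#' ablation zone is one region between the electrodes, splitting into at
#' most a few lobes at low voltage), and red pixels are kept only within a
#' small dilation of the white component. Areas are converted to cm^2 with
#' the calibration.
#'
#' @param image RGB array in 0..1 (or a `stain_bundle`).
#' @param calib A `scale_calibration` from [calibrate_scale()].
#' @param thresholds A [seg_thresholds()].
#' @return An object of class `segmentation_result`: logical `white_mask`,
#'   `red_mask`, `melanin_mask` (empty here), named `areas` in cm^2, and
#'   `qc_flags` (e.g. `"empty-white"`, `"multiple-components"`,
#'   `"touching-border"`). An empty white class yields zero areas and a QC
#'   flag, not an error.
#' @export
segment_ttc <- function(image, calib, thresholds = seg_thresholds()) {
  img <- if (inherits(image, "stain_bundle")) image$image else image
  stopifnot(inherits(calib, "scale_calibration"))
  p <- hsv_planes(img)
  th <- thresholds
  qc <- character(0)

  white <- p$s < th$white_s_max & p$v > th$white_v_min
  white <- morph_clean(white, th$morph_radius)
  wk <- keep_main_components(white, th$min_component_px, th$component_frac)
  white <- wk$mask
  if (!any(white)) qc <- c(qc, "empty-white")
  if (wk$n_kept > 1L) qc <- c(qc, "multiple-components")
  if (any(white) && touches_border(white)) qc <- c(qc, "touching-border")

  red <- (p$h > th$red_hue_lo | p$h < th$red_hue_hi) &
    p$s > th$red_s_min & p$v > th$red_v_min & p$v < th$red_v_max
  red <- morph_clean(red, th$morph_radius)
  if (any(red)) {
    if (any(white)) {
      brush <- EBImage::makeBrush(2L * th$red_adjacency_px + 1L, "disc")
      near_white <- EBImage::dilate(white * 1, brush) > 0.5
      lab <- EBImage::bwlabel(red * 1)
      keep <- unique(as.integer(lab[near_white & lab > 0]))
      red <- matrix(as.integer(lab) %in% keep[keep > 0], nrow(red), ncol(red))
      red <- keep_main_components(red, th$min_component_px,
                                  th$component_frac)$mask
    } else {
      red <- matrix(FALSE, nrow(red), ncol(red))
      qc <- c(qc, "red-without-white")
    }
  }

  structure(list(white_mask = white, red_mask = red & !white,
                 melanin_mask = matrix(FALSE, nrow(white), ncol(white)),
                 areas = c(white = measure_area(white, calib),
                           red = measure_area(red & !white, calib),
                           melanin = 0),
                 qc_flags = qc, calib = calib),
            class = "segmentation_result")
}

#' Segment a melanin-accumulation slice photograph
#'
#' The melanin class is the dark (low-value) pixels; the same morphological
#' cleanup and component rule as [segment_ttc()] apply. Faint early-time
#' accumulation whose darkness has not yet crossed the value threshold is
#' not detected — mirroring the practical invisibility of the ablation zone
#' in the first hours after pulsing.
#'
#' @inheritParams segment_ttc
#' @return A `segmentation_result` with the melanin mask and area.
#' @export
segment_melanin <- function(image, calib, thresholds = seg_thresholds()) {
  img <- if (inherits(image, "stain_bundle")) image$image else image
  stopifnot(inherits(calib, "scale_calibration"))
  p <- hsv_planes(img)
  th <- thresholds
  qc <- character(0)

  mel <- p$v < th$melanin_v_max
  mel <- morph_clean(mel, th$morph_radius)
  mk <- keep_main_components(mel, th$min_component_px, th$component_frac)
  mel <- mk$mask
  if (!any(mel)) qc <- c(qc, "empty-melanin")
  if (mk$n_kept > 1L) qc <- c(qc, "multiple-components")
  if (any(mel) && touches_border(mel)) qc <- c(qc, "touching-border")

  structure(list(white_mask = matrix(FALSE, nrow(mel), ncol(mel)),
                 red_mask = matrix(FALSE, nrow(mel), ncol(mel)),
                 melanin_mask = mel,
                 areas = c(white = 0, red = 0,
                           melanin = measure_area(mel, calib)),
                 qc_flags = qc, calib = calib),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation: white %.3f, red %.3f, melanin %.3f cm2%s\n",
              x$areas["white"], x$areas["red"], x$areas["melanin"],
              if (length(x$qc_flags))
                paste0(" [", paste(x$qc_flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Read a stained-slice image from PNG or TIFF
#'
#' @param path File path; format chosen by extension.
#' @return Numeric RGB array in 0..1.
#' @export
read_stain_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
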