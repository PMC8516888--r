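#' Write a field map as a grayscale PNG with a sidecar header
#'
#' The magnitude is linearly scaled to 0..1 for the raster; the sidecar text
#' file records the grid spacing, origin convention, units, drive voltage
#' and the scaling so the raster is quantitatively interpretable.
#'
#' @param fm A `field_map`.
#' @param path Output PNG path; the sidecar is written next to it with a
#'   `.txt` extension.
#' @return Invisibly, the sidecar path.
#' @export
write_field_png <- function(fm, path) {
  stopifnot(inherits(fm, "field_map"))
  mx <- max(fm$magnitude)
  img <- if (mx > 0) t(fm$magnitude[, rev(seq_len(fm$grid$ny))]) / mx else
    t(fm$magnitude[, rev(seq_len(fm$grid$ny))])
  png::writePNG(img, path)
  side <- sub("\\.png$", ".txt", path)
  writeLines(c(
    sprintf("grid_spacing_mm: %g", fm$grid$spacing_h),
    sprintf("width_mm: %g", fm$grid$width),
    sprintf("height_mm: %g", fm$grid$height),
    "origin: midpoint-between-electrode-axes; row 1 = top (+y)",
    "units: V/cm",
    sprintf("v0_V: %g", fm$v0),
    sprintf("max_magnitude_V_per_cm: %.10g", mx),
    "encoding: gray = magnitude / max_magnitude"), side)
  invisible(side)
}

#' Write contour polylines to CSV
#'
#' @param polylines Data frame with `x_mm`, `y_mm`, `contour_id` (as
#'   produced by [isocontour_area()]).
#' @param path Output CSV path.
#' @export
write_polylines_csv <- function(polylines, path) {
  utils::write.csv(polylines, path, row.names = FALSE)
  invisible(path)
}

#' Write a stain bundle's image and ground-truth masks as PNG
#'
#' Masks are written as 0/255 grayscale PNGs alongside the image.
#'
#' @param bundle A `stain_bundle`.
#' @param dir Output directory.
#' @param id File stem.
#' @return Character vector of paths written.
#' @export
write_bundle_png <- function(bundle, dir, id) {
  stopifnot(inherits(bundle, "stain_bundle"))
  paths <- file.path(dir, paste0(id, ".png"))
  png::writePNG(bundle$image, paths)
  for (mk in grep("^truth_.*_mask$", names(bundle), value = TRUE)) {
    p <- file.path(dir, paste0(id, "_", sub("^truth_(.*)_mask$", "\\1", mk),
                               "_mask.png"))
    png::writePNG(bundle[[mk]] * 1.0, p)
    paths <- c(paths, p)
  }
  paths
}

#' Render a correlation matrix as a heat-map PNG
#'
#' A simple deterministic raster: each cell is coloured on a blue-white-red
#' scale over r in [-1, 1] and upscaled by an integer factor. (Publication
#' graphics are better made with a plotting package; this writer exists so
#' pipeline outputs are byte-reproducible.)
#'
#' @param cm A `correlation_matrix`.
#' @param path Output PNG path.
#' @param cell_px Cell edge length in pixels.
#' @export
write_heatmap_png <- function(cm, path, cell_px = 48L) {
  stopifnot(inherits(cm, "correlation_matrix"))
  r <- cm$r
  k <- nrow(r)
  img <- array(0, dim = c(k * cell_px, k * cell_px, 3L))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v <- max(-1, min(1, r[i, j]))
    col <- if (v >= 0) c(1, 1 - v, 1 - v) else c(1 + v, 1 + v, 1)
    rows <- (i - 1L) * cell_px + seq_len(cell_px)
    cols <- (j - 1L) * cell_px + seq_len(cell_px)
    for (ch in 1:3) img[rows, cols, ch] <- col[ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

# manifest: relative path, size, md5 for every file under dir (excluding the
# manifest itself), plus run metadata
write_manifest <- function(dir, meta, path = file.path(dir, "manifest.json")) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        basename(path)))
  abs <- file.path(dir, files)
  entries <- lapply(seq_along(files), function(i) {
    list(path = files[i],
         bytes = file.info(abs[i])$size,
         md5 = unname(tools::md5sum(abs[i])))
  })
  jsonlite::write_json(list(meta = meta, files = entries), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
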