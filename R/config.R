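#' Needle-electrode pair geometry and drive voltage
#'
#' Describes the two parallel stainless-steel needle electrodes used to pulse
#' the tuber: their radius, centre-to-centre spacing, exposed (non-insulated)
#' length, and the applied potential difference. The exposure length is
#' recorded for bookkeeping but unused by the two-dimensional cross-section
#' model, which assumes the exposed length is large compared with the
#' electrode spacing.
#'
#' Protocols in this field are labelled by their voltage-to-distance ratio
#' ("X V/cm"); with the standard 10-mm (1-cm) gap the applied voltage in
#' volts equals the field setting, so `applied_voltage_V0 = 1500` corresponds
#' to the 1500 V/cm condition.
#'
#' @param radius_a Electrode radius in mm (default 0.5, i.e. 1-mm outer
#'   diameter).
#' @param center_spacing_d Centre-to-centre electrode spacing in mm
#'   (default 10).
#' @param applied_voltage_V0 Potential of the driven electrode in volts; the
#'   other electrode is grounded. Must be non-negative.
#' @param exposure_length Exposed electrode length in mm (default 10);
#'   carried but unused by the 2-D model.
#' @return An object of class `electrode_config`.
#' @examples
#' electrode_config(applied_voltage_V0 = 1500)
#' @export
electrode_config <- function(radius_a = 0.5, center_spacing_d = 10,
                             applied_voltage_V0 = 1000, exposure_length = 10) {
  stopifnot(is.numeric(radius_a), length(radius_a) == 1L, radius_a > 0)
  stopifnot(is.numeric(center_spacing_d), length(center_spacing_d) == 1L)
  if (center_spacing_d <= 2 * radius_a)
    stop("center_spacing_d must exceed the electrode diameter (2 * radius_a)")
  stopifnot(is.numeric(applied_voltage_V0), length(applied_voltage_V0) == 1L,
            applied_voltage_V0 >= 0)
  structure(list(radius_a = radius_a,
                 center_spacing_d = center_spacing_d,
                 applied_voltage_V0 = applied_voltage_V0,
                 exposure_length = exposure_length),
            class = "electrode_config")
}

#' Regular finite-difference grid over the slice cross-section
#'
#' The grid is centred on the midpoint between the two electrode axes, with
#' the x-axis running through both axes. Width and height are snapped to an
#' even number of grid cells so that a node sits exactly at the origin and
#' the node coordinates are mirror-symmetric, which keeps the discretized
#' electrode disks exactly symmetric for symmetric geometries.
#'
#' @param width,height Domain extent in mm (default 60, the nominal width of
#'   a large tuber).
#' @param spacing_h Node spacing in mm (default 0.1).
#' @return An object of class `grid_spec` with node coordinates `x`, `y` (mm).
#' @export
grid_spec <- function(width = 60, height = 60, spacing_h = 0.1) {
  stopifnot(spacing_h > 0, width > 0, height > 0)
  half_nx <- max(1L, round(width / (2 * spacing_h)))
  half_ny <- max(1L, round(height / (2 * spacing_h)))
  x <- (seq_len(2L * half_nx + 1L) - (half_nx + 1L)) * spacing_h
  y <- (seq_len(2L * half_ny + 1L) - (half_ny + 1L)) * spacing_h
  structure(list(width = 2 * half_nx * spacing_h,
                 height = 2 * half_ny * spacing_h,
                 spacing_h = spacing_h,
                 origin = "midpoint-between-electrode-axes",
                 x = x, y = y, nx = length(x), ny = length(y)),
            class = "grid_spec")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("electrode pair: a = %g mm, d = %g mm, V0 = %g V, exposure = %g mm\n",
              x$radius_a, x$center_spacing_d, x$applied_voltage_V0,
              x$exposure_length))
  invisible(x)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %g x %g mm, h = %g mm (%d x %d nodes)\n",
              x$width, x$height, x$spacing_h, x$nx, x$ny))
  invisible(x)
}

# Boolean node masks for the two electrode disks. A node belongs to an
# electrode when its centre lies within the circle; a relative tolerance
# absorbs floating-point ties for nodes exactly on the circle.
electrode_masks <- function(config, grid) {
  cx <- config$center_spacing_d / 2
  a2 <- config$radius_a^2 * (1 + 1e-9)
  X <- matrix(grid$x, grid$nx, grid$ny)
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  list(pos = (X - cx)^2 + Y^2 <= a2,
       neg = (X + cx)^2 + Y^2 <= a2)
}
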