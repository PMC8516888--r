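#' Electric-field magnitude from a solved potential
#'
#' Differentiates the potential by central differences (one-sided at the
#' domain boundary and at nodes adjacent to an electrode) and returns the
#' field magnitude `|E| = |grad phi|` in V/cm (the grid is in mm, so V/mm
#' values are multiplied by 10). The magnitude is set to zero inside the
#' electrode disks, where the potential is constant.
#'
#' @param pf A `potential_field` from [solve_laplace()].
#' @return An object of class `field_map`: grid, `magnitude` matrix (V/cm),
#'   `v0`, and the electrode mask.
#' @export
field_magnitude <- function(pf) {
  stopifnot(inherits(pf, "potential_field"))
  phi <- pf$phi
  elec <- pf$electrode_mask
  h <- pf$grid$spacing_h
  nx <- nrow(phi); ny <- ncol(phi)

  Ex <- matrix(0, nx, ny)
  Ex[2:(nx - 1L), ] <- (phi[3:nx, ] - phi[1:(nx - 2L), ]) / (2 * h)
  Ex[1L, ] <- (phi[2L, ] - phi[1L, ]) / h
  Ex[nx, ] <- (phi[nx, ] - phi[nx - 1L, ]) / h
  Ey <- matrix(0, nx, ny)
  Ey[, 2:(ny - 1L)] <- (phi[, 3:ny] - phi[, 1:(ny - 2L)]) / (2 * h)
  Ey[, 1L] <- (phi[, 2L] - phi[, 1L]) / h
  Ey[, ny] <- (phi[, ny] - phi[, ny - 1L]) / h

  # one-sided differences next to electrode nodes (interior only; electrodes
  # are required to sit away from the domain boundary)
  ep <- rbind(elec[-1L, ], FALSE); emn <- rbind(FALSE, elec[-nx, ])
  fb <- which(!elec & ep & !emn); Ex[fb] <- (phi[fb] - phi[fb - 1L]) / h
  ff <- which(!elec & emn & !ep); Ex[ff] <- (phi[ff + 1L] - phi[ff]) / h
  Ex[!elec & emn & ep] <- 0
  ep <- cbind(elec[, -1L], FALSE); emn <- cbind(FALSE, elec[, -ny])
  fb <- which(!elec & ep & !emn); Ey[fb] <- (phi[fb] - phi[fb - nx]) / h
  ff <- which(!elec & emn & !ep); Ey[ff] <- (phi[ff + nx] - phi[ff]) / h
  Ey[!elec & emn & ep] <- 0

  mag <- 10 * sqrt(Ex^2 + Ey^2)  # V/mm -> V/cm
  mag[elec] <- 0
  structure(list(grid = pf$grid, magnitude = mag,
                 v0 = pf$config$applied_voltage_V0,
                 electrode_mask = elec, config = pf$config),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field map: %d x %d nodes, V0 = %g V, max |E| = %.1f V/cm\n",
              x$grid$nx, x$grid$ny, x$v0, max(x$magnitude)))
  invisible(x)
}

#' Area enclosed by an iso-field contour
#'
#' Counts grid nodes whose field magnitude meets or exceeds `threshold` and
#' converts the node count to an area (`count * h^2`, reported in cm^2).
#' Contour polylines at the threshold level are extracted by marching
#' squares for rendering and export.
#'
#' @param fm A `field_map` from [field_magnitude()].
#' @param threshold Iso-field level in V/cm; must be positive.
#' @param exclude_electrodes If `TRUE` (default) the electrode interiors are
#'   not counted; if `FALSE` they are counted as part of the enclosed region
#'   (the field is zero inside a conductor, but physically the electrode
#'   cross-section lies inside the ablation core).
#' @return A list with `area_cm2`, `n_nodes`, `threshold`, and `polylines`
#'   (a data frame with columns `x_mm`, `y_mm`, `contour_id`; empty when the
#'   threshold exceeds the grid maximum).
#' @export
isocontour_area <- function(fm, threshold, exclude_electrodes = TRUE) {
  stopifnot(inherits(fm, "field_map"), is.numeric(threshold),
            length(threshold) == 1L, threshold > 0)
  sel <- fm$magnitude >= threshold
  if (!exclude_electrodes) sel <- sel | fm$electrode_mask
  n <- sum(sel)
  h <- fm$grid$spacing_h
  cl <- grDevices::contourLines(fm$grid$x, fm$grid$y, fm$magnitude,
                                levels = threshold)
  poly <- if (length(cl) == 0L) {
    data.frame(x_mm = numeric(0), y_mm = numeric(0), contour_id = integer(0))
  } else {
    do.call(rbind, lapply(seq_along(cl), function(k)
      data.frame(x_mm = cl[[k]]$x, y_mm = cl[[k]]$y, contour_id = k)))
  }
  list(area_cm2 = n * h^2 / 100, n_nodes = n, threshold = threshold,
       polylines = poly)
}

#' Predict IRE and reversible-electroporation zones from a field map
#'
#' Thresholds the field magnitude into the predicted irreversible-ablation
#' core (`|E| >= ire_threshold`) and the surrounding reversible annulus
#' (`re_threshold <= |E| < ire_threshold`). The default thresholds, 250 and
#' 100 V/cm, are the contour levels conventionally drawn against ablation
#' boundaries in this model system; both are configurable and neither is
#' asserted as ground truth.
#'
#' @param fm A `field_map`.
#' @param ire_threshold,re_threshold Thresholds in V/cm with
#'   `re_threshold < ire_threshold`.
#' @return An object of class `ablation_zones` with disjoint logical masks
#'   `ire_mask` and `re_mask`, areas `ire_area_cm2` and `re_area_cm2`
#'   (node count times `h^2`), the thresholds, and the field map carried for
#'   downstream rendering.
#' @export
predict_zones <- function(fm, ire_threshold = 250, re_threshold = 100) {
  stopifnot(inherits(fm, "field_map"))
  if (!(re_threshold < ire_threshold))
    stop("re_threshold must be strictly below ire_threshold")
  if (re_threshold <= 0) stop("thresholds must be positive")
  mag <- fm$magnitude
  ire <- mag >= ire_threshold
  re <- mag >= re_threshold & !ire
  h <- fm$grid$spacing_h
  structure(list(ire_mask = ire, re_mask = re,
                 ire_area_cm2 = sum(ire) * h^2 / 100,
                 re_area_cm2 = sum(re) * h^2 / 100,
                 thresholds = c(ire = ire_threshold, re = re_threshold),
                 grid = fm$grid, magnitude = mag,
                 electrode_mask = fm$electrode_mask, v0 = fm$v0),
            class = "ablation_zones")
}

#' @export
print.ablation_zones <- function(x, ...) {
  cat(sprintf(
    "ablation zones at V0 = %g V: IRE (>= %g V/cm) %.3f cm2, RE [%g, %g) %.3f cm2\n",
    x$v0, x$thresholds["ire"], x$ire_area_cm2, x$thresholds["re"],
    x$thresholds["ire"], x$re_area_cm2))
  invisible(x)
}

#' Rescale a field map to a different drive voltage
#'
#' The Laplace problem is linear in the drive voltage, so a solved field at
#' one voltage determines the field at any other exactly; rescaling avoids
#' re-solving when sweeping voltages over a fixed geometry.
#'
#' @param fm A `field_map`.
#' @param v0_new New drive voltage in volts (the source map must have
#'   `v0 > 0`).
#' @return The rescaled `field_map`.
#' @export
scale_field_map <- function(fm, v0_new) {
  stopifnot(inherits(fm, "field_map"), v0_new >= 0, fm$v0 > 0)
  fm$magnitude <- fm$magnitude * (v0_new / fm$v0)
  fm$v0 <- v0_new
  fm$config$applied_voltage_V0 <- v0_new
  fm
}
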