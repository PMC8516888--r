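#' Rendering parameters for synthetic stained-slice photographs
#'
#' Controls the raster scale, the palette, the per-channel Gaussian noise,
#' and the ruler drawn into each frame. The default palette (tan tuber
#' flesh, near-white TTC-unstained core, deep-red formazan annulus, near-black
#' melanin) was chosen for unambiguous colour segmentation and is stated
#' explicitly so that measured areas are reproducible; a minimum pairwise
#' channel separation is enforced so segmentation stays well-posed.
#'
#' @param pixels_per_mm Raster scale (default 10).
#' @param background_color,white_core_color,deep_red_color,melanin_color RGB
#'   triplets in 0..255.
#' @param noise_sigma Per-channel Gaussian noise standard deviation on the
#'   0..255 scale (default 8).
#' @param ruler A [ruler_spec()] describing the calibration ruler drawn
#'   outside the tissue region.
#' @return An object of class `render_params`.
#' @export
render_params <- function(pixels_per_mm = 10,
                          background_color = c(210, 190, 150),
                          white_core_color = c(245, 243, 238),
                          deep_red_color = c(150, 30, 40),
                          melanin_color = c(40, 35, 30),
                          noise_sigma = 8,
                          ruler = ruler_spec()) {
  stopifnot(pixels_per_mm > 0, noise_sigma >= 0)
  cols <- list(background_color, white_core_color, deep_red_color,
               melanin_color)
  stopifnot(all(vapply(cols, length, 1L) == 3L))
  for (i in 1:3) for (j in (i + 1):4)
    if (max(abs(cols[[i]] - cols[[j]])) < 20)
      stop("palette colors must differ by at least 20 in some channel")
  structure(list(pixels_per_mm = pixels_per_mm,
                 background_color = background_color,
                 white_core_color = white_core_color,
                 deep_red_color = deep_red_color,
                 melanin_color = melanin_color,
                 noise_sigma = noise_sigma,
                 ruler = ruler),
            class = "render_params")
}

#' Ruler drawn into synthetic frames
#'
#' A strip appended below the tissue region carrying tick marks at a known
#' millimetre pitch; [calibrate_scale()] recovers the image scale from the
#' tick periodicity, emulating the set-the-distance-with-a-ruler step of
#' manual image analysis.
#'
#' @param tick_mm Tick pitch in mm (default 1).
#' @param height_mm Strip height in mm (default 4).
#' @param major_every_mm Pitch of the taller major ticks in mm (default 10).
#' @export
ruler_spec <- function(tick_mm = 1, height_mm = 4, major_every_mm = 10) {
  stopifnot(tick_mm > 0, height_mm > 0, major_every_mm >= tick_mm)
  structure(list(tick_mm = tick_mm, height_mm = height_mm,
                 major_every_mm = major_every_mm),
            class = "ruler_spec")
}

#' Star-shaped inner-medulla distortion parameters
#'
#' The heterogeneous inner medullar zone of the tuber distorts the melanin
#' ablation area into a star shape. The boundary radius is modulated as
#' `r(theta) * (1 + amplitude * cos(lobes * theta + phase))`, with the mean
#' radius renormalized so the enclosed area is preserved; the phase is drawn
#' from the bundle seed. Applied to melanin renders by default; TTC white
#' areas are much less affected and are rendered undistorted unless a star
#' is passed explicitly.
#'
#' @param amplitude Fractional radius modulation in `[0, 1)` (default 0.15).
#' @param lobes Number of lobes, at least 3 (default 5).
#' @export
star_params <- function(amplitude = 0.15, lobes = 5) {
  if (!(amplitude >= 0 && amplitude < 1))
    stop("amplitude must be in [0, 1)")
  if (lobes < 3) stop("lobes must be >= 3")
  structure(list(amplitude = amplitude, lobes = lobes), class = "star_params")
}

# pixel-centre coordinates of the tissue frame (row 1 = top of frame)
pixel_grid <- function(grid, ppm) {
  nxp <- round(grid$width * ppm)
  nyp <- round(grid$height * ppm)
  list(nx = nxp, ny = nyp,
       x = -grid$width / 2 + (seq_len(nxp) - 0.5) / ppm,
       y = grid$height / 2 - (seq_len(nyp) - 0.5) / ppm)
}

# bilinear interpolation of a grid field at arbitrary points (mm)
bilinear_sample <- function(grid, values, qx, qy) {
  h <- grid$spacing_h
  tx <- pmin(pmax((qx - grid$x[1L]) / h, 0), grid$nx - 1L)
  ty <- pmin(pmax((qy - grid$y[1L]) / h, 0), grid$ny - 1L)
  i0 <- pmin(floor(tx), grid$nx - 2L); fx <- tx - i0
  j0 <- pmin(floor(ty), grid$ny - 2L); fy <- ty - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  v00 <- values[cbind(i0 + 1L, j0 + 1L)]
  v10 <- values[cbind(i0 + 2L, j0 + 1L)]
  v01 <- values[cbind(i0 + 1L, j0 + 2L)]
  v11 <- values[cbind(i0 + 2L, j0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

# sample |E| at the pixel centres of the tissue frame, optionally through a
# star-shaped coordinate warp about the inter-electrode midpoint; pixels whose
# (source) centre falls inside an electrode disk are assigned +Inf so they
# always join the ablation core (electrode puncture marks are not rendered)
sample_field_pixels <- function(zones, ppm, star = NULL, phase = 0) {
  pg <- pixel_grid(zones$grid, ppm)
  qx <- rep(pg$x, each = pg$ny)
  qy <- rep(pg$y, times = pg$nx)
  if (!is.null(star) && star$amplitude > 0) {
    th <- atan2(qy, qx)
    f <- (1 + star$amplitude * cos(star$lobes * th + phase)) /
      sqrt(1 + star$amplitude^2 / 2)
    qx <- qx / f
    qy <- qy / f
  }
  v <- bilinear_sample(zones$grid, zones$magnitude, qx, qy)
  # electrode geometry recovered from the electrode mask so zones built from
  # scaled field maps behave identically
  em <- zones$electrode_mask
  if (any(em)) {
    idx <- which(em, arr.ind = TRUE)
    gx <- zones$grid$x[idx[, 1L]]
    gy <- zones$grid$y[idx[, 2L]]
    pos <- gx > 0
    for (side in list(which(pos), which(!pos))) {
      if (!length(side)) next
      cxs <- mean(range(gx[side])); cys <- mean(range(gy[side]))
      rad <- max(sqrt((gx[side] - cxs)^2 + (gy[side] - cys)^2)) +
        zones$grid$spacing_h / 2
      v[(qx - cxs)^2 + (qy - cys)^2 <= rad^2] <- Inf
    }
  }
  # qy (rows) varies fastest, qx (columns) slowest: column-major fill
  matrix(v, nrow = pg$ny, ncol = pg$nx)
}

# masks of the k1 strongest-field pixels (core) and the next k2 (annulus)
topk_masks <- function(samp, k1, k2 = 0L) {
  n <- length(samp)
  if (k1 + k2 > n) stop("requested mask area exceeds the tissue frame")
  ord <- order(samp, decreasing = TRUE)
  core <- matrix(FALSE, nrow(samp), ncol(samp))
  ann <- matrix(FALSE, nrow(samp), ncol(samp))
  if (k1 > 0) core[ord[seq_len(k1)]] <- TRUE
  if (k2 > 0) ann[ord[k1 + seq_len(k2)]] <- TRUE
  list(core = core, annulus = ann)
}

area_to_pixels <- function(area_cm2, ppm) as.integer(round(area_cm2 * 100 * ppm^2))

# full frame = tissue frame + ruler strip below; returns background image and
# frame geometry
blank_frame <- function(grid, params) {
  ppm <- params$pixels_per_mm
  pg <- pixel_grid(grid, ppm)
  strip <- max(1L, round(params$ruler$height_mm * ppm))
  ny <- pg$ny + strip
  img <- array(0, dim = c(ny, pg$nx, 3L))
  for (ch in 1:3) img[, , ch] <- params$background_color[ch] / 255
  list(img = img, nx = pg$nx, ny_tissue = pg$ny, ny = ny, strip = strip)
}

draw_ruler <- function(frame, params) {
  ppm <- params$pixels_per_mm
  rl <- params$ruler
  wpx <- max(1L, round(ppm / 10))
  width_mm <- frame$nx / ppm
  for (m in seq(0, width_mm, by = rl$tick_mm)) {
    col <- round(m * ppm)
    if (col < 1L || col > frame$nx) next
    cols <- col:min(frame$nx, col + wpx - 1L)
    hfrac <- if (m %% rl$major_every_mm == 0) 0.85 else 0.5
    rows <- (frame$ny_tissue + 1L):(frame$ny_tissue +
                                      max(1L, round(hfrac * frame$strip)))
    frame$img[rows, cols, ] <- 0
  }
  frame
}

paint_mask <- function(img, mask_tissue, color255) {
  idx <- which(mask_tissue, arr.ind = TRUE)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- color255[ch] / 255
    img[, , ch] <- plane
  }
  img
}

full_frame_mask <- function(mask_tissue, frame) {
  m <- matrix(FALSE, frame$ny, frame$nx)
  m[seq_len(frame$ny_tissue), ] <- mask_tissue
  m
}

add_noise_clip <- function(img, sigma255) {
  if (sigma255 > 0)
    img <- img + rnorm(length(img), sd = sigma255 / 255)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Render a synthetic TTC-stained slice photograph
#'
#' Draws the TTC-unstained white ablation core over the predicted IRE mask
#' and the deep-red formazan annulus over the reversible-zone mask, on a tan
#' tissue background, with a calibration ruler outside the tissue region and
#' seeded i.i.d. Gaussian channel noise (clipped to the valid range). Ground
#' truth is recorded before noise. When explicit target areas are supplied
#' (as the experiment generator does, after replicate jitter and
#' staining-delay kinetics), the masks are built from the strongest-field
#' pixels so that the stored truth areas equal the pixel counts exactly;
#' otherwise the zones' own masks are rasterized.
#'
#' @param zones An [predict_zones()] result (carries the field map).
#' @param params A [render_params()].
#' @param star Optional [star_params()] distortion (default none for TTC).
#' @param seed Integer seed for the noise (and star phase).
#' @param ire_area_cm2,re_area_cm2 Optional target areas overriding the
#'   zones' areas.
#' @param time_h Staining delay recorded in the bundle's condition (hours).
#' @return A `stain_bundle`: `image` (numeric array, 0..1), logical
#'   `truth_ire_mask` and `truth_re_mask` matching the image dimensions,
#'   `truth_areas` (cm^2), `scale` (pixels per mm), `seed`, `condition`.
#' @export
render_ttc <- function(zones, params = render_params(), star = NULL,
                       seed = 1L, ire_area_cm2 = NULL, re_area_cm2 = NULL,
                       time_h = 0) {
  stopifnot(inherits(zones, "ablation_zones"))
  ppm <- params$pixels_per_mm
  ire_target <- ire_area_cm2 %||% zones$ire_area_cm2
  re_target <- re_area_cm2 %||% zones$re_area_cm2
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    samp <- sample_field_pixels(zones, ppm, star = star, phase = phase)
    k1 <- area_to_pixels(ire_target, ppm)
    k2 <- area_to_pixels(re_target, ppm)
    mk <- topk_masks(samp, k1, k2)
    frame <- blank_frame(zones$grid, params)
    frame$img <- paint_mask(frame$img, mk$annulus, params$deep_red_color)
    frame$img <- paint_mask(frame$img, mk$core, params$white_core_color)
    frame <- draw_ruler(frame, params)
    img <- add_noise_clip(frame$img, params$noise_sigma)
    structure(list(image = img,
                   truth_ire_mask = full_frame_mask(mk$core, frame),
                   truth_re_mask = full_frame_mask(mk$annulus, frame),
                   truth_areas = c(ire = k1 / (100 * ppm^2),
                                   re = k2 / (100 * ppm^2)),
                   scale = ppm, seed = seed,
                   condition = list(voltage = zones$v0, modality = "ttc",
                                    time_h = time_h),
                   ruler = params$ruler),
              class = "stain_bundle")
  })
}

#' Render a synthetic melanin-accumulation slice photograph
#'
#' The blackened melanin region is the IRE core shrunk (along the field
#' contours) so that its area equals [melanin_area_at()] evaluated at
#' `time_h`; its darkness ramps with the same kinetics, interpolating from
#' the background colour towards the melanin colour. The star-shaped
#' inner-medulla distortion is applied by default. There is no deep-red
#' annulus in this modality.
#'
#' @inheritParams render_ttc
#' @param time_h Hours since pulsing.
#' @param kin A [kinetics_params()].
#' @param final_area_cm2 Optional final (48-h) area target overriding the
#'   zones' IRE area.
#' @return A `stain_bundle` with `truth_melanin_mask` and `truth_areas`.
#' @export
render_melanin <- function(zones, time_h, params = render_params(),
                           kin = kinetics_params(), seed = 1L,
                           star = star_params(), final_area_cm2 = NULL) {
  stopifnot(inherits(zones, "ablation_zones"), time_h >= 0)
  ppm <- params$pixels_per_mm
  final <- final_area_cm2 %||% zones$ire_area_cm2
  m_area <- melanin_area_at(final, time_h, kin)
  alpha <- if (final > 0) m_area / final else 0
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    samp <- sample_field_pixels(zones, ppm, star = star, phase = phase)
    k <- area_to_pixels(m_area, ppm)
    mk <- topk_masks(samp, k)
    col <- params$background_color +
      alpha * (params$melanin_color - params$background_color)
    frame <- blank_frame(zones$grid, params)
    frame$img <- paint_mask(frame$img, mk$core, col)
    frame <- draw_ruler(frame, params)
    img <- add_noise_clip(frame$img, params$noise_sigma)
    structure(list(image = img,
                   truth_melanin_mask = full_frame_mask(mk$core, frame),
                   truth_areas = c(melanin = k / (100 * ppm^2)),
                   scale = ppm, seed = seed,
                   condition = list(voltage = zones$v0, modality = "melanin",
                                    time_h = time_h),
                   ruler = params$ruler),
              class = "stain_bundle")
  })
}

#' @export
print.stain_bundle <- function(x, ...) {
  cat(sprintf("stain bundle: %s at %g V/cm, t = %g h, %d x %d px, areas: %s cm2\n",
              x$condition$modality, x$condition$voltage, x$condition$time_h,
              nrow(x$image), ncol(x$image),
              paste(sprintf("%s=%.3f", names(x$truth_areas), x$truth_areas),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a star-shaped boundary distortion to a binary mask
#'
#' Modulates the region boundary radius about the mask centroid as
#' `r(theta) * (1 + amplitude * cos(lobes * theta + phase))`, with the mean
#' radius renormalized by `sqrt(1 + amplitude^2 / 2)` so the enclosed area is
#' preserved to within a few percent. The phase is drawn deterministically
#' from `seed`. `amplitude = 0` returns the mask unchanged.
#'
#' @param mask Logical matrix.
#' @param amplitude Fractional modulation in `[0, 1)`.
#' @param lobes Number of lobes (>= 3).
#' @param seed Integer seed fixing the phase.
#' @return Logical matrix of the same dimensions.
#' @export
apply_star_distortion <- function(mask, amplitude, lobes, seed = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!(amplitude >= 0 && amplitude < 1)) stop("amplitude must be in [0, 1)")
  if (lobes < 3) stop("lobes must be >= 3")
  if (amplitude == 0 || !any(mask)) return(mask)
  phase <- with_seed(seed, runif(1, 0, 2 * pi))
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1L]); cx <- mean(idx[, 2L])
  nr <- nrow(mask); nc <- ncol(mask)
  ry <- rep(seq_len(nr), times = nc) - cy
  rx <- rep(seq_len(nc), each = nr) - cx
  th <- atan2(ry, rx)
  f <- (1 + amplitude * cos(lobes * th + phase)) / sqrt(1 + amplitude^2 / 2)
  sy <- pmin(pmax(round(cy + ry / f), 1L), nr)
  sx <- pmin(pmax(round(cx + rx / f), 1L), nc)
  matrix(mask[cbind(sy, sx)], nr, nc)
}
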