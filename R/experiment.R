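#' Default experimental conditions
#'
#' One TTC and one melanin reading per voltage: TTC stained within 5 minutes
#' of pulsing (staining delay 1/12 h) and melanin photographed 12 h after
#' pulsing, the conventional read times for the two modalities.
#'
#' @param voltages Field settings in V/cm (default the five standard
#'   settings 300, 600, 900, 1200, 1500).
#' @param ttc_delay_h TTC staining delay in hours.
#' @param melanin_time_h Melanin read time in hours.
#' @return Data frame with columns `voltage_vcm`, `modality`, `time_h`.
#' @export
default_conditions <- function(voltages = c(300, 600, 900, 1200, 1500),
                               ttc_delay_h = 5 / 60, melanin_time_h = 12) {
  rbind(
    data.frame(voltage_vcm = voltages, modality = "ttc", time_h = ttc_delay_h),
    data.frame(voltage_vcm = voltages, modality = "melanin",
               time_h = melanin_time_h))
}

#' Generate a full synthetic staining experiment
#'
#' For every condition (voltage, modality, read time) and replicate, solves
#' the electrode field (one reference solve per geometry, scaled exactly by
#' linearity to each voltage), predicts the IRE/RE zones, applies
#' multiplicative lognormal replicate jitter to the zone areas, applies the
#' staining/melanin time kinetics, renders the synthetic photograph with its
#' ground-truth masks, and generates the matching electrical records. The
#' TTC and melanin bundles of the same (voltage, replicate) share the same
#' jittered base areas — they emulate two sections of the same pulsed tuber.
#' All randomness derives from per-item seeds hashed from `master_seed`, so
#' regeneration is byte-identical and adding conditions never perturbs
#' existing items.
#'
#' @param conditions Data frame with columns `voltage_vcm`, `modality`
#'   (`"ttc"` or `"melanin"`), `time_h`; see [default_conditions()].
#' @param reps Number of replicates per condition (>= 1).
#' @param kin A [kinetics_params()].
#' @param params A [render_params()].
#' @param electrical An [electrical_params()].
#' @param config An [electrode_config()] (its voltage is overridden per
#'   condition).
#' @param grid A [grid_spec()].
#' @param thresholds Named vector `c(ire = , re = )` in V/cm.
#' @param star A [star_params()] applied to melanin renders (`NULL` for
#'   none).
#' @param master_seed Integer master seed.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   and electrical tables only (the truth areas are identical either way).
#' @param field_ref Optional pre-solved `field_map` for this geometry and
#'   grid (any positive voltage); it is rescaled exactly per voltage,
#'   avoiding a repeated solve. Must match `grid` and the electrode
#'   geometry.
#' @return An `experiment_bundle`: `bundles` (named list of `stain_bundle`s,
#'   or `NULL` when `render = FALSE`), `truth` (one row per bundle),
#'   `measurements` (wide per voltage and replicate: melanin, TTC white and
#'   red truth areas, last-pulse current, conductivity ratio), `zones` (per
#'   voltage), and the configuration used.
#' @export
generate_experiment <- function(conditions = default_conditions(), reps = 3,
                                kin = kinetics_params(),
                                params = render_params(),
                                electrical = electrical_params(),
                                config = electrode_config(),
                                grid = grid_spec(),
                                thresholds = c(ire = 250, re = 100),
                                star = star_params(),
                                master_seed = 1L,
                                render = TRUE, field_ref = NULL) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0L)
    stop("conditions must be a non-empty data frame")
  stopifnot(all(c("voltage_vcm", "modality", "time_h") %in% names(conditions)),
            all(conditions$modality %in% c("ttc", "melanin")),
            reps >= 1)

  voltages <- sort(unique(conditions$voltage_vcm))
  ref_v <- max(voltages)
  if (is.null(field_ref)) {
    cfg <- electrode_config(radius_a = config$radius_a,
                            center_spacing_d = config$center_spacing_d,
                            applied_voltage_V0 = ref_v,
                            exposure_length = config$exposure_length)
    fm_ref <- field_magnitude(solve_laplace(cfg, grid))
  } else {
    stopifnot(inherits(field_ref, "field_map"))
    if (!isTRUE(all.equal(field_ref$grid$x, grid$x)) ||
        !isTRUE(all.equal(field_ref$grid$y, grid$y)) ||
        field_ref$config$radius_a != config$radius_a ||
        field_ref$config$center_spacing_d != config$center_spacing_d)
      stop("field_ref does not match the requested grid/electrode geometry")
    fm_ref <- field_ref
    grid <- field_ref$grid
  }
  zones <- lapply(voltages, function(v)
    predict_zones(scale_field_map(fm_ref, v), thresholds[["ire"]],
                  thresholds[["re"]]))
  names(zones) <- as.character(voltages)

  ppm <- params$pixels_per_mm
  bundles <- list()
  truth <- list()
  meas <- list()

  for (v in voltages) {
    zv <- zones[[as.character(v)]]
    for (r in seq_len(reps)) {
      jit <- with_seed(derive_seed(master_seed, "jitter", v, r),
                       rlnorm_cv(2L, kin$rep_noise_cv))
      ire_base <- zv$ire_area_cm2 * jit[1L]
      re_base <- zv$re_area_cm2 * jit[2L]

      cond_rows <- conditions[conditions$voltage_vcm == v, , drop = FALSE]
      row_areas <- list(melanin = NA_real_, white = NA_real_, red = NA_real_)
      for (ci in seq_len(nrow(cond_rows))) {
        mod <- cond_rows$modality[ci]
        th <- cond_rows$time_h[ci]
        id <- sprintf("%s_%04d_t%g_r%d", mod, v, th, r)
        seed_i <- derive_seed(master_seed, mod, v, th, r)
        if (mod == "ttc") {
          red_shown <- red_area_at(re_base, th, kin)
          k_ire <- area_to_pixels(ire_base, ppm)
          k_re <- area_to_pixels(red_shown, ppm)
          if (render) {
            b <- render_ttc(zv, params, star = NULL, seed = seed_i,
                            ire_area_cm2 = ire_base, re_area_cm2 = red_shown,
                            time_h = th)
            bundles[[id]] <- b
          }
          t_ire <- k_ire / (100 * ppm^2)
          t_re <- k_re / (100 * ppm^2)
          row_areas$white <- t_ire
          row_areas$red <- t_re
          truth[[id]] <- data.frame(condition_id = id, voltage_vcm = v,
                                    modality = mod, time_h = th, rep = r,
                                    truth_ire_cm2 = t_ire,
                                    truth_re_cm2 = t_re, seed = seed_i)
        } else {
          m_area <- melanin_area_at(ire_base, th, kin)
          k_m <- area_to_pixels(m_area, ppm)
          if (render) {
            b <- render_melanin(zv, th, params, kin, seed = seed_i,
                                star = star, final_area_cm2 = ire_base)
            bundles[[id]] <- b
          }
          t_m <- k_m / (100 * ppm^2)
          row_areas$melanin <- t_m
          truth[[id]] <- data.frame(condition_id = id, voltage_vcm = v,
                                    modality = mod, time_h = th, rep = r,
                                    truth_ire_cm2 = t_m,
                                    truth_re_cm2 = NA_real_, seed = seed_i)
        }
      }

      tr <- simulate_current_train(pulse_protocol(v), electrical,
                                   seed = derive_seed(master_seed, "current",
                                                      v, r))
      cr <- generate_conductivity(v, electrical,
                                  seed = derive_seed(master_seed, "sigma",
                                                     v, r))
      np <- length(tr$per_pulse_amplitude)
      meas[[sprintf("%d_%d", v, r)]] <- data.frame(
        condition_id = sprintf("%04d", v), voltage_vcm = v, rep = r,
        melanin_area_cm2 = row_areas$melanin,
        ttc_white_area_cm2 = row_areas$white,
        ttc_red_area_cm2 = row_areas$red,
        i_first_A = tr$per_pulse_amplitude[1L],
        current_A = tr$per_pulse_amplitude[np],
        sigma_before = cr$sigma_before, sigma_after = cr$sigma_after,
        conductivity_ratio = cr$ratio)
    }
  }

  structure(list(bundles = if (render) bundles else NULL,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 measurements = do.call(rbind, c(meas,
                                                 list(make.row.names = FALSE))),
                 zones = zones, conditions = conditions, reps = reps,
                 kin = kin, params = params, electrical = electrical,
                 thresholds = thresholds, star = star, grid = grid,
                 master_seed = master_seed),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment: %d conditions x %d reps (%d bundles%s), master seed %d\n",
              nrow(x$conditions), x$reps, nrow(x$truth),
              if (is.null(x$bundles)) ", not rendered" else "",
              x$master_seed))
  invisible(x)
}
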