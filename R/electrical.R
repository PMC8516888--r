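#' Pulse protocol
#'
#' The standard square-pulse protocol for the tuber model: a field setting in
#' V/cm (numerically equal to the applied voltage at the 1-cm electrode gap),
#' 100-microsecond pulses, 2000-microsecond interpulse delay, 32 pulses.
#'
#' @param field_setting Field-strength setting in V/cm.
#' @param pulse_width_us Pulse width, microseconds.
#' @param interpulse_delay_us Delay between pulses, microseconds.
#' @param pulse_count Number of pulses (positive integer).
#' @export
pulse_protocol <- function(field_setting, pulse_width_us = 100,
                           interpulse_delay_us = 2000, pulse_count = 32) {
  stopifnot(field_setting > 0, pulse_width_us > 0, interpulse_delay_us > 0,
            pulse_count >= 1, pulse_count == round(pulse_count))
  structure(list(field_setting = field_setting,
                 pulse_width_us = pulse_width_us,
                 interpulse_delay_us = interpulse_delay_us,
                 pulse_count = as.integer(pulse_count)),
            class = "pulse_protocol")
}

#' Generative parameters for the electrical observables
#'
#' Anchors of the per-pulse current model and of the conductivity-change
#' trend. At the 1500 V/cm reference condition the first-pulse and saturated
#' currents are anchored at 12.5 A and 15.0 A; `i_first_frac` and
#' `i_sat_frac` express these anchors per unit field setting (A per V/cm),
#' with linear (ohmic) scaling to other settings — an acknowledged
#' simplification. `kappa_pulses` is the e-folding constant of the
#' saturation; with the default 5.5 the 17th pulse is the first to pass 99%
#' of the saturated current. `ratio_slope` makes the 10-Hz conductivity change
#' ratio `1 + ratio_slope * E`; the default anchors the 1500 V/cm ratio at
#' about 2 (an invented, clearly-configurable anchor: the source charts show
#' only the increasing trend, not absolute values).
#'
#' @param i_first_frac First-pulse current per unit field setting (A per
#'   V/cm).
#' @param i_sat_frac Saturated current per unit field setting (A per V/cm);
#'   must exceed `i_first_frac`.
#' @param kappa_pulses Saturation e-folding constant in pulses.
#' @param ratio_slope Conductivity-ratio slope per (V/cm).
#' @param sigma_baseline Nominal pre-pulse conductivity at 10 Hz, S/m.
#' @param meas_noise_cv Coefficient of variation of the multiplicative
#'   measurement noise.
#' @export
electrical_params <- function(i_first_frac = 12.5 / 1500,
                              i_sat_frac = 15.0 / 1500,
                              kappa_pulses = 5.5,
                              ratio_slope = 1 / 1500,
                              sigma_baseline = 0.05,
                              meas_noise_cv = 0.05) {
  stopifnot(i_first_frac > 0, i_sat_frac > i_first_frac, kappa_pulses > 0,
            ratio_slope >= 0, sigma_baseline > 0, meas_noise_cv >= 0)
  structure(list(i_first_frac = i_first_frac, i_sat_frac = i_sat_frac,
                 kappa_pulses = kappa_pulses, ratio_slope = ratio_slope,
                 sigma_baseline = sigma_baseline,
                 meas_noise_cv = meas_noise_cv),
            class = "electrical_params")
}

#' Simulate a saturating per-pulse current train
#'
#' Per-pulse current amplitudes
#' `I_k = I_inf - (I_inf - I_1) * exp(-(k - 1) / kappa)`, where the first
#' and saturated currents `I_1`, `I_inf` scale linearly with the field
#' setting relative to the 1500 V/cm anchors (12.5 A and 15.0 A). Seeded
#' multiplicative lognormal noise with coefficient of variation
#' `meas_noise_cv` is applied per pulse; the noiseless train is strictly
#' increasing and saturates (past 99% of `I_inf` by the 17th pulse under the
#' defaults).
#'
#' @param protocol A [pulse_protocol()].
#' @param params An [electrical_params()].
#' @param seed Integer seed for the measurement noise.
#' @return An object of class `current_trace` with `per_pulse_amplitude`
#'   (amperes) and the protocol.
#' @export
simulate_current_train <- function(protocol, params = electrical_params(),
                                   seed = 1L) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  E <- protocol$field_setting
  i1 <- params$i_first_frac * E
  iinf <- params$i_sat_frac * E
  k <- seq_len(protocol$pulse_count)
  ik <- iinf - (iinf - i1) * exp(-(k - 1) / params$kappa_pulses)
  ik <- ik * with_seed(seed, rlnorm_cv(length(ik), params$meas_noise_cv))
  structure(list(per_pulse_amplitude = ik, protocol = protocol),
            class = "current_trace")
}

#' Conductivity change ratio
#'
#' Post-pulse over pre-pulse conductivity at a fixed measurement frequency;
#' the proxy for membrane permeabilization.
#'
#' @param before,after Conductivities in S/m; `before` must be positive.
#' @return The dimensionless ratio `after / before`.
#' @export
conductivity_change_ratio <- function(before, after) {
  if (any(before <= 0)) stop("pre-pulse conductivity must be positive")
  after / before
}

#' Generate a synthetic 10-Hz conductivity record
#'
#' The true change ratio rises linearly with the field setting
#' (`1 + ratio_slope * E`). The pre-pulse conductivity is drawn around the
#' nominal baseline with multiplicative lognormal noise, the post-pulse value
#' around `before * ratio`, and the reported ratio is recomputed from the
#' noisy pair.
#'
#' @param field_setting Field setting in V/cm (>= 0).
#' @param params An [electrical_params()].
#' @param seed Integer seed.
#' @return An object of class `conductivity_record` with `sigma_before`,
#'   `sigma_after` (S/m) and `ratio`.
#' @export
generate_conductivity <- function(field_setting, params = electrical_params(),
                                  seed = 1L) {
  stopifnot(field_setting >= 0)
  ratio_truth <- 1 + params$ratio_slope * field_setting
  with_seed(seed, {
    noise <- rlnorm_cv(2L, params$meas_noise_cv)
    before <- params$sigma_baseline * noise[1L]
    after <- before * ratio_truth * noise[2L]
    structure(list(sigma_before = before, sigma_after = after,
                   ratio = conductivity_change_ratio(before, after),
                   ratio_truth = ratio_truth),
              class = "conductivity_record")
  })
}
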