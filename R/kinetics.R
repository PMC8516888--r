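#' Staining and melanin time-kinetics parameters
#'
#' Melanin accumulation in pulsed tuber tissue is modelled as a saturating
#' exponential: invisible until a short onset delay, then rising towards the
#' final ablation area with time constant `melanin_tau_h`. With the defaults
#' (onset 2 h, tau 12 h) the melanin area reaches ~98% of the final area at
#' 48 h, matching the observation that the blackened area converges to the
#' TTC-unstained white area two days after pulsing, and is barely visible at
#' 3 h. The deep-red annulus seen when TTC is applied promptly decays
#' exponentially with the staining delay (`red_decay_tau_h`, default 6 h),
#' so that by a 21-h delay less than 5% of it remains — emulating its
#' disappearance as cell membranes reseal. These are the simplest monotone
#' forms consistent with the observed time courses; the parameters are
#' configuration, not claims about potato physiology.
#'
#' @param melanin_tau_h Melanin accumulation time constant, hours.
#' @param melanin_onset_h Delay before any melanin is visible, hours.
#' @param red_decay_tau_h Decay time constant of the deep-red annulus with
#'   staining delay, hours.
#' @param rep_noise_cv Coefficient of variation of the multiplicative
#'   lognormal replicate-to-replicate area jitter (must be below 0.5).
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(melanin_tau_h = 12, melanin_onset_h = 2,
                            red_decay_tau_h = 6, rep_noise_cv = 0.08) {
  stopifnot(melanin_tau_h > 0, melanin_onset_h > 0, red_decay_tau_h > 0,
            rep_noise_cv >= 0, rep_noise_cv < 0.5)
  structure(list(melanin_tau_h = melanin_tau_h,
                 melanin_onset_h = melanin_onset_h,
                 red_decay_tau_h = red_decay_tau_h,
                 rep_noise_cv = rep_noise_cv),
            class = "kinetics_params")
}

#' Melanin area at a given time after pulsing
#'
#' `final_area * (1 - exp(-(time_h - onset) / tau))` after the onset delay,
#' zero before it.
#'
#' @param final_area Final (fully accumulated) area in cm^2.
#' @param time_h Hours since pulsing; must be non-negative.
#' @param kin A [kinetics_params()].
#' @return Area in cm^2.
#' @export
melanin_area_at <- function(final_area, time_h, kin = kinetics_params()) {
  stopifnot(final_area >= 0)
  if (any(time_h < 0)) stop("time_h must be non-negative")
  dt <- pmax(0, time_h - kin$melanin_onset_h)
  final_area * (1 - exp(-dt / kin$melanin_tau_h))
}

#' Deep-red annulus area as a function of staining delay
#'
#' `initial_red_area * exp(-delay / tau_r)`: the presumed reversibly
#' electroporated annulus stains deep red only while the membranes are still
#' permeabilized, so its apparent area shrinks the later the stain is
#' applied.
#'
#' @param initial_red_area Annulus area when staining immediately, cm^2.
#' @param staining_delay_h Hours between pulsing and staining (>= 0).
#' @param kin A [kinetics_params()].
#' @return Area in cm^2.
#' @export
red_area_at <- function(initial_red_area, staining_delay_h,
                        kin = kinetics_params()) {
  stopifnot(initial_red_area >= 0)
  if (any(staining_delay_h < 0)) stop("staining_delay_h must be non-negative")
  initial_red_area * exp(-staining_delay_h / kin$red_decay_tau_h)
}
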