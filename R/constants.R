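#' Physical decay data for fluorine-18
#'
#' Fixture constants for the F-18 radionuclide taken from standard decay
#' data: half-life 109.77 min; mean nonpenetrating (positron + Auger)
#' energy per decay 0.2416 MeV (mean beta energy 0.2498 MeV at a positron
#' yield of 0.9673); annihilation-photon energy per decay 0.9886 MeV.
#' All dosimetry in the package re-applies physical decay explicitly to
#' decay-corrected input curves.
#'
#' @param unit Rate unit, `"per_h"` (default) or `"per_min"`.
#' @return `f18_half_life_min()`: half-life in minutes. `f18_lambda()`:
#'   the physical decay constant in the requested unit.
#'   `f18_mean_life_h()`: 1/lambda in hours (about 2.639 h), the residence
#'   time of a source that retains the whole injection forever.
#' @examples
#' f18_lambda()          # 1/h
#' f18_mean_life_h()     # upper bound on any residence-time sum
#' @export
f18_half_life_min <- function() 109.77

#' @rdname f18_half_life_min
#' @export
f18_lambda <- function(unit = c("per_h", "per_min")) {
  unit <- match.arg(unit)
  lam_min <- log(2) / f18_half_life_min()
  if (unit == "per_min") lam_min else lam_min * 60
}

#' @rdname f18_half_life_min
#' @export
f18_mean_life_h <- function() 1 / f18_lambda("per_h")

# mGy * g per MBq * h per MeV-per-decay:
# 3.6e9 decays/(MBq h) * 1.602176634e-13 J/MeV * 1e3 g/kg * 1e3 mGy/Gy
.mev_to_mgy_g_per_mbq_h <- 3.6e9 * 1.602176634e-13 * 1e6

#' Mean energy per decay of F-18, as equilibrium dose constants
#'
#' `f18_delta_np()` is the nonpenetrating (locally absorbed) component used
#' by the unit-density sphere self-dose model; `f18_delta_photon()` is the
#' annihilation-photon component used by the synthetic S-value generator.
#' Units: mGy * g / (MBq * h).
#'
#' @return A single number.
#' @export
f18_delta_np <- function() 0.2416 * .mev_to_mgy_g_per_mbq_h

#' @rdname f18_delta_np
#' @export
f18_delta_photon <- function() 0.9886 * .mev_to_mgy_g_per_mbq_h
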