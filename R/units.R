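## Unit conversions between the model's intrinsic units and metric units.
## Intrinsic units: energy epsilon (~1.5 kcal/mol), length nm, time tau
## (~1 ns), so forces come out in epsilon/nm and speeds in nm/tau.

#' Unit conversions for the coarse-grained model
#'
#' The model works in intrinsic units: energies in \eqn{\epsilon} (about
#' 1.5 kcal/mol), lengths in nm and times in \eqn{\tau} (about 1 ns).
#' These helpers convert model forces and speeds to metric units and back.
#'
#' @param f force in \eqn{\epsilon}/nm (`force_to_pN`) or in nN
#'   (`force_to_eps_nm`).
#' @param epsilon_kcal energy unit in kcal/mol.
#' @param v speed in mm/s.
#' @return a numeric vector in the target unit.
#' @examples
#' force_to_pN(1)        # ~10.4 pN per epsilon/nm
#' speed_mm_s_to_nm_tau(2) # compression speed 2 mm/s in nm/tau
#' @export
force_to_pN <- function(f, epsilon_kcal = 1.5) {
  joule_per_eps <- epsilon_kcal * 4184 / 6.02214076e23
  f * joule_per_eps / 1e-9 * 1e12
}

#' @rdname force_to_pN
#' @export
force_to_nN <- function(f, epsilon_kcal = 1.5) force_to_pN(f, epsilon_kcal) / 1e3

#' @rdname force_to_pN
#' @export
force_to_eps_nm <- function(f, epsilon_kcal = 1.5) {
  f / force_to_nN(1, epsilon_kcal)
}

#' @rdname force_to_pN
#' @export
speed_mm_s_to_nm_tau <- function(v) v * 1e-3  # 1 mm/s = 1e-3 nm/ns

#' Oscillation frequency for a wall-drive period
#'
#' @param period_us drive period in microseconds.
#' @return frequency in kHz.
#' @examples
#' oscillation_frequency_kHz(40) # 25 kHz
#' @export
oscillation_frequency_kHz <- function(period_us) 1 / (period_us * 1e-6) / 1e3

#' Force a uniform pressure exerts on a wall
#'
#' Useful as a scale reference: atmospheric pressure on a ~100 nm^2
#' simulation wall amounts to about 0.01 nN.
#'
#' @param pressure_Pa pressure in pascal.
#' @param area_nm2 wall area in nm^2.
#' @return force in nN.
#' @examples
#' pressure_force_nN(101325, 100)
#' @export
pressure_force_nN <- function(pressure_Pa, area_nm2) {
  pressure_Pa * area_nm2 * 1e-18 * 1e9
}
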