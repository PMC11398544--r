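#' Unit conversion constants and helpers
#'
#' The package works internally in CGS units (dyn, cm, s): pressures in
#' dyn/cm2, flows in cm3/s, resistances in dyn.s/cm5. Clinical units
#' (mmHg, mL/min) appear only at I/O boundaries, converted with the exact
#' constants below.
#'
#' @name units
#' @keywords internal
NULL

#' @rdname units
#' @export
MMHG_TO_DYNCM2 <- 1333.22387415

#' Convert pressures between mmHg and dyn/cm2
#'
#' @param p numeric vector of pressures.
#' @return Converted pressures.
#' @export
mmHg_to_dyncm2 <- function(p) p * MMHG_TO_DYNCM2

#' @rdname mmHg_to_dyncm2
#' @export
dyncm2_to_mmHg <- function(p) p / MMHG_TO_DYNCM2

#' Convert flows between mL/min and cm3/s
#'
#' @param q numeric vector of flows.
#' @return Converted flows.
#' @export
mlmin_to_cm3s <- function(q) q / 60

#' @rdname mlmin_to_cm3s
#' @export
cm3s_to_mlmin <- function(q) q * 60
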