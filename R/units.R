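#' Physical constants and unit conversions
#'
#' All permeability arithmetic is carried out internally in CGS units
#' (cm, s, mol); micrometres, millimetres, microlitres and minutes appear
#' only at the I/O boundaries. These helpers are exact scale factors.
#'
#' @name units
#' @keywords internal
NULL

#' Partial molar volume of water
#'
#' The molar volume of liquid water, 18 cm^3 mol^-1, used in the osmotic
#' permeability relation P_f = J_v / (V_w * A * dc). Overridable in
#' [compute_Pf()] for sensitivity analyses.
#'
#' @format A length-one numeric, cm^3 mol^-1.
#' @export
VW_WATER_CM3_MOL <- 18

# exact decimal scale factors -------------------------------------------

um2_to_mm2 <- function(x) x * 1e-6
mm2_to_cm2 <- function(x) x * 1e-2
um_to_mm <- function(x) x * 1e-3
ul_to_cm3 <- function(x) x * 1e-3
per_min_to_per_s <- function(x) x / 60
ul_per_min_to_cm3_per_s <- function(x) x * 1e-3 / 60
mol_per_l_to_mol_per_cm3 <- function(x) x * 1e-3
per_cm2_to_per_um2 <- function(x) x / 1e8

# validation helpers ----------------------------------------------------

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cochperm_validation_error", "cochperm_error")))
}

stop_numerical <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cochperm_numerical_error", "cochperm_error")))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop_validation("'%s' must be strictly positive and non-missing", what)
  }
  invisible(x)
}
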