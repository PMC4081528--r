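#' Scala geometry
#'
#' One-dimensional geometry of a cochlear scala: its baso-apical length and
#' a cross-sectional area profile tabulated base to apex (linearly
#' interpolated onto the simulation grid).
#'
#' @param id one of `"SV"`, `"ST"`, `"SM"`.
#' @param length_mm baso-apical length (mm).
#' @param area_mm2 cross-sectional areas (mm^2) tabulated at equally spaced
#'   positions from base (x = 0) to apex (x = length); a scalar gives a
#'   uniform profile.
#' @return Object of class `scala_geometry` with derived `volume_ul`.
#' @export
scala_geometry <- function(id = c("SV", "ST", "SM"), length_mm, area_mm2) {
  id <- match.arg(id)
  check_positive(length_mm, "length_mm")
  check_positive(area_mm2, "area_mm2")
  if (length(area_mm2) == 1L) area_mm2 <- rep(area_mm2, 2L)
  xs <- seq(0, length_mm, length.out = length(area_mm2))
  # trapezoid volume of the tabulated profile; 1 mm^3 == 1 ul
  vol <- sum(diff(xs) * (utils::head(area_mm2, -1) + utils::tail(area_mm2, -1)) / 2)
  structure(list(id = id, length_mm = length_mm,
                 area_x_mm = xs, area_mm2 = area_mm2,
                 volume_ul = vol),
            class = "scala_geometry")
}

#' Default guinea-pig scala geometries (synthetic fixture)
#'
#' Apical ends at 15.5 mm (SV) and 16.2 mm (ST) from the base; the scala
#' media is given a uniform profile whose volume is exactly the endolymph
#' volume V_e = 1.2 ul. The perilymphatic profiles taper linearly base to
#' apex with volumes in the range reported for the adult guinea pig. These
#' profiles are a synthetic stand-in for unpublished anatomical sections,
#' so simulated rate constants are reproduced qualitatively, not
#' bit-exactly.
#'
#' @param v_e_ul endolymph volume forced onto the SM profile (ul).
#' @return Named list of three [scala_geometry()] objects (`SV`, `ST`, `SM`).
#' @export
default_geometry <- function(v_e_ul = 1.2) {
  sm_len <- 15.5
  list(
    SV = scala_geometry("SV", 15.5, c(0.50, 0.12)),
    ST = scala_geometry("ST", 16.2, c(0.65, 0.12)),
    SM = scala_geometry("SM", sm_len, v_e_ul / sm_len)
  )
}

#' Scala-scala and scala-blood communication half-times
#'
#' Half-times (min) of first-order relaxation of the local concentration
#' difference between compartments; the exchange rate constant is
#' k = ln(2) / t_half. A half-time of 9999 min denotes effectively blocked
#' exchange. Defaults are the calibrated guinea-pig tracer-perfusion
#' configuration.
#'
#' @param sv_sm_min,st_sv_min,st_sm_min pairwise half-times (min); `Inf`
#'   switches a pathway off entirely (used to isolate compartment pairs in
#'   tests; 9999 min is the conventional "blocked" sentinel).
#' @param sv_blood_min,st_blood_min,sm_blood_min clearance half-times to
#'   blood per scala (min); `Inf` disables clearance.
#' @return Object of class `communication_spec`.
#' @export
communication_spec <- function(sv_sm_min = 2.2, st_sv_min = 9999,
                               st_sm_min = 4.6,
                               sv_blood_min = 1.6, st_blood_min = 1.6,
                               sm_blood_min = 15) {
  vals <- c(sv_sm_min = sv_sm_min, st_sv_min = st_sv_min,
            st_sm_min = st_sm_min, sv_blood_min = sv_blood_min,
            st_blood_min = st_blood_min, sm_blood_min = sm_blood_min)
  if (any(vals <= 0)) {
    stop_validation("all communication half-times must be > 0")
  }
  structure(as.list(vals), class = "communication_spec")
}

#' Perfusion specification
#'
#' Constant-rate perfusion of one or both perilymphatic scalae, entering
#' near the base and exiting at the apical end (helicotrema cochleostomy in
#' the in vivo setup). Inlet concentration is in % of perfusate (tracer
#' normalised to 100); a scala can be perfused with tracer-free artificial
#' perilymph by setting its inlet to 0.
#'
#' @param scalae character vector, subset of `c("SV", "ST")`.
#' @param rate_ul_min flow rate per perfused scala (ul/min).
#' @param inlet_pct named (or recycled) inlet concentration per perfused
#'   scala, in \[0, 100\].
#' @param entry_mm entry position (mm from base).
#' @param exit_mm exit position; `NULL` means the apical end of each scala.
#' @param start_min,stop_min perfusion window (min).
#' @return Object of class `perfusion_spec`.
#' @export
perfusion_spec <- function(scalae = c("SV", "ST"), rate_ul_min = 8,
                           inlet_pct = 100, entry_mm = 0.1, exit_mm = NULL,
                           start_min = 0, stop_min = Inf) {
  scalae <- match.arg(scalae, c("SV", "ST"), several.ok = TRUE)
  if (rate_ul_min < 0) stop_validation("perfusion rate must be >= 0")
  if (any(inlet_pct < 0 | inlet_pct > 100)) {
    stop_validation("inlet concentration must be within [0, 100] %%")
  }
  inlet <- rep_len(inlet_pct, length(scalae))
  names(inlet) <- scalae
  if (!is.null(exit_mm) && any(entry_mm >= exit_mm)) {
    stop_validation("entry position must lie basal to the exit position")
  }
  structure(list(scalae = scalae, rate_ul_min = rate_ul_min,
                 inlet_pct = inlet, entry_mm = entry_mm, exit_mm = exit_mm,
                 start_min = start_min, stop_min = stop_min),
            class = "perfusion_spec")
}

#' Numerical configuration of a dispersal simulation
#'
#' @param D_cm2_s diffusion coefficient of the tracer (cm^2/s); default is
#'   the tritiated-water value used for the guinea-pig simulations.
#' @param dx_mm grid spacing (mm).
#' @param dt_s time step (s). Diffusion is integrated implicitly
#'   (Crank-Nicolson) and advection by implicit upwind, so there is no
#'   stability limit; dt controls splitting accuracy only.
#' @param duration_min simulated duration (min).
#' @param probes_mm named list/vector of probe positions (mm from base),
#'   one per scala, e.g. `c(SV = 1, ST = 1, SM = 1)`.
#' @param out_every_min output sampling interval (min).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(D_cm2_s = 2.3004e-5, dx_mm = 0.1, dt_s = 0.5,
                              duration_min = 10,
                              probes_mm = c(SV = 1, ST = 1, SM = 1),
                              out_every_min = 0.25) {
  check_positive(c(D_cm2_s, dx_mm, dt_s, duration_min, out_every_min),
                 "simulation parameters")
  structure(list(D_cm2_s = D_cm2_s, dx_mm = dx_mm, dt_s = dt_s,
                 duration_min = duration_min, probes_mm = probes_mm,
                 out_every_min = out_every_min),
            class = "simulation_config")
}
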