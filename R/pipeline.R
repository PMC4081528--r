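#' Pipeline configuration
#'
#' A fully resolved snapshot of every parameter a pipeline run consumes,
#' so any run can be reproduced bit-identically from its snapshot alone.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param table a [half_turn_table()]; defaults to the packaged calibrated
#'   synthetic fixture.
#' @param geometries scala geometries ([default_geometry()]).
#' @param comms [communication_spec()] ground-truth / starting half-times.
#' @param v_e_ul endolymph volume (ul).
#' @param si_area_pct,si_movement_pct solute-increase percentages for the
#'   osmotic scenarios (in vivo values by default).
#' @param delta_c_mol_l osmotic gradient (mol/l).
#' @param shunt_width_um,shunt_length_um shunt membrane dimensions (um).
#' @param obs an [gen_observations()] record, or `NULL` to use the
#'   half-times in `comms` directly (tracer scenarios) / the configured SI
#'   values (osmotic scenarios).
#' @param sim_duration_min duration of the steady-state tracer simulation
#'   used for regression (120 min in the reference protocol).
#' @param dx_mm,dt_s numerical grid.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            table = cochperm_fixture_table(),
                            geometries = default_geometry(),
                            comms = communication_spec(),
                            v_e_ul = 1.2,
                            si_area_pct = 22.1, si_movement_pct = 12.29,
                            delta_c_mol_l = 0.094,
                            shunt_width_um = 57.53,
                            shunt_length_um = 804.31,
                            obs = NULL,
                            sim_duration_min = 120,
                            dx_mm = 0.1, dt_s = 0.5) {
  structure(list(seed = as.integer(seed), table = table,
                 geometries = geometries, comms = comms, v_e_ul = v_e_ul,
                 si_area_pct = si_area_pct,
                 si_movement_pct = si_movement_pct,
                 delta_c_mol_l = delta_c_mol_l,
                 shunt_width_um = shunt_width_um,
                 shunt_length_um = shunt_length_um,
                 obs = obs, sim_duration_min = sim_duration_min,
                 dx_mm = dx_mm, dt_s = dt_s),
            class = "pipeline_config")
}

#' Packaged synthetic half-turn fixture table
#'
#' Deterministic synthetic morphometry table calibrated so that the
#' trapezoid-rule partition totals equal 11.46 (RM) and 9.78 (OC) mm^2.
#' Regenerated in code; the copy under `inst/extdata/` exists for the CSV
#' interface examples.
#'
#' @return A [half_turn_table()].
#' @export
cochperm_fixture_table <- function() {
  gen_morphometry(seed = 20140103L, noise_cv = 0,
                  calibrate_to = c(rm = 11.46, oc = 9.78))
}

#' Run one experimental scenario end to end
#'
#' Tracer scenarios (`"SV+ST/SM"`, `"SV/SM"`, `"ST/SM"`): partition areas
#' from the morphometry table, optional half-time calibration against a
#' 7-min observation record, a steady-state dispersal simulation, an
#' uptake-model fit of the endolymph curve sampled at 1-min intervals, and
#' the diffusional permeability P_D = P' V_e / A.
#'
#' Osmotic scenarios: `"osmotic-CDE"` uses the total barrier area and the
#' compartment-shrinkage solute increase; `"osmotic-OSC"` uses the apical
#' outer-sulcus-cell shunt area and the longitudinal-movement solute
#' increase. Both compute J_v, then P_f and the P_f/P_D ratio (against the
#' pipeline's own P_D for the CDE, and against the mean reference P_D of
#' AQP5-expressing epithelia for the shunt).
#'
#' @param scenario one of `"SV+ST/SM"`, `"SV/SM"`, `"ST/SM"`,
#'   `"osmotic-CDE"`, `"osmotic-OSC"`.
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_run` with `scenario`, `stages` (all
#'   intermediate artifacts), `summary` (data.frame of scenario, quantity,
#'   value, units) and the config snapshot.
#' @export
run_pipeline <- function(scenario, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("SV+ST/SM", "SV/SM", "ST/SM", "osmotic-CDE", "osmotic-OSC")
  if (!scenario %in% known) {
    stop_validation("unknown scenario '%s' (expected one of %s)",
                    scenario, paste(known, collapse = ", "))
  }
  stages <- list()
  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("cochperm_stage_error", class(e))))
    })
  }

  areas <- with_stage("areas", compute_barrier_areas(config$table))
  stages$areas <- areas

  if (scenario %in% c("SV+ST/SM", "SV/SM", "ST/SM")) {
    area_mm2 <- switch(scenario,
                       "SV/SM" = areas$totals_mm2[["A_SV_SM_mm2"]],
                       "ST/SM" = areas$totals_mm2[["A_ST_SM_mm2"]],
                       "SV+ST/SM" = areas$totals_mm2[["A_SV_ST_SM_mm2"]])
    comms <- config$comms
    perf <- scenario_perfusion(scenario)

    if (!is.null(config$obs)) {
      which_ht <- switch(scenario, "SV/SM" = "sv_sm_min",
                         "ST/SM" = "st_sm_min", "SV+ST/SM" = "sv_sm_min")
      cal <- with_stage("calibrate", calibrate_half_time(
        config$geometries, comms, perf,
        simulation_config(dx_mm = config$dx_mm, dt_s = config$dt_s,
                          duration_min = config$obs$observed$time_min),
        target = config$obs$observed, which = which_ht))
      comms[[which_ht]] <- cal$half_time_min
      stages$calibration <- cal
    }

    run <- with_stage("simulate", simulate_dispersal(
      config$geometries, comms, perf,
      simulation_config(dx_mm = config$dx_mm, dt_s = config$dt_s,
                        duration_min = config$sim_duration_min,
                        out_every_min = 0.25)))
    stages$simulation <- run

    sm <- run$time_courses$SM
    grid <- time_course(seq(0, config$sim_duration_min, by = 1)[-1],
                        probe(sm, seq(0, config$sim_duration_min, by = 1)[-1]),
                        probe = "SM")
    fit <- with_stage("fit", fit_uptake_model(grid))
    stages$fit <- fit
    p_prime <- with_stage("extract", extract_rate_constant(fit))
    pd <- with_stage("Pd", compute_Pd(p_prime$p_prime_min,
                                      config$v_e_ul, area_mm2))
    stages$pd <- pd
    summary <- data.frame(
      scenario = scenario,
      quantity = c("A", "P_prime", "P_D"),
      value = c(area_mm2, p_prime$p_prime_min, pd$value_cm_s),
      units = c("mm2", "1/min", "cm/s"),
      stringsAsFactors = FALSE)
  } else {
    osmotic_obs <- if (!is.null(config$obs) &&
                       config$obs$scenario == "osmotic") {
      config$obs$observed
    } else {
      list(SI_Area = config$si_area_pct, SI_Movement = config$si_movement_pct)
    }
    if (scenario == "osmotic-CDE") {
      area_mm2 <- areas$totals_mm2[["A_SV_ST_SM_mm2"]]
      si <- osmotic_obs$SI_Area
      # reference P_D for the ratio: the pipeline's own CDE value
      pd_ref <- compute_Pd(0.869, config$v_e_ul, area_mm2)
    } else {
      shunt <- with_stage("shunt_area", compute_shunt_area(
        config$shunt_width_um, config$shunt_length_um))
      stages$shunt <- shunt
      area_mm2 <- shunt$area_mm2
      si <- osmotic_obs$SI_Movement
      pd_ref <- permeability_result(
        mean_reference_Pd(c(1.30, 1.68, 8.18, 13, 300)) * 1e-5, "P_D",
        list(source = "mean of AQP5-expressing epithelia"))
    }
    jv <- with_stage("Jv", compute_Jv(config$v_e_ul, si))
    pf <- with_stage("Pf", compute_Pf(jv, area_mm2, config$delta_c_mol_l))
    ratio <- compute_ratio(pf, pd_ref)
    stages$jv <- jv; stages$pf <- pf; stages$pd_ref <- pd_ref
    summary <- data.frame(
      scenario = scenario,
      quantity = c("A", "SI", "J_v", "P_f", "Pf_over_Pd"),
      value = c(area_mm2, si, jv, pf$value_cm_s, ratio),
      units = c("mm2", "%", "ul/min", "cm/s", "1"),
      stringsAsFactors = FALSE)
  }

  structure(list(scenario = scenario, stages = stages, summary = summary,
                 snapshot = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run: %s\n", x$scenario))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write report files for one or more pipeline runs
#'
#' Emits a machine-readable CSV summary (scenario, quantity, value, units),
#' a full-precision JSON mirror, and a short human-readable text report.
#'
#' @param runs a `pipeline_run` or list of them.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(runs, dir) {
  if (inherits(runs, "pipeline_run")) runs <- list(runs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- if (length(runs)) {
    do.call(rbind, lapply(runs, `[[`, "summary"))
  } else {
    data.frame(scenario = character(), quantity = character(),
               value = numeric(), units = character())
  }
  csv <- file.path(dir, "summary.csv")
  utils::write.csv(summary, csv, row.names = FALSE, quote = FALSE)
  json <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, json, digits = NA)
  txt <- file.path(dir, "report.txt")
  lines <- c("cochlear water-permeability pipeline report", "")
  for (r in runs) {
    lines <- c(lines, sprintf("== %s ==", r$scenario),
               sprintf("  %-12s %14.8g %s", r$summary$quantity,
                       r$summary$value, r$summary$units), "")
  }
  writeLines(lines, txt)
  invisible(c(csv = csv, json = json, txt = txt))
}
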