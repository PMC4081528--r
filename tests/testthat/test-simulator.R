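test_that("zero inlet concentration keeps every probe at zero", {
  run <- simulate_dispersal(default_geometry(), communication_spec(),
                            perfusion_spec(inlet_pct = 0),
                            simulation_config(duration_min = 5))
  for (tc in run$time_courses) {
    expect_true(all(tc$concentration_pct == 0))
  }
})

test_that("tracer mass balances to 1e-3 relative under steady perfusion", {
  run <- simulate_dispersal(default_geometry(), communication_spec(),
                            perfusion_spec(),
                            simulation_config(duration_min = 10))
  mb <- mass_balance(run)
  expect_lt(mb$relative_error, 1e-3)
  expect_gt(mb$mass_cleared, 0)
  expect_gt(mb$mass_out, 0)
})

test_that("closed system conserves resident mass to 1e-6", {
  s <- two_compartment_setup()
  run <- simulate_dispersal(s$geometries, s$comms, s$perfusion,
                            simulation_config(duration_min = 10),
                            init_pct = c(100, 0, 0))
  mb <- mass_balance(run)
  expect_equal(mb$mass_in, 0)
  expect_equal(mb$mass_out, 0)
  expect_rel(mb$mass_resident, mb$mass_initial, 1e-6)
})

test_that("with blood clearance only, cleared + resident stays constant", {
  cm <- communication_spec(sv_sm_min = Inf, st_sv_min = Inf, st_sm_min = Inf,
                           sv_blood_min = 1.6, st_blood_min = 1.6,
                           sm_blood_min = 15)
  run <- simulate_dispersal(default_geometry(), cm,
                            perfusion_spec(rate_ul_min = 0),
                            simulation_config(duration_min = 10),
                            init_pct = c(100, 100, 100))
  mb <- mass_balance(run)
  expect_lt(mb$mass_resident, mb$mass_initial)
  expect_rel(mb$mass_cleared + mb$mass_resident, mb$mass_initial, 1e-9)
  # quadrature of the clearance term: uniform initial state decays as
  # exp(-ln2 t / t_half) per scala, so the SV probe is the closed form
  expect_rel(probe(run$time_courses$SV, 8), 100 * exp(-log(2) * 8 / 1.6),
             1e-6)
})

test_that("well-mixed pair matches the two-compartment closed form within 1%", {
  s <- two_compartment_setup(t_half_min = 2.2)
  run <- simulate_dispersal(s$geometries, s$comms, s$perfusion,
                            simulation_config(duration_min = 10),
                            init_pct = c(100, 0, 0))
  for (t in c(1, 2.2, 5, 10)) {
    d <- probe(run$time_courses$SV, t) - probe(run$time_courses$SM, t)
    expect_rel(d, 100 * exp(-log(2) * t / 2.2), 0.01)
  }
})

test_that("a 9999-min half-time behaves as blocked exchange", {
  g <- default_geometry()
  perf <- perfusion_spec(c("SV", "ST"), inlet_pct = c(100, 0))
  blocked <- simulate_dispersal(g, communication_spec(st_sv_min = 9999), perf,
                                simulation_config(duration_min = 120))
  off <- simulate_dispersal(g, communication_spec(st_sv_min = Inf), perf,
                            simulation_config(duration_min = 120))
  # pathway contribution < 0.1% of perfusate over the whole 120 min
  leak <- max(abs(blocked$time_courses$ST$concentration_pct -
                    off$time_courses$ST$concentration_pct))
  expect_lt(leak, 0.1)
  # and the ST probe stays below 2% of the SV probe at 10 min
  expect_lt(probe(blocked$time_courses$ST, 10),
            0.02 * probe(blocked$time_courses$SV, 10))
})

test_that("halving the grid spacing changes 7-min probe values by < 0.5%", {
  g <- default_geometry()
  coarse <- simulate_dispersal(g, communication_spec(), perfusion_spec(),
                               simulation_config(duration_min = 7, dx_mm = 0.1))
  fine <- simulate_dispersal(g, communication_spec(), perfusion_spec(),
                             simulation_config(duration_min = 7, dx_mm = 0.05))
  for (s in c("SV", "ST", "SM")) {
    expect_rel(probe(fine$time_courses[[s]], 7),
               probe(coarse$time_courses[[s]], 7), 5e-3)
  }
})

test_that("probe interpolation is linear with endpoint errors", {
  tc <- time_course(c(0, 2, 4, 6), c(10, 10, 20, 15))
  expect_identical(probe(tc, 4), 20)       # stored node
  expect_equal(probe(tc, 1), 10)           # midway between equal neighbours
  expect_equal(probe(tc, 3), 15)           # midway between 10 and 20
  expect_error(probe(tc, 6.5), "outside", class = "cochperm_validation_error")
  expect_error(probe(tc, -1), class = "cochperm_validation_error")
})

test_that("probe positions outside a scala are rejected by name", {
  expect_error(
    simulate_dispersal(default_geometry(), communication_spec(),
                       perfusion_spec(),
                       simulation_config(duration_min = 1,
                                         probes_mm = c(SV = 99, ST = 1, SM = 1))),
    "probe position.*SV", class = "cochperm_validation_error")
})

test_that("calibration recovers a forward half-time within 1%", {
  g <- default_geometry()
  cm <- communication_spec()
  perf <- perfusion_spec(c("SV", "ST"), inlet_pct = c(100, 0))
  cfg <- simulation_config(duration_min = 7)
  fwd <- simulate_dispersal(g, cm, perf, cfg)
  target <- list(probe = "SM", time_min = 7,
                 conc_pct = probe(fwd$time_courses$SM, 7))
  cal <- calibrate_half_time(g, cm, perf, cfg, target, which = "sv_sm_min")
  expect_identical(cal$flag, "converged")
  expect_rel(cal$half_time_min, 2.2, 0.01)
})

test_that("calibration flags unreachable targets", {
  g <- default_geometry()
  cm <- communication_spec()
  perf <- perfusion_spec(c("SV", "ST"), inlet_pct = c(100, 0))
  cfg <- simulation_config(duration_min = 7)
  zero <- calibrate_half_time(g, cm, perf, cfg,
                              list(probe = "SM", time_min = 7, conc_pct = 0),
                              which = "sv_sm_min")
  expect_identical(zero$flag, "unreachable")
  expect_equal(zero$half_time_min, 1000)
  expect_error(
    calibrate_half_time(g, cm, perf, cfg,
                        list(probe = "SM", time_min = 7, conc_pct = 99.9),
                        which = "sv_sm_min", bracket = c(0.5, 100)),
    "outside achievable range", class = "cochperm_numerical_error")
})

test_that("probe concentration is monotone decreasing in a feeding half-time", {
  g <- default_geometry()
  perf <- perfusion_spec(c("SV", "ST"), inlet_pct = c(100, 0))
  cfg <- simulation_config(duration_min = 7)
  conc <- vapply(c(0.5, 2.2, 10, 50), function(th) {
    run <- simulate_dispersal(g, communication_spec(sv_sm_min = th), perf, cfg)
    probe(run$time_courses$SM, 7)
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
})

test_that("time courses round-trip through the tidy CSV dialect", {
  run <- simulate_dispersal(default_geometry(), communication_spec(),
                            perfusion_spec(),
                            simulation_config(duration_min = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_time_courses_csv(run, path)
  back <- read_time_course_csv(path, probe_id = "SM")
  expect_equal(back$concentration_pct, run$time_courses$SM$concentration_pct,
               tolerance = 1e-9)
})
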