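# shared fixtures, built in code at test time

# regression parameter triples (P', P'', alpha) of the three tracer
# configurations, as obtained from the reference steady-state fits
TABLE3_TRIPLES <- list(
  sv_sm = c(p_prime = 0.691, p_dprime = 0.938, alpha = 0.504),
  st_sm = c(p_prime = 0.499, p_dprime = 0.940, alpha = 0.435),
  sv_st_sm = c(p_prime = 0.869, p_dprime = 0.898, alpha = 0.549)
)

fixture_table <- function() cochperm_fixture_table()

# uniform two-box world used for the analytic two-compartment oracle:
# zero perfusion, no blood clearance, only the SV-SM pathway open
two_compartment_setup <- function(t_half_min = 2.2) {
  list(geometries = default_geometry(),
       comms = communication_spec(sv_sm_min = t_half_min, st_sv_min = Inf,
                                  st_sm_min = Inf, sv_blood_min = Inf,
                                  st_blood_min = Inf, sm_blood_min = Inf),
       perfusion = perfusion_spec(rate_ul_min = 0))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
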