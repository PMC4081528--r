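test_that("calibrated fixture reproduces the published partition totals", {
  areas <- compute_barrier_areas(fixture_table())
  expect_equal(areas$totals_mm2[["A_SV_SM_mm2"]], 11.46, tolerance = 1e-8)
  expect_equal(areas$totals_mm2[["A_ST_SM_mm2"]], 9.78, tolerance = 1e-8)
  # combined area is exactly additive
  expect_identical(areas$totals_mm2[["A_SV_ST_SM_mm2"]],
                   areas$totals_mm2[["A_SV_SM_mm2"]] +
                     areas$totals_mm2[["A_ST_SM_mm2"]])
  expect_equal(areas$totals_mm2[["A_SV_ST_SM_mm2"]], 21.24, tolerance = 1e-8)
})

test_that("constant-width table degenerates to 9 * w * l", {
  w <- 500; l <- 2000
  tab <- half_turn_table(c("hook", "I", "II", "III", "IV", "V", "VI",
                           "VII", "VIII"),
                         c(NA, rep(w, 8)), c(NA, rep(w, 8)), rep(l, 9))
  for (part in c("RM", "OC")) {
    a <- compute_partition_areas(tab, part)
    expect_equal(a$total_mm2, 9 * w * l * 1e-6, tolerance = 1e-12)
    # additivity: total is the sum of the per-segment areas
    expect_identical(a$total_mm2, sum(a$per_segment_mm2))
  }
})

test_that("areas are homogeneous of degree 2 in the linear dimensions", {
  for (seed in 1:5) {
    tab <- gen_morphometry(seed, noise_cv = 0.1)
    c2 <- runif(1, 0.5, 3)
    tab2 <- tab
    tab2$w_rm_um <- tab$w_rm_um * c2
    tab2$w_oc_um <- tab$w_oc_um * c2
    tab2$l_um <- tab$l_um * c2
    a1 <- compute_partition_areas(tab, "RM")$per_segment_mm2
    a2 <- compute_partition_areas(tab2, "RM")$per_segment_mm2
    expect_equal(a2, a1 * c2^2, tolerance = 1e-12)
  }
})

test_that("table validation reports the offending segment", {
  tab <- as.data.frame(fixture_table())
  bad <- tab[tab$label != "IV", ]
  expect_error(compute_partition_areas(bad, "RM"),
               "missing segment.*IV", class = "cochperm_validation_error")
  tab2 <- tab
  tab2$w_oc_um[tab2$label == "VI"] <- -1
  expect_error(compute_partition_areas(tab2, "OC"),
               "w_oc_um.*VI", class = "cochperm_validation_error")
  tab3 <- tab
  tab3$l_um[3] <- 0
  expect_error(compute_partition_areas(tab3, "RM"),
               class = "cochperm_validation_error")
})

test_that("replicate summaries reproduce the published mean/SD rows", {
  cases <- list(
    list(values = c(904.12, 953.16, 933.74), mean = 930.34, sd = 24.70),
    list(values = c(726.99, 872.73, 813.22), mean = 804.31, sd = 73.28),
    list(values = c(60.23, 57.93, 54.44), mean = 57.53, sd = 2.92))
  for (cs in cases) {
    r <- summarize_replicates(cs$values)
    expect_equal(round(r$mean, 2), cs$mean)
    expect_equal(round(r$sd, 2), cs$sd)
  }
})

test_that("sd matches a brute-force two-pass computation on random input", {
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1), mean = 500, sd = 40)
    r <- summarize_replicates(v)
    m <- sum(v) / length(v)
    expect_equal(r$sd, sqrt(sum((v - m)^2) / (length(v) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("replicate edge cases", {
  r <- summarize_replicates(42.5)
  expect_equal(r$mean, 42.5)
  expect_true(is.na(r$sd))
  expect_error(summarize_replicates(numeric(0)),
               class = "cochperm_validation_error")
})

test_that("shunt area is the exact product with unit conversion", {
  s <- compute_shunt_area(57.53, 804.31)
  expect_equal(s$area_um2, 46271.95, tolerance = 1e-6)
  expect_equal(s$area_mm2, 0.04627195, tolerance = 1e-7)
  expect_equal(compute_shunt_area(1, 1)$area_um2, 1)
  expect_equal(compute_shunt_area(100, 200)$area_um2, 20000)
  expect_equal(compute_shunt_area(100, 200)$area_mm2, 0.02)
  expect_error(compute_shunt_area(0, 10), class = "cochperm_validation_error")
})

test_that("half-turn CSV round trips through the documented dialect", {
  tab <- fixture_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_half_turn_csv(tab, path)
  back <- read_half_turn_csv(path)
  expect_equal(back$w_rm_um, tab$w_rm_um, tolerance = 1e-9)
  expect_equal(back$l_um, tab$l_um)
  a1 <- compute_barrier_areas(tab)$totals_mm2
  a2 <- compute_barrier_areas(back)$totals_mm2
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("areas JSON report carries per-segment and total blocks", {
  path <- withr::local_tempfile(fileext = ".json")
  write_areas_json(compute_barrier_areas(fixture_table()), path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(rep$per_segment), 9)
  expect_equal(rep$totals$A_SV_ST_SM_mm2, 21.24, tolerance = 1e-6)
})
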