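spec_for <- function(n, sdlog = 0.5, seed = 0, mean_target = 18) {
  synthetic_site_spec(meanlog = c(et = log(mean_target) - sdlog^2 / 2),
                      sdlog = c(et = sdlog), n_samples = n, seed = seed)
}

test_that("waste-sample generation is reproducible and degenerates correctly", {
  s0 <- spec_for(20, sdlog = 0)
  tab <- generate_waste_samples(s0)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$et == exp(s0$meanlog[["et"]])))
  a <- generate_waste_samples(spec_for(50, seed = 1))
  b <- generate_waste_samples(spec_for(50, seed = 1))
  c <- generate_waste_samples(spec_for(50, seed = 2))
  expect_identical(a, b)
  expect_false(identical(a$et, c$et))
})

test_that("generated concentrations hit the configured arithmetic mean", {
  # lognormal mean exp(mu + sigma^2/2) as the oracle: spec is parameterized
  # so the arithmetic mean is 18 mg/kg
  tab <- generate_waste_samples(spec_for(10000, seed = 4))
  expect_equal(mean(tab$et), 18, tolerance = 0.03)
})

test_that("generator output round trips through fit_lognormal within 3 SE", {
  n <- 10000; sdlog <- 0.5
  spec <- spec_for(n, sdlog = sdlog, seed = 77)
  d <- fit_lognormal(generate_waste_samples(spec)$et)
  expect_lt(abs(d$params$meanlog - spec$meanlog[["et"]]), 3 * sdlog / sqrt(n))
  expect_lt(abs(d$params$sdlog - sdlog), 3 * sdlog / sqrt(2 * n))
})

test_that("synthetic meteorology follows the frequency table and wind ranges", {
  all_d <- generate_meteo_set(c(D = 1), n = 25, seed = 1)
  expect_true(all(vapply(all_d, function(m) as.character(m$stability), "") == "D"))
  freq <- c(A = 0.1, D = 0.6, F = 0.3)
  set <- generate_meteo_set(freq, n = 10000, seed = 8)
  classes <- vapply(set, function(m) as.character(m$stability), "")
  emp <- table(factor(classes, levels = names(freq))) / length(set)
  expect_true(all(abs(as.numeric(emp) - freq) < 0.02))
  for (m in set[1:200]) {
    r <- WIND_RANGES[[as.character(m$stability)]]
    expect_true(m$wind_speed >= r[1] && m$wind_speed <= r[2])
  }
  expect_identical(generate_meteo_set(freq, 20, seed = 3),
                   generate_meteo_set(freq, 20, seed = 3))
})

test_that("the packaged case study bundle is self-consistent", {
  b <- make_case_study_scenario(seed = 1)
  expect_equal(b$distances, c(20, 50, 100, 150, 200, 250))
  expect_equal(b$scenario$excavation$dig_rate, 150)
  expect_length(b$scenario$cs_mean, 4)
  expect_equal(nrow(b$samples), 100)
  expect_s3_class(b$scenario, "odor_scenario")
  # cs distributions were fitted from the generated table
  expect_true(all(vapply(b$scenario$cs_dist, inherits, TRUE, "param_dist")))
  # regenerating with the same seed reproduces the bundle exactly
  expect_identical(make_case_study_scenario(seed = 1)$samples, b$samples)
})

test_that("the fixture's odor hazard ranking is toluene-led", {
  b <- make_case_study_scenario(seed = 1)
  reg <- b$registry
  phi <- vapply(names(b$scenario$cs_mean), function(nm) {
    cair <- pore_gas_concentration(b$scenario$cs_mean[[nm]], reg[[nm]],
                                   b$scenario$matrix)
    phi_odor(cair, reg[[nm]]$odor_threshold)
  }, numeric(1))
  expect_identical(names(sort(phi, decreasing = TRUE)),
                   c("toluene", "m/p-xylene", "styrene", "ethylbenzene"))
})

test_that("site spec invariants are enforced", {
  expect_error(synthetic_site_spec(c(a = 1), c(a = -0.1)), "sdlog")
  expect_error(synthetic_site_spec(c(a = 1), c(b = 0.5)), "same pollutants")
  expect_error(synthetic_site_spec(c(a = 1), c(a = 0.5),
                                   stability_freq = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(synthetic_site_spec(c(a = 1), c(a = 0.5), distances = c(-5)),
               "distances")
})
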