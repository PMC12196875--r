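test_that("dispersion coefficients follow the power-law oracle", {
  p <- dispersion_params(gamma1 = 0.1, alpha1 = 0.9, gamma2 = 0.05,
                         alpha2 = 0.7, valid_range = c(1, 1000))
  sig <- dispersion_coefficients(p, 100)
  expect_equal(sig[["sigma_y"]], 0.1 * 100^0.9)
  expect_equal(sig[["sigma_z"]], 0.05 * 100^0.7)
  # exponent identity at x = 1 m
  expect_equal(unname(dispersion_coefficients(p, 1)), c(0.1, 0.05))
  # strictly increasing in x
  xs <- c(2, 5, 20, 100, 400, 1000)
  sy <- vapply(xs, function(x) dispersion_coefficients(p, x)[["sigma_y"]],
               numeric(1))
  expect_true(all(diff(sy) > 0))
  expect_error(dispersion_coefficients(p, 2000), "valid range")
})

test_that("the packaged stability table is total, ordered and regime-continuous", {
  for (cl in c("A", "B", "C", "D", "E", "F")) {
    sig <- dispersion_coefficients(stability_param_table(cl, 100), 100)
    expect_true(all(is.finite(sig)) && all(sig > 0))
  }
  # unstable air disperses more: sigma decreases monotonically A -> F
  for (x in c(20, 50, 100, 250)) {
    sigs <- t(vapply(c("A", "B", "C", "D", "E", "F"), function(cl) {
      dispersion_coefficients(stability_param_table(cl, x), x)
    }, numeric(2)))
    expect_true(all(diff(sigs[, "sigma_y"]) < 0), label = paste("sigma_y at", x))
    expect_true(all(diff(sigs[, "sigma_z"]) < 0), label = paste("sigma_z at", x))
  }
  expect_gt(dispersion_coefficients(stability_param_table("A", 50), 50)[["sigma_z"]],
            dispersion_coefficients(stability_param_table("F", 50), 50)[["sigma_z"]])
  # consecutive distance regimes agree within 5% at their shared boundary
  tab <- load_dispersion_table()
  for (cl in names(tab)) {
    regimes <- tab[[cl]]
    for (i in seq_len(length(regimes) - 1)) {
      xb <- regimes[[i]]$valid_range[2]
      expect_equal(regimes[[i + 1]]$valid_range[1], xb)
      near <- dispersion_coefficients(regimes[[i]], xb)
      far <- dispersion_coefficients(regimes[[i + 1]], xb)
      expect_equal(far[["sigma_y"]], near[["sigma_y"]], tolerance = 0.05)
      expect_equal(far[["sigma_z"]], near[["sigma_z"]], tolerance = 0.05)
    }
  }
  expect_error(stability_param_table("G", 50), "stability class")
  expect_error(stability_param_table("D", 5), "regime")
})

test_that("plume concentration matches the closed-form hand evaluation", {
  # x = 1 m makes sigma equal the table gamma exactly, so gamma = 10 gives
  # sigma_y = sigma_z = 10; at y = z = h = 0 both reflection terms are 1
  params <- dispersion_params(10, 0.9, 10, 0.8, valid_range = c(0.5, 10))
  met <- meteo_scenario("D", 2)
  rec <- receptor(downwind = 1, lateral = 0, receptor_height = 0,
                  release_height = 0)
  expect_equal(plume_concentration(1, met, rec, params), 2 / (2 * pi * 2 * 100))
  expect_identical(plume_concentration(0, met, rec, params), 0)
})

test_that("plume is laterally symmetric, linear in ER and inverse in wind", {
  params <- stability_param_table("D", 50)
  rec <- function(y) receptor(50, lateral = y)
  met <- meteo_scenario("D", 3)
  expect_equal(plume_concentration(2, met, rec(15), params),
               plume_concentration(2, met, rec(-15), params))
  expect_equal(plume_concentration(6, met, rec(0), params),
               3 * plume_concentration(2, met, rec(0), params))
  expect_equal(plume_concentration(2, meteo_scenario("D", 6), rec(0), params),
               plume_concentration(2, met, rec(0), params) / 2)
})

test_that("centerline ground-level concentration decays monotonically downwind", {
  xs <- seq(20, 250, by = 10)
  for (cl in c("A", "B", "C", "D", "E", "F")) {
    epc <- vapply(xs, function(x) {
      plume_concentration(5, meteo_scenario(cl, 3),
                          receptor(x, receptor_height = 0))
    }, numeric(1))
    expect_true(all(diff(epc) < 0), label = paste("class", cl))
  }
})

test_that("at fixed distance, ground-level exposure rises from class A to F", {
  # deteriorating dispersion concentrates the ground-release plume
  epc <- vapply(c("A", "B", "C", "D", "E", "F"), function(cl) {
    plume_concentration(5, meteo_scenario(cl, 3),
                        receptor(50, receptor_height = 0))
  }, numeric(1))
  expect_true(all(diff(epc) > 0))
})

test_that("crosswind-integrated flux conserves the emitted mass", {
  met <- meteo_scenario("D", 3)
  expect_equal(crosswind_integrated_flux(5, met, x = 100) / 5, 1,
               tolerance = 1e-3)
  # flux is independent of downwind distance
  f1 <- crosswind_integrated_flux(2, met, x = 50)
  f2 <- crosswind_integrated_flux(2, met, x = 250)
  expect_equal(f1, f2, tolerance = 1e-3)
  # and of the geometry convention details for an elevated source
  f3 <- crosswind_integrated_flux(2, met, x = 100, release_height = 2)
  expect_equal(f3 / 2, 1, tolerance = 1e-3)
})

test_that("geometry and meteorology invariants are enforced", {
  expect_error(receptor(-10), "downwind")
  expect_error(receptor(0), "downwind")
  expect_error(meteo_scenario("D", 0), "wind_speed")
  expect_error(meteo_scenario("Q", 3), "stability class")
  expect_error(dispersion_params(0.1, 2.5, 0.1, 0.8), "alpha")
  expect_error(dispersion_params(-0.1, 0.9, 0.1, 0.8), "gamma1")
})
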