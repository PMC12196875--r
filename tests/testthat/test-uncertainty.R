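test_that("parameter distributions validate and draw reproducibly", {
  expect_error(dist_uniform(3, 1), "min")
  expect_error(dist_triangular(0, 5, 4), "mode")
  expect_error(dist_lognormal(0, -1), "sdlog")
  expect_error(dist_discrete(c("A", "B"), c(0.6, 0.5)), "sum to 1")
  withr::local_seed(11)
  d <- dist_triangular(1, 2, 6)
  x <- draw_samples(d, 5000)
  expect_true(all(x > 1 & x < 6))
  expect_equal(mean(x), 3, tolerance = 0.05)  # (1+2+6)/3
  set.seed(3); a <- draw_samples(d, 10)
  set.seed(3); b <- draw_samples(d, 10)
  expect_identical(a, b)
  expect_equal(mean(dist_lognormal(1, 0.5)), exp(1 + 0.125))
})

test_that("fit_lognormal recovers hand log-space fits and refuses bad input", {
  d <- fit_lognormal(c(5, 5, 5, 5))
  expect_equal(d$params$meanlog, log(5))
  expect_equal(d$params$sdlog, 0)
  d2 <- fit_lognormal(c(1, 10, 100))          # log10-symmetric, median 10
  expect_equal(exp(d2$params$meanlog), 10)
  expect_equal(d2$params$sdlog, sd(log(c(1, 10, 100))))
  expect_error(fit_lognormal(c(1, 2)), "at least 3")
  expect_error(fit_lognormal(c(1, -2, 3, 0)), "index\\(es\\): 2, 4")
})

test_that("fit_lognormal recovers generating parameters within 3 standard errors", {
  withr::local_seed(202)
  n <- 10000
  x <- rlnorm(n, meanlog = 1, sdlog = 0.5)
  d <- fit_lognormal(x)
  expect_lt(abs(d$params$meanlog - 1), 3 * 0.5 / sqrt(n))
  expect_lt(abs(d$params$sdlog - 0.5), 3 * 0.5 / sqrt(2 * n))
})

test_that("a single-draw point-distribution run equals the deterministic chain", {
  sc <- toy_scenario(cs = 80, wind = 3,
                     cs_dist = list(toyene = dist_point(80)))
  mc <- run_monte_carlo(sc, mc_config(n_iterations = 1, seed = 5,
                                      randomized = "cs"))
  det <- assess_deterministic(sc)
  expect_equal(unname(mc$samples$epc[1, ]), det$epc)
  expect_equal(unname(mc$samples$oav[1, ]), det$oav)
  expect_equal(unname(mc$samples$oi[1, ]), det$oi)
})

test_that("identical seeds give bit-identical results, different seeds differ", {
  sc <- toy_scenario(cs_dist = list(toyene = dist_lognormal(log(50), 0.4)),
                     wind = dist_uniform(2, 5))
  cfg <- mc_config(n_iterations = 200, seed = 42)
  expect_identical(run_monte_carlo(sc, cfg), run_monte_carlo(sc, cfg))
  other <- run_monte_carlo(sc, mc_config(n_iterations = 200, seed = 43))
  expect_false(identical(other$samples$oi, run_monte_carlo(sc, cfg)$samples$oi))
})

test_that("randomized parameters without distributions are rejected up front", {
  sc <- toy_scenario()  # no cs_dist
  expect_error(run_monte_carlo(sc, mc_config(10, 1, randomized = "cs")),
               "cs\\[toyene\\]")
  expect_error(run_monte_carlo(sc, mc_config(10, 1, randomized = "theta_air")),
               "theta_air")
  expect_error(mc_config(10, 1, randomized = "humidity"), "unknown randomized")
})

test_that("an all-zero source degenerates to -Inf intensities with a warning", {
  sc <- toy_scenario(cs = 0, cs_dist = list(toyene = dist_point(0)))
  expect_warning(mc <- run_monte_carlo(sc, mc_config(50, 1, randomized = "cs")),
                 "all-zero")
  expect_true(all(mc$samples$oi == -Inf))
  expect_equal(exceedance_probability(mc, "toyene", 1), 0)
})

test_that("Monte Carlo pushforward matches the closed-form normal oracle", {
  # with only cs lognormal, OI is affine in log10(cs): every other factor in
  # the chain is a constant computed here by hand from the model formulas
  mu <- log(50); sig <- 0.6; n <- 10000
  sc <- toy_scenario(cs = exp(mu + sig^2 / 2), x = 50, z = 0, wind = 3,
                     cs_dist = list(toyene = dist_lognormal(mu, sig)))
  mc <- run_monte_carlo(sc, mc_config(n_iterations = n, seed = 9,
                                      randomized = "cs"))
  sy <- 0.2 * 50^0.9; sz <- 0.1 * 50^0.8
  amp <- (0.25 * 1500 / 1.775) * (150 / 3600 * 0.3) * 2 /
    (2 * pi * 3 * sy * sz) / 0.1                 # OAV per unit cs
  m <- 1.4 * (log10(amp) + mu / log(10)) + 1
  s <- 1.4 * sig / log(10)
  oi <- mc$samples$oi[, "toyene"]
  ks <- suppressWarnings(stats::ks.test(oi, "pnorm", m, s))
  expect_lt(unname(ks$statistic), 0.02)
  for (L in c(m - s, m, m + s)) {
    p_true <- 1 - pnorm(L, m, s)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(exceedance_probability(mc, "toyene", L) - p_true), 3 * se)
  }
  q_true <- qnorm(0.95, m, s)
  se_q <- sqrt(0.95 * 0.05 / n) / dnorm(q_true, m, s)
  expect_lt(abs(percentile_value(mc, "toyene", 95) - q_true), 3 * se_q)
  expect_equal(percentile_value(mc, "toyene", 95), q_true, tolerance = 0.02)
})

fake_result <- function(v, name = "x") {
  structure(list(pollutants = name,
                 samples = list(oi = matrix(v, ncol = 1,
                                            dimnames = list(NULL, name)))),
            class = "mc_result")
}

test_that("exceedance uses strict inequality and complements exactly", {
  r <- fake_result(c(1, 2, 2, 3, 5))
  expect_equal(exceedance_probability(r, "x", 0), 1)     # below the minimum
  expect_equal(exceedance_probability(r, "x", 10), 0)    # above the maximum
  expect_equal(exceedance_probability(r, "x", 2), 2 / 5) # ties not exceeding
  levels <- seq(0, 6, by = 0.5)
  ps <- vapply(levels, function(L) exceedance_probability(r, "x", L), numeric(1))
  expect_true(all(diff(ps) <= 0))
  oi <- r$samples$oi[, 1]
  for (L in levels) {
    expect_identical(exceedance_probability(r, "x", L) + mean(oi <= L), 1)
  }
  expect_error(exceedance_probability(r, "nope", 1), "not present")
})

test_that("percentiles use the linear-interpolation convention and stay ordered", {
  r <- fake_result(as.numeric(1:100))
  expect_equal(percentile_value(r, "x", 50), 50.5)
  qs <- c(5, 25, 50, 75, 95)
  vals <- vapply(qs, function(q) percentile_value(r, "x", q), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(percentile_value(r, "x", 0), "strictly within")
  expect_error(percentile_value(r, "x", 100), "strictly within")
})

test_that("percentile-ratio reporting reproduces the printed toluene contrast", {
  # a sample whose 50th/95th empirical percentiles are the printed odor
  # concentrations 67 and 206 yields the printed 32.5% median-to-UCL ratio
  v <- c(seq(1, 67, length.out = 51),      # v[51] is the exact 50th percentile
         seq(70, 206, length.out = 45),    # v[96] is the exact 95th percentile
         seq(230, 310, length.out = 5))
  r <- fake_result(v)
  p50 <- percentile_value(r, "x", 50)
  p95 <- percentile_value(r, "x", 95)
  expect_equal(p50, 67)
  expect_equal(p95, 206)
  expect_equal(round(100 * p50 / p95, 1), 32.5)
})

test_that("the sampled ECDF is a valid distribution function", {
  sc <- toy_scenario(cs_dist = list(toyene = dist_lognormal(log(20), 0.5)),
                     wind = dist_uniform(2, 5))
  mc <- run_monte_carlo(sc, mc_config(500, 3))
  F <- mc_ecdf(mc, "toyene")
  grid <- seq(min(mc$samples$oi) - 1, max(mc$samples$oi) + 1, length.out = 200)
  vals <- F(grid)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[1], 0)
  expect_equal(vals[length(vals)], 1)
})
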