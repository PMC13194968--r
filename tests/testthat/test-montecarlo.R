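test_that("distribution specs draw correctly", {
  expect_equal(sample_dist(dist_spec("point", value = 5), 3), c(5, 5, 5))
  d <- dist_spec("normal", mean = 10, sd = 4, low = 8, high = 13)
  x <- sample_dist(d, 5000, seed = 1)
  expect_true(all(x >= 8 & x <= 13))
  # lognormal empirical median vs analytic e^mu
  dl <- dist_spec("lognormal", meanlog = 1.2, sdlog = 0.7)
  x <- sample_dist(dl, 1e6, seed = 2)
  med <- median(x)
  # SE of the median: 1/(2 f(m) sqrt(n)) with lognormal density at e^mu
  f_med <- stats::dlnorm(exp(1.2), 1.2, 0.7)
  se <- 1 / (2 * f_med * sqrt(1e6))
  expect_lt(abs(med - exp(1.2)), 3 * se)
  # reproducibility
  expect_identical(sample_dist(dl, 100, seed = 9),
                   sample_dist(dl, 100, seed = 9))
  expect_error(dist_spec("triangular", min = 2, mode = 1, max = 3), "min")
  expect_error(dist_spec("uniform", min = 2, max = 1), "min")
})

test_that("triangular quantile inverts its CDF", {
  d <- dist_spec("triangular", min = 1, mode = 3, max = 7)
  p <- seq(0.001, 0.999, length.out = 101)
  q <- dist_quantile(d, p)
  expect_true(all(diff(q) > 0))
  expect_equal(soilrisk:::ptri(q, 1, 3, 7), p, tolerance = 1e-12)
})

test_that("point-mass simulation equals the deterministic model", {
  p <- default_exposure_profiles()$child
  model <- build_hi_model("Cr", p)
  point_dists <- list(
    conc = dist_spec("point", value = 184.85),
    ing_r = dist_spec("point", value = p$ing_r),
    inh_r = dist_spec("point", value = p$inh_r),
    bw = dist_spec("point", value = p$bw),
    sa = dist_spec("point", value = p$sa),
    af = dist_spec("point", value = p$af),
    ef_d = dist_spec("point", value = p$ef_d),
    ed = dist_spec("point", value = p$ed)
  )
  mc <- run_simulation(model, point_dists, n = 100, seed = 1,
                       thresholds = 1)
  tox <- default_toxicity()
  r <- tox[tox$metal == "Cr", ]
  adi <- c(ing = adi_ingestion(184.85, p),
           inh = adi_inhalation(184.85, p),
           derm = adi_dermal(184.85, p, r$abs))
  det <- hazard_quotients(adi, r)$hi
  for (s in c("p5", "p50", "p95", "mean")) {
    expect_equal(mc$stats[[s]], det, tolerance = 1e-12)
  }
  expect_true(mc$exceedance$p_exceed %in% c(0, 1))
})

test_that("identity model reproduces analytic uniform quantiles", {
  mc <- run_simulation(function(p) p$x,
                       list(x = dist_spec("uniform", min = 0, max = 1)),
                       n = 1e6, seed = 3, thresholds = 0.9)
  # binomial SE for the exceedance, quantile SE for the median
  expect_lt(abs(mc$exceedance$p_exceed - 0.1),
            3 * sqrt(0.1 * 0.9 / 1e6))
  expect_lt(abs(mc$stats[["p50"]] - 0.5), 3 * 0.5 / sqrt(1e6))
})

test_that("output variance adds across independent terms", {
  dists <- list(a = dist_spec("point", value = 2),
                b = dist_spec("normal", mean = 0, sd = 3))
  mc <- run_simulation(function(p) p$a + p$b, dists, n = 2e5, seed = 4)
  # var = 9; sampling SE of the variance ~ sqrt(2/n) * var
  expect_lt(abs(mc$stats[["sd"]]^2 - 9), 3 * sqrt(2 / 2e5) * 9)
})

test_that("summaries are percentile-monotone, seeded, and linear in scale", {
  p <- default_exposure_profiles()$child
  model <- build_hi_model("Cd", p)
  dists <- default_risk_distributions("Cd", p)
  mc1 <- run_simulation(model, dists, n = 2000, seed = 5, thresholds = 1)
  mc2 <- run_simulation(model, dists, n = 2000, seed = 5, thresholds = 1)
  expect_identical(mc1$stats, mc2$stats)
  expect_lte(mc1$stats[["p5"]], mc1$stats[["p50"]])
  expect_lte(mc1$stats[["p50"]], mc1$stats[["p95"]])
  expect_gte(mc1$exceedance$p_exceed, 0)
  expect_lte(mc1$exceedance$p_exceed, 1)
  # scaling the concentration scales every percentile
  k <- 2.5
  dists_k <- dists
  dists_k$conc <- dist_spec("lognormal",
                            meanlog = dists$conc$par$meanlog + log(k),
                            sdlog = dists$conc$par$sdlog)
  mc_k <- run_simulation(model, dists_k, n = 2000, seed = 5)
  for (s in c("p5", "p50", "p95")) {
    expect_equal(mc_k$stats[[s]], k * mc1$stats[[s]], tolerance = 1e-9)
  }
})

test_that("model failures abort with the draw index", {
  dists <- list(x = dist_spec("uniform", min = -1, max = 1))
  expect_error(suppressWarnings(
    run_simulation(function(p) sqrt(p$x), dists, n = 50, seed = 1)),
    "draw")
})

test_that("convergence diagnostics behave at both extremes", {
  dists <- list(x = dist_spec("point", value = 2))
  cc <- convergence_check(function(p) p$x, dists,
                          ns = c(100, 200, 400), seed = 1)
  expect_true(all(cc$rel_diff == 0))
  expect_false(any(cc$flag))
  # heavy-tailed output at tiny n: at least one statistic flagged
  heavy <- list(x = dist_spec("lognormal", meanlog = 0, sdlog = 3))
  cc2 <- convergence_check(function(p) p$x, heavy, ns = c(10, 50),
                           seed = 2)
  expect_true(any(cc2$flag[cc2$n == 10]))
  expect_error(convergence_check(function(p) p$x, dists,
                                 ns = c(200, 100), seed = 1), "ascending")
})
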