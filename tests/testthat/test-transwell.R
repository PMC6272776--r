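test_that("time-course and geometry constructors validate inputs", {
  expect_error(time_course(c(5, 5), c(1, 2), 10), "strictly increasing")
  expect_error(time_course(5, 1, 10), "length >= 2")
  expect_error(time_course(c(5, 15), c(-1, 2), 10), ">= 0")
  expect_error(time_course(c(5, 15), c(1, 2), 0), "c0_apical")
  expect_error(transwell_geometry(v_sample = 0.9), "smaller")
  expect_error(transwell_geometry(area = -1), "positive")
})

test_that("sampling correction restores previously removed aliquot mass", {
  geom <- transwell_geometry()   # Vb 0.9 mL, 0.1 mL aliquots
  tc <- time_course(c(5, 15), c(10, 10), 100)
  expect_equal(cumulative_amounts(tc, geom), c(9.0, 10.0))

  tc0 <- time_course(c(5, 15, 30), c(0, 0, 0), 100)
  expect_equal(cumulative_amounts(tc0, geom), c(0, 0, 0))

  tc2 <- time_course(c(5, 15), c(5, 0), 100)
  expect_equal(cumulative_amounts(tc2, geom), c(4.5, 0.5))

  expect_equal(cumulative_amounts(tc2, geom, correct_sampling = FALSE),
               c(4.5, 0))
})

test_that("cumulative amounts re-simulate the chamber mass balance", {
  # independent oracle: step the chamber forward, drawing and replacing
  set.seed(6)
  conc <- cumsum(abs(rnorm(6)))
  tc <- time_course(c(5, 10, 20, 40, 60, 120), conc, 1000)
  geom <- transwell_geometry()
  removed <- 0
  oracle <- numeric(6)
  for (i in seq_along(conc)) {
    present <- geom$v_basolateral * conc[i]
    oracle[i] <- present + removed
    removed <- removed + geom$v_sample * conc[i]
  }
  expect_equal(cumulative_amounts(tc, geom), oracle, tolerance = 1e-12)
})

test_that("quadratic fitting reproduces exact polynomials", {
  t_min <- c(1, 2, 4, 8, 16)
  t_s <- t_min * 60
  expect_equal(unname(fit_cumulative(t_min, 2 * t_s)), c(0, 2, 0),
               tolerance = 1e-9)
  q <- 1 + 3 * t_s - 0.5 * t_s^2
  expect_equal(unname(fit_cumulative(t_min, q)), c(1, 3, -0.5),
               tolerance = 1e-9)
  # two points: linear fallback
  expect_equal(unname(fit_cumulative(c(1, 2), c(60, 120))), c(0, 1, 0),
               tolerance = 1e-12)
  expect_error(fit_cumulative(1, 1), "at least 2")
})

test_that("least-squares residuals are orthogonal to the design columns", {
  set.seed(17)
  t_min <- c(5, 15, 30, 60, 120)
  t_s <- t_min * 60
  q <- 0.3 + 0.02 * t_s - 1e-6 * t_s^2 + rnorm(5, sd = 0.5)
  co <- fit_cumulative(t_min, q)
  res <- q - (co[["a"]] + co[["b"]] * t_s + co[["c"]] * t_s^2)
  for (col in list(rep(1, 5), t_s, t_s^2))
    expect_lt(abs(sum(res * col)) / sqrt(sum(col^2)), 1e-8)
})

test_that("initial slope modes read the fit and the leading points", {
  expect_equal(initial_slope(c(a = 0, b = 2, c = 0)), 2)
  expect_equal(initial_slope(c(a = 1, b = 3, c = -0.5)), 3)
  t_min <- c(1, 2, 3, 10)
  q <- 4 * t_min * 60
  co <- fit_cumulative(t_min, q)
  expect_equal(initial_slope(co, "first_k_points", t_min, q, k = 3), 4,
               tolerance = 1e-9)
  expect_warning(initial_slope(c(a = 0, b = -1, c = 0)), "flux reversal")
})

test_that("papp_fit recovers the permeability implied by a linear course", {
  # cumulative-concentration slope 0.460 ug/mL/s at C0 = 1e5 ug/mL
  geom <- transwell_geometry()
  spec <- synthetic_spec(seed = 1,
                         transwell = list(papp_true = 12.32e-6,
                                          noise_sd = 0))
  fit <- papp_fit(simulate_transwell(spec, geom), geom)
  expect_equal(fit$slope, 0.460, tolerance = 1e-3)
  expect_equal(fit$papp, 1.232e-5, tolerance = 1e-3)
  expect_equal(fit$papp, 0.460 * 0.9 / (0.336 * 1e5), tolerance = 1e-3)
  expect_equal(fit$permeation_class, "high_bioavailable")
  expect_equal(fit$n_points_used, 5L)

  # zero flux
  tc0 <- time_course(c(5, 15, 30), c(0, 0, 0), 1000)
  f0 <- papp_fit(tc0, geom)
  expect_equal(f0$papp, 0)

  # doubling C0 at a fixed measured course halves Papp
  tc1 <- simulate_transwell(spec, geom)
  tc2 <- time_course(tc1$times_min, tc1$conc, tc1$c0_apical * 2)
  expect_equal(papp_fit(tc2, geom)$papp, fit$papp / 2, tolerance = 1e-12)
})

test_that("papp_fit behaves like a model object", {
  spec <- synthetic_spec(seed = 9, transwell = list(noise_sd = 0.05))
  tc <- simulate_transwell(spec)
  fit <- papp_fit(tc)
  expect_s3_class(fit, "papp_fit")
  expect_named(coef(fit), c("a", "b", "c"))
  expect_length(fitted(fit), 5L)
  expect_equal(residuals(fit), fit$q_conc - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), unname(coef(fit)[["a"]]))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "time_course")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("late samples can be excluded through max_time_min", {
  spec <- synthetic_spec(seed = 2,
                         transwell = list(model = "two_compartment",
                                          noise_sd = 0))
  tc <- simulate_transwell(spec)
  fit_all <- papp_fit(tc)
  fit_early <- papp_fit(tc, max_time_min = 60)
  expect_equal(fit_early$n_points_used, 4L)
  expect_gt(fit_early$papp, 0)
  expect_error(papp_fit(tc, max_time_min = 4), "fewer than 2")
  expect_false(identical(fit_all$papp, fit_early$papp))
})

test_that("permeability classification applies the printed thresholds", {
  expect_equal(classify_permeability(12.32e-6), "high_bioavailable")
  expect_equal(classify_permeability(0.5e-6), "low")
  expect_equal(classify_permeability(1.5e-6), "high")
  expect_equal(classify_permeability(1e-6), "low")       # boundary: <= low
  expect_equal(classify_permeability(2e-6), "high")      # boundary: <= high
  expect_error(classify_permeability(-1e-6), ">= 0")
})

test_that("dose equivalence converts drug to complex concentration", {
  expect_equal(dose_equivalent(40, 0.086), 465.1, tolerance = 1e-3)
  expect_equal(dose_equivalent(12.5, 1.0), 12.5)
  expect_equal(dose_equivalent(8.6, 0.086), 100)
  expect_error(dose_equivalent(40, 0), "\\(0, 1\\]")
  expect_error(dose_equivalent(40, 1.2), "\\(0, 1\\]")
})

test_that("time-course CSV round-trips", {
  spec <- synthetic_spec(seed = 5)
  tc <- simulate_transwell(spec)
  p <- tempfile(fileext = ".csv")
  write_time_course(tc, p)
  back <- read_time_course(p, tc$c0_apical)
  expect_equal(back$times_min, tc$times_min)
  expect_equal(back$conc, tc$conc, tolerance = 1e-12)
})
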