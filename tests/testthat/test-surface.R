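test_that("noise-free quadratic responses are interpolated exactly", {
  ks <- known_surface()
  fit <- fit_surface(ks$design, "y")
  expect_rel_equal(fit$coefficients$intercept, ks$coefs$intercept, 1e-9)
  for (f in names(ks$coefs$linear)) {
    expect_rel_equal(fit$coefficients$linear[[f]], ks$coefs$linear[[f]], 1e-9)
    expect_rel_equal(fit$coefficients$quadratic[[f]], ks$coefs$quadratic[[f]], 1e-9)
  }
  for (nm in names(ks$coefs$interaction)) {
    expect_rel_equal(fit$coefficients$interaction[[nm]], ks$coefs$interaction[[nm]], 1e-9)
  }
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # prediction at a design point returns the generating value
  expect_equal(predict(fit, ks$design[1, ]), ks$design$y[1], tolerance = 1e-9)
})

test_that("a constant response gives intercept c and zero effects", {
  design <- bbd_design_from_surface()
  design$y <- 3.7
  fit <- fit_surface(design, "y")
  expect_equal(fit$coefficients$intercept, 3.7, tolerance = 1e-9)
  expect_equal(max(abs(c(fit$coefficients$linear, fit$coefficients$quadratic,
                         fit$coefficients$interaction))), 0, tolerance = 1e-9)
  expect_equal(predict(fit, design[4, ]), 3.7, tolerance = 1e-9)
})

test_that("the Box-Behnken selectivity refit matches the published R2", {
  fit <- fit_surface(bbd3(), "selectivity", scale = "fraction")
  expect_equal(fit$r_squared, 0.9125, tolerance = 5e-4 / 0.9125)
})

test_that("degenerate designs are rejected informatively", {
  design <- bbd_design_from_surface()
  expect_error(fit_surface(design[1:8, ], "y"), "at least")
  # collapse G to a single level -> G and G^2 collinear with the intercept
  flat <- design
  flat$G <- 60
  attr(flat, "factors") <- attr(design, "factors")
  expect_error(fit_surface(flat, "y"), "rank deficient")
  expect_error(fit_surface(design, "nope"), "unknown response")
})

test_that("runs with missing responses are dropped with a warning", {
  ks <- known_surface()
  design <- ks$design
  design$y[3] <- NA
  expect_warning(fit <- fit_surface(design, "y"), "dropping 1 run")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("percent/fraction refits differ by exactly 100x with invariant inference", {
  d <- bbd3()
  f_pct <- fit_surface(d, "selectivity", scale = "percent")
  f_frc <- fit_surface(d, "selectivity", scale = "fraction")
  est_p <- tidy(f_pct)$estimate
  est_f <- tidy(f_frc)$estimate
  expect_lt(max(abs(est_p / est_f - 100)), 1e-10 * 100)
  expect_rel_equal(f_pct$r_squared, f_frc$r_squared, 1e-12)
  # rescale_surface is exact by construction
  r <- rescale_surface(f_frc, "percent")
  expect_identical(tidy(r)$estimate, est_f * 100)
  expect_equal(predict(r, d[1, ]), predict(f_pct, d[1, ]), tolerance = 1e-10)
})

test_that("two-level factorial effects match direct arithmetic on the corners", {
  t1 <- fact1()
  corners <- design_table(
    tibble::as_tibble(t1)[t1$P != 180, ],
    attr(t1, "factors"), attr(t1, "responses")
  )
  fit <- fit_factorial(corners, "yield")
  # hand least squares on corner yields 1.25, 1.70, 1.71, 2.49
  expect_equal(fit$coefficients$intercept, 1.7875, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients$linear["P"]), 0.3125, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients$linear["M"]), 0.3075, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients$interaction), 0.0825, tolerance = 1e-12)
  expect_equal(unname(fit$effects), c(0.625, 0.615, 0.165), tolerance = 1e-12)

  # all 7 runs with the centre indicator: curvature = mean(centre) - mean(corners)
  fit7 <- fit_factorial(t1, "yield", center_term = TRUE)
  expect_equal(fit7$coefficients$curvature, 2.30 - 1.7875, tolerance = 1e-12)
  expect_equal(unname(fit7$coefficients$linear["P"]), 0.3125, tolerance = 1e-12)

  # constant response -> zero effects
  flat <- corners
  flat$yield <- 2
  expect_equal(max(abs(fit_factorial(flat, "yield")$effects)), 0, tolerance = 1e-12)

  expect_error(fit_factorial(corners, "yield", center_term = TRUE), "no centre")
})

test_that("coefficient recovery error shrinks with the noise level", {
  ks <- known_surface()
  truth <- tidy(fit_surface(ks$design, "y"))$estimate
  mean_err <- vapply(c(1e-1, 1e-2, 1e-3), function(sigma) {
    errs <- vapply(1:100, function(s) {
      noisy <- simulate_design_response(
        fit_surface(ks$design, "y"), ks$design,
        noise = noise_spec("additive", sigma = sigma, seed = s)
      )
      mean(abs(tidy(fit_surface(noisy, "y"))$estimate - truth))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("printed reference coefficients are available for display", {
  eq2 <- printed_surface_coefficients("bbd_selectivity")
  expect_equal(nrow(eq2), 10L)
  expect_equal(eq2$estimate[eq2$term == "(Intercept)"], -9.742)
  eq1 <- printed_surface_coefficients("factorial_yield")
  expect_equal(eq1$estimate[eq1$term == "P"], 0.32906)
})
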