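test_that("a perfect line is fitted exactly at degree 1", {
  fit <- fit_polynomial(line_curve(), 1)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(100, -1), tolerance = 1e-9)
})

test_that("an exact quadratic returns its generating coefficients", {
  t <- seq(0, 100, by = 10)
  cv <- kinetic_curve(t, 100 - 0.01 * t^2)
  fit <- fit_polynomial(cv, 2)
  expect_equal(unname(fit$coefficients), c(100, 0, -0.01), tolerance = 1e-8)
})

test_that("overall-F p-values are uniform on a flat noisy curve", {
  n <- 20; times <- seq(0, 336, length.out = n)
  pvals <- vapply(1:400, function(r) {
    y <- withr::with_seed(r, c(100, 100 + rnorm(n - 1, 0, 3)))
    y[1] <- 100
    fit_polynomial(kinetic_curve(times, abs(y)), 1)$f_pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("r2 never decreases with degree on the same data", {
  cv <- simulate_kinetic_curve(logistic_trajectory(hours14d, 150),
                               noise_sd = 0.05, seed = 21)
  r2s <- vapply(1:6, function(d) fit_polynomial(cv, d)$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("degree selection finds exact low-degree generators", {
  t <- seq(0, 300, by = 20)
  cubic <- kinetic_curve(t, 100 - 0.4 * t + 0.005 * t^2 - 1e-5 * t^3)
  expect_identical(select_degree(cubic)$degree, 3L)
  expect_identical(select_degree(line_curve())$degree, 1L)
})

test_that("degenerate curves are rejected with named errors", {
  flat <- kinetic_curve(seq(0, 100, 10), rep(100, 11))
  expect_error(fit_polynomial(flat, 1), "no variance")
  short <- kinetic_curve(c(0, 1, 2), c(100, 90, 80))
  expect_error(fit_polynomial(short, 2), "insufficient points")
  expect_error(select_degree(kinetic_curve(c(0, 1, 2), c(100, 90, 80))),
               "at least 4 points")
})

test_that("t50 of a fitted line is analytic and shifts with time", {
  fit <- t50_fit(line_curve(seq(0, 300, by = 20), slope = 1))
  expect_equal(fit$t50, 50, tolerance = 1e-6)
  # time-shift equivariance
  shifted <- kinetic_curve(seq(0, 300, by = 20) + 37, 100 - seq(0, 300, by = 20))
  fit2 <- t50_fit(shifted)
  expect_equal(fit2$t50, 87, tolerance = 1e-6)
})

test_that("curves that never reach the level are censored, not numbers", {
  t <- seq(0, 300, by = 20)
  slow <- kinetic_curve(t, 100 - 0.1 * t)  # ends at 70%
  fit <- t50_fit(slow)
  expect_true(is.na(fit$t50))
  expect_identical(fit$censored, "> 300")
  # a curve entirely below the level is left-censored
  low <- t50_fit(line_curve(), level = 101)
  expect_identical(low$censored, "< 0")
})

test_that("pure-noise curves are declared non-significant at about the alpha rate", {
  n <- 20; times <- seq(0, 336, length.out = n)
  none <- vapply(1:300, function(r) {
    y <- withr::with_seed(1000 + r, abs(c(100, 100 + rnorm(n - 1, 0, 4))))
    y[1] <- 100
    inherits(tryCatch(select_degree(kinetic_curve(times, y)),
                      error = function(e) e), "error")
  }, logical(1))
  expect_gt(mean(none), 0.90)
  expect_lt(mean(none), 0.99)
})

test_that("t50_fit recovers a known logistic t50 from noisy replicates", {
  errs <- vapply(1:20, function(r) {
    cv <- simulate_kinetic_curve(logistic_trajectory(hours14d, 120),
                                 noise_sd = 0.05, seed = 3000 + r)
    abs(t50_fit(cv)$t50 - 120) / 120
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("t50_fit behaves like a model object", {
  cv <- simulate_kinetic_curve(logistic_trajectory(hours14d, 150),
                               noise_sd = 0.03, seed = 41)
  fit <- t50_fit(cv)
  expect_s3_class(fit, "t50_fit")
  expect_length(coef(fit), fit$degree + 1)
  expect_equal(unname(predict(fit)), fitted(fit), tolerance = 1e-9)
  expect_equal(fitted(fit) + residuals(fit), cv$values, tolerance = 1e-9)
  expect_output(print(fit), "t50 = ")
  expect_output(print(summary(fit)), "Candidate degrees")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(15L, 3L))
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
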