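# frozen values: printed success probability and odds at eta = 0,
# cross-checked against pi/(1-pi) with pi = 0.419974341614026
PI0 <- 0.419974341614026
ODDS0 <- 0.724061660966311

test_that("success probability and odds match their printed forms", {
  expect_equal(taba_success_prob(0), PI0, tolerance = 1e-12)
  eta <- seq(-20, 20, length.out = 401)
  expect_true(all(diff(taba_success_prob(eta)) > 0))
  expect_true(all(diff(taba_odds(eta)) > 0))
  # complement identity: pi + tanh^2(sqrt(1+eta^2) - eta) = 1
  u <- sqrt(1 + eta^2) - eta
  expect_equal(taba_success_prob(eta) + tanh(u)^2, rep(1, length(eta)),
               tolerance = 1e-12)
  expect_equal(taba_odds(0), ODDS0, tolerance = 1e-10)
  pi <- taba_success_prob(eta)
  expect_equal(taba_odds(eta) * (1 - pi), pi, tolerance = 1e-12)
  # log-space path keeps deep-tail odds finite (underflow to 0 is the
  # closest double to the true 1e-869-scale odds)
  expect_true(is.finite(taba_odds(-500)) && taba_odds(-500) >= 0)
  expect_gt(taba_odds(-100), 0)
  expect_error(taba_success_prob(Inf), "non-finite")
})

test_that("binary loglik has its closed form at zero and is additive", {
  md <- simulate_taba_binary(400, beta = c(0.4, 0.9), seed = 13)
  ybar <- mean(md$outcome)
  expect_equal(taba_binary_loglik(c(0, 0), md),
               400 * (ybar * log(PI0) + (1 - ybar) * log(1 - PI0)),
               tolerance = 1e-10)
  # additivity over observations
  parts <- vapply(seq_len(md$n), function(i) {
    # single-row designs are trivially rank deficient; the warning is
    # not the point here
    one_obs <- suppressWarnings(
      taba_model_data(md$outcome[i], md$design[i, , drop = FALSE]))
    taba_binary_loglik(c(0.3, -0.2), one_obs)
  }, numeric(1))
  expect_equal(sum(parts), taba_binary_loglik(c(0.3, -0.2), md),
               tolerance = 1e-8)
  # certainty limit: y = 1 with a huge positive predictor
  one <- suppressWarnings(taba_model_data(1, matrix(c(1, 100), 1, 2)))
  expect_gt(taba_binary_loglik(c(0, 2), one), -1e-5)
  expect_error(taba_binary_loglik(c(0, 0, 0), md), "design columns")
})

test_that("fit recovers truth, scales with duplication, and needs two classes", {
  md <- simulate_taba_binary(5000, beta = c(0.3, 0.6, -0.4), seed = 41)
  fit <- taba_binary(md, diagnostics = FALSE)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$coefficients - c(0.3, 0.6, -0.4)) < 3 * se))

  # duplicating the data doubles the loglik, leaves estimates unchanged
  md2 <- taba_model_data(rep(md$outcome, 2), rbind(md$design, md$design))
  fit2 <- taba_binary(md2, diagnostics = FALSE)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-5)
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-6)

  expect_error(taba_binary(taba_model_data(rep(1, 10), cbind(1, rnorm(10)))),
               "single class")
})

test_that("complete separation is warned about", {
  x <- c(-(5:1), 1:5)
  md <- taba_model_data(as.numeric(x > 0), cbind(1, x))
  expect_warning(fit <- taba_binary(md, diagnostics = FALSE), "separation")
})

test_that("predict honours layout, threshold boundaries, and unused columns", {
  md <- simulate_taba_binary(200, beta = c(0.1, 0.5), seed = 51)
  fit <- taba_binary(md, diagnostics = FALSE)
  pr <- predict(fit)
  expect_true(all(pr > 0 & pr < 1))
  # all-zero row under beta = 0 gives pi(0), class 0 at threshold 0.5
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(predict(fit0, matrix(0, 1, 1)), PI0, tolerance = 1e-12)
  expect_equal(predict(fit0, matrix(0, 1, 1), type = "class"), 0)
  # boundary conventions (>=)
  expect_true(all(predict(fit, type = "class", threshold = 0) == 1))
  expect_true(all(predict(fit, type = "class", threshold = 1) == 0))
  # probabilities unaffected by a zero-coefficient appended column
  fitpad <- fit
  fitpad$coefficients <- c(fit$coefficients, extra = 0)
  Xpad <- cbind(md$design, rnorm(md$n))
  expect_equal(predict(fitpad, Xpad), pr, tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 1, 5)), "column count")
})

test_that("location-scale view matches the reparameterised distribution", {
  fit <- taba_binary(simulate_taba_binary(500, c(-2, 4), seed = 61),
                     diagnostics = FALSE)
  ls <- location_scale_view(fit)
  b <- fit$coefficients
  expect_equal(ls$location, -b[[1]] / b[[2]])
  expect_equal(ls$scale, 1 / b[[2]])
  # arithmetic example
  ls2 <- location_scale_view(fake_fit(c(-2, 4), diag(2), -1, 10, 2))
  expect_equal(ls2$location, 0.5)
  expect_equal(ls2$scale, 0.25)
  # pi computed both ways agrees
  x <- seq(-3, 3, length.out = 50)
  expect_equal(taba_success_prob(b[[1]] + b[[2]] * x),
               ptaba((x - ls$location) / ls$scale), tolerance = 1e-10)
  # negative slope: orientation flip warned, pi equality still holds
  fitn <- fake_fit(c(1, -2), diag(2), -1, 10, 2)
  expect_warning(lsn <- location_scale_view(fitn), "negative")
  expect_equal(taba_success_prob(1 - 2 * x),
               ptaba((x - lsn$location) / lsn$scale), tolerance = 1e-10)
  expect_error(location_scale_view(fake_fit(c(1, 0), diag(2), -1, 10, 2)),
               "zero")
  expect_error(location_scale_view(fake_fit(c(1, 2, 3), diag(3), -1, 10, 3)),
               "one predictor")
})

test_that("assumption diagnostics warn without altering the fit", {
  set.seed(71)
  x1 <- rnorm(150)
  x2 <- x1 + rnorm(150, sd = 0.01)  # near-collinear pair
  y <- as.numeric(runif(150) < taba_success_prob(0.4 * x1))
  md <- taba_model_data(y, cbind(1, x1, x2))
  expect_warning(fit <- taba_binary(md), "multicollinearity")
  fit_silent <- suppressWarnings(taba_binary(md))
  quiet <- taba_binary(md, diagnostics = FALSE)
  expect_equal(fit_silent$coefficients, quiet$coefficients)
})
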