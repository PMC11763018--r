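test_that("model data validates and encodes", {
  X <- cbind(1, rnorm(20))
  md <- taba_model_data(rep(0:1, 10), X)
  expect_s3_class(md, "taba_model_data")
  expect_equal(md$n, 20L)
  expect_equal(md$p, 1L)
  expect_null(md$k)

  # intercept prepended when absent
  md2 <- taba_model_data(rep(0:1, 10), matrix(rnorm(20), 20, 1))
  expect_equal(ncol(md2$design), 2L)
  expect_true(all(md2$design[, 1] == 1))

  # factor outcome -> 1..k codes with labels
  f <- factor(rep(c("a", "b", "c"), 7))
  mdf <- taba_model_data(f, cbind(1, rnorm(21)))
  expect_equal(mdf$k, 3L)
  expect_equal(sort(unique(mdf$outcome)), c(1, 2, 3))

  expect_error(taba_model_data(c(0, 1), X), "length")
  expect_error(taba_model_data(c(rep(0:1, 9), NA, 0), X), "missing")
  expect_error(taba_model_data(rep(1:2, 10)[-1], X), "length")
  # a category present in levels but absent in data
  expect_error(taba_model_data(factor(rep("a", 20), levels = c("a", "b")),
                               X), "category")
  expect_warning(taba_model_data(rep(0:1, 10), cbind(1, 1:20, 2 * (1:20))),
                 "rank")
})

test_that("formula interface builds the same design as model.matrix", {
  df <- data.frame(y = rep(0:1, 15), a = rnorm(30),
                   g = factor(rep(c("u", "v", "w"), 10)))
  md <- taba_model_frame(y ~ a + g, df)
  expect_equal(md$p, 3L)  # a + two indicator columns
  expect_equal(md$column_names[1], "(Intercept)")
})

test_that("maximize finds optima and reports convergence honestly", {
  # 1-D concave quadratic
  r <- taba_maximize(function(b) (b - 2)^2, init = 0)
  expect_true(r$converged)
  expect_equal(r$estimates, 2, tolerance = 1e-6)

  # init at the optimum: immediate convergence
  r2 <- taba_maximize(function(b) sum((b - c(1, -1))^2), init = c(1, -1))
  expect_true(r2$converged)
  expect_equal(r2$estimates, c(1, -1), tolerance = 1e-8)

  expect_error(taba_maximize(function(b) NaN, init = 0), "finite")
})

test_that("maximize agrees with the exhaustive grid oracle on a 1-predictor toy", {
  md <- simulate_taba_binary(60, beta = c(0.5, -1.2), seed = 21)
  x <- md$design[, 2]
  y <- md$outcome
  ll <- function(b0, b1) taba_binary_loglik(c(b0, b1), md)
  oracle <- grid_argmax2(ll)
  r <- taba_maximize(function(b) -taba_binary_loglik(b, md), init = c(0, 0))
  expect_true(r$converged)
  expect_equal(r$estimates, oracle, tolerance = 2e-3)
})

test_that("observed information matches closed forms and is symmetric", {
  # unit quadratic: -loglik = b^2/2 has curvature 1
  expect_equal(observed_information(function(b) b^2 / 2, 0),
               matrix(1), tolerance = 1e-6)

  # logistic regression toy: information is X' W X with W = p(1-p)
  set.seed(4)
  n <- 300
  X <- cbind(1, rnorm(n))
  eta <- drop(X %*% c(0.4, -0.7))
  y <- rbinom(n, 1, plogis(eta))
  bh <- coef(glm(y ~ X[, 2], family = binomial))
  negll <- function(b) {
    e <- drop(X %*% b)
    -sum(y * e - log1p(exp(e)))
  }
  w <- plogis(drop(X %*% bh)); w <- w * (1 - w)
  closed <- crossprod(X, X * w)
  H <- observed_information(negll, unname(bh))
  expect_equal(H, closed, tolerance = 1e-4)
  expect_equal(H, t(H), tolerance = 1e-12)
})

test_that("wald table follows the t(n) convention of the published table", {
  # the printed cirrhosis row: estimate/SE must reproduce the printed t,
  # and t referred to t(312) the printed p, to printed precision.
  # (df = n is the only convention that does: df = n - q = 292 puts the
  # prothrombin p at 0.000754 against a printed 0.000748, while df = 312
  # reproduces every printed p-value to within 6e-7.)
  expect_equal(0.316535 / 0.092958, 3.405133, tolerance = 1e-4)
  rows <- data.frame(t = c(3.405133, 3.582989, -3.993013),
                     p = c(0.000748, 0.000394, 0.000081))
  p_t312 <- 2 * pt(abs(rows$t), df = 312, lower.tail = FALSE)
  expect_lt(max(abs(p_t312 - rows$p)), 1e-6)

  fit <- fake_fit(c(a = 0.316535, b = 0), diag(c(0.092958^2, 1)),
                  loglik = -10, n_obs = 312, n_params = 20)
  wt <- wald_table(fit)
  expect_equal(wt$t_value, wt$estimate / wt$se, tolerance = 1e-6)
  expect_equal(wt$t_value[1], 3.405133, tolerance = 1e-4)
  expect_lt(abs(wt$p_value[1] - 0.000748), 1e-6)
  # zero estimate: t = 0, p = 1
  expect_equal(wt$t_value[2], 0)
  expect_equal(wt$p_value[2], 1)
})

test_that("non-positive variance rows are flagged, not dropped", {
  fit <- fake_fit(c(a = 1, b = 2), diag(c(0.04, -1)),
                  loglik = -5, n_obs = 50, n_params = 2)
  expect_warning(wt <- wald_table(fit), "non-positive")
  expect_equal(nrow(wt), 2L)
  expect_true(is.na(wt$se[2]) && !is.na(wt$estimate[2]))
})

test_that("information criteria reproduce the published values and identities", {
  # published AIC/BIC pair is consistent with -2l = 244.584, q = 20, n = 312
  fit <- fake_fit(numeric(20), diag(20), loglik = -122.292,
                  n_obs = 312, n_params = 20)
  ic <- information_criteria(fit)
  expect_equal(ic$minus2_loglik, 244.584, tolerance = 1e-10)
  expect_equal(ic$aic, 284.584, tolerance = 1e-10)
  expect_equal(ic$bic, 359.444, tolerance = 5e-4)
  expect_equal(ic$bic - ic$aic, 20 * (log(312) - 2), tolerance = 1e-10)

  fit0 <- fake_fit(numeric(0), matrix(0, 0, 0), loglik = -7,
                   n_obs = 10, n_params = 0)
  ic0 <- information_criteria(fit0)
  expect_equal(ic0$aic, 14)
  expect_equal(ic0$bic, 14)
})

test_that("reported loglik equals direct evaluation at the estimates", {
  md <- simulate_taba_binary(300, beta = c(0.2, 0.7), seed = 31)
  fit <- taba_binary(md, diagnostics = FALSE)
  expect_equal(fit$loglik, taba_binary_loglik(fit$coefficients, md),
               tolerance = 1e-10)
})
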