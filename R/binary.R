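#' Taba success probability and odds
#'
#' The binary Taba model links a linear predictor
#' \eqn{\eta = \beta_0 + \beta_1 x_1 + \dots + \beta_p x_p} to the success
#' probability through the Taba CDF:
#' \deqn{\pi(\eta) = \frac{1}{1 + \sinh^2(e^{-\mathrm{asinh}\,\eta})}
#'   = \mathrm{sech}^2\!\big(\sqrt{1+\eta^2} - \eta\big),}
#' strictly increasing in \eqn{\eta} with \eqn{\pi(0) \approx 0.42}.  The
#' odds of success are \eqn{\pi/(1-\pi) = 1/\sinh^2(e^{-\mathrm{asinh}\,\eta})},
#' evaluated in log space so that very negative \eqn{\eta} do not underflow.
#'
#' @param eta finite numeric vector of linear predictor values.
#' @return `taba_success_prob` a probability in (0, 1); `taba_odds` a
#'   positive odds value.
#' @examples
#' taba_success_prob(0)   # 0.4199743...
#' taba_odds(0)           # 1/sinh(1)^2
#' @export
taba_success_prob <- function(eta) ptaba(check_finite(eta, "eta"))

#' @rdname taba_success_prob
#' @export
taba_odds <- function(eta) {
  u <- taba_u(check_finite(eta, "eta"))
  exp(-2 * log_cosh(u) - 2 * log_tanh(u))
}

# log pi and log(1 - pi) at eta, stable over the whole real line
binary_logp <- function(eta) {
  u <- taba_u(eta)
  list(lf = -2 * log_cosh(u), ls = 2 * log_tanh(u))
}

# d log pi / d eta and d log(1-pi) / d eta (see dtaba for the density form)
binary_logp_grad <- function(eta) {
  u <- taba_u(eta)
  r <- sqrt(1 + eta * eta)
  list(g1 = 2 * u * tanh(u) / r,
       g0 = -4 * u / (sinh(2 * u) * r))
}

#' Binary Taba log-likelihood
#'
#' \eqn{\ell(\beta) = \sum_i y_i \ln \pi(x_i;\beta) +
#'   (1-y_i) \ln(1 - \pi(x_i;\beta))}, computed through the stable
#' log-CDF/log-survival forms.
#'
#' @param beta coefficient vector, ordered as the design columns.
#' @param data a [taba_model_data()] with 0/1 outcome.
#' @return the log-likelihood (a scalar, always \eqn{\le 0}).
#' @export
taba_binary_loglik <- function(beta, data) {
  stopifnot(inherits(data, "taba_model_data"))
  if (length(beta) != ncol(data$design))
    stop("length(beta) must equal the number of design columns", call. = FALSE)
  lp <- binary_logp(drop(data$design %*% beta))
  sum(ifelse(data$outcome == 1, lp$lf, lp$ls))
}

binary_negloglik <- function(theta, Z, y) {
  lp <- binary_logp(drop(Z %*% theta))
  -sum(ifelse(y == 1, lp$lf, lp$ls))
}

binary_neggrad <- function(theta, Z, y) {
  g <- binary_logp_grad(drop(Z %*% theta))
  -drop(crossprod(Z, ifelse(y == 1, g$g1, g$g0)))
}

#' Fit a binary Taba regression
#'
#' Maximum-likelihood fit of the binary Taba model.  Internally the
#' non-constant design columns are standardised for optimisation and the
#' estimates and covariance mapped back, so results are expressed on the
#' raw predictor scale.  The covariance is the inverse observed Fisher
#' information (central-difference Hessian at the optimum).
#'
#' Assumption diagnostics are advisory only: a large design condition
#' number (multicollinearity) or high-leverage rows trigger warnings and
#' never alter the fit.
#'
#' @param data a [taba_model_data()] with both outcome classes present, or
#'   a formula (with `df` supplying the variables).
#' @param df data frame used when `data` is a formula.
#' @param threshold classification threshold for [predict.taba_binary()];
#'   predicted class is 1 when the fitted probability is `>= threshold`.
#' @param tol gradient tolerance passed to [taba_maximize()].
#' @param diagnostics logical; run the collinearity/leverage warnings.
#' @return an object of class `taba_binary` (also `taba_fit`); see
#'   [wald_table()], [information_criteria()], [predict.taba_binary()].
#' @examples
#' md <- simulate_taba_binary(500, beta = c(0.3, 0.8), seed = 7)
#' fit <- taba_binary(md)
#' wald_table(fit)
#' @export
taba_binary <- function(data, df = NULL, threshold = 0.5, tol = 1e-6,
                        diagnostics = TRUE) {
  if (inherits(data, "formula")) data <- taba_model_frame(data, df)
  stopifnot(inherits(data, "taba_model_data"))
  y <- data$outcome
  if (!all(y %in% c(0, 1)) && !is.null(data$k) && data$k == 2) {
    y <- as.numeric(data$outcome == 2)  # second category is the event
  }
  if (!all(y %in% c(0, 1)))
    stop("binary Taba regression needs a 0/1 outcome", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)", call. = FALSE)

  if (diagnostics) design_diagnostics(data$design)

  std <- standardize_design(data$design)
  negll <- function(th) binary_negloglik(th, std$Z, y)
  grad <- function(th) binary_neggrad(th, std$Z, y)
  opt <- taba_maximize(negll, init = numeric(ncol(std$Z)), gradient = grad,
                       tol = tol)
  # The Taba tails flatten so fast that separated data stall the gradient
  # long before coefficients reach the magnitude guard in taba_maximize;
  # check the fitted predictor for a perfect split as well.
  eta_hat <- drop(std$Z %*% opt$estimates)
  if (min(eta_hat[y == 1]) > max(eta_hat[y == 0]))
    warning("fitted linear predictor separates the classes perfectly; ",
            "possible complete separation (estimates unstable)",
            call. = FALSE)
  info <- observed_information(negll, opt$estimates, gradient = grad)
  cov_z <- information_to_covariance(info)
  back <- unstandardize_beta(opt$estimates, std$m, std$s)
  beta <- back$beta
  names(beta) <- data$column_names
  covariance <- back$A %*% cov_z %*% t(back$A)
  dimnames(covariance) <- list(data$column_names, data$column_names)
  attr(covariance, "reliable") <- attr(cov_z, "reliable")

  new_taba_fit("binary", beta, covariance, loglik = -opt$value,
               n_obs = data$n, n_params = length(beta),
               converged = opt$converged, n_iter = opt$n_iter, data = data,
               extra = list(threshold = threshold))
}

design_diagnostics <- function(X) {
  nonconst <- apply(X, 2, function(col) length(unique(col)) > 1L)
  if (sum(nonconst) >= 2L) {
    Z <- scale(X[, nonconst, drop = FALSE])
    kap <- kappa(Z, exact = TRUE)
    if (is.finite(kap) && kap > 30)
      warning(sprintf("design condition number %.1f suggests multicollinearity",
                      kap), call. = FALSE)
  }
  h <- stats::hat(X)
  if (any(h > 0.9))
    warning(sum(h > 0.9), " observation(s) with extreme leverage (hat > 0.9)",
            call. = FALSE)
  invisible(NULL)
}

#' Predict from a binary Taba fit
#'
#' @param object a `taba_binary` fit.
#' @param newdata matrix of design rows in the training column layout
#'   (an intercept column is prepended if absent), or a data frame when the
#'   model was built from a formula; defaults to the training design.
#' @param type `"response"` for probabilities, `"class"` for 0/1 labels at
#'   the fit's threshold (class 1 iff probability >= threshold).
#' @param threshold optional override of the fit's threshold; any value in
#'   `[0, 1]` (0 labels everything 1, 1 labels everything 0, by the `>=`
#'   convention and because probabilities are strictly inside (0, 1)).
#' @param ... unused.
#' @return numeric vector of probabilities or labels.
#' @export
predict.taba_binary <- function(object, newdata = NULL,
                                type = c("response", "class"),
                                threshold = NULL, ...) {
  type <- match.arg(type)
  X <- resolve_design(object, newdata)
  pr <- taba_success_prob(drop(X %*% object$coefficients))
  if (is.null(threshold)) threshold <- object$threshold
  if (type == "response") pr else as.numeric(pr >= threshold)
}

resolve_design <- function(object, newdata) {
  if (is.null(newdata)) return(object$data$design)
  X <- as.matrix(newdata)
  if (ncol(X) == length(object$coefficients) - 1L) X <- cbind(1, X)
  if (ncol(X) != length(object$coefficients))
    stop("newdata column count does not match the training design",
         call. = FALSE)
  X
}

#' Location-scale view of a single-predictor binary fit
#'
#' For the one-predictor model the success probability can be rewritten as
#' the Taba CDF of \eqn{(x - L)/S} with \eqn{L = -\beta_0/\beta_1} and
#' \eqn{S = 1/\beta_1}: the regression is the distribution in
#' location-scale form.  A negative slope yields a negative `S`
#' (orientation flip), reported with a warning.
#'
#' @param fit a `taba_binary` fit with exactly one predictor.
#' @return object of class `taba_location_scale` with fields `location`
#'   and `scale`.
#' @export
location_scale_view <- function(fit) {
  stopifnot(inherits(fit, "taba_binary"))
  if (length(fit$coefficients) != 2L)
    stop("location-scale view requires exactly one predictor", call. = FALSE)
  b0 <- fit$coefficients[[1L]]
  b1 <- fit$coefficients[[2L]]
  if (b1 == 0) stop("slope is zero; location-scale form undefined",
                    call. = FALSE)
  if (b1 < 0)
    warning("negative slope: scale parameter is negative (orientation flip)",
            call. = FALSE)
  structure(list(location = -b0 / b1, scale = 1 / b1),
            class = "taba_location_scale")
}

#' @export
print.taba_location_scale <- function(x, ...) {
  cat(sprintf("Taba location-scale: location = %g, scale = %g\n",
              x$location, x$scale))
  invisible(x)
}
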