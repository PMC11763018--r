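#' Ordinal Taba cumulative probabilities and log-odds
#'
#' The ordinal (proportional-odds-style) Taba model puts
#' \eqn{P(y \le j \mid x) = F_{Taba}(L_j)} with
#' \eqn{L_j = \alpha_j - \beta_1 x_1 - \dots - \beta_p x_p} and strictly
#' increasing cutpoints \eqn{\alpha_1 < \dots < \alpha_{k-1}}.  The ordinal
#' log-odds of falling at or below category j is
#' \deqn{\gamma_j = \ln\frac{F_j}{1-F_j}
#'   = -2 \ln \sinh\!\big(e^{-\mathrm{asinh}\,L_j}\big),}
#' evaluated in log space.  `taba_cumulative_prob` is simply the Taba CDF;
#' it is exposed under this name because the ordinal family reads better
#' in terms of cumulative probabilities.
#'
#' @param L finite numeric vector of cumulative linear predictors.
#' @return probabilities (cumulative) or log-odds values.
#' @examples
#' taba_cumulative_prob(0)          # 0.4199743...
#' taba_ordinal_log_odds(0)         # -2 log sinh(1)
#' @export
taba_cumulative_prob <- function(L) ptaba(check_finite(L, "L"))

#' @rdname taba_cumulative_prob
#' @export
taba_ordinal_log_odds <- function(L) {
  u <- taba_u(check_finite(L, "L"))
  -2 * (u + log1p(-exp(-2 * u)) - log(2))
}

#' Ordinal Taba category probabilities
#'
#' Differences of cumulative Taba probabilities:
#' \eqn{\pi_1 = F_1}, \eqn{\pi_j = F_j - F_{j-1}} for interior categories,
#' \eqn{\pi_k = 1 - F_{k-1}}; non-negative and summing to one by
#' telescoping whenever the cutpoints are increasing.
#'
#' @param alpha strictly increasing cutpoint vector of length k-1.
#' @param beta slope vector (no intercept).
#' @param x_row predictor values, a vector of length p or an n x p matrix.
#' @return n x k matrix of category probabilities.
#' @export
taba_ordinal_probs <- function(alpha, beta, x_row) {
  if (any(diff(alpha) <= 0))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  X <- if (is.null(dim(x_row))) matrix(x_row, nrow = 1L) else as.matrix(x_row)
  if (length(beta) != ncol(X))
    stop("length(beta) must match the predictor columns", call. = FALSE)
  eta <- drop(X %*% beta)
  k <- length(alpha) + 1L
  L <- outer(-eta, alpha, `+`)
  Fj <- cbind(0, ptaba(L), 1)
  Fj[, 2:(k + 1L), drop = FALSE] - Fj[, 1:k, drop = FALSE]
}

# theta = (alpha_1, log(alpha_2 - alpha_1), ..., beta); the log-increment
# reparameterization keeps the cutpoints ordered at every iterate.  The
# exponent is capped so wild line-search steps cannot overflow to Inf
# (the likelihood is decreasing long before the cap binds).
INCREMENT_CAP <- 80

theta_to_alpha <- function(theta, k) {
  cumsum(c(theta[1L], exp(pmin(theta[seq_len(k - 2L) + 1L], INCREMENT_CAP))))
}

alpha_to_theta <- function(alpha) {
  c(alpha[1L], log(diff(alpha)))
}

ordinal_negloglik <- function(theta, X, y, k) {
  alpha <- theta_to_alpha(theta, k)
  beta <- theta[-seq_len(k - 1L)]
  eta <- if (length(beta)) drop(X %*% beta) else numeric(nrow(X))
  L <- outer(-eta, alpha, `+`)               # n x (k-1)
  Fj <- cbind(0, ptaba(L), 1)
  pr <- Fj[cbind(seq_along(y), y + 1L)] - Fj[cbind(seq_along(y), y)]
  -sum(log(pmax(pr, 1e-300)))
}

ordinal_neggrad <- function(theta, X, y, k) {
  alpha <- theta_to_alpha(theta, k)
  beta <- theta[-seq_len(k - 1L)]
  n <- length(y)
  eta <- if (length(beta)) drop(X %*% beta) else numeric(n)
  L <- outer(-eta, alpha, `+`)
  Fj <- cbind(0, ptaba(L), 1)
  fj <- cbind(0, dtaba(L), 0)
  pr <- pmax(Fj[cbind(seq_len(n), y + 1L)] - Fj[cbind(seq_len(n), y)], 1e-300)
  wu <- ifelse(y < k, fj[cbind(seq_len(n), y + 1L)] / pr, 0)   # weight on L_y
  wl <- ifelse(y > 1, -fj[cbind(seq_len(n), y)] / pr, 0)       # weight on L_{y-1}
  galpha <- numeric(k - 1L)
  for (j in seq_len(k - 1L))
    galpha[j] <- sum(wu[y == j]) + sum(wl[y == j + 1L])
  gbeta <- if (length(beta)) -drop(crossprod(X, wu + wl)) else numeric(0)
  # chain rule through the log-increment map
  J <- theta_jacobian(theta, k)
  gtheta <- c(drop(galpha %*% J), gbeta)
  -gtheta
}

# d alpha / d theta_cut: lower-triangular-ish Jacobian of theta_to_alpha
theta_jacobian <- function(theta, k) {
  J <- matrix(0, k - 1L, k - 1L)
  J[, 1L] <- 1
  if (k > 2L) for (l in 2:(k - 1L))
    J[l:(k - 1L), l] <- exp(pmin(theta[l], INCREMENT_CAP))
  J
}

#' Ordinal Taba log-likelihood
#'
#' @param alpha strictly increasing cutpoints (length k-1).
#' @param beta slope vector (length p, no intercept).
#' @param data a [taba_model_data()] with an ordered categorical outcome.
#' @return scalar log-likelihood.
#' @export
taba_ordinal_loglik <- function(alpha, beta, data) {
  stopifnot(inherits(data, "taba_model_data"), !is.null(data$k))
  if (any(diff(alpha) <= 0))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  X <- data$design[, -1L, drop = FALSE]
  -ordinal_negloglik(c(alpha_to_theta(alpha), beta), X, data$outcome, data$k)
}

#' Fit an ordinal Taba regression
#'
#' Maximum likelihood over the reparameterised space
#' \eqn{(\alpha_1, \ln(\alpha_2-\alpha_1), \dots, \beta)}, which keeps the
#' cutpoints strictly ordered at every optimizer iterate; estimates and
#' the covariance are mapped back to the natural \eqn{(\alpha, \beta)}
#' scale by the delta method.  Category order follows the factor level
#' order (or increasing integer codes).
#'
#' @inheritParams taba_binary
#' @return object of class `taba_ordinal` (also `taba_fit`) with elements
#'   `alpha`, `beta_slopes`, `categories`.
#' @export
taba_ordinal <- function(data, df = NULL, tol = 1e-6) {
  if (inherits(data, "formula")) data <- taba_model_frame(data, df)
  stopifnot(inherits(data, "taba_model_data"))
  if (is.null(data$k))
    stop("ordinal regression needs a categorical outcome (factor or 1..k)",
         call. = FALSE)
  k <- data$k
  y <- data$outcome
  X <- data$design[, -1L, drop = FALSE]
  p <- ncol(X)

  std <- if (p) standardize_design(cbind(1, X)) else NULL
  Z <- if (p) std$Z[, -1L, drop = FALSE] else X
  # init: cutpoints at the outcome's empirical quantiles, zero slopes
  cum <- cumsum(tabulate(y, k))[seq_len(k - 1L)] / length(y)
  init <- c(alpha_to_theta(qtaba(pmin(pmax(cum, 1e-3), 1 - 1e-3))),
            numeric(p))

  negll <- function(th) ordinal_negloglik(th, Z, y, k)
  grad <- function(th) ordinal_neggrad(th, Z, y, k)
  opt <- taba_maximize(negll, init, gradient = grad, tol = tol)

  info <- observed_information(negll, opt$estimates, gradient = grad)
  cov_theta <- information_to_covariance(info)

  # natural parameters in the standardized space
  theta <- opt$estimates
  alpha_z <- theta_to_alpha(theta, k)
  beta_z <- theta[-seq_len(k - 1L)]
  # undo standardization: beta_j = beta_z_j / s_j, alpha = alpha_z + beta . m
  s <- if (p) std$s[-1L] else numeric(0)
  m <- if (p) std$m[-1L] else numeric(0)
  beta_nat <- if (p) beta_z / s else numeric(0)
  alpha_nat <- alpha_z + if (p) sum(beta_nat * m) else 0

  # Jacobian of (alpha_nat, beta_nat) wrt theta
  q <- length(theta)
  J <- matrix(0, q, q)
  Jc <- theta_jacobian(theta, k)
  J[seq_len(k - 1L), seq_len(k - 1L)] <- Jc
  if (p) {
    J[seq_len(k - 1L), k:q] <- matrix(m / s, k - 1L, p, byrow = TRUE)
    J[k:q, k:q] <- diag(1 / s, p)
  }
  covariance <- J %*% cov_theta %*% t(J)
  attr(covariance, "reliable") <- attr(cov_theta, "reliable")

  nms <- c(paste0("alpha_", seq_len(k - 1L),
                  " [<=", data$categories[seq_len(k - 1L)], "]"),
           if (p) colnames(data$design)[-1L])
  est <- c(alpha_nat, beta_nat)
  names(est) <- nms
  dimnames(covariance) <- list(nms, nms)

  new_taba_fit("ordinal", est, covariance, loglik = -opt$value,
               n_obs = data$n, n_params = q, converged = opt$converged,
               n_iter = opt$n_iter, data = data,
               extra = list(alpha = alpha_nat, beta_slopes = beta_nat,
                            categories = data$categories))
}

#' Predict from an ordinal Taba fit
#'
#' @param object a `taba_ordinal` fit.
#' @param newdata predictor rows without intercept (default: training
#'   predictors).
#' @param type `"response"` for the probability matrix, `"class"` for the
#'   argmax category (ties toward the lower index).
#' @param ... unused.
#' @export
predict.taba_ordinal <- function(object, newdata = NULL,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$data$design[, -1L, drop = FALSE]
       else as.matrix(newdata)
  pr <- taba_ordinal_probs(object$alpha, object$beta_slopes, X)
  colnames(pr) <- object$categories
  if (type == "response") pr
  else object$categories[max.col(pr, ties.method = "first")]
}

#' Descriptive proportional-odds diagnostic
#'
#' Fits a separate binary Taba model to each cumulative split
#' \eqn{1\{y \le j\}} and tabulates every predictor's slope across splits
#' together with its range.  Under proportional odds the split-specific
#' slopes should agree up to sampling noise; a predictor whose range is
#' large relative to its standard errors is the one violating the shared
#' slope.  This is a descriptive device; no test statistic or p-value is
#' produced.
#'
#' @param fit a `taba_ordinal` fit with at least 3 categories.
#' @return data frame with one row per predictor per split (columns
#'   `term`, `split`, `slope`, `se`) plus an attribute `range` giving each
#'   predictor's max-min slope spread.
#' @export
proportional_odds_diagnostic <- function(fit) {
  stopifnot(inherits(fit, "taba_ordinal"))
  data <- fit$data
  k <- data$k
  if (k < 3L)
    stop("diagnostic needs at least 3 categories", call. = FALSE)
  p <- data$p
  if (p < 1L) stop("no predictors to diagnose", call. = FALSE)
  rows <- list()
  for (j in seq_len(k - 1L)) {
    md <- taba_model_data(as.numeric(data$outcome <= j), data$design,
                          data$column_names)
    bf <- taba_binary(md, diagnostics = FALSE)
    wt <- wald_table(bf)[-1L, , drop = FALSE]
    rows[[j]] <- data.frame(term = wt$term, split = j,
                            slope = -wt$estimate, se = wt$se)
  }
  out <- do.call(rbind, rows)
  rng <- tapply(out$slope, out$term, function(v) diff(range(v)))
  attr(out, "range") <- rng
  out
}
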