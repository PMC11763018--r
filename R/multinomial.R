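#' Multinomial Taba category probabilities
#'
#' Baseline-category probabilities for an unordered k-class outcome.  With
#' \eqn{s_s = \sinh(e^{-\mathrm{asinh}\,\varphi_s})} for each non-reference
#' category's linear predictor \eqn{\varphi_s},
#' \deqn{\pi_r = \frac{1}{1 + \sum_{s \ne r} s_s^2}, \qquad
#'   \pi_j = \frac{s_j^2}{1 + \sum_{s \ne r} s_s^2} \; (j \ne r),}
#' so the probabilities sum to one by construction.  Note the sign
#' convention this model implies: \eqn{s_j} is *decreasing* in
#' \eqn{\varphi_j}, so a positive coefficient lowers its own category's
#' probability (and at \eqn{k = 2} the reference-category probability is
#' exactly the binary success probability of \eqn{\varphi}).
#' Everything is evaluated in log space (log-sum-exp over
#' \eqn{\{0, \log s_s^2\}}) so extreme predictors cannot overflow.
#'
#' @param phi numeric matrix (n rows, k-1 columns) of linear predictors
#'   for the non-reference categories, in category order with the
#'   reference column omitted; a vector is taken as one observation.
#' @param reference index (1..k) of the reference category.
#' @return n x k matrix of probabilities, rows summing to 1.
#' @examples
#' taba_multinom_probs(cbind(0, 0), reference = 3)
#' @export
taba_multinom_probs <- function(phi, reference) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L)
  check_finite(phi, "phi")
  k <- ncol(phi) + 1L
  if (length(reference) != 1L || !(reference %in% seq_len(k)))
    stop("'reference' must be a category index in 1..k", call. = FALSE)
  exp(log_multinom_probs(phi, reference))
}

# log s^2 = 2 log sinh(u(phi)); log sinh(u) = u + log1p(-exp(-2u)) - log 2
log_s2 <- function(phi) {
  u <- taba_u(phi)
  2 * (u + log1p(-exp(-2 * u)) - log(2))
}

# d log s^2 / d phi = -2 u coth(u) / sqrt(1 + phi^2)
dlog_s2 <- function(phi) {
  u <- taba_u(phi)
  -2 * (u / tanh(u)) / sqrt(1 + phi * phi)
}

log_multinom_probs <- function(phi, reference) {
  n <- nrow(phi)
  k <- ncol(phi) + 1L
  ls2 <- log_s2(phi)                     # n x (k-1)
  M <- rep(0, n)                         # running row max (log-sum-exp guard)
  for (j in seq_len(ncol(ls2))) M <- pmax(M, ls2[, j])
  log_denom <- M + log(exp(-M) + rowSums(exp(ls2 - M)))
  out <- matrix(0, n, k)
  out[, -reference] <- ls2 - log_denom
  out[, reference] <- -log_denom
  out
}

#' Multinomial Taba log-likelihood
#'
#' Sum over observations of the log probability of the observed category,
#' \eqn{\sum_i \sum_j y_{ij} \ln \pi_j(x_i; B)}.
#'
#' @param B coefficient matrix, one row per non-reference category (in
#'   increasing category order), one column per design column.
#' @param data a [taba_model_data()] with a categorical outcome.
#' @param reference reference category index.
#' @return scalar log-likelihood.
#' @export
taba_multinomial_loglik <- function(B, data, reference) {
  stopifnot(inherits(data, "taba_model_data"), !is.null(data$k))
  B <- rbind(B)
  if (nrow(B) != data$k - 1L || ncol(B) != ncol(data$design))
    stop("B must be (k-1) x (p+1)", call. = FALSE)
  lp <- log_multinom_probs(data$design %*% t(B), reference)
  sum(lp[cbind(seq_len(data$n), data$outcome)])
}

multinom_negloglik <- function(theta, Z, y, k, reference) {
  B <- matrix(theta, nrow = k - 1L)
  lp <- log_multinom_probs(Z %*% t(B), reference)
  -sum(lp[cbind(seq_along(y), y)])
}

# dl/dB[j, m] = sum_i (1{y_i = cat_j} - pi_ij) * dlogs2(phi_ij) * Z[i, m]
multinom_neggrad <- function(theta, Z, y, k, reference) {
  B <- matrix(theta, nrow = k - 1L)
  phi <- Z %*% t(B)
  pr <- exp(log_multinom_probs(phi, reference))
  cats <- setdiff(seq_len(k), reference)
  W <- dlog_s2(phi) *
    ((matrix(y, nrow(Z), k - 1L) == matrix(cats, nrow(Z), k - 1L,
                                           byrow = TRUE)) -
       pr[, cats, drop = FALSE])
  -as.vector(t(crossprod(Z, W)))
}

#' Fit a baseline-category multinomial Taba regression
#'
#' Joint maximum-likelihood estimation of all (k-1)(p+1) coefficients.
#' Coefficient layout follows the design columns within each non-reference
#' category block; Wald inference and information criteria work as for the
#' binary family.  The default reference is the last category in sorted
#' label order.
#'
#' Unlike the baseline-category *logit*, this family is not invariant to
#' the reference choice once predictors are present: the ratio of two
#' \eqn{\sinh^2(e^{-\mathrm{asinh}\,\varphi})} terms is not itself of that
#' form in a linear predictor, so different references span genuinely
#' different model spaces (they coincide for intercept-only models, which
#' are saturated, and at k = 2 where the reference category reduces to the
#' binary model).  Relabelling the non-reference categories merely permutes
#' the rows of the coefficient matrix.
#'
#' @inheritParams taba_binary
#' @param reference reference category label or index (default: last).
#' @return object of class `taba_multinomial` (also `taba_fit`) with a
#'   `coef_matrix` element of shape (k-1) x (p+1).
#' @export
taba_multinomial <- function(data, df = NULL, reference = NULL, tol = 1e-6) {
  if (inherits(data, "formula")) data <- taba_model_frame(data, df)
  stopifnot(inherits(data, "taba_model_data"))
  if (is.null(data$k)) {
    data$outcome <- data$outcome + 1
    data$categories <- c("0", "1")
    data$k <- 2L
  }
  k <- data$k
  reference <- resolve_reference(reference, data$categories)

  std <- standardize_design(data$design)
  y <- data$outcome
  negll <- function(th) multinom_negloglik(th, std$Z, y, k, reference)
  grad <- function(th) multinom_neggrad(th, std$Z, y, k, reference)
  q <- (k - 1L) * ncol(std$Z)
  opt <- taba_maximize(negll, numeric(q), gradient = grad, tol = tol)

  info <- observed_information(negll, opt$estimates, gradient = grad)
  cov_z <- information_to_covariance(info)
  # per-category back-transform: block diagonal in the category blocks
  Acol <- unstandardize_beta(numeric(ncol(std$Z)), std$m, std$s)$A
  Afull <- kronecker(Acol, diag(k - 1L))   # theta is stacked by column
  beta <- drop(Afull %*% opt$estimates)
  covariance <- Afull %*% cov_z %*% t(Afull)
  attr(covariance, "reliable") <- attr(cov_z, "reliable")

  cats <- setdiff(seq_len(k), reference)
  nms <- as.vector(outer(paste0("[", data$categories[cats], "] "),
                         data$column_names, paste0))
  names(beta) <- nms
  dimnames(covariance) <- list(nms, nms)
  B <- matrix(beta, nrow = k - 1L,
              dimnames = list(data$categories[cats], data$column_names))

  new_taba_fit("multinomial", beta, covariance, loglik = -opt$value,
               n_obs = data$n, n_params = q, converged = opt$converged,
               n_iter = opt$n_iter, data = data,
               extra = list(coef_matrix = B, reference = reference,
                            categories = data$categories))
}

resolve_reference <- function(reference, categories) {
  k <- length(categories)
  if (is.null(reference)) return(k)
  if (is.character(reference)) {
    idx <- match(reference, categories)
    if (is.na(idx)) stop("unknown reference category '", reference, "'",
                         call. = FALSE)
    return(idx)
  }
  if (!(reference %in% seq_len(k)))
    stop("'reference' out of range", call. = FALSE)
  as.integer(reference)
}

#' Predict from a multinomial Taba fit
#'
#' @param object a `taba_multinomial` fit.
#' @param newdata design rows (see [predict.taba_binary()]).
#' @param type `"response"` for the row-stochastic probability matrix,
#'   `"class"` for the argmax category label (ties broken toward the lower
#'   category index).
#' @param ... unused.
#' @export
predict.taba_multinomial <- function(object, newdata = NULL,
                                     type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$data$design else {
    X <- as.matrix(newdata)
    if (ncol(X) == ncol(object$coef_matrix) - 1L) X <- cbind(1, X)
    if (ncol(X) != ncol(object$coef_matrix))
      stop("newdata column count does not match the training design",
           call. = FALSE)
    X
  }
  pr <- taba_multinom_probs(X %*% t(object$coef_matrix), object$reference)
  colnames(pr) <- object$categories
  if (type == "response") pr
  else object$categories[max.col(pr, ties.method = "first")]
}
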