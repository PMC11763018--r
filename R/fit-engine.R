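#' Encoded outcome and design matrix for Taba regression
#'
#' Bundles an outcome vector with a design matrix whose first column is the
#' intercept, after validation.  All three regression families consume this
#' container; [taba_model_frame()] builds one from a formula.
#'
#' @param outcome for a binary model, a 0/1 vector; for multinomial or
#'   ordinal models, a factor or an integer vector of category indices
#'   `1..k` with every category present.
#' @param design numeric matrix with `n` rows; if its first column is not
#'   constant 1, an intercept column is prepended.
#' @param column_names optional labels for the design columns (including
#'   the intercept).
#'
#' @return An object of class `taba_model_data` with elements `outcome`
#'   (numeric 0/1 or integer codes), `design`, `column_names`, `n`, `p`
#'   (number of predictors, excluding the intercept), and for categorical
#'   outcomes `categories` (labels) and `k`.
#' @export
taba_model_data <- function(outcome, design, column_names = NULL) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- nrow(design)
  if (length(outcome) != n)
    stop("'outcome' length does not match the design row count", call. = FALSE)
  if (anyNA(outcome) || anyNA(design))
    stop("missing values in outcome or design", call. = FALSE)
  if (!all(is.finite(design)))
    stop("non-finite values in design", call. = FALSE)

  if (!all(design[, 1L] == 1)) design <- cbind(1, design)
  if (is.null(column_names)) {
    column_names <- colnames(design)
    if (is.null(column_names))
      column_names <- c("(Intercept)",
                        if (ncol(design) > 1L) paste0("x", seq_len(ncol(design) - 1L)))
  }
  if (length(column_names) != ncol(design))
    stop("'column_names' length does not match the design", call. = FALSE)
  colnames(design) <- column_names

  if (qr(design)$rank < ncol(design))
    warning("design matrix is column rank deficient", call. = FALSE)

  categories <- NULL
  if (is.factor(outcome)) {
    categories <- levels(outcome)
    outcome <- as.integer(outcome)
  } else if (is.character(outcome)) {
    f <- factor(outcome)
    categories <- levels(f)
    outcome <- as.integer(f)
  }
  binary <- is.null(categories) && all(outcome %in% c(0, 1))
  if (!binary) {
    if (is.null(categories)) {
      if (!all(outcome == round(outcome)) || any(outcome < 1))
        stop("categorical outcome must be a factor or 1..k integer codes",
             call. = FALSE)
      categories <- as.character(sort(unique(outcome)))
      outcome <- match(outcome, sort(unique(outcome)))
    }
    k <- length(categories)
    if (!all(seq_len(k) %in% outcome))
      stop("every outcome category must be present in the data", call. = FALSE)
  }

  structure(
    list(outcome = as.numeric(outcome), design = design,
         column_names = column_names, n = n, p = ncol(design) - 1L,
         categories = categories,
         k = if (is.null(categories)) NULL else length(categories)),
    class = "taba_model_data")
}

#' Build model data from a formula
#'
#' @param formula model formula; the response may be numeric 0/1, a factor,
#'   or category codes.
#' @param data a data frame.
#' @return A [taba_model_data()] object.
#' @export
taba_model_frame <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  taba_model_data(stats::model.response(mf), X, colnames(X))
}

#' @export
print.taba_model_data <- function(x, ...) {
  kind <- if (is.null(x$k)) "binary" else paste0(x$k, "-category")
  cat("Taba model data: ", x$n, " observations, ", x$p, " predictor(s), ",
      kind, " outcome\n", sep = "")
  invisible(x)
}

# ---- optimizer driver -------------------------------------------------------

central_gradient <- function(fn, theta, h = NULL) {
  q <- length(theta)
  if (is.null(h)) h <- pmax(1e-6, 1e-6 * abs(theta))
  g <- numeric(q)
  for (j in seq_len(q)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    g[j] <- (fn(tp) - fn(tm)) / (2 * h[j])
  }
  g
}

#' Maximise a log-likelihood
#'
#' Quasi-Newton (BFGS) minimisation of a negative log-likelihood followed
#' by Newton refinement, declaring convergence when the max-norm of the
#' gradient falls below `tol` and the relative objective change below
#' 1e-10.  On failure the search restarts from up to three jittered
#' initial points (seeded, hence reproducible) before the result is
#' flagged non-converged.  Gradients are central differences unless an
#' analytic `gradient` is supplied.
#'
#' @param negative_loglik function of the parameter vector returning the
#'   negative log-likelihood.
#' @param init numeric starting values; the objective must be finite there.
#' @param gradient optional analytic gradient of `negative_loglik`.
#' @param tol gradient max-norm tolerance (default 1e-6).
#' @param max_iter iteration cap passed to the quasi-Newton stage.
#' @return list with `estimates`, `value` (minimised objective),
#'   `converged`, `n_iter`.
#' @export
taba_maximize <- function(negative_loglik, init, gradient = NULL,
                          tol = 1e-6, max_iter = 500L) {
  if (!is.finite(negative_loglik(init)))
    stop("objective is not finite at the initial values", call. = FALSE)
  gr <- if (is.null(gradient)) function(th) central_gradient(negative_loglik, th)
        else gradient

  run_once <- function(start) {
    opt <- stats::optim(start, negative_loglik, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-13))
    theta <- opt$par
    value <- opt$value
    n_iter <- opt$counts[["function"]]
    # Newton polish: quadratic convergence pushes the gradient to ~machine
    # precision even when BFGS stalls on ill-scaled problems.
    for (it in 1:40) {
      g <- gr(theta)
      if (max(abs(g)) < tol) break
      H <- hessian_of_gradient(gr, theta)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      lambda <- 1
      repeat {
        cand <- theta - lambda * step
        v <- negative_loglik(cand)
        if (is.finite(v) && v <= value + 1e-12 * abs(value)) break
        lambda <- lambda / 2
        if (lambda < 1e-8) break
      }
      moved <- lambda >= 1e-8
      if (moved) {
        rel_change <- abs(value - v) / max(1, abs(value))
        theta <- cand
        value <- v
        n_iter <- n_iter + 1L
        if (max(abs(gr(theta))) < tol && rel_change < 1e-10) break
      } else break
    }
    g <- gr(theta)
    list(estimates = theta, value = value,
         converged = max(abs(g)) < tol, n_iter = n_iter)
  }

  res <- run_once(init)
  restart <- 0L
  while (!res$converged && restart < 3L) {
    restart <- restart + 1L
    jitter <- withr_preserve_seed(restart, length(init))
    cand <- run_once(init + jitter)
    if (cand$value < res$value || cand$converged) res <- cand
  }
  if (any(abs(res$estimates) > 1e3))
    warning("very large coefficient magnitude; possible complete separation",
            call. = FALSE)
  res
}

# deterministic jitter for restarts without disturbing the caller's RNG
withr_preserve_seed <- function(restart, q) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(1000L + restart)
  stats::rnorm(q, sd = 0.25 * restart)
}

# central-difference Jacobian of a gradient function, used by the Newton
# polish; same step rule as observed_information()
hessian_of_gradient <- function(gr, theta) {
  q <- length(theta)
  h <- pmax(1e-5, 1e-5 * abs(theta))
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Observed information matrix
#'
#' Central-difference Hessian of the negative log-likelihood at the
#' maximum-likelihood estimates, symmetrised as \eqn{(H + H^T)/2}.  The
#' per-coordinate step is `max(1e-5, 1e-5 * |theta_j|)`.  When an analytic
#' `gradient` is available the Hessian is differenced from it (one order
#' more accurate); otherwise second differences of the objective are used.
#'
#' @inheritParams taba_maximize
#' @param estimates parameter vector, normally from a converged fit.
#' @return symmetric q x q matrix.
#' @export
observed_information <- function(negative_loglik, estimates, gradient = NULL) {
  if (!is.null(gradient)) return(hessian_of_gradient(gradient, estimates))
  q <- length(estimates)
  h <- pmax(1e-5, 1e-5 * abs(estimates))
  H <- matrix(0, q, q)
  f0 <- negative_loglik(estimates)
  for (j in seq_len(q)) {
    tp <- tm <- estimates
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    H[j, j] <- (negative_loglik(tp) + negative_loglik(tm) - 2 * f0) / h[j]^2
    if (j < q) for (l in (j + 1):q) {
      tpp <- tpm <- tmp <- tmm <- estimates
      tpp[c(j, l)] <- tpp[c(j, l)] + h[c(j, l)]
      tmm[c(j, l)] <- tmm[c(j, l)] - h[c(j, l)]
      tpm[j] <- tpm[j] + h[j]; tpm[l] <- tpm[l] - h[l]
      tmp[j] <- tmp[j] - h[j]; tmp[l] <- tmp[l] + h[l]
      H[j, l] <- H[l, j] <-
        (negative_loglik(tpp) - negative_loglik(tpm) -
           negative_loglik(tmp) + negative_loglik(tmm)) / (4 * h[j] * h[l])
    }
  }
  (H + t(H)) / 2
}

# invert an information matrix into a covariance, flagging indefiniteness
information_to_covariance <- function(info) {
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  reliable <- all(ev > 0)
  if (!reliable)
    warning("observed information is not positive definite; ",
            "standard errors are unreliable", call. = FALSE)
  cov <- tryCatch(solve(info), error = function(e) {
    warning("observed information is numerically singular", call. = FALSE)
    matrix(NA_real_, nrow(info), ncol(info))
  })
  attr(cov, "reliable") <- reliable
  cov
}

# shared constructor for fitted-model objects
new_taba_fit <- function(family, coefficients, covariance, loglik, n_obs,
                         n_params, converged, n_iter, data, extra = list()) {
  structure(
    c(list(family = family, coefficients = coefficients,
           covariance = covariance, loglik = loglik, n_obs = n_obs,
           n_params = n_params, converged = converged, n_iter = n_iter,
           data = data), extra),
    class = c(paste0("taba_", family), "taba_fit"))
}

# ---- inference summaries ----------------------------------------------------

#' Wald coefficient table
#'
#' Per-coefficient estimate, standard error (square root of the covariance
#' diagonal), t statistic `estimate/se`, and two-sided p-value from the
#' Student-t distribution with `n_obs` degrees of freedom.  (Among the
#' candidate conventions — normal, t with n - q, t with n — only df = n
#' reproduces every p-value of the published cirrhosis coefficient table
#' at printed precision, so that is the convention adopted.)  Rows with a
#' non-positive covariance diagonal keep their estimate but carry `NA`
#' inference columns.
#'
#' @param fit a fitted Taba regression.
#' @return data frame with columns `term`, `estimate`, `se`, `t_value`,
#'   `p_value`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "taba_fit"))
  est <- fit$coefficients
  d <- diag(fit$covariance)
  bad <- !is.finite(d) | d <= 0
  if (any(bad))
    warning("non-positive variance for: ",
            paste(names(est)[bad], collapse = ", "), call. = FALSE)
  se <- ifelse(bad, NA_real_, sqrt(pmax(d, 0)))
  tv <- est / se
  pv <- 2 * stats::pt(abs(tv), df = fit$n_obs, lower.tail = FALSE)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t_value = unname(tv), p_value = unname(pv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Information criteria
#'
#' @param fit a fitted Taba regression.
#' @return list with `minus2_loglik` (\eqn{-2\hat\ell}), `aic`
#'   (\eqn{-2\hat\ell + 2q}) and `bic` (\eqn{-2\hat\ell + q\ln n}).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "taba_fit"))
  m2 <- -2 * fit$loglik
  q <- fit$n_params
  list(minus2_loglik = m2, aic = m2 + 2 * q, bic = m2 + q * log(fit$n_obs))
}

#' @export
logLik.taba_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.taba_fit <- function(x, digits = 6, ...) {
  cat("Taba", x$family, "regression\n")
  cat("  n =", x$n_obs, " parameters =", x$n_params,
      if (!x$converged) " (NOT converged)", "\n")
  print(wald_table(x), digits = digits)
  ic <- information_criteria(x)
  cat(sprintf("-2 logLik = %.*g   AIC = %.*g   BIC = %.*g\n",
              digits, ic$minus2_loglik, digits, ic$aic, digits, ic$bic))
  invisible(x)
}

#' Write a coefficient table as TSV
#'
#' Serialises [wald_table()] output (columns Parameter, Estimate, SE,
#' t Value, p-Value) to a tab-separated file.
#'
#' @param fit a fitted Taba regression.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_wald_tsv <- function(fit, path) {
  tab <- wald_table(fit)
  names(tab) <- c("Parameter", "Estimate", "SE", "t Value", "p-Value")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# standardize non-constant design columns; returns transform metadata
standardize_design <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  fixed <- !is.finite(s) | s == 0 | seq_len(ncol(X)) == 1L
  m[fixed] <- 0
  s[fixed] <- 1
  Z <- sweep(sweep(X, 2, m), 2, s, "/")
  list(Z = Z, m = m, s = s)
}

# map standardized-space coefficients back to the raw design scale:
# eta = Z theta = X beta with beta_j = theta_j / s_j and the intercept
# absorbing -sum theta_j m_j / s_j
unstandardize_beta <- function(theta, m, s) {
  A <- diag(1 / s, length(s))
  A[1, ] <- -m / s
  A[1, 1] <- 1
  list(beta = drop(A %*% theta), A = A)
}
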