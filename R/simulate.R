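#' Simulate outcomes from the Taba regression families
#'
#' Seeded generators drawing predictors, computing the family's category
#' probabilities at the supplied true coefficients, and sampling the
#' outcome — the data-generating process the estimators assume:
#' independent observations with Bernoulli/multinomial outcomes whose
#' means come from the Taba response.  Used throughout the test suite for
#' parameter-recovery and coverage studies.
#'
#' Predictor columns default to independent standard normal draws.  A
#' `predictor_spec` entry may instead be a number in (0, 1), giving a
#' Bernoulli column with that prevalence (mimicking the indicator-coded
#' clinical covariates of the cirrhosis study).
#'
#' @param n number of observations.
#' @param beta (binary) coefficient vector `(b0, b1, ..., bp)`; (ordinal)
#'   slope vector of length p.
#' @param B (multinomial) coefficient matrix, `(k-1) x (p+1)`.
#' @param alpha (ordinal) strictly increasing cutpoints, length k-1.
#' @param reference (multinomial) reference category index (default k).
#' @param predictor_spec character/numeric vector of length p: `"normal"`
#'   or a Bernoulli prevalence in (0, 1).
#' @param seed integer seed; identical seeds give identical data.
#' @return a [taba_model_data()].
#' @examples
#' md <- simulate_taba_binary(200, beta = c(0, 1), seed = 1)
#' mean(md$outcome)
#' @export
simulate_taba_binary <- function(n, beta, predictor_spec = NULL, seed = 1L) {
  p <- length(beta) - 1L
  X <- draw_predictors(n, p, predictor_spec, seed)
  pr <- taba_success_prob(drop(X %*% beta))
  y <- as.numeric(stats::runif(n) < pr)
  taba_model_data(y, X, design_names(p))
}

#' @rdname simulate_taba_binary
#' @export
simulate_taba_multinomial <- function(n, B, reference = nrow(B) + 1L,
                                      predictor_spec = NULL, seed = 1L) {
  B <- rbind(B)
  p <- ncol(B) - 1L
  k <- nrow(B) + 1L
  X <- draw_predictors(n, p, predictor_spec, seed)
  pr <- taba_multinom_probs(X %*% t(B), reference)
  y <- draw_categories(pr)
  taba_model_data(factor(y, levels = seq_len(k)), X, design_names(p))
}

#' @rdname simulate_taba_binary
#' @export
simulate_taba_ordinal <- function(n, alpha, beta, predictor_spec = NULL,
                                  seed = 1L) {
  if (any(diff(alpha) <= 0))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  p <- length(beta)
  k <- length(alpha) + 1L
  X <- draw_predictors(n, p, predictor_spec, seed)
  pr <- taba_ordinal_probs(alpha, beta, X[, -1L, drop = FALSE])
  y <- draw_categories(pr)
  taba_model_data(factor(y, levels = seq_len(k)), X, design_names(p))
}

draw_predictors <- function(n, p, predictor_spec, seed) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (is.null(predictor_spec)) predictor_spec <- rep("normal", p)
  if (length(predictor_spec) != p)
    stop("'predictor_spec' must have one entry per predictor", call. = FALSE)
  set.seed(as.integer(seed))
  cols <- lapply(predictor_spec, function(sp) {
    if (identical(sp, "normal")) stats::rnorm(n)
    else {
      prev <- suppressWarnings(as.numeric(sp))
      if (is.na(prev) || prev <= 0 || prev >= 1)
        stop("predictor spec must be \"normal\" or a prevalence in (0,1)",
             call. = FALSE)
      as.numeric(stats::runif(n) < prev)
    }
  })
  cbind(1, do.call(cbind, c(list(matrix(0, n, 0)), cols)))
}

design_names <- function(p) {
  c("(Intercept)", if (p > 0) paste0("x", seq_len(p)))
}

draw_categories <- function(pr) {
  cum <- t(apply(pr, 1, cumsum))
  if (nrow(pr) == 1L) cum <- matrix(cum, nrow = 1L)
  u <- stats::runif(nrow(pr))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

#' Write and read simulated data as CSV
#'
#' Round-trippable plain-CSV serialisation: the outcome in a column named
#' `outcome` followed by the predictor columns (intercept omitted).
#'
#' @param data a [taba_model_data()].
#' @param path file path.
#' @export
write_model_data_csv <- function(data, path) {
  stopifnot(inherits(data, "taba_model_data"))
  out <- if (is.null(data$categories)) data$outcome
         else data$categories[data$outcome]
  df <- data.frame(outcome = out, data$design[, -1L, drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_model_data_csv
#' @param outcome_col name of the outcome column.
#' @param categorical force the outcome to be treated as categorical.
#' @export
read_model_data_csv <- function(path, outcome_col = "outcome",
                                categorical = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_col %in% names(df))
    stop("no column '", outcome_col, "' in ", path, call. = FALSE)
  y <- df[[outcome_col]]
  if (categorical && !is.character(y) && !is.factor(y)) y <- factor(y)
  X <- as.matrix(df[setdiff(names(df), outcome_col)])
  taba_model_data(y, cbind(1, X), c("(Intercept)", colnames(X)))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates from a family at known truth and refits, reporting
#' per-coefficient bias, Monte-Carlo standard error of the bias, the
#' empirical SD of the estimates, the mean model-reported SE, and the
#' empirical coverage of 95% Wald intervals.  Non-convergent replicates
#' are excluded and counted.
#'
#' @param family `"binary"`, `"multinomial"`, or `"ordinal"`.
#' @param n observations per replicate.
#' @param replicates number of replicates (>= 2).
#' @param beta,B,alpha,reference truth, as in the simulators.
#' @param predictor_spec passed to the simulator.
#' @param seed base seed; per-replicate seeds are drawn from a generator
#'   seeded with it (consecutive integer seeds give measurably correlated
#'   Mersenne-Twister streams, which deflates the Monte-Carlo SE).
#' @return data frame with one row per coefficient (`term`, `truth`,
#'   `bias`, `mc_se`, `empirical_se`, `mean_reported_se`, `coverage`);
#'   attribute `n_nonconverged`.
#' @export
recovery_experiment <- function(family = c("binary", "multinomial", "ordinal"),
                                n, replicates, beta = NULL, B = NULL,
                                alpha = NULL, reference = NULL,
                                predictor_spec = NULL, seed = 1L) {
  family <- match.arg(family)
  if (replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  if (family == "multinomial") B <- rbind(B)
  truth <- switch(family,
    binary = beta,
    multinomial = as.vector(B),  # column-major, the fit coefficient layout
    ordinal = c(alpha, beta))
  q <- length(truth)
  est <- se <- matrix(NA_real_, replicates, q)
  bad <- 0L
  zc <- stats::qt(0.975, df = n)  # same df convention as wald_table
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, replicates)
  for (r in seq_len(replicates)) {
    s <- rep_seeds[r]
    fit <- switch(family,
      binary = taba_binary(simulate_taba_binary(n, beta, predictor_spec, s),
                           diagnostics = FALSE),
      multinomial = taba_multinomial(
        simulate_taba_multinomial(n, B, reference = if (is.null(reference))
          nrow(B) + 1L else reference, predictor_spec, s),
        reference = if (is.null(reference)) nrow(B) + 1L else reference),
      ordinal = taba_ordinal(simulate_taba_ordinal(n, alpha, beta,
                                                   predictor_spec, s)))
    if (!fit$converged) { bad <- bad + 1L; next }
    est[r, ] <- fit$coefficients
    se[r, ] <- sqrt(pmax(diag(fit$covariance), 0))
  }
  ok <- stats::complete.cases(est)
  est <- est[ok, , drop = FALSE]
  se <- se[ok, , drop = FALSE]
  cover <- colMeans(abs(sweep(est, 2, truth)) <= zc * se)
  out <- data.frame(
    term = paste0("theta", seq_len(q)), truth = truth,
    bias = colMeans(est) - truth,
    mc_se = apply(est, 2, stats::sd) / sqrt(nrow(est)),
    empirical_se = apply(est, 2, stats::sd),
    mean_reported_se = colMeans(se),
    coverage = cover, row.names = NULL)
  attr(out, "n_nonconverged") <- bad
  out
}
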