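# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the AUC oracle enumerates pairs, the
# grid oracle exhaustively scans the coefficient plane, and derivatives
# come from central differences.

# Mann-Whitney AUC by brute-force pair enumeration (half credit for ties)
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# Exhaustive two-stage grid search for a 2-parameter log-likelihood.
# Stage 1 scans [lo, hi]^2 at `coarse`; stage 2 rescans around the stage-1
# argmax at `fine` resolution.  Valid as an exhaustive oracle because the
# stage-2 window (+/- 2*coarse) always brackets the optimum of these
# unimodal toy likelihoods.
grid_argmax2 <- function(loglik2, lo = -5, hi = 5, coarse = 0.02,
                         fine = 1e-3) {
  stage <- function(b0s, b1s) {
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(loglik2, grid$b0, grid$b1)
    grid[which.max(vals), ]
  }
  g1 <- stage(seq(lo, hi, by = coarse), seq(lo, hi, by = coarse))
  g2 <- stage(seq(g1$b0 - 2 * coarse, g1$b0 + 2 * coarse, by = fine),
              seq(g1$b1 - 2 * coarse, g1$b1 + 2 * coarse, by = fine))
  c(g2$b0, g2$b1)
}

# central-difference first derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# minimal fit-shaped object for testing the inference summaries alone
fake_fit <- function(coefficients, covariance, loglik, n_obs, n_params,
                     family = "binary") {
  structure(list(family = family, coefficients = coefficients,
                 covariance = covariance, loglik = loglik, n_obs = n_obs,
                 n_params = n_params, converged = TRUE, n_iter = 1L),
            class = c(paste0("taba_", family), "taba_fit"))
}
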