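# Independent oracles used across the suite. These deliberately avoid the
# package's own fitting code paths.

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- as.vector(X %*% beta)
  list(intercept = beta[1], slope = beta[2],
       ssr = sum((y - fitted)^2))
}

# Brute-force grid search for the exponential model y = P0 * exp(-k t);
# returns the smallest sum of squared residuals on the grid.
grid_ssr_exp <- function(t, y, P0_range, k_range, n = 200) {
  P0s <- seq(P0_range[1], P0_range[2], length.out = n)
  ks <- seq(k_range[1], k_range[2], length.out = n)
  best <- Inf
  for (P0 in P0s) {
    preds <- outer(ks, t, function(k, tt) P0 * exp(-k * tt))
    ssrs <- rowSums(sweep(preds, 2, y)^2)
    best <- min(best, min(ssrs))
  }
  best
}

# Brute-force grid for the one-term Fickian model A * exp(-D pi^2 t / L^2).
grid_ssr_fick <- function(t, y, L, A_range, D_range, n = 200) {
  As <- seq(A_range[1], A_range[2], length.out = n)
  Ds <- seq(D_range[1], D_range[2], length.out = n)
  best <- Inf
  for (A in As) {
    preds <- outer(Ds, t, function(D, tt) A * exp(-D * pi^2 * tt / L^2))
    ssrs <- rowSums(sweep(preds, 2, y)^2)
    best <- min(best, min(ssrs))
  }
  best
}

# Triplicate-mean trajectory: the study measures everything in triplicate
# and fits the mean; replicate seeds are derived deterministically.
simulate_triplicate_mean <- function(model, truth, n_points, dt, noise_sd,
                                     seed) {
  reps <- lapply(0:2, function(j) {
    cfg <- sim_config(model, truth = truth, n_points = n_points, dt = dt,
                      seed = seed + j, noise_sd = noise_sd)
    simulate_stability(cfg)$value
  })
  decay_series((seq_len(n_points) - 1) * dt, Reduce(`+`, reps) / 3)
}
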