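# Independent oracles used to check the solver and metrics, plus a shared
# gain/batch cache so expensive solves happen once per test session.

# Steady-state discrete LQR gain by value iteration on the Riccati map.
dare_lqr <- function(A, B, Q, R, tol = 1e-13, max_iter = 200000) {
  P <- Q
  for (i in seq_len(max_iter)) {
    S <- R + t(B) %*% P %*% B
    Lg <- solve(S, t(B) %*% P %*% A)
    P2 <- Q + t(A) %*% P %*% A - t(A) %*% P %*% B %*% Lg
    P2 <- (P2 + t(P2)) / 2
    if (max(abs(P2 - P)) < tol * (1 + max(abs(P2)))) {
      P <- P2
      break
    }
    P <- P2
  }
  S <- R + t(B) %*% P %*% B
  list(P = P, L = solve(S, t(B) %*% P %*% A))
}

# Steady-state predictive Kalman gain by value iteration on the filter map.
dare_kalman <- function(A, H, Oxi, Oom, tol = 1e-13, max_iter = 200000) {
  S <- Oxi
  for (i in seq_len(max_iter)) {
    Sy <- H %*% S %*% t(H) + Oom
    K <- t(solve(Sy, H %*% S %*% t(A)))
    AKH <- A - K %*% H
    S2 <- AKH %*% S %*% t(AKH) + K %*% Oom %*% t(K) + Oxi
    S2 <- (S2 + t(S2)) / 2
    if (max(abs(S2 - S)) < tol * (1 + max(abs(S2)))) {
      S <- S2
      break
    }
    S <- S2
  }
  Sy <- H %*% S %*% t(H) + Oom
  list(Sigma = S, K = t(solve(Sy, H %*% S %*% t(A))))
}

# Brute-force peak Pearson cross-correlation over integer lags, with the same
# smallest-|lag|, positive-preferred tie-break as the implementation.
brute_xcorr <- function(hand, cursor, dt, max_lag_s = 1) {
  nn <- length(hand)
  kmax <- min(nn - 3L, round(max_lag_s / dt))
  lags <- (-kmax):kmax
  rs <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(hand[(1 + k):nn], cursor[1:(nn - k)])
    else stats::cor(hand[1:(nn + k)], cursor[(1 - k):nn])
  }, numeric(1))
  top <- max(abs(rs), na.rm = TRUE)
  cand <- which(!is.na(rs) & abs(rs) >= top - 1e-12)
  best <- cand[order(abs(lags[cand]), -sign(lags[cand]))][1]
  c(r = rs[best], lag = lags[best] * dt)
}

# Session-level cache: gain schedules and simulated batches are reused across
# test files that ask for the same configuration.
.cst_cache <- new.env(parent = emptyenv())

default_gains <- function(lam, objective, delay_steps = 5, noise = cst_noise(),
                          n = 800, dt = 0.01, weight = 1e4, U = 10) {
  key <- paste("g", lam, objective, delay_steps, noise$C, noise$motor_scale,
               noise$sensory_sd, n, dt, weight, U, sep = "|")
  if (is.null(.cst_cache[[key]])) {
    sysd <- discretize(build_continuous_system(lam, cst_plant()), dt = dt,
                       delay_steps = delay_steps)
    .cst_cache[[key]] <- solve_gains(sysd, make_objective(objective, weight,
                                                          U = U, n = n), noise)
  }
  .cst_cache[[key]]
}

default_batch <- function(objective, lam_grid, n_per_lam, base_seed,
                          weight = 1e4) {
  key <- paste("b", objective, paste(lam_grid, collapse = ","), n_per_lam,
               base_seed, weight, sep = "|")
  if (is.null(.cst_cache[[key]])) {
    .cst_cache[[key]] <- run_batch(objective, lam_grid = lam_grid,
                                   n_per_lam = n_per_lam,
                                   base_seed = base_seed, weight = weight,
                                   cache = .cst_cache)
  }
  .cst_cache[[key]]
}

default_features <- function(objective, lam_grid, n_per_lam, base_seed,
                             weight = 1e4) {
  key <- paste("f", objective, paste(lam_grid, collapse = ","), n_per_lam,
               base_seed, weight, sep = "|")
  if (is.null(.cst_cache[[key]])) {
    .cst_cache[[key]] <- trial_features(
      default_batch(objective, lam_grid, n_per_lam, base_seed, weight))
  }
  .cst_cache[[key]]
}

# Two well-separated Gaussian clusters in RMS space, for classifier tests.
make_clusters <- function(n = 200, gap = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    objective = rep(c("position", "velocity"), each = n),
    rms_x = c(stats::rnorm(n, 1, 0.3), stats::rnorm(n, 1 + gap, 0.3)),
    rms_xdot = c(stats::rnorm(n, 1 + gap, 0.3), stats::rnorm(n, 1, 0.3)))
}
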