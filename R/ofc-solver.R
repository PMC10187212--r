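#' Build a control objective (state-cost specification)
#'
#' Position Control penalizes deviation of the cursor position from the screen
#' center (`Q = diag(q, 0, 0, 0, 0)` on the physical states); Velocity Control
#' penalizes cursor velocity regardless of position
#' (`Q = diag(0, v, 0, 0, 0)`). The scalar effort weight `U` penalizes the
#' control signal. The realized cost of a trajectory is
#' `J = sum_t x_t' Q x_t + u_t' U u_t`.
#'
#' @param kind `"position"`, `"velocity"`, or `"custom"`.
#' @param weight State-cost weight (`q` for position, `v` for velocity).
#' @param U Effort weight (> 0).
#' @param n Horizon in control steps.
#' @param Q For `kind = "custom"`, a 5 x 5 state-cost matrix on the physical
#'   states.
#' @return A list of class `cst_cost` with the assembled 5 x 5 `Q`, weights,
#'   and horizon.
#' @export
make_objective <- function(kind = c("position", "velocity", "custom"),
                           weight = 1e4, U = 10, n = 800, Q = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) rlang::abort(
                     "unknown objective kind.", class = "cst_invalid_parameter"))
  if (weight < 0) rlang::abort("`weight` must be >= 0.", class = "cst_invalid_parameter")
  if (U <= 0) rlang::abort("`U` must be > 0.", class = "cst_invalid_parameter")
  if (n < 1) rlang::abort("`n` must be >= 1.", class = "cst_invalid_parameter")
  q <- v <- 0
  if (kind == "position") {
    q <- weight
    Q <- diag(c(weight, 0, 0, 0, 0))
  } else if (kind == "velocity") {
    v <- weight
    Q <- diag(c(0, weight, 0, 0, 0))
  } else {
    if (is.null(Q) || !is.matrix(Q) || any(dim(Q) != 5)) {
      rlang::abort("custom kind needs a 5 x 5 `Q`.", class = "cst_invalid_parameter")
    }
  }
  structure(list(kind = kind, q = q, v = v, U = U, n = as.integer(n), Q = Q),
            class = "cst_cost")
}

# Stationary estimation-error covariance of the predictive Kalman filter,
# by iterating the filter Riccati recursion to its fixed point.
stationary_filter_cov <- function(A, H, Oxi, Oom) {
  na <- nrow(A)
  no <- nrow(H)
  Sig <- Oxi
  tA <- t(A)
  for (i in seq_len(100000)) {
    Sy <- H %*% Sig %*% t(H) + Oom
    K <- if (max(abs(Sy)) < 1e-300) matrix(0, na, no) else
      t(solve(Sy, H %*% Sig %*% tA))
    AKH <- A - K %*% H
    Sig2 <- AKH %*% Sig %*% t(AKH) + K %*% Oom %*% t(K) + Oxi
    Sig2 <- (Sig2 + t(Sig2)) / 2
    d <- max(abs(Sig2 - Sig)) / (max(abs(Sig2)) + 1e-300)
    Sig <- Sig2
    if (d < 1e-13) break
  }
  Sig
}

# Lift the 5x5 physical-state cost to the delay-augmented space.
# Cost acts on the newest copy: the controller's objective concerns the true
# current state, not the delayed observed one.
lift_cost <- function(cost, sys) {
  n <- sys$n_states
  Qa <- matrix(0, n, n)
  Qa[1:5, 1:5] <- cost$Q
  Qa
}

#' Solve finite-horizon feedback and filter gains under signal-dependent noise
#'
#' Computes time-varying control gains `L_t` (control law `u_t = -L_t xhat_t`)
#' and estimator gains `K_t` (predictive filter
#' `xhat[t+1] = (Ad - Bd L_t) xhat[t] + K_t (y[t] - H xhat[t])`) for the
#' stochastic plant with multiplicative (signal-dependent) motor noise.
#'
#' The filter gains solve the standard delay-augmented Kalman recursion for
#' the additive noise statistics, in a single forward pass:
#' \deqn{K_t = A \Sigma_t H' (H \Sigma_t H' + \Omega_\omega)^{-1}, \quad
#'       \Sigma_{t+1} = (A-K_tH)\Sigma_t(A-K_tH)' + K_t\Omega_\omega K_t' +
#'       \Omega_\xi}
#' The control gains are then solved in a single backward pass that accounts
#' for the signal-dependent noise (cautious control), propagating value
#' matrices on the true state and on the estimation error:
#' \deqn{L_t = (U + B'S^x_{t+1}B + C_1'(S^x_{t+1}+S^e_{t+1})C_1)^{-1}
#'       B'S^x_{t+1}A}
#' \deqn{S^x_t = Q + A'S^x_{t+1}(A - BL_t), \quad
#'       S^e_t = A'S^x_{t+1}BL_t + (A-K_tH)'S^e_{t+1}(A-K_tH)}
#' with `C_1 = C * B`. With `C = 0` this reduces exactly to the separated
#' LQG solution, whose interior gains match the steady-state
#' linear-quadratic-regulator and Kalman gains. Designing the filter from the
#' additive-noise statistics keeps the whole solve a deterministic two-pass
#' computation: at difficulties where the closed loop is mean-square unstable
#' (large lambda with strong signal-dependent noise — the regime where trials
#' fail), second moments grow without bound over the horizon and a
#' fully-coupled gain fixed point is not numerically attainable. The backward
#' pass rescales its value matrices by a running scale factor so that gain
#' formulas stay well-conditioned even when the value matrices grow by
#' hundreds of orders of magnitude over an unstable horizon.
#'
#' @param sys A `cst_system_d` from [discretize()].
#' @param cost A `cst_cost` from [make_objective()].
#' @param noise A [cst_noise()] specification.
#' @param Sigma0 Initial estimation-error covariance (augmented space) used by
#'   the filter recursion. The default is the stationary filter covariance, so
#'   the gain schedule is designed for the steady-state sensing regime; with a
#'   zero start the first filter gains are zero (the plant is open-loop
#'   unstable there) and the backward pass inherits a large spurious transient
#'   in the early control gains.
#' @return A list of class `cst_gains`: `L` (n x n_states matrix, row t is
#'   L_t), `K` (n_states x n_obs x n array), `iterations` (passes),
#'   `converged`, `residual` (max relative change of the filter gain over the
#'   final steps of its forward recursion, a stationarity diagnostic), plus
#'   the inputs for provenance.
#' @export
solve_gains <- function(sys, cost, noise = cst_noise(), Sigma0 = NULL) {
  stopifnot(inherits(sys, "cst_system_d"), inherits(cost, "cst_cost"),
            inherits(noise, "cst_noise"))
  A <- sys$Ad
  B <- sys$Bd
  H <- sys$H
  na <- sys$n_states
  no <- nrow(H)
  n <- cost$n
  Qa <- lift_cost(cost, sys)
  U <- cost$U
  C1 <- noise$C * B                      # signal-dependent noise direction
  Oxi <- noise$motor_scale * tcrossprod(B)
  Oom <- diag(noise$sensory_sd^2, no)
  tA <- t(A)
  tH <- t(H)
  if (is.null(Sigma0)) {
    Sigma0 <- stationary_filter_cov(A, H, Oxi, Oom)
  }

  # forward filter pass (independent of L; bounded covariances)
  Karr <- array(0, dim = c(na, no, n))
  Sig <- Sigma0
  for (t in 1:n) {
    Sy <- H %*% Sig %*% tH + Oom
    if (max(abs(Sy)) < 1e-300) {
      Kt <- matrix(0, na, no)
    } else {
      Kt <- t(solve(Sy, H %*% Sig %*% tA))
    }
    Karr[, , t] <- Kt
    AKH <- A - Kt %*% H
    Sig2 <- AKH %*% Sig %*% t(AKH) + Kt %*% Oom %*% t(Kt) + Oxi
    Sig <- (Sig2 + t(Sig2)) / 2
  }
  resid <- if (n >= 2) {
    max(abs(Karr[, , n] - Karr[, , n - 1])) / (max(abs(Karr[, , n])) + 1e-12)
  } else NA_real_

  # backward control pass with signal-dependent caution; value matrices are
  # kept explicitly symmetric (A'S B L = denom L'L) and renormalized each
  # step (gains are scale-invariant ratios), which keeps the recursion
  # well-conditioned over mean-square-unstable horizons
  L <- matrix(0, n, na)
  Sx <- Qa                               # terminal cost: Q at the final step
  Se <- matrix(0, na, na)
  sig <- 1
  for (t in n:1) {
    SxB <- Sx %*% B
    denom <- U / sig + as.numeric(crossprod(B, SxB)) +
      as.numeric(crossprod(C1, (Sx + Se) %*% C1))
    Lt <- crossprod(SxB, A) / denom      # 1 x na
    L[t, ] <- Lt
    AKH <- A - Karr[, , t] %*% H
    Se <- denom * crossprod(Lt) + crossprod(AKH, Se %*% AKH)
    Se <- (Se + t(Se)) / 2
    Sx <- Qa / sig + crossprod(A, Sx %*% A) - denom * crossprod(Lt)
    Sx <- (Sx + t(Sx)) / 2
    m <- max(abs(Sx), abs(Se))
    if (m > 0) {
      Sx <- Sx / m
      Se <- Se / m
      sig <- sig * m
    }
  }

  structure(list(L = L, K = Karr, iterations = 2L, converged = TRUE,
                 residual = resid, n = n, sys = sys, cost = cost,
                 noise = noise),
            class = "cst_gains")
}

#' Realized quadratic cost of a trial
#'
#' Evaluates `J = sum_t x_t' Q x_t + u_t' U u_t` over the physical state
#' series of a trial, using the 5 x 5 `Q` of the objective. States are taken
#' in SI units (the units the cost was solved in); kinematic series columns
#' are stored in cm and converted here.
#'
#' @param data A per-step series tibble with columns `x, xdot, p, pdot, u`
#'   (as stored in a trial set's `data` list-column).
#' @param cost A `cst_cost`.
#' @return The scalar realized cost.
#' @export
trajectory_cost <- function(data, cost) {
  X <- cbind(data$x, data$xdot, data$p, data$pdot) / 100
  X <- cbind(X, data$F_force)
  u <- data$u
  u[is.na(u)] <- 0
  sum((X %*% cost$Q) * X) + cost$U * sum(u^2)
}

# In-memory gain cache keyed by (lambda, objective, parameter fingerprint);
# batch simulation solves once per key.
gain_cache_key <- function(lam, cost, plant, noise, dt, delay_steps) {
  paste(format(c(lam, cost$q, cost$v, cost$U, cost$n, plant$M, plant$tau,
                 noise$C, noise$motor_scale, noise$sensory_sd, dt, delay_steps),
               digits = 17), collapse = "|")
}

cached_gains <- function(cache, lam, objective, weight, U, n, plant, noise,
                         dt, delay_steps) {
  cost <- make_objective(objective, weight = weight, U = U, n = n)
  key <- gain_cache_key(lam, cost, plant, noise, dt, delay_steps)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sysd <- discretize(build_continuous_system(lam, plant), dt = dt,
                     delay_steps = delay_steps)
  g <- solve_gains(sysd, cost, noise)
  if (!is.null(cache)) cache[[key]] <- g
  g
}

#' Export / import a gain schedule as JSON
#'
#' Stores the full time-indexed gain matrices with the (lambda, objective,
#' parameter) provenance so batch simulations can reuse solved schedules.
#'
#' @param gains A `cst_gains` object.
#' @param path File to write / read.
#' @return `write_gains_json` returns `path` invisibly; `read_gains_json`
#'   returns a `cst_gains` object.
#' @export
write_gains_json <- function(gains, path) {
  stopifnot(inherits(gains, "cst_gains"))
  doc <- list(
    type = "cst_gains",
    lam = gains$sys$lam,
    dt = gains$sys$dt,
    delay_steps = gains$sys$delay_steps,
    plant = unclass(gains$sys$continuous$plant),
    noise = unclass(gains$noise),
    cost = list(kind = gains$cost$kind, q = gains$cost$q, v = gains$cost$v,
                U = gains$cost$U, n = gains$cost$n),
    iterations = gains$iterations,
    residual = gains$residual,
    L = gains$L,
    K = as.numeric(gains$K),
    K_dim = dim(gains$K)
  )
  writeLines(as.character(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)),
             path)
  invisible(path)
}

#' @rdname write_gains_json
#' @export
read_gains_json <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  if (is.null(doc$type) || doc$type != "cst_gains") {
    rlang::abort("not a cst_gains JSON document.", class = "cst_bad_input")
  }
  sysd <- discretize(
    build_continuous_system(doc$lam, cst_plant(doc$plant$M, doc$plant$tau)),
    dt = doc$dt, delay_steps = doc$delay_steps)
  cost <- make_objective(doc$cost$kind,
                         weight = if (doc$cost$kind == "position") doc$cost$q else doc$cost$v,
                         U = doc$cost$U, n = doc$cost$n)
  noise <- cst_noise(C = doc$noise$C, motor_scale = doc$noise$motor_scale,
                     sensory_sd = doc$noise$sensory_sd)
  structure(list(L = doc$L, K = array(doc$K, dim = doc$K_dim),
                 iterations = doc$iterations, converged = TRUE,
                 residual = doc$residual, n = doc$cost$n, sys = sysd,
                 cost = cost, noise = noise),
            class = "cst_gains")
}
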