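#' Task configuration for the Critical Stability Task
#'
#' The CST asks a subject (or a simulated controller) to keep an unstable
#' cursor inside a lateral workspace by moving the hand. Cursor dynamics are
#' `xdot = lambda * (x + p)` where `x` is cursor position, `p` hand position,
#' and `lambda` the instability gain that sets task difficulty.
#'
#' @param lam Difficulty constant lambda (1/s), strictly positive.
#' @param c Workspace half-width (cm). A trial fails when `|x| > c` within the
#'   analyzed duration.
#' @param trial_duration Analyzed duration (s) used for success evaluation and
#'   all behavioural metrics.
#' @param sim_duration Simulated horizon (s); must be at least `trial_duration`.
#' @param dt Integration/control time step (s).
#' @return A list of class `cst_task`.
#' @examples
#' cst_task(lam = 3)
#' @export
cst_task <- function(lam = 4, c = 10, trial_duration = 6, sim_duration = 8,
                     dt = 0.01) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    rlang::abort("`lam` must be a single positive number.",
                 class = "cst_invalid_parameter")
  }
  if (c <= 0) rlang::abort("`c` must be positive.", class = "cst_invalid_parameter")
  if (dt <= 0) rlang::abort("`dt` must be positive.", class = "cst_invalid_parameter")
  if (trial_duration <= 0 || trial_duration > sim_duration) {
    rlang::abort("need 0 < trial_duration <= sim_duration.",
                 class = "cst_invalid_parameter")
  }
  structure(list(lam = lam, c = c, trial_duration = trial_duration,
                 sim_duration = sim_duration, dt = dt),
            class = "cst_task")
}

#' Hand and muscle plant parameters
#'
#' The hand is a point mass `M` driven by a muscle-like actuator modelled as a
#' first-order low-pass filter with time constant `tau`:
#' `tau * Fdot = -F + u`, `pddot = F / M`.
#'
#' @param M Hand mass (kg).
#' @param tau Muscle time constant (s).
#' @return A list of class `cst_plant`.
#' @export
cst_plant <- function(M = 1, tau = 0.06) {
  if (M <= 0 || tau <= 0) {
    rlang::abort("`M` and `tau` must be positive.", class = "cst_invalid_parameter")
  }
  structure(list(M = M, tau = tau), class = "cst_plant")
}

#' Noise specification for the stochastic plant
#'
#' Three noise sources enter the discrete dynamics
#' `x[t+1] = Ad x[t] + Bd (1 + eps[t] * C) u[t] + xi[t]`,
#' `y[t] = H x[t] + omega[t]`:
#' signal-dependent multiplicative motor noise with scalar `C`
#' (`eps ~ N(0, 1)`), additive motor noise
#' `xi ~ N(0, motor_scale * Bd Bd')`, and additive sensory noise
#' `omega` with per-channel standard deviation `sensory_sd`.
#'
#' All noise magnitudes are in the plant's SI units (m, m/s, N) — the units
#' the hand mass and muscle constant are stated in; kinematic trial series are
#' reported in cm.
#'
#' @param C Signal-dependent noise scalar (dimensionless).
#' @param motor_scale Multiplier on `Bd Bd'` giving the additive motor noise
#'   covariance (SI).
#' @param sensory_sd Standard deviation of the additive sensory noise on each
#'   observed channel (in the channel's own SI units: m, m/s, N).
#' @param seed Optional integer seed recorded for provenance; per-trial seeds
#'   are managed by the simulator.
#' @return A list of class `cst_noise`.
#' @export
cst_noise <- function(C = 1.5, motor_scale = 0.4, sensory_sd = 0.05,
                      seed = NULL) {
  if (C < 0 || motor_scale < 0 || sensory_sd < 0) {
    rlang::abort("noise magnitudes must be non-negative.",
                 class = "cst_invalid_parameter")
  }
  structure(list(C = C, motor_scale = motor_scale, sensory_sd = sensory_sd,
                 seed = seed),
            class = "cst_noise")
}

cst_state_labels <- c("x", "xdot", "p", "pdot", "F")

#' Continuous-time state-space plant of the hand-muscle-cursor system
#'
#' Builds the five-state linear system with state vector
#' `[x, xdot, p, pdot, F]` (cursor position and velocity, hand position and
#' velocity, actuator force). Differentiating the cursor dynamics once gives
#' `xddot = lambda^2 x + lambda^2 p + lambda pdot`, which makes cursor
#' velocity an explicit state so that velocity-penalizing objectives can be
#' expressed.
#'
#' @param lam Difficulty constant lambda (1/s), positive.
#' @param plant A [cst_plant()] object.
#' @return A list of class `cst_system_c` with entries `A` (5 x 5), `B`
#'   (5 x 1), `state_labels`, `lam`, and `plant`.
#' @examples
#' sys <- build_continuous_system(2, cst_plant())
#' sys$A[2, ]  # lambda^2, 0, lambda^2, lambda, 0
#' @export
build_continuous_system <- function(lam, plant = cst_plant()) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    rlang::abort("`lam` must be a single positive number.",
                 class = "cst_invalid_parameter")
  }
  stopifnot(inherits(plant, "cst_plant"))
  A <- rbind(
    c(0,       1, 0,       0,   0),
    c(lam^2,   0, lam^2,   lam, 0),
    c(0,       0, 0,       1,   0),
    c(0,       0, 0,       0,   1 / plant$M),
    c(0,       0, 0,       0,   -1 / plant$tau)
  )
  B <- matrix(c(0, 0, 0, 0, 1 / plant$tau), ncol = 1)
  dimnames(A) <- list(cst_state_labels, cst_state_labels)
  rownames(B) <- cst_state_labels
  structure(list(A = A, B = B, state_labels = cst_state_labels,
                 lam = lam, plant = plant),
            class = "cst_system_c")
}

#' Discretize the plant, optionally augmenting for sensory delay
#'
#' Uses the forward-Euler discretization `Ad = I + dt * A`, `Bd = dt * B`.
#' Sensory delay of `delay_steps` control steps is represented by state
#' augmentation: the augmented state stacks the current physical state with
#' copies from the `delay_steps` preceding steps, and the observation matrix
#' `H` reads the oldest copy. Control and state costs act on the newest copy.
#'
#' @param sys A `cst_system_c` from [build_continuous_system()].
#' @param dt Time step (s).
#' @param delay_steps Sensory delay in steps (>= 0); the default 5 steps at
#'   `dt = 0.01` s gives the 50 ms loop delay.
#' @return A list of class `cst_system_d` with `Ad`, `Bd`, `H`, `delay_steps`,
#'   `n_states` (augmented dimension), `dt`, the unaugmented `Ad5`/`Bd5`, and
#'   the originating continuous system.
#' @export
discretize <- function(sys, dt = 0.01, delay_steps = 5) {
  stopifnot(inherits(sys, "cst_system_c"))
  if (dt <= 0) rlang::abort("`dt` must be positive.", class = "cst_invalid_parameter")
  if (delay_steps < 0 || delay_steps != round(delay_steps)) {
    rlang::abort("`delay_steps` must be a non-negative integer.",
                 class = "cst_invalid_parameter")
  }
  m <- nrow(sys$A)
  Ad5 <- diag(m) + dt * sys$A
  Bd5 <- dt * sys$B
  d <- as.integer(delay_steps)
  n <- m * (d + 1L)
  if (d == 0L) {
    Ad <- Ad5
    Bd <- Bd5
    H <- diag(m)
  } else {
    Ad <- matrix(0, n, n)
    Ad[1:m, 1:m] <- Ad5
    # each stored copy moves one step older per transition
    for (k in seq_len(d)) {
      rows <- k * m + 1:m
      cols <- (k - 1L) * m + 1:m
      Ad[rows, cols] <- diag(m)
    }
    Bd <- matrix(0, n, 1)
    Bd[1:m, 1] <- Bd5
    H <- matrix(0, m, n)
    H[, d * m + 1:m] <- diag(m)
  }
  structure(list(Ad = Ad, Bd = Bd, H = H, delay_steps = d, n_states = n,
                 dt = dt, Ad5 = Ad5, Bd5 = Bd5, continuous = sys,
                 lam = sys$lam),
            class = "cst_system_d")
}

#' Reconstruct cursor kinematics from a hand trajectory
#'
#' Integrates the cursor dynamics `xdot = lambda * (x + p)` along a uniformly
#' sampled hand-position series. The default `"euler"` scheme matches the
#' simulator's forward-Euler propagation exactly, so reconstructing the cursor
#' from a simulated hand trace round-trips to the simulated cursor at machine
#' precision. The `"exact"` scheme uses the zero-order-hold matrix exponential
#' of the scalar dynamics and is preferred for externally recorded data.
#'
#' @param hand Numeric vector of hand positions (cm) sampled every `dt`
#'   seconds, or a data frame with columns `time_s` and `hand_cm` (any uniform
#'   rate; resampled linearly to `dt`).
#' @param lam Difficulty constant of the trial.
#' @param dt Model time step (s) of the returned series.
#' @param x0 Initial cursor position (cm).
#' @param method Integration scheme, `"euler"` or `"exact"`.
#' @return A tibble with columns `t`, `x`, `xdot`, `p`.
#' @examples
#' out <- cursor_from_hand(rep(1, 51), lam = 2, dt = 0.01, method = "exact")
#' out$x[51]  # exp(2 * 0.5) - 1
#' @export
cursor_from_hand <- function(hand, lam, dt = 0.01, x0 = 0,
                             method = c("euler", "exact")) {
  method <- match.arg(method)
  if (is.data.frame(hand)) {
    if (!all(c("time_s", "hand_cm") %in% names(hand))) {
      rlang::abort("hand data frame needs columns `time_s` and `hand_cm`.",
                   class = "cst_bad_input")
    }
    hand <- resample_hand(hand$time_s, hand$hand_cm, dt)
  }
  hand <- as.numeric(hand)
  if (length(hand) < 2L) {
    rlang::abort("hand series needs at least 2 samples.", class = "cst_bad_input")
  }
  bad <- which(!is.finite(hand))
  if (length(bad)) {
    rlang::abort(sprintf("non-finite hand sample at index %d.", bad[1]),
                 class = "cst_bad_input")
  }
  if (lam <= 0) rlang::abort("`lam` must be positive.", class = "cst_invalid_parameter")
  nn <- length(hand)
  x <- numeric(nn)
  x[1] <- x0
  if (method == "euler") {
    # op order matches the simulator's propagation so the round-trip is exact
    for (k in seq_len(nn - 1L)) {
      xd <- lam * (x[k] + hand[k])
      x[k + 1L] <- x[k] + dt * xd
    }
  } else {
    a <- exp(lam * dt)
    for (k in seq_len(nn - 1L)) {
      x[k + 1L] <- a * x[k] + (a - 1) * hand[k]
    }
  }
  tibble::tibble(
    t = (seq_len(nn) - 1L) * dt,
    x = x,
    xdot = lam * (x + hand),
    p = hand
  )
}

# Linear resampling of an externally recorded hand trace onto the model step.
resample_hand <- function(time_s, hand_cm, dt) {
  keep <- is.finite(time_s)
  if (!any(keep)) rlang::abort("no finite time stamps.", class = "cst_bad_input")
  t0 <- min(time_s[keep])
  t1 <- max(time_s[keep])
  grid <- seq(t0, t1, by = dt)
  stats::approx(time_s, hand_cm, xout = grid, rule = 2)$y
}

#' Read a recorded hand trace from a delimited text file
#'
#' Expects a header row and columns `time_s` and `hand_cm`; optional columns
#' `trial_id` and `lambda` are carried through. Comma- and tab-delimited files
#' are auto-detected.
#'
#' @param path Path to a CSV or TSV file.
#' @return A tibble with one row per sample.
#' @export
read_hand_trace <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "cst_bad_input")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE)
  need <- c("time_s", "hand_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("hand trace is missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "cst_bad_input")
  }
  tibble::as_tibble(df)
}

#' Serialize a system description to JSON
#'
#' Round-trips the discrete (possibly delay-augmented) system together with
#' its continuous parent and parameters, for inspection or archiving.
#'
#' @param sys A `cst_system_d` object.
#' @param path File to write. If `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_system_json <- function(sys, path = NULL) {
  stopifnot(inherits(sys, "cst_system_d"))
  doc <- list(
    type = "cst_system_d",
    lam = sys$lam,
    plant = unclass(sys$continuous$plant),
    dt = sys$dt,
    delay_steps = sys$delay_steps,
    n_states = sys$n_states,
    state_labels = sys$continuous$state_labels,
    A = sys$continuous$A,
    B = sys$continuous$B,
    Ad = sys$Ad,
    Bd = sys$Bd,
    H = sys$H
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a system description written by [write_system_json()]
#'
#' @param path File path or a JSON string.
#' @return A `cst_system_d` object equal (entrywise) to the one serialized.
#' @export
read_system_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n") else path
  doc <- jsonlite::fromJSON(txt)
  if (is.null(doc$type) || doc$type != "cst_system_d") {
    rlang::abort("not a cst_system_d JSON document.", class = "cst_bad_input")
  }
  sysc <- build_continuous_system(doc$lam,
                                  cst_plant(M = doc$plant$M, tau = doc$plant$tau))
  sysd <- discretize(sysc, dt = doc$dt, delay_steps = doc$delay_steps)
  # verify stored matrices agree with the reconstruction
  if (max(abs(sysd$Ad - doc$Ad)) > 1e-12 || max(abs(sysd$Bd - doc$Bd)) > 1e-12) {
    rlang::abort("stored matrices disagree with stored parameters.",
                 class = "cst_bad_input")
  }
  sysd
}
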