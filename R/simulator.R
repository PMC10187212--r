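#' @importFrom rlang .data
NULL

# Counter-based per-trial seed derivation: reproducible and independent of
# batch composition/order. Plain LCG-style mixing kept below 2^31.
derive_seed <- function(base_seed, counter) {
  m <- 2147483647
  as.integer(((base_seed %% m) * 1103515 + counter * 12820163) %% m)
}

# Deterministic integer from a tag string, for fanning one base seed out to
# pipeline stages.
seed_for <- function(base_seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  derive_seed(base_seed, h)
}

# Vectorized forward simulation of many trials sharing one gain schedule.
# Noise streams are generated per trial from that trial's own seed, so a
# trial's noise realization is identical whether simulated alone or inside a
# batch.
#
# Units: the noise magnitudes and plant parameters are SI (m, kg, N). The
# state is propagated in a cm-scaled basis [cm, cm/s, cm, cm/s, 100*N] in
# which the dynamics matrices are unchanged and the solved gains apply as-is
# (the control and filter gains are invariant to a common scaling of state,
# observation and control); only the additive noise magnitudes convert
# (x100). Kinematic series then come out in cm natively, with no per-sample
# unit conversion that would perturb exact hand->cursor round-trips; force
# and control are converted back to N on output.
simulate_trials_core <- function(sys, gains, noise, task, seeds,
                                 x_init_offset = 0) {
  A <- sys$Ad
  B <- sys$Bd
  H <- sys$H
  na <- sys$n_states
  no <- nrow(H)
  n <- gains$n
  dt <- sys$dt
  lam <- sys$lam
  ntr <- length(seeds)
  stopifnot(ntr >= 1)
  n_expect <- round(task$sim_duration / task$dt)
  if (n != n_expect) {
    rlang::abort(sprintf(
      "gain schedule horizon (%d) does not match task sim_duration/dt (%d).",
      n, n_expect), class = "cst_invalid_parameter")
  }

  # per-trial noise streams (eps, z, omega) in a fixed layout
  eps <- matrix(0, n, ntr)
  zmot <- matrix(0, n, ntr)
  omg <- matrix(0, no * n, ntr)
  for (j in seq_len(ntr)) {
    set.seed(seeds[j])
    draws <- stats::rnorm(n * (2L + no))
    eps[, j] <- draws[1:n]
    zmot[, j] <- draws[n + 1:n]
    omg[, j] <- draws[2L * n + 1:(no * n)]
  }

  X <- matrix(0, na, ntr)
  if (any(x_init_offset != 0)) {
    off <- rep_len(x_init_offset, ntr)                # cm
    idx_x <- seq(1, na, by = 5)       # cursor position in every delayed copy
    idx_xd <- seq(2, na, by = 5)      # cursor velocity copies
    X[idx_x, ] <- matrix(off, length(idx_x), ntr, byrow = TRUE)
    # xdot initialized to satisfy xdot = lam * (x + p) with p = 0
    X[idx_xd, ] <- matrix(lam * off, length(idx_xd), ntr, byrow = TRUE)
  }
  Xh <- X                              # estimate initialized to the true state

  xs <- matrix(0, n + 1L, ntr)
  xds <- matrix(0, n + 1L, ntr)
  ps <- matrix(0, n + 1L, ntr)
  pds <- matrix(0, n + 1L, ntr)
  fs <- matrix(0, n + 1L, ntr)
  us <- matrix(NA_real_, n + 1L, ntr)
  xs[1, ] <- X[1, ]; xds[1, ] <- X[2, ]

  sm <- 100 * sqrt(noise$motor_scale)               # SI -> cm-scaled state
  sw <- 100 * noise$sensory_sd
  Cn <- noise$C
  L <- gains$L
  K <- gains$K

  for (t in seq_len(n)) {
    U <- -(L[t, , drop = FALSE] %*% Xh)                  # 1 x ntr
    Y <- H %*% X + sw * omg[(t - 1L) * no + 1:no, , drop = FALSE]
    Xh <- A %*% Xh + B %*% U + K[, , t] %*% (Y - H %*% Xh)
    xprev <- X[1, ]
    xdprev <- X[2, ]
    X <- A %*% X + B %*% (U * (1 + Cn * eps[t, ])) +
      B %*% (sm * zmot[t, , drop = FALSE])
    # cursor rows are recomputed with plain elementwise arithmetic: the Euler
    # position update in the exact operation order cursor_from_hand() uses
    # (BLAS kernels may fuse it differently), and the velocity state pinned to
    # its defining relation xdot = lam (x + p). Both are no-ops in exact
    # arithmetic; together they make hand->cursor reconstruction invert the
    # propagation bit-for-bit instead of drifting by e^(lam t) * eps.
    X[1, ] <- xprev + dt * xdprev
    X[2, ] <- lam * (X[1, ] + X[3, ])
    us[t, ] <- U
    xs[t + 1L, ] <- X[1, ]
    xds[t + 1L, ] <- X[2, ]
    ps[t + 1L, ] <- X[3, ]
    pds[t + 1L, ] <- X[4, ]
    fs[t + 1L, ] <- X[5, ]
  }

  tvec <- (0:n) * dt
  rows <- vector("list", ntr)
  success <- logical(ntr)
  for (j in seq_len(ntr)) {
    xj <- xs[, j]
    finite <- is.finite(xj) & is.finite(ps[, j]) & is.finite(xds[, j])
    cut <- if (all(finite)) n + 1L else which(!finite)[1] - 1L
    keep <- seq_len(max(cut, 1L))
    an <- keep[tvec[keep] <= task$trial_duration + 1e-12]
    diverged <- cut < n + 1L && tvec[min(cut + 1L, n + 1L)] <= task$trial_duration
    success[j] <- !diverged && all(abs(xj[an]) <= task$c)
    rows[[j]] <- tibble::tibble(
      t = tvec[keep], x = xs[keep, j], xdot = xds[keep, j],
      p = ps[keep, j], pdot = pds[keep, j],
      F_force = fs[keep, j] / 100, u = us[keep, j] / 100)
  }
  list(data = rows, success = success)
}

#' Simulate one CST trial under solved feedback gains
#'
#' Forward-simulates the true (delay-augmented) state with signal-dependent
#' and additive motor noise, generates noisy delayed observations, runs the
#' state estimator, and applies the control law `u_t = -L_t xhat_t`. The trial
#' starts at the origin (optionally offset in cursor position, with cursor
#' velocity initialized consistently with the cursor dynamics) and the
#' estimator starts at the true state.
#'
#' @param sys A `cst_system_d`.
#' @param gains A `cst_gains` solved for the same system and horizon.
#' @param noise A [cst_noise()] specification.
#' @param task A [cst_task()] (must share `dt` with `sys`).
#' @param seed Integer seed for this trial's noise streams.
#' @param x_init_offset Initial cursor position offset (cm).
#' @param objective Label recorded on the trial (defaults to the objective the
#'   gains were solved for).
#' @return A one-row `cst_trialset` tibble: `trial_id, lam, objective, seed,
#'   success` and a `data` list-column holding the per-step series
#'   (`t, x, xdot, p, pdot, F_force, u`). Trials whose state diverges to
#'   non-finite values are truncated at the first bad step and flagged failed.
#' @export
simulate_trial <- function(sys, gains, noise = cst_noise(), task = NULL,
                           seed = 1L, x_init_offset = 0, objective = NULL) {
  if (is.null(task)) task <- cst_task(lam = sys$lam, dt = sys$dt)
  if (is.null(objective)) objective <- gains$cost$kind
  out <- simulate_trials_core(sys, gains, noise, task, seeds = seed,
                              x_init_offset = x_init_offset)
  new_trialset(
    tibble::tibble(
      trial_id = sprintf("%s_lam%.2f_s%d", objective, sys$lam, seed),
      lam = sys$lam, objective = objective, seed = as.integer(seed),
      success = out$success, data = out$data),
    task = task, plant = sys$continuous$plant, noise = noise,
    cost = gains$cost)
}

new_trialset <- function(df, task, plant, noise, cost) {
  structure(df, class = c("cst_trialset", class(df)),
            provenance = list(task = unclass(task), plant = unclass(plant),
                              noise = unclass(noise),
                              cost = if (!is.null(cost))
                                list(kind = cost$kind, q = cost$q, v = cost$v,
                                     U = cost$U, n = cost$n),
                              package_version = as.character(
                                utils::packageVersion("cstcontrol"))))
}

#' Provenance of a trial set
#'
#' @param set A `cst_trialset`.
#' @return The provenance list (task, plant, noise, cost, package version)
#'   recorded when the set was generated.
#' @export
trial_provenance <- function(set) attr(set, "provenance")

#' Evaluate trial success from the cursor series
#'
#' A trial fails if and only if the cursor leaves the workspace
#' (`|x| > c`) at any time up to `trial_duration`; excursions after the
#' analyzed window (the simulation runs longer) are ignored.
#'
#' @param data A per-step series tibble with columns `t` and `x`.
#' @param task A [cst_task()].
#' @return `TRUE` for success.
#' @export
evaluate_success <- function(data, task) {
  an <- data$t <= task$trial_duration + 1e-12
  if (!any(an)) rlang::abort("series shorter than the analyzed window.",
                             class = "cst_bad_input")
  x <- data$x[an]
  all(is.finite(x)) && all(abs(x) <= task$c) &&
    max(data$t) >= task$trial_duration - 1e-12
}

#' Simulate a batch of trials over a difficulty grid
#'
#' Solves the gain schedule once per (lambda, objective) — reusing `cache`
#' when supplied — and simulates `n_per_lam` trials at each difficulty with
#' per-trial seeds derived from `base_seed` by a counter scheme, so any trial
#' is reproducible in isolation.
#'
#' @param objective `"position"` or `"velocity"`.
#' @param lam_grid Difficulty values; default is the 28-level grid 1.5 to 7 in
#'   steps of 0.2.
#' @param n_per_lam Trials per difficulty level.
#' @param base_seed Integer base seed.
#' @param task,plant,noise Model configuration ([cst_task()] constants other
#'   than `lam` are used; `lam` is taken from the grid).
#' @param weight,U State-cost and effort weights passed to [make_objective()].
#' @param delay_steps Sensory delay in steps.
#' @param x_init_offset Initial cursor offset applied to every trial.
#' @param cache Optional environment used as a gain cache across calls.
#' @return A `cst_trialset` with `length(lam_grid) * n_per_lam` rows.
#' @export
run_batch <- function(objective = c("position", "velocity"),
                      lam_grid = seq(1.5, 7, by = 0.2), n_per_lam = 500,
                      base_seed = 1L, task = cst_task(), plant = cst_plant(),
                      noise = cst_noise(), weight = 1e4, U = 10,
                      delay_steps = 5, x_init_offset = 0, cache = NULL) {
  objective <- match.arg(objective)
  if (!length(lam_grid)) rlang::abort("`lam_grid` must be nonempty.",
                                      class = "cst_invalid_parameter")
  n <- round(task$sim_duration / task$dt)
  pieces <- vector("list", length(lam_grid))
  cost <- NULL
  for (i in seq_along(lam_grid)) {
    lam <- lam_grid[i]
    g <- tryCatch(
      cached_gains(cache, lam, objective, weight, U, n, plant, noise,
                   task$dt, delay_steps),
      error = function(e) rlang::abort(
        sprintf("gain solve failed at lambda = %.3g: %s", lam,
                conditionMessage(e)),
        class = "cst_no_convergence", parent = e))
    cost <- g$cost
    if (n_per_lam == 0) next
    seeds <- vapply(seq_len(n_per_lam),
                    function(j) derive_seed(base_seed,
                                            (i - 1L) * n_per_lam + j),
                    integer(1))
    task_i <- task
    task_i$lam <- lam
    out <- simulate_trials_core(g$sys, g, noise, task_i, seeds,
                                x_init_offset = x_init_offset)
    pieces[[i]] <- tibble::tibble(
      trial_id = sprintf("%s_lam%.2f_%05d", objective, lam, seq_len(n_per_lam)),
      lam = lam, objective = objective, seed = seeds,
      success = out$success, data = out$data)
  }
  df <- if (n_per_lam == 0) {
    tibble::tibble(trial_id = character(), lam = numeric(),
                   objective = character(), seed = integer(),
                   success = logical(), data = list())
  } else {
    dplyr::bind_rows(pieces)
  }
  new_trialset(df, task = task, plant = plant, noise = noise, cost = cost)
}

trialset_format_version <- "1"

#' Export / import a trial set as delimited text plus a JSON sidecar
#'
#' Writes `trials.csv` (one row per time step: `trial_id, t_s, x_cm,
#' xdot_cms, p_cm, pdot_cms, F_N, u`) and `trials.json` (per-trial lambda,
#' objective, seed, success, plus the generating configuration and a format
#' version). The round-trip is lossless up to float text representation.
#'
#' @param set A `cst_trialset`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `export_trials` returns `dir` invisibly; `import_trials` returns a
#'   `cst_trialset`.
#' @export
export_trials <- function(set, dir) {
  stopifnot(inherits(set, "cst_trialset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(set), "trial_id", "data"), "data")
  long <- dplyr::rename(long, t_s = "t", x_cm = "x", xdot_cms = "xdot",
                        p_cm = "p", pdot_cms = "pdot", F_N = "F_force")
  utils::write.csv(long, file.path(dir, "trials.csv"), row.names = FALSE)
  meta <- list(
    format_version = trialset_format_version,
    provenance = trial_provenance(set),
    trials = dplyr::select(tibble::as_tibble(set), "trial_id", "lam",
                           "objective", "seed", "success"))
  writeLines(as.character(jsonlite::toJSON(meta, digits = NA,
                                           auto_unbox = TRUE, na = "null")),
             file.path(dir, "trials.json"))
  invisible(dir)
}

#' @rdname export_trials
#' @export
import_trials <- function(dir) {
  csv <- file.path(dir, "trials.csv")
  js <- file.path(dir, "trials.json")
  for (f in c(csv, js)) {
    if (!file.exists(f)) rlang::abort(sprintf("missing file: %s", f),
                                      class = "cst_bad_input")
  }
  meta <- tryCatch(jsonlite::fromJSON(paste(readLines(js), collapse = "\n")),
                   error = function(e) rlang::abort(
                     sprintf("corrupt trial-set sidecar %s: %s", js,
                             conditionMessage(e)),
                     class = "cst_bad_input"))
  if (is.null(meta$format_version) ||
      !identical(as.character(meta$format_version), trialset_format_version)) {
    rlang::abort(sprintf("trial-set format version mismatch (found %s, need %s).",
                         meta$format_version %||% "<none>",
                         trialset_format_version),
                 class = "cst_version_mismatch")
  }
  long <- tryCatch(
    utils::read.csv(csv, stringsAsFactors = FALSE),
    error = function(e) rlang::abort(
      sprintf("parse error in %s: %s", csv, conditionMessage(e)),
      class = "cst_bad_input"))
  need <- c("trial_id", "t_s", "x_cm", "xdot_cms", "p_cm", "pdot_cms", "F_N", "u")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    rlang::abort(sprintf("trials.csv truncated or malformed: missing column(s) %s.",
                         paste(miss, collapse = ", ")),
                 class = "cst_bad_input")
  }
  tr <- tibble::as_tibble(meta$trials)
  split_idx <- split(seq_len(nrow(long)), long$trial_id)
  if (!setequal(names(split_idx), tr$trial_id)) {
    rlang::abort("trials.csv and trials.json disagree on trial ids (file truncated?).",
                 class = "cst_bad_input")
  }
  tr$data <- lapply(tr$trial_id, function(id) {
    d <- long[split_idx[[id]], , drop = FALSE]
    tibble::tibble(t = d$t_s, x = d$x_cm, xdot = d$xdot_cms, p = d$p_cm,
                   pdot = d$pdot_cms, F_force = d$F_N, u = d$u)
  })
  tr$seed <- as.integer(tr$seed)
  pv <- meta$provenance
  structure(tibble::as_tibble(tr),
            class = c("cst_trialset", class(tibble::tibble())),
            provenance = pv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
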