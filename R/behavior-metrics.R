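#' Peak hand-cursor cross-correlation and lag
#'
#' Computes the Pearson correlation between the (mean-subtracted) hand and
#' cursor position series at every lag within `max_lag_s`, and returns the
#' signed correlation at the lag maximizing `|r|`. Positive lag means the hand
#' lags the cursor, i.e. the hand at time `t` co-varies with the cursor at
#' `t - lag`. In the CST the hand counteracts cursor drift, so peak
#' correlations are negative and strengthen toward -1 as difficulty grows.
#'
#' @param hand,cursor Equal-length numeric series (cm).
#' @param dt Sampling step (s).
#' @param max_lag_s Half-width of the lag window (s).
#' @return A one-row tibble with `r_peak` and `lag_s`.
#' @export
xcorr_peak_lag <- function(hand, cursor, dt, max_lag_s = 1) {
  if (length(hand) != length(cursor)) {
    rlang::abort("hand and cursor series must have equal length.",
                 class = "cst_bad_input")
  }
  nn <- length(hand)
  if (stats::sd(hand) == 0 || stats::sd(cursor) == 0) {
    rlang::abort("correlation undefined for a constant (zero-variance) series.",
                 class = "cst_degenerate")
  }
  kmax <- min(nn - 3L, round(max_lag_s / dt))
  lags <- (-kmax):kmax
  # per-lag Pearson over the overlapping segments, with the cross terms for
  # all lags from one FFT and the segment means/variances from prefix sums
  m <- stats::nextn(2L * nn, 2)
  Xf <- stats::fft(c(hand, rep(0, m - nn)))
  Yf <- stats::fft(c(cursor, rep(0, m - nn)))
  cc <- Re(stats::fft(Xf * Conj(Yf), inverse = TRUE)) / m
  cross <- cc[ifelse(lags >= 0, lags + 1L, m + lags + 1L)]
  Sh <- cumsum(hand); Sh2 <- cumsum(hand^2)
  Sc <- cumsum(cursor); Sc2 <- cumsum(cursor^2)
  nk <- nn - abs(lags)
  pos <- lags >= 0
  k <- abs(lags)
  Sa <- ifelse(pos, Sh[nn] - c(0, Sh)[k + 1L], Sh[nk])
  Saa <- ifelse(pos, Sh2[nn] - c(0, Sh2)[k + 1L], Sh2[nk])
  Sb <- ifelse(pos, Sc[nk], Sc[nn] - c(0, Sc)[k + 1L])
  Sbb <- ifelse(pos, Sc2[nk], Sc2[nn] - c(0, Sc2)[k + 1L])
  va <- nk * Saa - Sa^2
  vb <- nk * Sbb - Sb^2
  tol <- 1e-12 * max(nk * Saa, nk * Sbb)
  rs <- ifelse(va > tol & vb > tol,
               (nk * cross - Sa * Sb) / sqrt(pmax(va, 0) * pmax(vb, 0)),
               NA_real_)
  # peak = extremum of |r|; ties (exactly periodic series) resolved toward the
  # smallest |lag|, positive lag preferred
  top <- max(abs(rs), na.rm = TRUE)
  cand <- which(!is.na(rs) & abs(rs) >= top - 1e-12)
  best <- cand[order(abs(lags[cand]), -sign(lags[cand]))][1]
  tibble::tibble(r_peak = rs[best], lag_s = lags[best] * dt)
}

#' Hand/cursor RMS ratio of a trial
#'
#' Ratio of the root-mean-square of raw (not mean-subtracted) hand position to
#' that of cursor position over the analyzed window, a measure of how large
#' the control response is relative to the cursor displacement it corrects.
#'
#' @param data Per-step series tibble with columns `t`, `x`, `p`.
#' @param trial_duration Analyzed duration (s).
#' @return The scalar ratio.
#' @export
rms_ratio <- function(data, trial_duration = 6) {
  an <- data$t <= trial_duration + 1e-12
  rms_x <- sqrt(mean(data$x[an]^2))
  if (!is.finite(rms_x) || rms_x == 0) {
    rlang::abort("cursor RMS is zero; ratio undefined.", class = "cst_degenerate")
  }
  sqrt(mean(data$p[an]^2)) / rms_x
}

#' Per-trial behavioural features
#'
#' Summarizes one trial's analyzed window into the feature set used
#' throughout: signed peak hand-cursor correlation and its lag, hand/cursor
#' RMS ratio, and the means and RMS of cursor position and velocity (the
#' state-space and RMS-space coordinates of the trial).
#'
#' @param data Per-step series tibble (`t, x, xdot, p, ...`).
#' @param dt Sampling step (s); inferred from `t` when `NULL`.
#' @param trial_duration Analyzed duration (s).
#' @param max_lag_s Lag window for the cross-correlation (s).
#' @return A one-row tibble: `r_peak, lag_s, rms_ratio, mean_x, mean_xdot,
#'   rms_x, rms_xdot`.
#' @export
trial_summary <- function(data, dt = NULL, trial_duration = 6, max_lag_s = 1) {
  if (is.null(dt)) dt <- stats::median(diff(data$t))
  an <- data$t <= trial_duration + 1e-12
  x <- data$x[an]
  xd <- data$xdot[an]
  p <- data$p[an]
  xc <- tryCatch(xcorr_peak_lag(p, x, dt, max_lag_s),
                 cst_degenerate = function(e) tibble::tibble(r_peak = NA_real_,
                                                             lag_s = NA_real_))
  rr <- tryCatch(rms_ratio(data, trial_duration),
                 cst_degenerate = function(e) NA_real_)
  tibble::tibble(
    r_peak = xc$r_peak, lag_s = xc$lag_s, rms_ratio = rr,
    mean_x = mean(x), mean_xdot = mean(xd),
    rms_x = sqrt(mean(x^2)), rms_xdot = sqrt(mean(xd^2)))
}

#' Feature table for a trial set
#'
#' Applies [trial_summary()] to every trial and binds the per-trial metadata,
#' giving the tidy table the classifier and the aggregate analyses consume.
#'
#' @param set A `cst_trialset`.
#' @param max_lag_s Lag window for the cross-correlation (s).
#' @return A tibble with one row per trial: metadata (`trial_id, lam,
#'   objective, seed, success`) plus the [trial_summary()] columns.
#' @export
trial_features <- function(set, max_lag_s = 1) {
  stopifnot(inherits(set, "cst_trialset"))
  pv <- trial_provenance(set)
  td <- pv$task$trial_duration %||% 6
  dt <- pv$task$dt %||% 0.01
  feats <- purrr::map(set$data, trial_summary, dt = dt,
                      trial_duration = td, max_lag_s = max_lag_s)
  dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(set), "trial_id", "lam", "objective",
                  "seed", "success"),
    dplyr::bind_rows(feats))
}

#' Success rate binned over difficulty
#'
#' Bins trials into half-open lambda bins of width `bin_width` starting at
#' `bin_start` (default bins \[1.5, 1.8), \[1.8, 2.1), ...) and reports the
#' percentage of successful trials per bin. Empty bins are omitted.
#'
#' @param set A `cst_trialset`, or any data frame with `lam` and `success`
#'   columns (e.g. a feature table).
#' @param bin_width,bin_start Bin geometry in lambda units.
#' @return A tibble with `bin_center`, `rate` (percent), `n`.
#' @export
bin_success_rate <- function(set, bin_width = 0.3, bin_start = 1.5) {
  if (!nrow(set)) rlang::abort("empty trial set.", class = "cst_bad_input")
  df <- tibble::tibble(lam = set$lam, success = set$success)
  df$bin <- floor((df$lam - bin_start) / bin_width + 1e-9)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    rate = 100 * mean(.data$success),
    n = dplyr::n(), .groups = "drop")
  out$bin_center <- bin_start + (out$bin + 0.5) * bin_width
  dplyr::arrange(dplyr::select(out, "bin_center", "rate", "n"), .data$bin_center)
}

#' Fit a psychometric curve to binned success rates
#'
#' Fits `rate = 100 * (1 - Phi((lambda - lambda_c) / sigma))` — a descending
#' Gaussian cumulative — by weighted least squares (weights = trials per bin),
#' estimating the critical instability `lambda_c` (where predicted success is
#' exactly 50%) and the spread `sigma`.
#'
#' @param table A success table from [bin_success_rate()] (`bin_center`,
#'   `rate`, `n`).
#' @return An object of class `cst_psychfit` with `lam_c`, `sigma`, `rss`,
#'   `n_bins`, and the underlying `nls` fit. Supports [tidy()], [glance()],
#'   `predict()` and [autoplot()].
#' @export
fit_psychometric <- function(table) {
  tb <- table[table$n > 0, , drop = FALSE]
  if (nrow(tb) < 3) {
    rlang::abort("need at least 3 nonempty bins.", class = "cst_degenerate")
  }
  if (all(tb$rate >= 50) || all(tb$rate <= 50)) {
    rlang::abort("success rates do not span 50%; lambda_c is not identifiable.",
                 class = "cst_degenerate")
  }
  # crossing-point start value by linear interpolation around 50%
  lo <- which(tb$rate <= 50)[1]
  start_lc <- if (is.na(lo) || lo == 1) stats::median(tb$bin_center) else {
    x1 <- tb$bin_center[lo - 1]; x2 <- tb$bin_center[lo]
    y1 <- tb$rate[lo - 1]; y2 <- tb$rate[lo]
    if (y1 == y2) (x1 + x2) / 2 else x1 + (50 - y1) * (x2 - x1) / (y2 - y1)
  }
  fit <- minpack.lm::nlsLM(
    rate ~ 100 * (1 - stats::pnorm((bin_center - lam_c) / sigma)),
    data = tb, weights = tb$n,
    start = list(lam_c = start_lc, sigma = 0.5),
    lower = c(1e-6, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(lam_c = unname(est["lam_c"]), sigma = unname(est["sigma"]),
                 rss = sum(stats::residuals(fit)^2), n_bins = nrow(tb),
                 fit = fit, table = tb),
            class = "cst_psychfit")
}

#' @export
predict.cst_psychfit <- function(object, lam, ...) {
  100 * (1 - stats::pnorm((lam - object$lam_c) / object$sigma))
}

#' @export
print.cst_psychfit <- function(x, ...) {
  cat(sprintf("Psychometric fit: lambda_c = %.3f, sigma = %.3f (%d bins, rss = %.3g)\n",
              x$lam_c, x$sigma, x$n_bins, x$rss))
  invisible(x)
}

#' @method tidy cst_psychfit
#' @export
tidy.cst_psychfit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(stats::vcov(x$fit))), error = function(e) c(NA, NA))
  tibble::tibble(term = c("lam_c", "sigma"),
                 estimate = c(x$lam_c, x$sigma),
                 std.error = unname(se))
}

#' @method glance cst_psychfit
#' @export
glance.cst_psychfit <- function(x, ...) {
  tibble::tibble(lam_c = x$lam_c, sigma = x$sigma, rss = x$rss,
                 n_bins = x$n_bins)
}

qualifying_features <- function(features, success_only, lam_max) {
  if (is.null(lam_max)) {
    fit <- fit_psychometric(bin_success_rate(features))
    lam_max <- fit$lam_c
  }
  keep <- features$lam <= lam_max + 1e-9
  if (success_only) keep <- keep & features$success
  features[keep, , drop = FALSE]
}

#' Correlation between mean cursor position and mean cursor velocity
#'
#' Across qualifying trials (by default: successful trials with difficulty up
#' to the critical lambda), correlates each trial's mean cursor position with
#' its mean cursor velocity. Velocity Control lets the cursor drift, producing
#' an elongated, strongly correlated cloud; Position Control keeps trials
#' scattered near the origin with little correlation.
#'
#' @param features A feature table from [trial_features()].
#' @param success_only Restrict to successful trials.
#' @param lam_max Difficulty cutoff; when `NULL`, the critical lambda fitted
#'   from `features` is used.
#' @return A one-row tibble with `r` (Pearson) and `n`.
#' @export
meanstate_correlation <- function(features, success_only = TRUE,
                                  lam_max = NULL) {
  f <- qualifying_features(features, success_only, lam_max)
  if (nrow(f) < 3) rlang::abort("need at least 3 qualifying trials.",
                                class = "cst_degenerate")
  tibble::tibble(r = stats::cor(f$mean_x, f$mean_xdot), n = nrow(f))
}

#' RMS-space regression slope
#'
#' Ordinary least-squares slope of RMS cursor velocity on RMS cursor position
#' across qualifying trials. Position Control restricts cursor position while
#' tolerating velocity, so its cloud leans toward the velocity axis (large
#' slope); Velocity Control gives small slopes.
#'
#' @inheritParams meanstate_correlation
#' @param through_origin Fit without an intercept.
#' @return A one-row tibble with `slope`, `intercept`, `n`.
#' @export
rms_slope <- function(features, success_only = TRUE, lam_max = NULL,
                      through_origin = FALSE) {
  f <- qualifying_features(features, success_only, lam_max)
  if (nrow(f) < 3) rlang::abort("need at least 3 qualifying trials.",
                                class = "cst_degenerate")
  if (stats::sd(f$rms_x) == 0) {
    rlang::abort("zero variance in rms_x; slope undefined.",
                 class = "cst_degenerate")
  }
  fml <- if (through_origin) rms_xdot ~ rms_x + 0 else rms_xdot ~ rms_x
  co <- stats::coef(stats::lm(fml, data = f))
  tibble::tibble(slope = unname(co[["rms_x"]]),
                 intercept = if (through_origin) 0 else unname(co[[1]]),
                 n = nrow(f))
}

#' Aggregate metric curves over difficulty bins
#'
#' Per lambda bin: success rate, mean signed peak correlation, mean absolute
#' peak correlation, mean lag, and mean RMS ratio, averaged across trials.
#'
#' @param features A feature table from [trial_features()] (needs `lam`,
#'   `success` and the metric columns).
#' @inheritParams bin_success_rate
#' @return A tibble with one row per nonempty bin.
#' @export
metric_curves <- function(features, bin_width = 0.3, bin_start = 1.5) {
  df <- features
  df$bin <- floor((df$lam - bin_start) / bin_width + 1e-9)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    success_pct = 100 * mean(.data$success),
    r_peak = mean(.data$r_peak, na.rm = TRUE),
    abs_r_peak = mean(abs(.data$r_peak), na.rm = TRUE),
    lag_s = mean(.data$lag_s, na.rm = TRUE),
    rms_ratio = mean(.data$rms_ratio, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
  out$bin_center <- bin_start + (out$bin + 0.5) * bin_width
  dplyr::arrange(
    dplyr::select(out, "bin_center", "success_pct", "r_peak", "abs_r_peak",
                  "lag_s", "rms_ratio", "n"),
    .data$bin_center)
}
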