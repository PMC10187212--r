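#' Train the RMS-space strategy classifier
#'
#' Fits a linear-kernel support-vector machine on standardized
#' `(rms_x, rms_xdot)` features labelled by generating objective, then
#' calibrates a Platt-style sigmoid (logistic fit on the training decision
#' values) mapping the SVM decision value to a posterior probability of
#' Position Control. The discriminant is effectively a slope threshold in RMS
#' space: trials above it look like Position Control (position restricted,
#' velocity free), trials below like Velocity Control.
#'
#' @param features A feature table with columns `rms_x`, `rms_xdot`, and
#'   `objective` containing both `"position"` and `"velocity"` labels.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @param cost SVM box constraint.
#' @return An object of class `cst_classifier`. Supports [tidy()], [glance()]
#'   and [classify_trials()].
#' @importFrom e1071 svm
#' @export
train_classifier <- function(features, seed = 1L, cost = 1) {
  need <- c("rms_x", "rms_xdot", "objective")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    rlang::abort(sprintf("features missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "cst_bad_input")
  }
  y <- factor(features$objective, levels = c("velocity", "position"))
  if (any(is.na(y)) || length(unique(y)) < 2 || any(table(y) == 0)) {
    rlang::abort("training data must contain both objectives.",
                 class = "cst_bad_input")
  }
  X <- cbind(rms_x = features$rms_x, rms_xdot = features$rms_xdot)
  if (any(!is.finite(X))) {
    rlang::abort("non-finite training features.", class = "cst_bad_input")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  set.seed(seed)
  svm_fit <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = cost,
                        scale = FALSE, probability = FALSE)
  dv <- attr(stats::predict(svm_fit, Xs, decision.values = TRUE),
             "decision.values")[, 1]
  # orient the decision value so larger means more position-like
  if (stats::cor(dv, as.numeric(y == "position")) < 0) dv_sign <- -1 else dv_sign <- 1
  dv <- dv_sign * dv
  # Platt's sigmoid with regularized targets: keeps the slope finite (and the
  # fit warning-free) when the classes are completely separable
  np <- sum(y == "position")
  nv <- sum(y == "velocity")
  tgt <- ifelse(y == "position", (np + 1) / (np + 2), 1 / (nv + 2))
  calib <- stats::glm(tgt ~ dv, family = stats::quasibinomial())
  structure(list(
    svm = svm_fit, dv_sign = dv_sign,
    scaler = list(center = center, scale = scale_),
    calibration = stats::coef(calib),
    provenance = list(seed = seed, cost = cost,
                      n_per_class = as.list(table(y)),
                      lam_range = if ("lam" %in% names(features))
                        range(features$lam) else NULL)),
    class = "cst_classifier")
}

decision_values <- function(model, features) {
  X <- cbind(rms_x = features$rms_x, rms_xdot = features$rms_xdot)
  if (any(!is.finite(X))) {
    rlang::abort("non-finite features; cannot classify.", class = "cst_bad_input")
  }
  Xs <- scale(X, center = model$scaler$center, scale = model$scaler$scale)
  if (!is.null(model$linear)) {
    return(drop(Xs %*% model$linear$w) + model$linear$b)
  }
  dv <- attr(stats::predict(model$svm, Xs, decision.values = TRUE),
             "decision.values")[, 1]
  model$dv_sign * dv
}

posterior_from_dv <- function(model, dv) {
  stats::plogis(model$calibration[1] + model$calibration[2] * dv)
}

#' Classify trials by control objective
#'
#' Applies the calibrated classifier to each trial's RMS-space features and
#' labels it `position` when the posterior P(position) is at least 0.95,
#' `velocity` when it is below 0.05, and `uncertain` otherwise.
#'
#' @param model A `cst_classifier` from [train_classifier()].
#' @param features A feature table with `rms_x` and `rms_xdot` (other columns
#'   are carried through).
#' @return The input tibble with added columns `p_pos` and `label`.
#' @export
classify_trials <- function(model, features) {
  stopifnot(inherits(model, "cst_classifier"))
  dv <- decision_values(model, features)
  p <- unname(posterior_from_dv(model, dv))
  out <- tibble::as_tibble(features)
  out$p_pos <- p
  out$label <- dplyr::case_when(
    p >= 0.95 ~ "position",
    p < 0.05 ~ "velocity",
    TRUE ~ "uncertain")
  out
}

#' Average Position-Control probability of a set of trials
#'
#' One summary number per subject (or batch): the arithmetic mean of the
#' per-trial posterior P(position) across all classified trials, uncertain
#' ones included.
#'
#' @param labels Output of [classify_trials()] (needs a `p_pos` column).
#' @return A one-row tibble with `p_position` and `n`.
#' @export
subject_probability <- function(labels) {
  if (!nrow(labels)) rlang::abort("no classified trials.", class = "cst_bad_input")
  tibble::tibble(p_position = mean(labels$p_pos), n = nrow(labels))
}

#' Misclassification rates on a labelled test set
#'
#' Fraction of position-generated trials labelled velocity, and of
#' velocity-generated trials labelled position. Uncertain trials count in the
#' denominators but are not errors.
#'
#' @param model A `cst_classifier`.
#' @param test A labelled feature table (must contain both objectives and be
#'   disjoint from the training set by seed bookkeeping).
#' @return A one-row tibble: `pos_as_vel_pct`, `vel_as_pos_pct`,
#'   `pos_uncertain_pct`, `vel_uncertain_pct`, `n_position`, `n_velocity`.
#' @export
confusion_rates <- function(model, test) {
  if (!all(c("position", "velocity") %in% test$objective)) {
    rlang::abort("test set must contain both objectives.", class = "cst_bad_input")
  }
  lab <- classify_trials(model, test)
  pos <- lab[lab$objective == "position", ]
  vel <- lab[lab$objective == "velocity", ]
  tibble::tibble(
    pos_as_vel_pct = 100 * mean(pos$label == "velocity"),
    vel_as_pos_pct = 100 * mean(vel$label == "position"),
    pos_uncertain_pct = 100 * mean(pos$label == "uncertain"),
    vel_uncertain_pct = 100 * mean(vel$label == "uncertain"),
    n_position = nrow(pos), n_velocity = nrow(vel))
}

#' @export
print.cst_classifier <- function(x, ...) {
  td <- tidy.cst_classifier(x)
  cat("RMS-space strategy classifier (linear SVM + sigmoid calibration)\n")
  cat(sprintf("  boundary (standardized): %.3f * rms_x + %.3f * rms_xdot + %.3f = 0\n",
              td$estimate[td$term == "rms_x"],
              td$estimate[td$term == "rms_xdot"],
              td$estimate[td$term == "(intercept)"]))
  invisible(x)
}

#' @method tidy cst_classifier
#' @export
tidy.cst_classifier <- function(x, ...) {
  if (!is.null(x$linear)) {
    w <- x$linear$w
    b <- x$linear$b
  } else {
    w <- drop(crossprod(x$svm$coefs, x$svm$SV)) * x$dv_sign
    b <- -x$svm$rho * x$dv_sign
  }
  tibble::tibble(term = c("rms_x", "rms_xdot", "(intercept)",
                          "calib_intercept", "calib_slope"),
                 estimate = c(unname(w), b, unname(x$calibration)))
}

#' @method glance cst_classifier
#' @export
glance.cst_classifier <- function(x, ...) {
  tibble::tibble(n_position = x$provenance$n_per_class$position,
                 n_velocity = x$provenance$n_per_class$velocity,
                 n_support = x$svm$tot.nSV,
                 seed = x$provenance$seed)
}

#' Export / import a trained classifier as JSON
#'
#' Serializes the support vectors, coefficients, scaler and calibration with
#' training provenance.
#'
#' @param model A `cst_classifier`.
#' @param path File to write / read.
#' @return `write_classifier_json` returns `path` invisibly;
#'   `read_classifier_json` returns a function-equivalent `cst_classifier`
#'   (same decision values and posteriors).
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "cst_classifier"))
  w <- drop(crossprod(model$svm$coefs, model$svm$SV)) * model$dv_sign
  b <- -model$svm$rho * model$dv_sign
  doc <- list(type = "cst_classifier", w = unname(w), b = unname(b),
              center = as.list(model$scaler$center),
              scale = as.list(model$scaler$scale),
              calibration = unname(model$calibration),
              provenance = model$provenance)
  writeLines(as.character(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)),
             path)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  if (is.null(doc$type) || doc$type != "cst_classifier") {
    rlang::abort("not a cst_classifier JSON document.", class = "cst_bad_input")
  }
  structure(list(
    linear = list(w = doc$w, b = doc$b),
    svm = NULL, dv_sign = 1,
    scaler = list(center = unlist(doc$center), scale = unlist(doc$scale)),
    calibration = doc$calibration,
    provenance = doc$provenance),
    class = c("cst_classifier_linear", "cst_classifier"))
}
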