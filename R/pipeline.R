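cst_default_config <- function() {
  list(
    task = list(c = 10, trial_duration = 6, sim_duration = 8, dt = 0.01),
    plant = list(M = 1, tau = 0.06),
    noise = list(C = 1.5, motor_scale = 0.4, sensory_sd = 0.05),
    cost = list(q = 1e4, v = 1e4, U = 10),
    grid = list(lam_min = 1.5, lam_max = 7, lam_step = 0.2),
    delay_steps = 5,
    n_train_per_lam = 300,
    n_test_per_lam = 300,
    n_train_per_class = 2250,
    n_test_per_class = 2500,
    seed = 1
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    rlang::abort(sprintf("unknown configuration key(s): %s",
                         paste0(path, bad, collapse = ", ")),
                 class = "cst_bad_config")
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Builds the configuration for a full simulate-analyze-classify run. Defaults
#' are the stated study conditions: lambda grid 1.5 to 7 in steps of 0.2,
#' `dt = 0.01` s, `M = 1` kg, `tau = 0.06` s, `C = 1.5`,
#' `motor_scale = 0.4`, 50 ms (5-step) sensory delay, `U = 10`,
#' workspace half-width 10 cm, 6 s analyzed / 8 s simulated. Unknown keys are
#' rejected by name.
#'
#' @param x `NULL` (all defaults), a named list of overrides, or the path of a
#'   JSON file of overrides.
#' @return A validated configuration list of class `cst_config`.
#' @examples
#' cst_config(list(noise = list(C = 0)))
#' @export
cst_config <- function(x = NULL) {
  user <- if (is.null(x)) {
    list()
  } else if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) rlang::abort(sprintf("config file not found: %s", x),
                                      class = "cst_bad_config")
    jsonlite::fromJSON(paste(readLines(x), collapse = "\n"),
                       simplifyVector = TRUE)
  } else if (is.list(x)) {
    x
  } else {
    rlang::abort("`x` must be NULL, a list, or a file path.",
                 class = "cst_bad_config")
  }
  cfg <- merge_config(cst_default_config(), user)
  with(cfg, {
    if (task$dt <= 0 || plant$M <= 0 || plant$tau <= 0 || cost$U <= 0 ||
        grid$lam_min <= 0 || grid$lam_step <= 0 ||
        grid$lam_max < grid$lam_min) {
      rlang::abort("invalid configuration values.", class = "cst_bad_config")
    }
  })
  structure(cfg, class = "cst_config")
}

config_grid <- function(cfg) {
  seq(cfg$grid$lam_min, cfg$grid$lam_max, by = cfg$grid$lam_step)
}

config_task <- function(cfg) {
  cst_task(lam = cfg$grid$lam_min, c = cfg$task$c,
           trial_duration = cfg$task$trial_duration,
           sim_duration = cfg$task$sim_duration, dt = cfg$task$dt)
}

# Simulate a pool for one objective, summarize features, fit the psychometric
# curve, and subsample `n_keep` trials. selection = "qualifying" keeps
# successful trials with lambda <= lam_c (the training inclusion rule);
# "all" keeps every trial across the grid (the held-out test protocol).
simulate_feature_pool <- function(objective, cfg, base_seed, n_per_lam, n_keep,
                                  cache, selection = "qualifying") {
  weight <- if (objective == "position") cfg$cost$q else cfg$cost$v
  set <- run_batch(objective, lam_grid = config_grid(cfg),
                   n_per_lam = n_per_lam, base_seed = base_seed,
                   task = config_task(cfg),
                   plant = cst_plant(cfg$plant$M, cfg$plant$tau),
                   noise = cst_noise(cfg$noise$C, cfg$noise$motor_scale,
                                     cfg$noise$sensory_sd),
                   weight = weight, U = cfg$cost$U,
                   delay_steps = cfg$delay_steps, cache = cache)
  feats <- trial_features(set)
  fit <- fit_psychometric(bin_success_rate(feats))
  qual <- if (selection == "all") feats else
    feats[feats$success & feats$lam <= fit$lam_c + 1e-9, , drop = FALSE]
  if (nrow(qual) < n_keep) {
    rlang::abort(sprintf(
      "%s pool yielded %d eligible trials (< %d); increase n_per_lam.",
      objective, nrow(qual), n_keep), class = "cst_bad_config")
  }
  set.seed(seed_for(base_seed, paste0("subsample-", objective)))
  keep <- sort(sample.int(nrow(qual), n_keep))
  list(features = feats, fit = fit, selected = qual[keep, , drop = FALSE],
       curves = metric_curves(feats))
}

#' Run the full simulate-analyze-classify pipeline
#'
#' Chains the generative model end to end: simulates training pools under both
#' control objectives over the difficulty grid, fits per-objective
#' psychometric curves, selects successful trials up to each objective's
#' critical lambda, trains the RMS-space classifier (2250 trials per class by
#' default), simulates disjoint-seed test pools, and reports the two
#' misclassification rates together with the aggregate metric tables,
#' mean-state correlations and RMS-space slopes. Held-out test trials are
#' drawn from the full difficulty grid without a success filter — a trial
#' whose cursor escaped is still a trial the classifier must label — while
#' the training set follows the successful-up-to-critical-lambda inclusion
#' rule used for the RMS-space clouds.
#'
#' @param config A [cst_config()] (or anything accepted by it).
#' @param progress Print stage messages.
#' @return A list of class `cst_report`: `confusion` (one-row tibble),
#'   `psychometric` (per-objective lambda_c and sigma), `curves`
#'   (per-objective metric tables), `meanstate` and `rms_space` summaries,
#'   `subject_probability` per objective, and the resolved `config`. The
#'   report is JSON-serializable via [report_to_json()].
#' @export
cst_reproduce <- function(config = cst_config(), progress = FALSE) {
  if (!inherits(config, "cst_config")) config <- cst_config(config)
  cfg <- config
  say <- function(...) if (progress) message(sprintf(...))
  cache <- new.env(parent = emptyenv())
  base <- cfg$seed

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) rlang::abort(
      sprintf("pipeline stage '%s' failed: %s", label, conditionMessage(e)),
      parent = e, class = "cst_pipeline_error"))
  }

  say("simulating training pools")
  train <- stage("simulate-train", lapply(
    c(position = "position", velocity = "velocity"), function(obj)
      simulate_feature_pool(obj, cfg, seed_for(base, paste0("train-", obj)),
                            cfg$n_train_per_lam, cfg$n_train_per_class, cache)))

  say("training classifier")
  model <- stage("train-classifier", train_classifier(
    dplyr::bind_rows(train$position$selected, train$velocity$selected),
    seed = seed_for(base, "svm")))

  say("simulating test pools")
  test <- stage("simulate-test", lapply(
    c(position = "position", velocity = "velocity"), function(obj)
      simulate_feature_pool(obj, cfg, seed_for(base, paste0("test-", obj)),
                            cfg$n_test_per_lam, cfg$n_test_per_class, cache,
                            selection = "all")))

  say("classifying held-out trials")
  test_feats <- dplyr::bind_rows(test$position$selected, test$velocity$selected)
  conf <- stage("confusion", confusion_rates(model, test_feats))

  labelled <- classify_trials(model, test_feats)
  subj <- dplyr::bind_rows(lapply(c("position", "velocity"), function(obj) {
    dplyr::mutate(subject_probability(labelled[labelled$objective == obj, ]),
                  objective = obj, .before = 1)
  }))

  psych <- dplyr::bind_rows(lapply(c("position", "velocity"), function(obj) {
    tibble::tibble(objective = obj, lam_c = train[[obj]]$fit$lam_c,
                   sigma = train[[obj]]$fit$sigma)
  }))
  meanstate <- dplyr::bind_rows(lapply(c("position", "velocity"), function(obj) {
    dplyr::mutate(meanstate_correlation(train[[obj]]$features,
                                        lam_max = train[[obj]]$fit$lam_c),
                  objective = obj, .before = 1)
  }))
  slopes <- dplyr::bind_rows(lapply(c("position", "velocity"), function(obj) {
    dplyr::mutate(rms_slope(train[[obj]]$features,
                            lam_max = train[[obj]]$fit$lam_c),
                  objective = obj, .before = 1)
  }))
  curves <- dplyr::bind_rows(
    dplyr::mutate(train$position$curves, objective = "position", .before = 1),
    dplyr::mutate(train$velocity$curves, objective = "velocity", .before = 1))

  structure(list(
    confusion = conf,
    psychometric = psych,
    curves = curves,
    meanstate = meanstate,
    rms_space = slopes,
    subject_probability = subj,
    expectation = list(
      pos_as_vel = "small (single-digit percent) misclassification of Position trials as Velocity",
      vel_as_pos = "small (single-digit percent) misclassification of Velocity trials as Position",
      lag = "Position Control lag >= Velocity Control lag across most bins",
      rms_ratio = "Position Control RMS ratio >= Velocity Control across most bins",
      meanstate = "mean-state correlation larger under Velocity Control",
      rms_slope = "RMS-space slope larger under Position Control"),
    model = model,
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("cstcontrol"))),
    class = "cst_report")
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `cst_report` from [cst_reproduce()].
#' @param path Optional file to write.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  doc <- report[c("confusion", "psychometric", "curves", "meanstate",
                  "rms_space", "subject_probability", "expectation", "config",
                  "package_version")]
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.cst_report <- function(x, ...) {
  cat("CST pipeline report\n")
  cat(sprintf("  position -> velocity misclassification: %.2f%%\n",
              x$confusion$pos_as_vel_pct))
  cat(sprintf("  velocity -> position misclassification: %.2f%%\n",
              x$confusion$vel_as_pos_pct))
  cat(sprintf("  lambda_c: position %.2f, velocity %.2f\n",
              x$psychometric$lam_c[1], x$psychometric$lam_c[2]))
  invisible(x)
}
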