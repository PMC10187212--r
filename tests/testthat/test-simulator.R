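test_that("with all noise terms zero a trial starting at the origin stays there", {
  noise0 <- cst_noise(C = 0, motor_scale = 0, sensory_sd = 0)
  sysd <- discretize(build_continuous_system(2, cst_plant()), 0.01, 5)
  g <- solve_gains(sysd, make_objective("position", 1e4, n = 800), noise0)
  tr <- simulate_trial(sysd, g, noise = noise0, task = cst_task(lam = 2), seed = 5)
  d <- tr$data[[1]]
  expect_equal(max(abs(d$x)), 0)
  expect_equal(max(abs(d$p)), 0)
  expect_equal(max(abs(d$u), na.rm = TRUE), 0)
  expect_true(tr$success)
})

test_that("per-trial seeding is reproducible and independent of batch context", {
  g <- default_gains(3, "position")
  task <- cst_task(lam = 3)
  t1 <- simulate_trial(g$sys, g, task = task, seed = 123)
  t2 <- simulate_trial(g$sys, g, task = task, seed = 123)
  t3 <- simulate_trial(g$sys, g, task = task, seed = 124)
  expect_identical(t1$data[[1]], t2$data[[1]])
  expect_false(identical(t1$data[[1]]$x, t3$data[[1]]$x))

  # a batch trial matches the same trial simulated alone with its derived
  # seed (same noise streams; equal up to BLAS-kernel rounding in the
  # estimator update, which differs with batch width)
  set <- run_batch("position", lam_grid = 3, n_per_lam = 4, base_seed = 50,
                   cache = .cst_cache)
  alone <- simulate_trial(g$sys, g, task = cst_task(lam = 3),
                          seed = set$seed[3])
  expect_identical(set$seed[3], alone$seed)
  expect_lt(max(abs(set$data[[3]]$x - alone$data[[1]]$x)), 1e-9)
  expect_lt(max(abs(set$data[[3]]$u - alone$data[[1]]$u), na.rm = TRUE), 1e-9)

  # same base seed -> identical success vector
  s2 <- run_batch("position", lam_grid = 3, n_per_lam = 4, base_seed = 50,
                  cache = .cst_cache)
  expect_identical(set$success, s2$success)
})

test_that("a controller solved for an easy plant fails on a hard one", {
  g_easy <- default_gains(1.5, "position")
  sys_hard <- discretize(build_continuous_system(7, cst_plant()), 0.01, 5)
  task <- cst_task(lam = 7)
  fails <- 0
  for (s in 1:100) {
    tr <- simulate_trial(sys_hard, g_easy, task = task, seed = s)
    if (!tr$success) fails <- fails + 1
  }
  expect_gte(fails, 95)
})

test_that("success is judged on the first 6 s only, against the workspace bound", {
  task <- cst_task(lam = 3, c = 10, trial_duration = 6, sim_duration = 8)
  tt <- seq(0, 8, by = 0.01)
  mk <- function(x) tibble::tibble(t = tt, x = x)
  expect_true(evaluate_success(mk(9.9 * sin(tt)), task))
  x_fail <- rep(0, length(tt)); x_fail[tt >= 4] <- 10.2
  expect_false(evaluate_success(mk(x_fail), task))
  x_late <- rep(0, length(tt)); x_late[tt > 6.4] <- 12
  expect_true(evaluate_success(mk(x_late), task))
  expect_error(evaluate_success(tibble::tibble(t = numeric(), x = numeric()),
                                task), class = "cst_bad_input")
})

test_that("batches have the expected shape, including the empty case", {
  set <- default_batch("velocity", c(2, 4), 5, 77)
  expect_s3_class(set, "cst_trialset")
  expect_equal(nrow(set), 10)
  expect_equal(sort(unique(set$lam)), c(2, 4))
  expect_true(all(lengths(lapply(set$data, nrow)) > 0))
  pv <- trial_provenance(set)
  expect_equal(pv$noise$C, 1.5)
  expect_equal(pv$task$sim_duration, 8)

  empty <- run_batch("position", lam_grid = 2, n_per_lam = 0, base_seed = 1,
                     cache = .cst_cache)
  expect_equal(nrow(empty), 0)
  expect_false(is.null(trial_provenance(empty)))
})

test_that("every simulated trial satisfies the cursor-dynamics residual", {
  for (lam in c(2, 5)) {
    set <- default_batch("position", lam, 30, 31)
    for (i in seq_len(nrow(set))) {
      d <- set$data[[i]]
      an <- d$t <= 6
      res <- diff(d$x[an]) / 0.01 - lam * (d$x[an] + d$p[an])[-sum(an)]
      expect_lt(max(abs(res)), 1e-9)
    }
  }
})

test_that("trial sets round-trip through the delimited export", {
  set <- default_batch("velocity", c(2, 4), 5, 77)
  dir <- withr::local_tempdir()
  export_trials(set, dir)
  back <- import_trials(dir)
  expect_equal(back$trial_id, set$trial_id)
  expect_equal(back$lam, set$lam)
  expect_equal(back$seed, set$seed)
  expect_identical(back$success, set$success)
  for (i in seq_len(nrow(set))) {
    expect_equal(back$data[[i]]$x, set$data[[i]]$x, tolerance = 1e-12)
    expect_equal(back$data[[i]]$u, set$data[[i]]$u, tolerance = 1e-12)
  }
  pv <- trial_provenance(back)
  expect_equal(pv$noise$motor_scale, 0.4)

  # version mismatch is refused explicitly
  js <- file.path(dir, "trials.json")
  meta <- jsonlite::fromJSON(paste(readLines(js), collapse = ""))
  meta$format_version <- "999"
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)), js)
  expect_error(import_trials(dir), "version", class = "cst_version_mismatch")

  # truncated table is detected
  dir2 <- withr::local_tempdir()
  export_trials(set, dir2)
  csv <- readLines(file.path(dir2, "trials.csv"))
  writeLines(csv[1:100], file.path(dir2, "trials.csv"))
  expect_error(import_trials(dir2), class = "cst_bad_input")
  expect_error(import_trials(withr::local_tempdir()), class = "cst_bad_input")
})

test_that("exported hand series reconstruct the exported cursor", {
  set <- default_batch("position", 3, 3, 13)
  dir <- withr::local_tempdir()
  export_trials(set, dir)
  long <- utils::read.csv(file.path(dir, "trials.csv"))
  one <- long[long$trial_id == set$trial_id[2], ]
  rec <- cursor_from_hand(one$p_cm, lam = 3, dt = 0.01, x0 = one$x_cm[1])
  expect_lt(max(abs(rec$x - one$x_cm)), 1e-6)
})

test_that("an initial cursor offset is applied consistently with the dynamics", {
  g <- default_gains(2, "position")
  tr <- simulate_trial(g$sys, g, noise = cst_noise(C = 0, motor_scale = 0,
                                                   sensory_sd = 0),
                       task = cst_task(lam = 2), seed = 1, x_init_offset = 3)
  d <- tr$data[[1]]
  expect_equal(d$x[1], 3)
  expect_equal(d$xdot[1], 2 * 3)   # xdot(0) = lam * (x0 + p0), p0 = 0
  # controller drives the offset back toward the center
  expect_lt(abs(d$x[nrow(d)]), 3)
})
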