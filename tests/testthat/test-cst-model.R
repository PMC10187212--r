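test_that("continuous system matches the stated dynamics for random parameters", {
  set.seed(42)
  for (i in 1:100) {
    lam <- runif(1, 0.5, 8)
    M <- runif(1, 0.5, 3)
    tau <- runif(1, 0.02, 0.2)
    sys <- build_continuous_system(lam, cst_plant(M = M, tau = tau))
    expect_equal(sys$A[1, ], c(0, 1, 0, 0, 0), ignore_attr = TRUE)
    expect_equal(sys$A[2, ], c(lam^2, 0, lam^2, lam, 0), ignore_attr = TRUE)
    expect_equal(sys$A[3, ], c(0, 0, 0, 1, 0), ignore_attr = TRUE)
    expect_equal(sys$A[4, ], c(0, 0, 0, 0, 1 / M), ignore_attr = TRUE)
    expect_equal(sys$A[5, ], c(0, 0, 0, 0, -1 / tau), ignore_attr = TRUE)
    expect_equal(as.numeric(sys$B), c(0, 0, 0, 0, 1 / tau))
    # cursor acceleration from the state equations equals its closed form
    s <- rnorm(5)
    xddot <- (sys$A %*% s)[2]
    expect_equal(xddot, lam^2 * s[1] + lam^2 * s[3] + lam * s[4])
  }
  expect_error(build_continuous_system(0), class = "cst_invalid_parameter")
  expect_error(build_continuous_system(-1), class = "cst_invalid_parameter")
  expect_error(cst_plant(M = 0), class = "cst_invalid_parameter")
  expect_error(cst_plant(tau = -0.1), class = "cst_invalid_parameter")
})

test_that("forward-Euler discretization is exact and augmentation shifts copies", {
  sys <- build_continuous_system(2, cst_plant())
  d <- discretize(sys, dt = 0.01, delay_steps = 0)
  expect_identical(d$Ad, diag(5) + 0.01 * sys$A)
  expect_identical(d$Bd, 0.01 * sys$B)
  expect_equal(d$Ad[2, 1], 0.04)
  expect_equal(unname(d$H), diag(5))

  # dt -> 0 limit
  d0 <- discretize(sys, dt = 1e-300, delay_steps = 0)
  expect_equal(d0$Ad, diag(5), ignore_attr = TRUE, tolerance = 1e-290)
  expect_equal(max(abs(d0$Bd)), 0, tolerance = 1e-290)

  # Euler error against the matrix exponential is O(dt^2)
  for (dt in c(1e-3, 1e-4)) {
    dd <- discretize(sys, dt = dt, delay_steps = 0)
    ex <- as.matrix(Matrix::expm(dt * sys$A))
    err <- max(abs(dd$Ad - ex))
    expect_lt(err, 10 * dt^2 * max(abs(sys$A %*% sys$A)))
  }

  # augmented transition: newest copy propagates, older copies shift
  da <- discretize(sys, dt = 0.01, delay_steps = 5)
  expect_equal(da$n_states, 30)
  x <- as.numeric(matrix(rnorm(30), 30))
  xn <- da$Ad %*% x
  expect_equal(as.numeric(xn[1:5]), as.numeric(d$Ad %*% x[1:5]))
  for (k in 1:5) {
    expect_equal(as.numeric(xn[k * 5 + 1:5]), x[(k - 1) * 5 + 1:5])
  }
  # observation reads the oldest copy
  expect_equal(as.numeric(da$H %*% x), x[26:30])
  expect_equal(as.numeric(da$Bd[1:5]), as.numeric(d$Bd))
  expect_equal(max(abs(da$Bd[6:30])), 0)
  expect_error(discretize(sys, dt = 0), class = "cst_invalid_parameter")
  expect_error(discretize(sys, delay_steps = -1), class = "cst_invalid_parameter")
})

test_that("cursor reconstruction: fixed point, closed form, and error handling", {
  # hand at rest keeps the cursor at the fixed point
  out <- cursor_from_hand(rep(0, 100), lam = 3, dt = 0.01)
  expect_equal(max(abs(out$x)), 0)
  expect_equal(max(abs(out$xdot)), 0)

  # constant hand offset: x(t) = exp(lam t) - 1 for p = 1, lam = 2
  out <- cursor_from_hand(rep(1, 51), lam = 2, dt = 0.01, method = "exact")
  expect_equal(out$x[51], exp(2 * 0.5) - 1, tolerance = 1e-12)
  # Euler agrees with a fine-step integrator at dt/100
  eu <- cursor_from_hand(rep(1, 51), lam = 2, dt = 0.01, method = "euler")
  fine <- rep(1, 5001)
  xf <- 0
  for (k in 1:5000) xf <- xf + 1e-4 * 2 * (xf + 1)
  expect_equal(eu$x[51], xf, tolerance = 2e-2)
  expect_equal(eu$x[51], exp(1) - 1, tolerance = 2e-2)

  bad <- c(1, 2, NaN, 4)
  expect_error(cursor_from_hand(bad, lam = 2, dt = 0.01), "index 3",
               class = "cst_bad_input")
  expect_error(cursor_from_hand(1, lam = 2, dt = 0.01), class = "cst_bad_input")
})

test_that("cursor reconstruction inverts the simulator's propagation", {
  g <- default_gains(3, "position")
  task <- cst_task(lam = 3)
  tr <- simulate_trial(g$sys, g, task = task, seed = 77)
  d <- tr$data[[1]]
  rec <- cursor_from_hand(d$p, lam = 3, dt = 0.01, x0 = d$x[1])
  expect_lt(max(abs(rec$x - d$x)), 1e-9)
  expect_lt(max(abs(rec$xdot - d$xdot)), 1e-9)
})

test_that("hand-trace reader parses delimited files and resamples", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 1, by = 1 / 250)          # 250 Hz recording
  writeLines(c("time_s,hand_cm", paste(tt, sin(tt), sep = ",")), tmp)
  df <- read_hand_trace(tmp)
  expect_named(df, c("time_s", "hand_cm"))
  out <- cursor_from_hand(df, lam = 2, dt = 0.01, method = "exact")
  expect_equal(median(diff(out$t)), 0.01)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\thand_cm", paste(tt, sin(tt), sep = "\t")), tsv)
  expect_equal(read_hand_trace(tsv)$hand_cm, df$hand_cm)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_hand_trace(bad), "time_s", class = "cst_bad_input")
  expect_error(read_hand_trace("no/such/file.csv"), class = "cst_bad_input")
})

test_that("system description round-trips through JSON", {
  sysd <- discretize(build_continuous_system(2.7, cst_plant(M = 1.2, tau = 0.05)),
                     dt = 0.01, delay_steps = 5)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_system_json(sysd, tmp)
  back <- read_system_json(tmp)
  expect_equal(back$Ad, sysd$Ad, ignore_attr = TRUE)
  expect_equal(back$Bd, sysd$Bd, ignore_attr = TRUE)
  expect_equal(back$H, sysd$H, ignore_attr = TRUE)
  expect_equal(back$lam, 2.7)
  expect_error(read_system_json('{"type": "other"}'), class = "cst_bad_input")
})
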