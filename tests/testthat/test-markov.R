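test_that("propagation follows X_{r+1} = X_r P and conserves mass", {
  P <- known_absorbing_matrix()
  init <- interior_initial()

  # identity fixed point
  tr <- propagate(init, diag(5), steps = 3)
  for (r in 1:4) expect_equal(unname(tr[r, ]), init)

  # hand-computed single product
  x0 <- c(0, 1, 0, 0, 0)
  P2 <- diag(5); P2[2, ] <- c(0.3, 0.6, 0.1, 0, 0)
  tr2 <- propagate(x0, P2, steps = 1)
  expect_equal(unname(tr2[2, ]), c(0.3, 0.6, 0.1, 0, 0))

  # absorbing endpoints: certain-best and certain-worst never change
  for (x in list(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1))) {
    trA <- propagate(x, P, steps = 6)
    expect_equal(unname(trA[7, ]), x)
  }

  # mass conservation along random stochastic matrices
  set.seed(21)
  for (i in 1:20) {
    R <- matrix(stats::rgamma(25, 1), 5)
    R <- R / rowSums(R)
    x <- stats::rgamma(5, 1); x <- x / sum(x)
    trR <- propagate(x, R, steps = 8)
    expect_lt(max(abs(rowSums(trR) - 1)), 1e-9)
  }

  expect_equal(nrow(propagate(init, P, steps = 0)), 1L)
  expect_error(propagate(c(0.5, 0.6, 0, 0, 0), P, 1), "sums")
  expect_error(propagate(init, matrix(1, 5, 5), 1), "row")
})

test_that("calibration reader validates and renormalizes", {
  cal <- read_calibration(c("step,p1,p2,p3,p4,p5",
                            "1,0.2,0.3,0.3,0.1,0.1",
                            "2,0.4,0.3,0.2,0.1,0"))
  expect_identical(cal$step, 1:2)
  expect_warning(
    cal2 <- read_calibration(c("step,p1,p2,p3,p4,p5",
                               "1,0.2,0.3,0.3,0.1,0.2")),
    "renormal")
  expect_equal(sum(cal2[1, -1]), 1)
  expect_error(read_calibration(c("step,p1,p2,p3,p4,p5",
                                  "1,0.2,0.3,0.3,0.1,0.1",
                                  "1,0.4,0.3,0.2,0.1,0")), "unique")
  expect_error(read_calibration(c("step,p1,p2,p3,p4,p5",
                                  "0,1,0,0,0,0")), ">= 1")
})

test_that("simulate-then-fit recovers the calibration trajectory", {
  P <- known_absorbing_matrix()
  init <- interior_initial()
  calib <- simulated_calibration(P, init, m = 4)
  fit <- fit_transition_matrix(init, calib, restarts = 8, seed = 13)

  expect_lte(fit$Q, 0.05)
  # the returned Q equals an independent brute-force recomputation
  expect_equal(fit$Q, oracle_Q(unclass(fit$matrix), init, calib))
  # no worse than the uniform-interior start
  expect_lte(fit$Q, fit$diagnostics$uniform_start_Q + 1e-9)
  # hard absorbing-endpoint constraints
  M <- unclass(fit$matrix)
  expect_equal(M[1, ], c(1, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(M[5, ], c(0, 0, 0, 0, 1), ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(M) - 1)), 1e-9)
})

test_that("identity-feasible calibration reaches Q near zero", {
  init <- interior_initial()
  calib <- list(list(step = 1, observed = init))
  fit <- fit_transition_matrix(init, calib, restarts = 4, seed = 2)
  expect_lt(fit$Q, 1e-3)
})

test_that("zero observed probabilities use the safeguarded denominator", {
  P <- known_absorbing_matrix()
  init <- c(0, 0.5, 0.5, 0, 0)   # propagated states keep exact zeros at V
  calib <- simulated_calibration(P, init, m = 2)
  expect_true(any(unlist(lapply(calib, `[[`, "observed")) == 0))
  fit <- fit_transition_matrix(init, calib, restarts = 4, seed = 6)
  expect_true(is.finite(fit$Q))
  expect_equal(fit$Q, oracle_Q(unclass(fit$matrix), init, calib))
})

test_that("adding a calibration point cannot shrink the sub-objective", {
  P <- known_absorbing_matrix()
  init <- interior_initial()
  calib4 <- simulated_calibration(P, init, m = 4)
  # perturb the later points so the full objective is not trivially zero
  calib4[[3]]$observed <- rev(calib4[[3]]$observed)
  calib4[[4]]$observed <- rev(calib4[[4]]$observed)
  fit2 <- fit_transition_matrix(init, calib4[1:2], restarts = 6, seed = 3)
  fit4 <- fit_transition_matrix(init, calib4, restarts = 6, seed = 3)
  expect_gte(fit4$Q + 1e-6, fit2$Q)
})

test_that("dynamic evaluation chains the stages and is reproducible", {
  std <- slope_standard()
  s4 <- slope_sites()[[4]]
  # calibration that moves mass II -> I over time
  Pstar <- diag(5)
  Pstar[2, ] <- c(0.4, 0.6, 0, 0, 0)
  x <- c(0, 1, 0, 0, 0)
  calib <- simulated_calibration(Pstar, x, m = 2)
  dyn <- dynamic_evaluate(s4, std, calib, n_trials = 300, seed = 10,
                          restarts = 4)
  expect_equal(unname(dyn$trajectory[1, ]), unname(dyn$initial$p))
  expect_gt(dyn$initial$p[["II"]], 0.9)
  # fitted dynamics shift mass toward grade I
  last <- dyn$trajectory[nrow(dyn$trajectory), ]
  expect_gt(last[["I"]], dyn$initial$p[["I"]])

  dyn2 <- dynamic_evaluate(s4, std, calib, n_trials = 300, seed = 10,
                           restarts = 4)
  expect_equal(unclass(dyn$trajectory), unclass(dyn2$trajectory))
  # zero steps: trajectory is the initial state only
  dyn0 <- dynamic_evaluate(s4, std, calib, n_trials = 100, seed = 10,
                           steps = 0, restarts = 2)
  expect_identical(nrow(dyn0$trajectory), 1L)
})
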