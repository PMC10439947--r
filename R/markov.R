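# Dynamic evaluation: the grade-probability vector is treated as a Markov
# state and projected forward, X_{r+1} = X_r %*% P, with a row-stochastic
# transition matrix P. Lacking multi-year panel data, P is estimated by
# constrained optimization against sparse calibration distributions:
#   min Q = sum_r sum_k | (S_k(r) - Shat_k(r)) / S_k(r) |,
# subject to rows of P summing to 1 with non-negative entries, and (by
# default) absorbing endpoints: a site certainly in the best or worst
# grade stays there.

#' Validate (and tag) a transition matrix
#'
#' @param P Square numeric matrix; rows must sum to 1 within `1e-9` with
#'   entries in `[0, 1]`.
#' @param absorbing_endpoints When `TRUE`, additionally require the first
#'   and last states to be absorbing (`P[1,1] == 1`, `P[n,n] == 1`).
#' @return `P`, invisibly, with class `transition_matrix`.
#' @export
transition_matrix <- function(P, absorbing_endpoints = FALSE) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n) stopf("transition matrix must be square")
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stopf("transition probabilities must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stopf("row %d of the transition matrix sums to %.12f, not 1",
          which(abs(rs - 1) > 1e-9)[1L], rs[which(abs(rs - 1) > 1e-9)[1L]])
  if (absorbing_endpoints && (abs(P[1, 1] - 1) > 0 || abs(P[n, n] - 1) > 0))
    stopf("absorbing endpoints require P[1,1] = 1 and P[%d,%d] = 1", n, n)
  class(P) <- c("transition_matrix", class(P))
  invisible(P)
}

check_distribution <- function(x, what = "distribution", tol = 1e-9) {
  x <- as.numeric(x)
  if (any(x < -1e-12)) stopf("%s has a negative entry", what)
  if (abs(sum(x) - 1) > tol)
    stopf("%s sums to %.12f, not 1", what, sum(x))
  x
}

#' Project a grade distribution forward in time
#'
#' @param initial Grade distribution (sums to 1); e.g. the `p` field of a
#'   [evaluate_object()] result.
#' @param matrix A row-stochastic transition matrix.
#' @param steps Number of transfer steps (>= 0).
#' @return Object of class `state_trajectory`: a `(steps + 1) x n` matrix
#'   of distributions with rows `r0..r<steps>`; row `r0` is `initial`.
#' @export
propagate <- function(initial, matrix, steps) {
  if (inherits(initial, "grade_probabilities")) initial <- initial$p
  x <- check_distribution(initial, "initial state")
  P <- unclass(transition_matrix(matrix))
  if (length(x) != nrow(P))
    stopf("initial state length %d does not match the %d-state matrix",
          length(x), nrow(P))
  if (!is.numeric(steps) || steps < 0) stopf("steps must be >= 0")
  steps <- as.integer(steps)
  traj <- base::matrix(0, steps + 1L, length(x))
  traj[1L, ] <- x
  for (r in seq_len(steps)) {
    x <- as.vector(x %*% P)
    traj[r + 1L, ] <- check_distribution(x, sprintf("state at step %d", r))
  }
  rownames(traj) <- paste0("r", 0:steps)
  colnames(traj) <- colnames(P) %||% names(initial)
  structure(traj, class = c("state_trajectory", "matrix", "array"))
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d step(s), %d grades\n",
              nrow(x) - 1L, ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read calibration distributions from delimited text
#'
#' Expected columns: `step,p1,...,pN`; one row per observed grade
#' distribution at a known transfer step. Rows off unit mass by more than
#' `1e-6` are renormalized with a warning.
#'
#' @param source File path or literal text.
#' @return Data frame with integer `step` and the distribution columns.
#' @export
read_calibration <- function(source) {
  df <- read_delim_source(source)
  if (!"step" %in% names(df)) stopf("calibration file: missing column 'step'")
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  if (length(pcols) < 2L) stopf("calibration file: missing p<k> columns")
  out <- data.frame(step = as.integer(df$step))
  for (pc in pcols) out[[pc]] <- as.numeric(df[[pc]])
  if (anyNA(out)) stopf("calibration file: non-numeric entry")
  validate_calibration(out)
}

validate_calibration <- function(calib) {
  pcols <- grep("^p[0-9]+$", names(calib), value = TRUE)
  if (any(calib$step < 1L)) stopf("calibration steps must be >= 1")
  if (anyDuplicated(calib$step)) stopf("calibration steps must be unique")
  for (i in seq_len(nrow(calib))) {
    p <- as.numeric(calib[i, pcols])
    if (any(p < 0)) stopf("calibration row %d: negative probability", i)
    s <- sum(p)
    if (abs(s - 1) > 1e-6) {
      warnf("calibration row %d sums to %.8f; renormalizing", i, s)
      calib[i, pcols] <- p / s
    }
  }
  calib[order(calib$step), , drop = FALSE]
}

# Objective of the fit: summed relative deviations between the observed
# calibration distributions and the propagated ones. Zero observations
# use a safeguarded denominator max(S, epsilon).
transition_objective <- function(P, initial, calib, epsilon = 1e-6) {
  pcols <- grep("^p[0-9]+$", names(calib), value = TRUE)
  Smat <- as.matrix(calib[, pcols, drop = FALSE])
  objective_core(P, initial, calib$step, Smat, epsilon)
}

# Fast core shared by the public oracle and the optimization loop:
# Smat holds one observed distribution per row, steps the transfer counts.
objective_core <- function(P, initial, steps, Smat, epsilon,
                           smooth = 0) {
  m <- max(steps)
  x <- initial
  traj <- base::matrix(0, m, length(initial))
  for (r in seq_len(m)) {
    x <- as.vector(x %*% P)
    traj[r, ] <- x
  }
  dev <- (Smat - traj[steps, , drop = FALSE]) / pmax(Smat, epsilon)
  if (smooth > 0) sum(sqrt(dev * dev + smooth * smooth) - smooth)
  else sum(abs(dev))
}

softmax_row <- function(z) { e <- exp(z - max(z)); e / sum(e) }

build_matrix_from_par <- function(par, n, absorbing) {
  P <- base::matrix(0, n, n)
  if (absorbing) {
    P[1L, 1L] <- 1; P[n, n] <- 1
    free <- seq(2L, n - 1L)
  } else free <- seq_len(n)
  for (k in seq_along(free))
    P[free[k], ] <- softmax_row(par[((k - 1L) * n + 1L):(k * n)])
  P
}

#' Fit a transition matrix to sparse calibration distributions
#'
#' Minimizes the summed relative deviation between observed and
#' propagated grade distributions over a row-stochastic matrix, by
#' multi-start local optimization (softmax row parametrization, BFGS
#' start then Nelder-Mead polish). The objective is non-smooth and
#' non-convex for steps > 1, so the minimizer is not claimed unique;
#' diagnostics report the spread of the objective across restarts.
#'
#' @param initial Grade distribution at step 0.
#' @param calibration Data frame as returned by [read_calibration()]
#'   (columns `step`, `p1..pN`), or a list of `list(step =, observed =)`.
#' @param restarts Random restarts in addition to the uniform-interior
#'   start (default 16).
#' @param absorbing_endpoints Constrain the best and worst grades to be
#'   absorbing (default `TRUE`): a certain-best or certain-worst state
#'   never changes.
#' @param epsilon Safeguard for zero observed probabilities in the
#'   relative-deviation objective.
#' @param max_iterations Iteration cap per local optimization stage.
#' @param tolerance Relative convergence tolerance of the exact polish
#'   stages.
#' @param seed Optional integer seed for the restart draws.
#' @return List with `matrix` (the fitted `transition_matrix`), `Q`
#'   (achieved objective), and `diagnostics` (`restart_Q`, the objective
#'   at every start, `uniform_start_Q`, `best_start`, iteration counts,
#'   and `uniform_rows`, flagging fitted rows that came out exactly
#'   uniform).
#' @export
fit_transition_matrix <- function(initial, calibration, restarts = 16,
                                  absorbing_endpoints = TRUE,
                                  epsilon = 1e-6, max_iterations = 2000,
                                  tolerance = 1e-10, seed = NULL) {
  if (inherits(initial, "grade_probabilities")) initial <- initial$p
  initial <- check_distribution(initial, "initial state")
  n <- length(initial)
  calib <- as_calibration_df(calibration, n)
  if (!nrow(calib)) stopf("at least one calibration point is required")
  if (restarts < 0) stopf("restarts must be >= 0")
  nfree <- if (absorbing_endpoints) n - 2L else n
  if (nfree < 1L)
    stopf("absorbing endpoints leave no free row for a %d-state chain", n)
  npar <- nfree * n

  pcols <- grep("^p[0-9]+$", names(calib), value = TRUE)
  Smat <- as.matrix(calib[, pcols, drop = FALSE])
  obj <- function(par)
    objective_core(build_matrix_from_par(par, n, absorbing_endpoints),
                   initial, calib$step, Smat, epsilon)
  # smoothed |.| for the gradient-based warm starts (kinks stall BFGS)
  obj_smooth <- function(par, s)
    objective_core(build_matrix_from_par(par, n, absorbing_endpoints),
                   initial, calib$step, Smat, epsilon, smooth = s)

  starts <- with_seed(seed, c(
    list(rep(0, npar)),                                  # uniform-interior rows
    lapply(seq_len(restarts), function(i) stats::rnorm(npar, 0, 2))))

  evals <- 0L
  runs <- lapply(starts, function(s0) {
    p <- s0
    for (s in c(1e-2, 1e-4)) {                 # graduated smoothing
      f1 <- stats::optim(p, obj_smooth, s = s, method = "BFGS",
                         control = list(maxit = min(300L, max_iterations)))
      p <- f1$par
      evals <<- evals + f1$counts[["function"]]
    }
    f2 <- stats::optim(p, obj, method = "Nelder-Mead",
                       control = list(maxit = max_iterations,
                                      reltol = tolerance))
    f2 <- stats::optim(f2$par, obj, method = "Nelder-Mead",
                       control = list(maxit = max_iterations,
                                      reltol = tolerance))
    evals <<- evals + f2$counts[["function"]]
    f2
  })
  Qs <- vapply(runs, `[[`, 0, "value")
  best <- which.min(Qs)
  P <- build_matrix_from_par(runs[[best]]$par, n, absorbing_endpoints)
  dimnames(P) <- list(names(initial), names(initial))
  uniform_rows <- which(apply(P, 1L, function(r) all(abs(r - 1 / n) < 1e-6)))
  list(matrix = transition_matrix(P, absorbing_endpoints),
       Q = Qs[best],
       diagnostics = list(restart_Q = Qs, uniform_start_Q = Qs[1L],
                          best_start = best, n_starts = length(starts),
                          function_evaluations = evals,
                          uniform_rows = uniform_rows,
                          absorbing_endpoints = absorbing_endpoints,
                          epsilon = epsilon))
}

as_calibration_df <- function(calibration, n) {
  if (is.data.frame(calibration)) return(validate_calibration(calibration))
  rows <- lapply(calibration, function(cp) {
    obs <- as.numeric(cp$observed %||% cp$obs)
    if (length(obs) != n)
      stopf("calibration point at step %s has %d entries, expected %d",
            cp$step, length(obs), n)
    out <- data.frame(step = as.integer(cp$step))
    for (k in seq_len(n)) out[[paste0("p", k)]] <- obs[k]
    out
  })
  validate_calibration(do.call(rbind, rows))
}

#' Full dynamic evaluation pipeline
#'
#' Chains the Monte-Carlo evaluation (initial state), the transition
#' matrix fit, and the forward projection.
#'
#' @inheritParams evaluate_object
#' @param calibration As in [fit_transition_matrix()].
#' @param steps Transfer steps to project (default: the largest
#'   calibration step).
#' @param ... Passed to [fit_transition_matrix()].
#' @return List with `initial` (`grade_probabilities`), `fit` (the fit
#'   result) and `trajectory` (`state_trajectory`, whose first row equals
#'   the initial probabilities).
#' @export
dynamic_evaluate <- function(target, standard, calibration,
                             n_trials = 1000, seed = NULL, steps = NULL,
                             normalize = FALSE, ...) {
  init <- evaluate_object(target, standard, n_trials = n_trials, seed = seed,
                          normalize = normalize)
  calib <- as_calibration_df(calibration, n_grades(standard))
  steps <- steps %||% max(calib$step)
  fit <- fit_transition_matrix(init$p, calib, seed = seed, ...)
  traj <- propagate(init$p, fit$matrix, steps)
  list(initial = init, fit = fit, trajectory = traj)
}
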