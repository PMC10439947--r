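# Local index sensitivity: the absolute ratio of the relative change in a
# scalar output functional F to the relative change in one index value,
#   S_i = | ((F(x + d e_i) - F(x)) / F(x)) / (d / x_i) |.
# The built-in Monte-Carlo functionals are evaluated under common random
# numbers (identical seed for base and perturbed runs) so the finite
# difference is not swamped by sampling noise.

builtin_functionals <- c("modal_prob", "midpoint_sim", "expected_grade")

# Resolve the output functional to a function of a raw value vector.
# Built-ins are anchored at the BASE evaluation's modal grade k0:
#   modal_prob     - probability that the classified grade equals k0
#   midpoint_sim   - similarity to the grade-k0 interval-midpoint
#                    representative (deterministic, noise-free)
#   expected_grade - mean grade number sum_k k * P(k)
make_functional <- function(functional, standard, n_trials, cr_seed,
                            normalize, base_eval) {
  if (is.function(functional)) return(functional)
  functional <- match.arg(functional, builtin_functionals)
  k0 <- base_eval$modal_index
  switch(functional,
    modal_prob = function(v)
      evaluate_object(v, standard, n_trials = n_trials, seed = cr_seed,
                      normalize = normalize)$p[[k0]],
    expected_grade = function(v) {
      p <- evaluate_object(v, standard, n_trials = n_trials, seed = cr_seed,
                           normalize = normalize)$p
      sum(seq_along(p) * p)
    },
    midpoint_sim = {
      rep0 <- midpoint_representative(standard, k0)
      scale <- if (normalize) 1 / index_scale(standard)
               else rep(1, length(rep0))
      function(v) sqrt_cosine_similarity(rep0 * scale, v * scale)
    })
}

# Deterministic stand-in for grade g: every interval's midpoint, ordinal
# indexes at the grade's score.
midpoint_representative <- function(standard, g) {
  vapply(standard$indexes, function(d)
    if (d$kind == "qualitative") d$lo[g] else (d$lo[g] + d$hi[g]) / 2, 0)
}

perturb_value <- function(standard, j, x, dx) {
  d <- standard$indexes[[j]]
  xp <- x + dx
  if (d$kind == "qualitative") {
    ng <- d$n_grades
    clipped <- min(max(xp, 1), ng)
    if (clipped != xp)
      warnf("index %s: perturbed score %g clipped to %g", d$id, xp, clipped)
    clipped
  } else if (xp < 0) {
    warnf("index %s: perturbed value %g clipped to 0", d$id, xp)
    0
  } else xp
}

#' Local sensitivity of the evaluation to one index
#'
#' One-sided finite difference of an output functional with respect to
#' index `index_id`, normalized to relative changes. With
#' `normal_draws = 0` (default) the perturbation is the fixed step
#' `delta`; with `normal_draws > 0` the perturbed value is instead drawn
#' `normal_draws` times from `Normal(x_i, delta)` truncated at 0 (the
#' index-uncertainty model) and the per-draw sensitivities are averaged.
#'
#' @param target [evaluation_object()] or numeric vector; the perturbed
#'   index's base value must be positive.
#' @param standard A [grade_standard()].
#' @param index_id Which index to perturb.
#' @param delta Perturbation step, and the standard deviation of the
#'   Normal-draw variant (default 2, the stated index uncertainty).
#' @param n_trials Trials per functional evaluation.
#' @param seed Integer seed shared by the base and perturbed runs (common
#'   random numbers). `NULL` draws one from the ambient stream.
#' @param functional `"modal_prob"` (default), `"midpoint_sim"`,
#'   `"expected_grade"`, or a `function(values) -> scalar` (used for
#'   surrogate oracles in tests).
#' @param normal_draws Number of Normal perturbation draws (0 = fixed
#'   step).
#' @param normalize Passed through to [evaluate_object()].
#' @param base Optional precomputed base evaluation (internal reuse).
#' @return The sensitivity `S >= 0`, with attributes `F0` (base
#'   functional value) and `dx` (realized step; `NA` for the averaged
#'   Normal-draw variant).
#' @export
sensitivity_one <- function(target, standard, index_id, delta = 2,
                            n_trials = 1000, seed = NULL,
                            functional = "modal_prob", normal_draws = 0,
                            normalize = FALSE, base = NULL) {
  if (!is.function(functional) && delta == 0)
    stopf("delta must be nonzero")
  x <- object_values(target)
  j <- match(index_id, index_ids(standard))
  if (is.na(j)) stopf("unknown index id '%s'", index_id)
  if (x[j] == 0)
    stopf("index %s: base value is 0; the relative step is undefined", index_id)
  cr_seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  need_base <- !is.function(functional)
  base_eval <- if (need_base) base %||%
    evaluate_object(x, standard, n_trials = n_trials, seed = cr_seed,
                    normalize = normalize)
  f <- make_functional(functional, standard, n_trials, cr_seed,
                       normalize, base_eval)
  F0 <- f(x)
  if (F0 == 0)
    stopf("base functional value is 0; the relative change is undefined")
  one_step <- function(dx) {
    xp <- perturb_value(standard, j, x[j], dx)
    dx_real <- xp - x[j]
    if (dx_real == 0) return(NA_real_)
    v <- x; v[j] <- xp
    abs(((f(v) - F0) / F0) / (dx_real / x[j]))
  }
  if (normal_draws > 0) {
    S <- with_seed(cr_seed + j, {
      draws <- stats::rnorm(normal_draws, 0, abs(delta))
      draws <- pmax(x[j] + draws, 0) - x[j]          # truncate value at 0
      vals <- vapply(draws, function(dd)
        if (abs(dd) < 1e-8) NA_real_ else suppressWarnings(one_step(dd)), 0)
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    })
  } else {
    S <- one_step(delta)
  }
  structure(S, F0 = F0, dx = if (normal_draws > 0) NA_real_ else delta)
}

#' Local sensitivity of every index, with ranking
#'
#' Applies [sensitivity_one()] to each index, reusing one base
#' evaluation. Indexes whose preconditions fail (zero base value, or a
#' perturbation fully clipped away) are reported with a reason instead of
#' being dropped silently.
#'
#' @inheritParams sensitivity_one
#' @return Object of class `sensitivity_result`: a list with `table`
#'   (data frame `index_id`, `value`, `S`, `rank`, sorted by rank),
#'   `skipped` (data frame `index_id`, `reason`), `functional`, `F0`,
#'   `modal_grade` and the settings used.
#' @export
sensitivity_all <- function(target, standard, delta = 2, n_trials = 1000,
                            seed = NULL, functional = "modal_prob",
                            normal_draws = 0, normalize = FALSE) {
  x <- object_values(target)
  ids <- index_ids(standard)
  cr_seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  need_base <- !is.function(functional)
  base_eval <- if (need_base)
    evaluate_object(x, standard, n_trials = n_trials, seed = cr_seed,
                    normalize = normalize)
  S <- rep(NA_real_, length(ids))
  reasons <- character(length(ids))
  for (j in seq_along(ids)) {
    res <- tryCatch(
      suppressWarnings(
        sensitivity_one(x, standard, ids[j], delta = delta,
                        n_trials = n_trials, seed = cr_seed,
                        functional = functional,
                        normal_draws = normal_draws,
                        normalize = normalize, base = base_eval)),
      error = function(e) structure(NA_real_, reason = conditionMessage(e)))
    S[j] <- as.numeric(res)
    if (is.na(S[j]))
      reasons[j] <- attr(res, "reason") %||% "perturbation clipped to a zero step"
  }
  ok <- !is.na(S)
  tab <- data.frame(index_id = ids[ok], value = unname(x[ok]), S = S[ok])
  tab$rank <- rank(-tab$S, ties.method = "min")
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  skipped <- data.frame(index_id = ids[!ok], reason = reasons[!ok])
  structure(list(table = tab, skipped = skipped,
                 functional = if (is.function(functional)) "custom"
                              else functional,
                 F0 = if (need_base) attr_or_null(base_eval) else NULL,
                 modal_grade = if (need_base) base_eval$modal_grade else NULL,
                 delta = delta, n_trials = n_trials, seed = cr_seed,
                 normal_draws = normal_draws, normalize = normalize),
            class = "sensitivity_result")
}

attr_or_null <- function(base_eval) max(base_eval$p)

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Index sensitivity (functional = %s, delta = %g%s)\n",
              x$functional, x$delta,
              if (x$normal_draws > 0)
                sprintf(", %d Normal draws", x$normal_draws) else ""))
  print(transform(x$table, S = signif(S, 4)), row.names = FALSE)
  if (nrow(x$skipped)) {
    cat("Skipped:\n")
    print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}
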