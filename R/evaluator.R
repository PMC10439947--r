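# Monte-Carlo trial loop: each trial draws a fresh representative set and
# classifies the target by maximum sqrt-cosine similarity; the grade
# frequencies over N trials are the evaluation's grade probabilities and
# the modal grade is the evaluation result.

#' Monte-Carlo grade evaluation of one object
#'
#' Runs `n_trials` independent trials. Each trial samples one
#' representative per grade (uniform within the grade's intervals, fixed
#' ordinal scores) and assigns the grade of the most similar
#' representative. Probabilities are exact trial fractions, so they sum
#' to 1 and the counts conserve `n_trials`.
#'
#' @param target [evaluation_object()] or numeric vector aligned to the
#'   standard.
#' @param standard A [grade_standard()].
#' @param n_trials Number of trials (default 1000, where the estimate is
#'   stable for the bundled application).
#' @param seed Optional integer seed (private stream; caller's RNG state
#'   untouched).
#' @param normalize When `TRUE`, each index (target and representatives
#'   alike) is divided by its standard's largest bound before the
#'   similarity, making indexes dimensionless and comparable in scale.
#'   Default `FALSE`: raw values, which reproduce the bundled engineering
#'   results.
#' @return Object of class `grade_probabilities` with fields `p` (named
#'   probabilities), `counts`, `n_trials`, `modal_grade` and
#'   `modal_index`; see also [evaluate_batch()].
#' @export
evaluate_object <- function(target, standard, n_trials = 1000, seed = NULL,
                            normalize = FALSE) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stopf("n_trials must be >= 1")
  n_trials <- as.integer(n_trials)
  tv <- object_values(target)
  if (length(tv) != length(standard$indexes))
    stopf("target has %d values but the standard %d indexes",
          length(tv), length(standard$indexes))
  if (any(tv < 0)) stopf("target has a negative value")
  ng <- n_grades(standard)
  scale <- if (normalize) 1 / index_scale(standard) else rep(1, length(tv))
  counts <- with_seed(seed, {
    R <- representative_matrix(standard, n_trials)
    Rs <- sweep(R, 2L, scale, `*`)
    ts <- tv * scale
    if (sum(ts) == 0) stopf("target is all-zero; similarity undefined")
    num <- sqrt(Rs) %*% sqrt(ts)
    sim <- num / (sqrt(rowSums(Rs)) * sqrt(sum(ts)))
    S <- matrix(sim, nrow = ng)                 # grade x trial
    k <- max.col(t(S), ties.method = "first")   # tie -> most favorable grade
    tabulate(k, nbins = ng)
  })
  grade_probabilities(counts, standard$grade_labels, n_trials,
                      target_id = if (inherits(target, "evaluation_object"))
                        target$id else NA_character_,
                      seed = seed, normalize = normalize)
}

# Largest bound per index (ordinal indexes: the top score); used by the
# optional normalization.
index_scale <- function(standard) {
  vapply(standard$indexes, function(d)
    if (d$kind == "qualitative") max(d$lo) else max(d$hi), 0)
}

grade_probabilities <- function(counts, labels, n_trials, target_id = NA,
                                seed = NULL, normalize = FALSE) {
  p <- counts / n_trials
  names(p) <- labels
  names(counts) <- labels
  mi <- unname(which.max(p))
  structure(list(p = p, counts = counts, n_trials = n_trials,
                 modal_grade = labels[mi], modal_index = mi,
                 target_id = target_id, seed = seed, normalize = normalize),
            class = "grade_probabilities")
}

#' @export
print.grade_probabilities <- function(x, ...) {
  id <- if (is.na(x$target_id)) "" else sprintf(" '%s'", x$target_id)
  cat(sprintf("Grade probabilities%s (N = %d trials)\n", id, x$n_trials))
  print(noquote(sprintf("%.2f%%", 100 * x$p)))
  cat(sprintf("Evaluation result: grade %s (P = %.2f%%)\n",
              x$modal_grade, 100 * max(x$p)))
  invisible(x)
}

#' Evaluate several objects with independent sub-streams
#'
#' Each object gets its own deterministic sub-seed derived from `seed`,
#' so results do not depend on batch composition or order.
#'
#' @param targets List of [evaluation_object()]s (or numeric vectors).
#' @inheritParams evaluate_object
#' @return List of `grade_probabilities`, one per target, order
#'   preserved; named by the targets' ids when available.
#' @export
evaluate_batch <- function(targets, standard, n_trials = 1000, seed = NULL,
                           normalize = FALSE) {
  if (!length(targets)) return(list())
  seeds <- if (is.null(seed)) vector("list", length(targets))
           else as.list(derive_subseeds(seed, length(targets)))
  out <- Map(function(tg, s)
    evaluate_object(tg, standard, n_trials = n_trials, seed = s,
                    normalize = normalize),
    targets, seeds)
  ids <- vapply(targets, function(tg)
    if (inherits(tg, "evaluation_object")) tg$id else NA_character_, "")
  if (!anyNA(ids)) names(out) <- ids
  out
}
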