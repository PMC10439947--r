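# Grade-representative sampling. A representative of grade g is an index
# vector whose quantitative components are drawn continuous-uniform from
# that index's grade-g interval and whose qualitative components carry the
# fixed grade-g score. Draws use R's native RNG stream; pass `seed` at an
# entry point (or set.seed() yourself) for reproducibility.

#' Sample one grade-representative object
#'
#' @param standard A [grade_standard()].
#' @param grade A grade label of the standard (e.g. `"II"`) or its
#'   1-based position.
#' @param seed Optional integer; when given, the draw is made from a
#'   private stream seeded with it and the caller's RNG state is restored.
#' @return An [evaluation_object()] whose every quantitative value lies in
#'   its index's grade interval.
#' @export
sample_representative <- function(standard, grade, seed = NULL) {
  g <- resolve_grade(standard, grade)
  with_seed(seed, {
    vals <- representative_draw(standard, g)
    evaluation_object(sprintf("rep_%s", standard$grade_labels[g]), vals,
                      standard, warn_out_of_range = FALSE)
  })
}

#' Sample a full representative set, one object per grade
#'
#' @inheritParams sample_representative
#' @return List of [evaluation_object()]s in grade order (best first),
#'   named by grade label.
#' @export
sample_representative_set <- function(standard, seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(n_grades(standard)), function(g)
      evaluation_object(sprintf("rep_%s", standard$grade_labels[g]),
                        representative_draw(standard, g),
                        standard, warn_out_of_range = FALSE))
    names(out) <- standard$grade_labels
    out
  })
}

resolve_grade <- function(standard, grade) {
  if (is.numeric(grade)) {
    g <- as.integer(grade)
    if (g < 1L || g > n_grades(standard))
      stopf("grade position %d outside 1..%d", g, n_grades(standard))
    return(g)
  }
  g <- match(as.character(grade), standard$grade_labels)
  if (is.na(g)) stopf("unknown grade label '%s'", grade)
  g
}

# One uniform draw per quantitative index, fixed score for qualitative.
representative_draw <- function(standard, g) {
  vapply(standard$indexes, function(d) {
    if (d$kind == "qualitative") d$lo[g]
    else stats::runif(1L, d$lo[g], d$hi[g])
  }, 0)
}

# Vectorised bulk sampler used by the trial loop: returns an
# (n_trials * n_grades) x n_indexes matrix, rows grouped by trial with
# grades in order. Consumes the ambient RNG stream index by index; the
# per-value distribution is identical to sample_representative's.
representative_matrix <- function(standard, n_trials) {
  ng <- n_grades(standard)
  grades <- rep.int(seq_len(ng), n_trials)
  cols <- lapply(standard$indexes, function(d) {
    if (d$kind == "qualitative") d$lo[grades]
    else stats::runif(length(grades), d$lo[grades], d$hi[grades])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- index_ids(standard)
  m
}
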