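# Synthetic grade standards and objects, used by the property-test suite
# and available for simulation studies. A generated standard mimics the
# structure of real grading tables: a mix of quantitative indexes (random
# contiguous breakpoints on scales spanning roughly 1 to a few hundred,
# in either grade direction) and ordinal indexes scored 1..n_grades.

#' Generate a random, valid grade standard
#'
#' @param n_indexes Number of indexes.
#' @param n_grades Number of grades (default 5).
#' @param p_qualitative Probability that an index is ordinal (default
#'   0.2, matching the 3-of-15 mix of the bundled standard).
#' @param seed Optional integer seed.
#' @return A validated [grade_standard()].
#' @export
random_grade_standard <- function(n_indexes = 8, n_grades = 5,
                                  p_qualitative = 0.2, seed = NULL) {
  with_seed(seed, {
    defs <- lapply(seq_len(n_indexes), function(j) {
      id <- paste0("X", j)
      if (stats::runif(1) < p_qualitative)
        return(index_definition(id, kind = "qualitative",
                                n_grades = n_grades))
      scale <- exp(stats::runif(1, 0, log(300)))   # top bound in ~(1, 300)
      gaps <- stats::rgamma(n_grades, shape = 2, rate = 1)
      breaks <- c(0, cumsum(gaps)) / sum(gaps) * scale
      if (stats::runif(1) < 0.5) {                 # larger value = better
        lo <- breaks[n_grades:1]; hi <- breaks[(n_grades + 1):2]
      } else {                                     # larger value = worse
        lo <- breaks[1:n_grades]; hi <- breaks[2:(n_grades + 1)]
      }
      index_definition(id, kind = "quantitative", lo = lo, hi = hi,
                       n_grades = n_grades)
    })
    grade_standard(defs,
                   grade_labels = as.character(utils::as.roman(seq_len(n_grades))))
  })
}

#' Generate a random evaluation object for a standard
#'
#' @param standard A [grade_standard()].
#' @param grade When given (label or position), every value is drawn from
#'   that grade's intervals, i.e. the object is a true grade-`grade`
#'   specimen (used for parameter-recovery checks). When `NULL`, values
#'   are drawn over each index's full range with a random ordinal score.
#' @param id Object id.
#' @param seed Optional integer seed.
#' @return An [evaluation_object()].
#' @export
random_object <- function(standard, grade = NULL, id = "synthetic",
                          seed = NULL) {
  with_seed(seed, {
    vals <- if (!is.null(grade)) {
      representative_draw(standard, resolve_grade(standard, grade))
    } else {
      ng <- n_grades(standard)
      vapply(standard$indexes, function(d) {
        if (d$kind == "qualitative") sample.int(ng, 1L)
        else stats::runif(1, min(d$lo), max(d$hi))
      }, 0)
    }
    evaluation_object(id, vals, standard, warn_out_of_range = FALSE)
  })
}
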