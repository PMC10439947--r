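# Sqrt-cosine (Hellinger-affinity) similarity and grade classification.
#
# For non-negative vectors a, b over the same indexes,
#   sim(a, b) = sum_j sqrt(a_j b_j) / (sqrt(sum_j a_j) * sqrt(sum_j b_j)),
# i.e. the cosine of the angle between sqrt(a) and sqrt(b). It is 1 iff
# a and b are proportional, 0 iff their supports are disjoint, and lies in
# [0, 1] by Cauchy-Schwarz. The sum runs over ALL indexes of the standard.

#' Sqrt-cosine similarity of two non-negative index vectors
#'
#' @param a,b [evaluation_object()]s or bare non-negative numeric vectors
#'   of equal length.
#' @return A similarity in `[0, 1]`; symmetric; 1 when `a` and `b` are
#'   proportional; invariant to rescaling both vectors by one positive
#'   scalar.
#' @export
sqrt_cosine_similarity <- function(a, b) {
  va <- object_values(a); vb <- object_values(b)
  if (length(va) != length(vb))
    stopf("similarity: vectors of different length (%d vs %d)",
          length(va), length(vb))
  if (anyNA(va) || anyNA(vb)) stopf("similarity: missing value")
  if (any(va < 0) || any(vb < 0)) stopf("similarity: negative component")
  sa <- sum(va); sb <- sum(vb)
  if (sa == 0 || sb == 0)
    stopf("similarity undefined for an all-zero vector")
  min(sum(sqrt(va * vb)) / (sqrt(sa) * sqrt(sb)), 1)
}

#' Classify a target against a representative set
#'
#' Assigns the grade whose representative attains the maximum sqrt-cosine
#' similarity with the target. Exact ties (probability zero under
#' continuous sampling) resolve to the most favorable (lowest-numbered)
#' grade and are flagged.
#'
#' @param target [evaluation_object()] or numeric vector.
#' @param representatives List of representatives in grade order, e.g.
#'   from [sample_representative_set()].
#' @param grade_labels Labels for the grades; defaults to the
#'   representatives' names or Roman numerals.
#' @return List with `grade` (label), `grade_index` (1-based),
#'   `similarities` (named numeric) and `tie` (logical).
#' @export
classify <- function(target, representatives, grade_labels = NULL) {
  sims <- vapply(representatives, function(r)
    sqrt_cosine_similarity(r, target), 0)
  labels <- grade_labels %||% names(representatives) %||%
    as.character(utils::as.roman(seq_along(sims)))
  names(sims) <- labels
  top <- unname(which(sims == max(sims)))
  list(grade = labels[top[1L]], grade_index = top[1L],
       similarities = sims, tie = length(top) > 1L)
}

#' Empirical separation diagnostic for a grade standard
#'
#' The classification rule is justified when representatives of one grade
#' resemble each other more than representatives of different grades. That
#' separation is a property of the standard, not a theorem: this
#' diagnostic estimates it empirically. Each trial draws two independent
#' representative sets and compares the smallest same-grade similarity
#' (matching grades across the two sets) with the largest
#' different-grade similarity (all cross-grade pairs within and across
#' sets); a trial violates separation when min-within <= max-between.
#'
#' @param standard A [grade_standard()].
#' @param trials Number of Monte-Carlo trials (>= 2).
#' @param seed Optional integer seed.
#' @return List with per-trial `min_within` and `max_between` vectors,
#'   their overall summaries, and `violation_rate` in `[0, 1]`.
#' @export
separation_diagnostic <- function(standard, trials = 1000, seed = NULL) {
  if (trials < 2) stopf("separation_diagnostic needs trials >= 2")
  ng <- n_grades(standard)
  with_seed(seed, {
    mw <- mb <- numeric(trials)
    for (t in seq_len(trials)) {
      A <- representative_matrix(standard, 1L)
      B <- representative_matrix(standard, 1L)
      M <- rbind(A, B)                    # 2*ng rows
      grade <- rep.int(seq_len(ng), 2L)
      sq <- sqrt(M)
      gram <- sq %*% t(sq)
      tot <- rowSums(M)
      sim <- gram / sqrt(outer(tot, tot))
      cross <- vapply(seq_len(ng), function(g) sim[g, ng + g], 0)
      mw[t] <- min(cross)
      mb[t] <- max(sim[!outer(grade, grade, `==`) & upper.tri(sim)])
    }
    list(min_within = mw, max_between = mb,
         overall_min_within = min(mw), overall_max_between = max(mb),
         violation_rate = mean(mw <= mb), trials = trials)
  })
}
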