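# Shared fixture builders. All standards are built in code; nothing is
# read from disk except the packaged engineering fixtures.

# Three-index standard: one increasing, one decreasing, one ordinal.
tiny_standard <- function() {
  grade_standard(list(
    index_definition("X1", kind = "quantitative",
                     lo = c(0, 1, 2, 3, 4), hi = c(1, 2, 3, 4, 5)),
    index_definition("X2", kind = "quantitative",
                     lo = c(40, 30, 20, 10, 0), hi = c(50, 40, 30, 20, 10)),
    index_definition("X3", kind = "qualitative")))
}

# Hand-assembled standard with one dominant index per grade and gaps
# between grade intervals. Deliberately bypasses the constructor: grade
# intervals here are NON-contiguous, which read/validation rejects but
# the separation diagnostic needs as its "widely separated" extreme.
onehot_standard <- function(ng = 5) {
  defs <- lapply(seq_len(ng), function(j) {
    lo <- 0.01 * seq_len(ng); hi <- lo + 0.001
    lo[j] <- 100; hi[j] <- 101
    structure(list(id = paste0("X", j), name = paste0("X", j),
                   kind = "quantitative", units = "",
                   lo = lo, hi = hi, n_grades = as.integer(ng)),
              class = "slopeval_index")
  })
  names(defs) <- vapply(defs, `[[`, "", "id")
  structure(list(indexes = defs,
                 grade_labels = as.character(utils::as.roman(seq_len(ng)))),
            class = "grade_standard")
}

# Every grade shares the identical interval: grades are statistically
# indistinguishable. Also bypasses contiguity validation on purpose.
degenerate_standard <- function() {
  d <- structure(list(id = "X1", name = "X1", kind = "quantitative",
                      units = "", lo = rep(0, 5), hi = rep(10, 5),
                      n_grades = 5L), class = "slopeval_index")
  d2 <- d; d2$id <- "X2"
  structure(list(indexes = list(X1 = d, X2 = d2),
                 grade_labels = c("I", "II", "III", "IV", "V")),
            class = "grade_standard")
}

# Known absorbing-endpoint transition matrix and an interior initial
# state, for simulate-then-fit recovery checks.
known_absorbing_matrix <- function() {
  rbind(c(1, 0, 0, 0, 0),
        c(0.3, 0.6, 0.1, 0, 0),
        c(0.05, 0.25, 0.6, 0.1, 0),
        c(0, 0.1, 0.3, 0.5, 0.1),
        c(0, 0, 0, 0, 1))
}

interior_initial <- function() c(0.1, 0.3, 0.3, 0.2, 0.1)

# Calibration generated by propagating a known matrix: list of
# step/observed pairs for r = 1..m.
simulated_calibration <- function(P, init, m = 4) {
  x <- init
  lapply(seq_len(m), function(r) {
    x <<- as.vector(x %*% P)
    list(step = r, observed = x)
  })
}

# Independent brute-force oracle for the fitting objective.
oracle_Q <- function(P, init, calib, epsilon = 1e-6) {
  Q <- 0
  for (cp in calib) {
    x <- init
    for (r in seq_len(cp$step)) x <- as.vector(x %*% P)
    for (k in seq_along(x))
      Q <- Q + abs((cp$observed[k] - x[k]) / max(cp$observed[k], epsilon))
  }
  Q
}

# Published initial modal grades of the seven bundled slopes.
published_initial_modal <- c("III", "III", "III", "II", "IV", "III", "II")
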