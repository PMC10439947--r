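#' Define one evaluation index of a grade standard
#'
#' An index is either *quantitative*, graded by five half-open value
#' intervals `(lo, hi]` (one per grade, jointly contiguous), or
#' *qualitative* (ordinal), graded by the fixed scores `1..n_grades` in
#' grade order. Interval direction may be increasing (larger is worse,
#' e.g. soil erosion intensity) or decreasing (larger is better, e.g.
#' root-soil shear strength); both validate.
#'
#' @param id Short label, e.g. `"X1"`.
#' @param name Free-text description.
#' @param kind `"quantitative"` or `"qualitative"`.
#' @param units Free text, may be empty.
#' @param lo,hi For quantitative indexes, numeric vectors of the interval
#'   bounds per grade (best grade first). Ignored for qualitative indexes,
#'   whose scores are always `1..n_grades`.
#' @param n_grades Number of grades (default 5).
#' @return An object of class `slopeval_index`.
#' @export
index_definition <- function(id, name = id,
                             kind = c("quantitative", "qualitative"),
                             units = "", lo = NULL, hi = NULL,
                             n_grades = 5L) {
  kind <- match.arg(kind)
  n_grades <- as.integer(n_grades)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("index id must be a non-empty string")
  if (kind == "qualitative") {
    lo <- as.numeric(seq_len(n_grades))
    hi <- rep(NA_real_, n_grades)
  } else {
    lo <- as.numeric(lo); hi <- as.numeric(hi)
    if (length(lo) != n_grades || length(hi) != n_grades)
      stopf("index '%s': expected %d grade intervals, got %d/%d",
            id, n_grades, length(lo), length(hi))
    if (anyNA(lo) || anyNA(hi))
      stopf("index '%s': missing interval bound", id)
    if (any(lo < 0) || any(hi < 0))
      stopf("index '%s': negative interval bound", id)
    bad <- which(lo >= hi)
    if (length(bad))
      stopf("index '%s': empty interval (lo >= hi) for grade %d", id, bad[1L])
    # adjacent grades must share an endpoint, consistently in one direction
    if (n_grades > 1L) {
      inc <- all(abs(hi[-n_grades] - lo[-1L]) < 1e-9)
      dec <- all(abs(lo[-n_grades] - hi[-1L]) < 1e-9)
      if (!inc && !dec) {
        g <- if (any(abs(hi[-n_grades] - lo[-1L]) >= 1e-9))
          which(abs(hi[-n_grades] - lo[-1L]) >= 1e-9)[1L] else 1L
        stopf("index '%s': grade intervals not contiguous between grades %d and %d",
              id, g, g + 1L)
      }
    }
  }
  structure(list(id = id, name = name, kind = kind, units = units,
                 lo = lo, hi = hi, n_grades = n_grades),
            class = "slopeval_index")
}

#' Assemble a grade standard from index definitions
#'
#' @param indexes List of [index_definition()] objects (order is kept).
#' @param grade_labels Ordered grade labels, best first.
#' @return Object of class `grade_standard`.
#' @export
grade_standard <- function(indexes,
                           grade_labels = c("I", "II", "III", "IV", "V")) {
  if (inherits(indexes, "slopeval_index")) indexes <- list(indexes)
  if (!length(indexes)) stopf("a grade standard needs at least one index")
  if (!all(vapply(indexes, inherits, TRUE, "slopeval_index")))
    stopf("`indexes` must be a list of index_definition() objects")
  ids <- vapply(indexes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stopf("duplicate index ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(grade_labels)
  bad <- vapply(indexes, function(d) d$n_grades != n, TRUE)
  if (any(bad))
    stopf("index '%s' has %d grades but the standard has %d labels",
          ids[bad][1L], indexes[[which(bad)[1L]]]$n_grades, n)
  names(indexes) <- ids
  structure(list(indexes = indexes, grade_labels = as.character(grade_labels)),
            class = "grade_standard")
}

n_grades <- function(standard) length(standard$grade_labels)

#' Index ids of a grade standard, in order
#' @param standard A [grade_standard()].
#' @return Character vector of index ids.
#' @export
index_ids <- function(standard) names(standard$indexes)
is_qualitative <- function(standard)
  vapply(standard$indexes, function(d) d$kind == "qualitative", TRUE)

#' @export
print.grade_standard <- function(x, ...) {
  cat(sprintf("Grade standard: %d indexes, %d grades (%s)\n",
              length(x$indexes), n_grades(x),
              paste(x$grade_labels, collapse = " > ")))
  for (d in x$indexes) {
    iv <- if (d$kind == "qualitative")
      paste(d$lo, collapse = " ")
    else
      paste(sprintf("(%g,%g]", d$lo, d$hi), collapse = " ")
    cat(sprintf("  %-4s %-12s %s\n", d$id, d$kind, iv))
  }
  invisible(x)
}

#' Construct an evaluation object (an observed or sampled index vector)
#'
#' @param id Label for the object.
#' @param values Numeric vector aligned to `standard`'s index order (a
#'   named vector is re-ordered by name).
#' @param standard A [grade_standard()].
#' @param warn_out_of_range Warn when a value lies outside the union of an
#'   index's grade intervals (such values are accepted: classification
#'   compares by similarity and never bins the target).
#' @return Object of class `evaluation_object`.
#' @export
evaluation_object <- function(id, values, standard, warn_out_of_range = TRUE) {
  ids <- index_ids(standard)
  if (!is.null(names(values))) {
    missing <- setdiff(ids, names(values))
    if (length(missing))
      stopf("object '%s': missing values for index(es) %s",
            id, paste(missing, collapse = ", "))
    values <- values[ids]
  }
  values <- as.numeric(values)
  if (length(values) != length(ids))
    stopf("object '%s': %d values for %d indexes", id, length(values), length(ids))
  if (anyNA(values)) stopf("object '%s': missing or non-numeric value", id)
  if (any(values < 0))
    stopf("object '%s': negative value for index %s",
          id, ids[which(values < 0)[1L]])
  ng <- n_grades(standard)
  for (j in seq_along(ids)) {
    d <- standard$indexes[[j]]
    if (d$kind == "qualitative") {
      if (!(values[j] %in% seq_len(ng)))
        stopf("object '%s': qualitative index %s must score in 1..%d, got %g",
              id, d$id, ng, values[j])
    } else if (warn_out_of_range &&
               (values[j] <= min(d$lo) || values[j] > max(d$hi))) {
      warnf("object '%s': value %g for index %s lies outside the standard's range (%g, %g]",
            id, values[j], d$id, min(d$lo), max(d$hi))
    }
  }
  names(values) <- ids
  structure(list(id = as.character(id), values = values),
            class = "evaluation_object")
}

#' @export
print.evaluation_object <- function(x, ...) {
  cat(sprintf("Evaluation object '%s' (%d indexes)\n", x$id, length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

# Accept an evaluation_object or a bare numeric vector.
object_values <- function(x) {
  if (inherits(x, "evaluation_object")) x$values else as.numeric(x)
}

#' Grade membership of a single index value
#'
#' Diagnostic helper: locates `value` in the index's half-open intervals
#' `(lo, hi]` (a shared endpoint belongs to the interval where it is the
#' upper bound), or matches the ordinal score for qualitative indexes.
#' Classification itself never uses this; it compares whole vectors by
#' similarity.
#'
#' @param index An index id (with `standard` given) or a `slopeval_index`.
#' @param value Numeric value.
#' @param standard Optional [grade_standard()] to resolve an index id and
#'   supply grade labels.
#' @return A grade label, or `NA_character_` when outside every interval.
#' @export
grade_of_value <- function(index, value, standard = NULL) {
  labels <- if (!is.null(standard)) standard$grade_labels
  if (is.character(index)) {
    if (is.null(standard)) stopf("supply `standard` to resolve index id '%s'", index)
    if (!index %in% index_ids(standard)) stopf("unknown index id '%s'", index)
    index <- standard$indexes[[index]]
  }
  labels <- labels %||% as.character(utils::as.roman(seq_len(index$n_grades)))
  g <- if (index$kind == "qualitative")
    which(abs(index$lo - value) < 1e-9)
  else
    which(value > index$lo & value <= index$hi)
  if (length(g) == 1L) labels[g] else NA_character_
}

# ---- delimited-text readers/writers -----------------------------------------

# `source` may be a path or literal text (one string with newlines, or a
# character vector of lines).
read_delim_source <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      !grepl("\n", source) && file.exists(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  } else {
    utils::read.csv(text = paste(source, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  }
}

#' Read a grade standard from delimited text
#'
#' Expected columns: `index_id,name,kind,units,g1_lo,g1_hi,...,gN_lo,gN_hi`
#' with `kind` one of `quantitative`/`qualitative`. For qualitative rows
#' the `g*_lo` fields hold the ordinal scores and `g*_hi` stay empty.
#'
#' @param source File path, the file's content as text, or an equivalent
#'   structured config: a list of per-index lists carrying the same keys
#'   (e.g. parsed from JSON).
#' @return A validated [grade_standard()]; row order preserved.
#' @export
read_grade_standard <- function(source) {
  df <- if (is.list(source) && !is.data.frame(source)) {
    do.call(rbind, lapply(source, function(row)
      as.data.frame(lapply(row, as.character), check.names = FALSE)))
  } else read_delim_source(source)
  need <- c("index_id", "name", "kind", "units")
  if (!all(need %in% names(df)))
    stopf("grade-standard file: missing column(s) %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  gcols <- grep("^g[0-9]+_lo$", names(df), value = TRUE)
  ng <- length(gcols)
  if (ng < 1L) stopf("grade-standard file: no g<k>_lo columns found")
  num <- function(v, what, row) {
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out) && nzchar(trimws(v)))
      stopf("grade-standard file row %d: non-numeric %s '%s'", row, what, v)
    out
  }
  defs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    kind <- match.arg(trimws(row$kind), c("quantitative", "qualitative"))
    if (kind == "qualitative") {
      scores <- vapply(seq_len(ng), function(g)
        num(row[[sprintf("g%d_lo", g)]], "score", i), 0)
      if (!identical(as.numeric(scores), as.numeric(seq_len(ng))))
        stopf("index '%s': qualitative scores must be %s in grade order, got %s",
              row$index_id, paste(seq_len(ng), collapse = " "),
              paste(scores, collapse = " "))
      index_definition(row$index_id, row$name, "qualitative", row$units,
                       n_grades = ng)
    } else {
      lo <- vapply(seq_len(ng), function(g)
        num(row[[sprintf("g%d_lo", g)]], "bound", i), 0)
      hi <- vapply(seq_len(ng), function(g)
        num(row[[sprintf("g%d_hi", g)]], "bound", i), 0)
      index_definition(row$index_id, row$name, "quantitative", row$units,
                       lo = lo, hi = hi, n_grades = ng)
    }
  })
  grade_standard(defs, grade_labels = as.character(utils::as.roman(seq_len(ng))))
}

#' Write a grade standard as delimited text
#'
#' @param standard A [grade_standard()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grade_standard <- function(standard, path) {
  ng <- n_grades(standard)
  rows <- lapply(standard$indexes, function(d) {
    v <- c(index_id = d$id, name = d$name, kind = d$kind, units = d$units)
    for (g in seq_len(ng)) {
      v[sprintf("g%d_lo", g)] <- format(d$lo[g], digits = 15)
      v[sprintf("g%d_hi", g)] <- if (d$kind == "qualitative") "" else
        format(d$hi[g], digits = 15)
    }
    as.data.frame(as.list(v), check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read evaluation objects from delimited text
#'
#' Expected columns: `object_id` plus one column per index id of
#' `standard` (order-insensitive; values are re-ordered to the standard).
#'
#' @param source File path, or the file's content as text.
#' @param standard A [grade_standard()].
#' @return List of [evaluation_object()]s (possibly empty).
#' @export
read_objects <- function(source, standard) {
  df <- read_delim_source(source)
  if (!"object_id" %in% names(df))
    stopf("objects file: missing column 'object_id'")
  ids <- index_ids(standard)
  missing <- setdiff(ids, names(df))
  if (length(missing))
    stopf("objects file: missing index column(s) %s",
          paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(ids, function(ix) {
      v <- suppressWarnings(as.numeric(df[i, ix]))
      if (is.na(v))
        stopf("objects file row %d, column %s: non-numeric value '%s'",
              i, ix, df[i, ix])
      v
    }, 0)
    evaluation_object(df$object_id[i], vals, standard)
  })
}

#' Write evaluation objects as delimited text
#'
#' @param objects List of [evaluation_object()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_objects <- function(objects, path) {
  df <- do.call(rbind, lapply(objects, function(o)
    cbind(data.frame(object_id = o$id),
          as.data.frame(as.list(o$values), check.names = FALSE))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- bundled engineering fixtures -------------------------------------------

#' Bundled grading standard for slope ecological restoration
#'
#' The published five-grade standard over 15 condition indexes: soil and
#' water conservation (root-soil composite shear strength X1, permeability
#' X2, soil erosion intensity X3, root weight density X4), ecology
#' (vegetation coverage X5, drought resistance X6, Shannon-Wiener
#' diversity X7, Pielou evenness X8), substrate chemistry (organic matter
#' X9, available N/P/K X10-X12, soil bulk density X13) and landscape
#' (coordination X14, visitor capacity X15). X6, X14 and X15 are ordinal
#' with scores 1-5.
#'
#' @return A [grade_standard()].
#' @export
slope_standard <- function() {
  read_grade_standard(system.file("extdata", "slope_restoration_standard.csv",
                                  package = "slopeval", mustWork = TRUE))
}

#' Bundled index data of seven restored engineering slopes
#'
#' Observed index vectors for seven mining-slope restoration projects
#' treated with different restoration technologies.
#'
#' @return List of seven [evaluation_object()]s named `"1"`..`"7"`.
#' @export
slope_sites <- function() {
  read_objects(system.file("extdata", "slope_restoration_sites.csv",
                           package = "slopeval", mustWork = TRUE),
               slope_standard())
}
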