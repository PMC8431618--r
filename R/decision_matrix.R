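#' Criterion direction specification
#'
#' A criterion is *beneficial* when larger values are better (accuracy,
#' sensitivity, specificity, F1, precision, MCC) and *non-beneficial* when
#' smaller values are better (classification error, false-positive and
#' false-negative rates, parameter count). Directions travel with the
#' decision matrix so downstream methods never re-infer them.
#'
#' @param names Character vector of unique criterion names.
#' @param direction Character vector, each `"beneficial"` or
#'   `"non_beneficial"`, recycled if length 1.
#' @return A data frame of class `criterion_spec` with columns `name`,
#'   `direction`.
#' @export
criterion_spec <- function(names, direction) {
  direction <- rep_len(direction, length(names))
  if (anyDuplicated(names)) {
    stop("criterion names must be unique", call. = FALSE)
  }
  bad <- setdiff(direction, c("beneficial", "non_beneficial"))
  if (length(bad)) {
    stop("unknown direction(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(
    data.frame(name = as.character(names), direction = direction,
               stringsAsFactors = FALSE),
    class = c("criterion_spec", "data.frame")
  )
}

#' Default directions for the ten benchmarking criteria
#'
#' @return A [criterion_spec] for the criteria of [criterion_names]:
#'   error, FPR, FNR and parameter count are non-beneficial, the rest
#'   beneficial.
#' @export
default_criteria <- function() {
  nm <- criterion_names()
  criterion_spec(
    nm,
    ifelse(nm %in% c("err", "fpr", "fnr", "n_params"),
           "non_beneficial", "beneficial")
  )
}

#' Construct a decision matrix
#'
#' An alternatives-by-criteria grid of strictly positive values carrying
#' direction metadata. At least two alternatives are required (ranking a
#' single alternative is vacuous) and no cell may be missing, zero or
#' negative: ratio normalization divides by the cell values of
#' non-beneficial columns.
#'
#' @param x Numeric matrix or data frame; rows are alternatives (rownames
#'   required, or taken from the first character column), columns criteria.
#' @param criteria A [criterion_spec] covering exactly the columns of `x`; by
#'   default all columns are treated as beneficial.
#' @return An object of class `decision_matrix`: the numeric matrix with a
#'   `criteria` attribute.
#' @examples
#' dm <- decision_matrix(rbind(a = c(x = 1, y = 4), b = c(x = 2, y = 3)),
#'                       criterion_spec(c("x", "y"), "beneficial"))
#' @export
decision_matrix <- function(x, criteria = NULL) {
  if (is.data.frame(x)) {
    chr <- vapply(x, is.character, logical(1))
    if (any(chr)) {
      ids <- x[[which(chr)[1]]]
      x <- as.matrix(x[, !chr, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(x) < 2L) {
    stop("a decision matrix needs at least two alternatives", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("alt%02d", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    stop("criterion columns must be named", call. = FALSE)
  }
  if (is.null(criteria)) {
    criteria <- criterion_spec(colnames(x), "beneficial")
  }
  stopifnot(inherits(criteria, "criterion_spec"))
  if (!identical(sort(criteria$name), sort(colnames(x)))) {
    stop("criterion spec does not match matrix columns", call. = FALSE)
  }
  x <- x[, criteria$name, drop = FALSE]
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("decision matrix requires strictly positive finite values; ",
         "offending cell: alternative '", rownames(x)[bad[1, 1]],
         "', criterion '", colnames(x)[bad[1, 2]], "'", call. = FALSE)
  }
  structure(x, criteria = criteria, class = c("decision_matrix", "matrix"))
}

#' Assemble the decision matrix from fold summaries
#'
#' Builds the alternatives-by-criteria grid from per-alternative
#' cross-validation summaries: nine criterion columns take the fold means
#' (percent scale, matching the reporting convention) and the tenth takes the
#' per-model parameter count in millions.
#'
#' @param summaries Named list of `fold_summary` objects covering every
#'   criterion mean.
#' @param n_params Named numeric vector of parameter counts (millions); may
#'   be omitted when the summaries already carry a finite `n_params` mean.
#' @param criteria A [criterion_spec]; defaults to [default_criteria()].
#' @return A [decision_matrix].
#' @export
build_decision_matrix <- function(summaries, n_params = NULL,
                                  criteria = default_criteria()) {
  if (length(summaries) < 2L) {
    stop("a decision matrix needs at least two alternatives", call. = FALSE)
  }
  alts <- names(summaries)
  pct <- setdiff(criteria$name, "n_params")
  grid <- t(vapply(alts, function(a) {
    mu <- summaries[[a]]$mean
    absent <- setdiff(pct, names(mu))
    if (length(absent)) {
      stop("alternative '", a, "' lacks criterion mean(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    v <- 100 * mu[pct]
    if ("n_params" %in% criteria$name) {
      np <- if (!is.null(n_params)) unname(n_params[a]) else
        unname(mu["n_params"])
      if (length(np) != 1L || !is.finite(np)) {
        stop("missing parameter count for alternative '", a, "'",
             call. = FALSE)
      }
      v <- c(v, n_params = np)
    }
    v
  }, numeric(length(criteria$name))))
  colnames(grid) <- criteria$name
  rownames(grid) <- alts
  decision_matrix(grid, criteria)
}

#' Direction-aware min/max (ratio) normalization
#'
#' Rescales every column onto (0, 1] so that all criteria become
#' max-oriented: beneficial columns are divided by their column maximum,
#' non-beneficial columns are replaced by column-minimum over value. Each
#' column attains 1 exactly at its direction-appropriate optimum. Column
#' extremes are taken over the supplied alternatives only.
#'
#' @param dm A [decision_matrix] with all entries strictly positive.
#' @return A `normalized_decision_matrix` (also a `decision_matrix`); its
#'   `criteria` attribute marks every column beneficial since all columns are
#'   max-oriented after normalization, and the original spec is kept in the
#'   `original_criteria` attribute.
#' @export
normalize_decision_matrix <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (inherits(dm, "normalized_decision_matrix")) {
    return(dm)
  }
  criteria <- attr(dm, "criteria")
  x <- unclass(dm)
  attr(x, "criteria") <- NULL
  out <- x
  for (j in seq_len(ncol(x))) {
    if (criteria$direction[j] == "beneficial") {
      out[, j] <- x[, j] / max(x[, j])
    } else {
      out[, j] <- min(x[, j]) / x[, j]
    }
  }
  structure(
    out,
    criteria = criterion_spec(criteria$name, "beneficial"),
    original_criteria = criteria,
    class = c("normalized_decision_matrix", "decision_matrix", "matrix")
  )
}

#' @export
print.decision_matrix <- function(x, digits = 4, ...) {
  criteria <- attr(x, "criteria")
  kind <- if (inherits(x, "normalized_decision_matrix")) {
    "Normalized decision matrix"
  } else {
    "Decision matrix"
  }
  cat(kind, ": ", nrow(x), " alternatives x ", ncol(x), " criteria\n",
      sep = "")
  nb <- criteria$name[criteria$direction == "non_beneficial"]
  if (length(nb)) {
    cat("Non-beneficial criteria:", paste(nb, collapse = ", "), "\n")
  }
  print(round(unclass(x), digits))
  invisible(x)
}

#' Read a decision matrix from CSV
#'
#' First column: alternative ids; header: criterion names. Directions come
#' from a config list `criteria = list(list(name=, direction=), ...)`, a
#' [criterion_spec], or default to [default_criteria()] when the header
#' matches the ten standard criteria.
#'
#' @param path CSV path.
#' @param criteria Optional [criterion_spec] or config-style list of
#'   `{name, direction}` entries.
#' @return A [decision_matrix].
#' @export
read_decision_matrix <- function(path, criteria = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.list(criteria) && !inherits(criteria, "criterion_spec")) {
    criteria <- criterion_spec(
      vapply(criteria, `[[`, character(1), "name"),
      vapply(criteria, `[[`, character(1), "direction")
    )
  }
  if (is.null(criteria) &&
      setequal(names(df)[-1], criterion_names())) {
    criteria <- default_criteria()
  }
  decision_matrix(df, criteria)
}

#' Write a (normalized) decision matrix as CSV
#'
#' @param dm A [decision_matrix].
#' @param path Output path.
#' @param digits Rounding applied at write time (normalized matrices are
#'   conventionally reported at 4 decimal places); `NULL` writes full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path, digits = NULL) {
  x <- unclass(dm)
  if (!is.null(digits)) x <- round(x, digits)
  df <- data.frame(alternative = rownames(x), x, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
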