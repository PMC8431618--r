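#' Entropy weights for the criteria of a decision matrix
#'
#' Objective criterion weighting by Shannon entropy. Each column is first
#' turned into a discrete distribution `p_ij = x_ij / sum_i(x_ij)`; the
#' column entropy `e_j = -(1/ln m) * sum_i p_ij ln p_ij` lies in \[0, 1\];
#' the contrast intensity `d_j = 1 - e_j` grows with the column's
#' dispersion; and the weights are the normalized contrasts
#' `w_j = d_j / sum(d_j)`. A criterion on which all alternatives agree
#' (uniform column) has maximum entropy and receives weight zero. The
#' convention `p ln p = 0` at `p = 0` is applied.
#'
#' @param matrix A [decision_matrix] (typically normalized) with
#'   non-negative entries; `m >= 2` alternatives.
#' @return A `weight_vector`: named numeric weights (non-negative, summing
#'   to 1) with attributes `provenance = "entropy"` and the intermediates
#'   `p` (column-stochastic grid), `e`, `d`, and `g = 1/ln(m)`.
#' @examples
#' dm <- decision_matrix(cbind(x = c(0.5, 0.3, 0.2), y = c(0.2, 0.3, 0.5)))
#' entropy_weights(dm)
#' @export
entropy_weights <- function(matrix) {
  x <- unclass(matrix)
  attr(x, "criteria") <- NULL
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`matrix` must be numeric", call. = FALSE)
  }
  m <- nrow(x)
  if (m < 2L) stop("entropy weighting needs at least two alternatives",
                   call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("entropy weighting requires finite non-negative entries",
         call. = FALSE)
  }
  g <- 1 / log(m)
  p <- sweep(x, 2, colSums(x), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -g * colSums(plogp)
  d <- 1 - e
  # guard tiny negative d from rounding on near-uniform columns
  d[d < 0 & d > -1e-12] <- 0
  if (sum(d) <= 0) {
    stop("no discriminating criterion: every column is uniform",
         call. = FALSE)
  }
  w <- d / sum(d)
  structure(w, provenance = "entropy", p = p, e = e, d = d, g = g,
            class = "weight_vector")
}

#' Store an externally supplied weight vector
#'
#' Weights obtained outside the entropy routine (e.g. transcribed from a
#' published analysis) are stored verbatim, signs included; the outranking
#' and compromise methods decide whether to use signed values or magnitudes.
#'
#' @param values Numeric weights, one per criterion, all finite, not all
#'   zero.
#' @param criteria Criterion names; defaults to `names(values)`.
#' @return A `weight_vector` with `provenance = "user_supplied"`.
#' @export
load_weights <- function(values, criteria = names(values)) {
  if (is.null(criteria)) {
    stop("criterion names are required", call. = FALSE)
  }
  if (length(values) != length(criteria)) {
    stop("got ", length(values), " weights for ", length(criteria),
         " criteria", call. = FALSE)
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("weights must be finite", call. = FALSE)
  if (all(values == 0)) stop("weights must not be all zero", call. = FALSE)
  structure(stats::setNames(values, criteria),
            provenance = "user_supplied", class = "weight_vector")
}

#' Magnitudes of a weight vector
#'
#' @param w A `weight_vector`.
#' @return The same vector with absolute values (provenance preserved).
#' @export
weight_magnitudes <- function(w) {
  structure(abs(unclass(w)), provenance = attr(w, "provenance"),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Criterion weights (", attr(x, "provenance"), "):\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Read a `{criterion: weight}` map from JSON or CSV
#'
#' JSON: an object mapping criterion names to numbers. CSV: columns
#' `criterion`, `weight`.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return A `weight_vector` with `provenance = "user_supplied"`.
#' @export
read_weights <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    load_weights(unlist(obj))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("criterion", "weight") %in% names(df))) {
      stop("'", path, "' must have columns `criterion`, `weight`",
           call. = FALSE)
    }
    load_weights(df$weight, df$criterion)
  }
}
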