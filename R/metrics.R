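#' Confusion-matrix cell counts for binary predictions
#'
#' Tallies the four cells of a binary contingency table (true/false
#' positives/negatives) from hard-label predictions. Labels are arbitrary
#' (e.g. `"melanoma"` / `"non-melanoma"`); the positive class is always
#' supplied by the caller and never inferred from sort order.
#'
#' @param y_true Vector of true class labels (two-value alphabet).
#' @param y_pred Vector of predicted class labels, same length and alphabet.
#' @param positive The label counted as the positive class. Must occur in the
#'   label alphabet.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `tn`, `fp`, `fn` summing to `length(y_true)`.
#' @examples
#' confusion_counts(c("m", "m", "b", "b"), c("m", "b", "b", "b"), positive = "m")
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) == 0L) {
    stop("`y_true` must be non-empty", call. = FALSE)
  }
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length (",
         length(y_true), " vs ", length(y_pred), ")", call. = FALSE)
  }
  alphabet <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(alphabet) > 2L) {
    stop("labels must be drawn from a two-value alphabet; found: ",
         paste(alphabet, collapse = ", "), call. = FALSE)
  }
  if (!as.character(positive) %in% alphabet) {
    stop("`positive` label '", positive, "' does not occur in the data",
         call. = FALSE)
  }
  tpos <- as.character(y_true) == as.character(positive)
  ppos <- as.character(y_pred) == as.character(positive)
  structure(
    list(
      tp = sum(tpos & ppos),
      tn = sum(!tpos & !ppos),
      fp = sum(!tpos & ppos),
      fn = sum(tpos & !ppos)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: tp =", x$tp, " tn =", x$tn,
      " fp =", x$fp, " fn =", x$fn, "\n")
  invisible(x)
}

#' The ten benchmarking criteria of one classifier on one fold
#'
#' Evaluates accuracy, classification error, precision, sensitivity, F1-score,
#' specificity, false-positive rate, false-negative rate and the Matthews
#' correlation coefficient from confusion counts, plus the model-complexity
#' criterion (parameter count in millions). All rates are returned as
#' fractions in \[0, 1\] (MCC in \[-1, 1\]); reporting helpers convert to the
#' percent scale.
#'
#' Degenerate denominators follow the common conventions: precision is 0 when
#' no positive prediction was made (`tp + fp = 0`), F1 is 0 when
#' `precision + sensitivity = 0`, and MCC is 0 when any of the four marginals
#' is zero (a constant truth or constant prediction carries no correlation
#' signal).
#'
#' @param counts A [confusion_counts] object with a positive total.
#' @param n_params Model complexity, in millions of parameters (`NA` if the
#'   complexity criterion is not used).
#' @return A named numeric vector of class `criterion_vector` with elements
#'   `acc`, `sen`, `spe`, `f1`, `fnr`, `fpr`, `pre`, `mcc`, `err`, `n_params`.
#' @examples
#' cc <- confusion_counts(rep(c("m", "b"), each = 4),
#'                        rep(c("m", "b"), each = 4), positive = "m")
#' criterion_vector(cc, n_params = 25.6)
#' @export
criterion_vector <- function(counts, n_params = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n <= 0) stop("confusion counts are all zero", call. = FALSE)

  acc <- (tp + tn) / n
  err <- 1 - acc
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sen <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spe <- if (tn + fp == 0) 0 else tn / (tn + fp)
  fpr <- 1 - spe
  fnr <- 1 - sen
  f1  <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(marg))
  }

  structure(
    c(acc = acc, sen = sen, spe = spe, f1 = f1, fnr = fnr, fpr = fpr,
      pre = pre, mcc = mcc, err = err, n_params = as.numeric(n_params)),
    class = "criterion_vector"
  )
}

#' Names of the ten benchmarking criteria
#'
#' Canonical criterion order used throughout the package: accuracy,
#' sensitivity, specificity, F1-score, false-negative rate, false-positive
#' rate, precision, Matthews correlation coefficient, classification error,
#' and parameter count (millions).
#'
#' @return Character vector of length 10.
#' @export
criterion_names <- function() {
  c("acc", "sen", "spe", "f1", "fnr", "fpr", "pre", "mcc", "err", "n_params")
}

#' Aggregate per-fold criterion vectors to mean and standard deviation
#'
#' Cross-validation summary in the usual "mean +/- sd" form: the arithmetic
#' mean and the sample standard deviation (n - 1 denominator) of each
#' criterion over the folds. With a single fold the standard deviation is
#' undefined and reported as `NA`.
#'
#' @param per_fold A list of [criterion_vector]s (or a numeric matrix with one
#'   row per fold and criterion columns) sharing an identical criterion set.
#' @return An object of class `fold_summary`: a list with named numeric
#'   vectors `mean` and `sd` and the integer `n_folds`.
#' @examples
#' acc <- c(81.82, 94.44, 96.97, 98.99, 99.49) / 100
#' folds <- lapply(acc, function(a)
#'   structure(c(acc = a), class = "criterion_vector"))
#' aggregate_folds(folds)
#' @export
aggregate_folds <- function(per_fold) {
  if (is.matrix(per_fold)) {
    m <- per_fold
  } else {
    if (length(per_fold) == 0L) stop("no folds supplied", call. = FALSE)
    nm <- names(unclass(per_fold[[1]]))
    same <- vapply(per_fold, function(v) identical(names(unclass(v)), nm),
                   logical(1))
    if (!all(same)) {
      stop("folds carry different criterion sets", call. = FALSE)
    }
    m <- do.call(rbind, lapply(per_fold, unclass))
  }
  if (nrow(m) == 0L) stop("no folds supplied", call. = FALSE)
  structure(
    list(
      mean = colMeans(m),
      sd = apply(m, 2, function(col) if (length(col) < 2) NA_real_ else stats::sd(col)),
      n_folds = nrow(m)
    ),
    class = "fold_summary"
  )
}

#' @export
print.fold_summary <- function(x, digits = 2, ...) {
  cat("Fold summary over", x$n_folds, "folds (mean +/- sd):\n")
  out <- sprintf("%.*f +/- %s", digits, x$mean,
                 ifelse(is.na(x$sd), "NA", sprintf("%.*f", digits, x$sd)))
  names(out) <- names(x$mean)
  print(noquote(out))
  invisible(x)
}

#' Per-fold criteria from a labeled prediction table
#'
#' Workhorse for the metrics stage: takes a long prediction table (one row per
#' evaluated case) and computes the ten criteria per alternative and fold,
#' then the per-alternative fold summaries.
#'
#' @param predictions A data frame with columns `alternative`, `fold`,
#'   `y_true`, `y_pred` (see [read_predictions]).
#' @param positive The positive-class label.
#' @param n_params Optional named numeric vector of per-alternative parameter
#'   counts (millions); names must cover every alternative.
#' @return A list with `per_fold` (data frame of criteria per alternative and
#'   fold, fraction scale) and `summaries` (named list of [aggregate_folds]
#'   results, one per alternative).
#' @export
fold_metrics <- function(predictions, positive, n_params = NULL) {
  required <- c("alternative", "fold", "y_true", "y_pred")
  missing_cols <- setdiff(required, names(predictions))
  if (length(missing_cols)) {
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  alts <- unique(as.character(predictions$alternative))
  if (!is.null(n_params)) {
    absent <- setdiff(alts, names(n_params))
    if (length(absent)) {
      stop("`n_params` missing for alternative(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  rows <- list()
  summaries <- list()
  for (a in alts) {
    sub <- predictions[predictions$alternative == a, , drop = FALSE]
    folds <- sort(unique(sub$fold))
    cvs <- lapply(folds, function(f) {
      fd <- sub[sub$fold == f, , drop = FALSE]
      cc <- confusion_counts(fd$y_true, fd$y_pred, positive)
      criterion_vector(cc, if (is.null(n_params)) NA_real_ else n_params[[a]])
    })
    summaries[[a]] <- aggregate_folds(cvs)
    rows[[a]] <- data.frame(
      alternative = a, fold = folds,
      do.call(rbind, lapply(cvs, unclass)),
      row.names = NULL, check.names = FALSE
    )
  }
  list(per_fold = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       summaries = summaries)
}

#' Read a predictions CSV
#'
#' Expected columns: `alternative`, `fold`, `y_true`, `y_pred`; labels are
#' arbitrary strings.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("alternative", "fold", "y_true", "y_pred")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("'", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Fold-summary table on the percent scale
#'
#' Renders per-alternative fold summaries as one row per alternative with
#' `mean_*` / `sd_*` column pairs. Rates and MCC are multiplied by 100
#' (MCC is reported on the percent scale as well, stated here to avoid
#' ambiguity); the parameter count stays in millions.
#'
#' @param summaries Named list of `fold_summary` objects (from
#'   [fold_metrics]).
#' @return A data frame with an `alternative` column and `mean_`/`sd_` pairs.
#' @export
summary_table <- function(summaries) {
  crit <- names(summaries[[1]]$mean)
  pct <- setdiff(crit, "n_params")
  rows <- lapply(names(summaries), function(a) {
    s <- summaries[[a]]
    mu <- s$mean; sd <- s$sd
    mu[pct] <- 100 * mu[pct]
    sd[pct] <- 100 * sd[pct]
    out <- as.list(c(stats::setNames(mu, paste0("mean_", crit)),
                     stats::setNames(sd, paste0("sd_", crit))))
    data.frame(alternative = a, out, check.names = FALSE)
  })
  do.call(rbind, rows)
}
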