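#' Stratified k-fold test/train sizes
#'
#' Plans a stratified k-fold split for a two-class data set: per class, fold
#' sizes differ by at most one, with the larger folds placed first
#' (deterministic remainder rule). Each fold serves once as the test set;
#' the complement trains. For 491 positives / 500 negatives in five folds
#' this yields test folds of 99,98,98,98,98 positives and 100 each
#' negatives, i.e. four of the five training cycles hold 393 positives and
#' one holds 392 — the per-class arithmetic of a balanced melanoma
#' benchmark.
#'
#' @param n_pos,n_neg Class totals; each must be at least `folds`.
#' @param folds Number of folds (>= 2).
#' @return A data frame with one row per fold: `fold`, `test_pos`,
#'   `test_neg`, `train_pos`, `train_neg`.
#' @examples
#' stratified_fold_sizes(491, 500, 5)
#' @export
stratified_fold_sizes <- function(n_pos, n_neg, folds) {
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (n_pos < folds || n_neg < folds) {
    stop("each class needs at least one case per fold (", n_pos, "/",
         n_neg, " cases, ", folds, " folds)", call. = FALSE)
  }
  split_class <- function(n) {
    base <- n %/% folds
    rem <- n %% folds
    base + as.integer(seq_len(folds) <= rem)
  }
  test_pos <- split_class(n_pos)
  test_neg <- split_class(n_neg)
  data.frame(
    fold = seq_len(folds),
    test_pos = test_pos, test_neg = test_neg,
    train_pos = n_pos - test_pos, train_neg = n_neg - test_neg
  )
}

#' Specification of a synthetic binary classifier
#'
#' @param model Model id.
#' @param sensitivity,specificity True per-class correctness probabilities
#'   in \[0, 1\].
#' @param n_params Parameter count in millions (complexity criterion).
#' @return A one-row data frame; rbind several to form a spec table.
#' @export
synthetic_model_spec <- function(model, sensitivity, specificity,
                                 n_params = NA_real_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  data.frame(model = as.character(model), sensitivity = sensitivity,
             specificity = specificity, n_params = n_params,
             stringsAsFactors = FALSE)
}

#' Simulate fold-wise predictions of planted-performance classifiers
#'
#' Emulates binary classifiers with known operating characteristics
#' evaluated over stratified folds: in every test fold, each positive case
#' is predicted positive independently with probability equal to the
#' model's sensitivity, and each negative predicted negative with
#' probability equal to its specificity. Draws are independent Bernoulli
#' per case and per model — no correlation structure across models (real
#' benchmarks share test cases, which induces correlation; that is out of
#' scope here). The RNG state is saved and restored, so the simulation is
#' reproducible from `seed` without disturbing the caller's random stream.
#'
#' @param specs Data frame of model specs (see [synthetic_model_spec]).
#' @param n_pos,n_neg Per-class totals across all folds.
#' @param folds Number of folds.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @param positive,negative Labels used in the output.
#' @return A predictions data frame with columns `alternative`, `fold`,
#'   `y_true`, `y_pred` (one row per model, fold and test case).
#' @export
simulate_predictions <- function(specs, n_pos, n_neg, folds = 5L, seed = 1L,
                                 positive = "melanoma",
                                 negative = "non-melanoma") {
  stopifnot(is.data.frame(specs),
            all(c("model", "sensitivity", "specificity") %in% names(specs)))
  plan <- stratified_fold_sizes(n_pos, n_neg, folds)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  rows <- vector("list", nrow(specs) * folds)
  k <- 0L
  for (i in seq_len(nrow(specs))) {
    for (f in seq_len(folds)) {
      np <- plan$test_pos[f]; nn <- plan$test_neg[f]
      pred_pos <- ifelse(stats::runif(np) < specs$sensitivity[i],
                         positive, negative)
      pred_neg <- ifelse(stats::runif(nn) < specs$specificity[i],
                         negative, positive)
      k <- k + 1L
      rows[[k]] <- data.frame(
        alternative = specs$model[i], fold = f,
        y_true = c(rep(positive, np), rep(negative, nn)),
        y_pred = c(pred_pos, pred_neg),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Random decision matrix with a planted dominant alternative
#'
#' Generates an m-by-k decision matrix of random positive values in which
#' one designated alternative is strictly best on every criterion,
#' direction-aware: strictly larger than all others on beneficial columns,
#' strictly smaller on non-beneficial ones. Such an alternative must come
#' out rank 1 under PROMETHEE and attain Q = 0 under VIKOR — the planted
#' structure used to validate the ranking stack end to end.
#'
#' @param m Number of alternatives (>= 2).
#' @param k Number of criteria (>= 1).
#' @param seed Integer seed (RNG state restored on exit).
#' @param criteria Optional [criterion_spec] of length `k`; defaults to all
#'   beneficial.
#' @param winner Row index of the dominant alternative (default 1).
#' @return A [decision_matrix] with attribute `winner` (the dominant
#'   alternative's id).
#' @export
planted_dominance_matrix <- function(m, k, seed = 1L, criteria = NULL,
                                     winner = 1L) {
  stopifnot(m >= 2, k >= 1, winner >= 1, winner <= m)
  if (is.null(criteria)) {
    criteria <- criterion_spec(sprintf("c%02d", seq_len(k)), "beneficial")
  }
  stopifnot(nrow(criteria) == k)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  x <- base::matrix(stats::runif(m * k, 0.5, 1.5), m, k,
                    dimnames = list(sprintf("alt%02d", seq_len(m)),
                                    criteria$name))
  for (j in seq_len(k)) {
    others <- x[-winner, j]
    x[winner, j] <- if (criteria$direction[j] == "beneficial") {
      max(others) * 1.1
    } else {
      min(others) * 0.9
    }
  }
  dm <- decision_matrix(x, criteria)
  attr(dm, "winner") <- rownames(x)[winner]
  dm
}
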