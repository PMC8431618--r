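#' The bundled melanoma CNN benchmarking case study
#'
#' Loads the packaged transcription of a published benchmark of 19
#' ImageNet-pretrained CNN architectures fine-tuned for binary melanoma
#' diagnosis on balanced dermoscopic-image folds: per-model parameter
#' counts, fold-averaged criterion means and standard deviations (percent
#' scale, MCC included), per-fold test accuracies, the published normalized
#' decision matrix (4 decimal places), the published ten-criterion weight
#' vector (stored verbatim, signs included), and the published PROMETHEE
#' net flows, VIKOR Q values and both rank columns. Unicode minus signs in
#' the source tables were normalized to ASCII at transcription time.
#'
#' @return A list with elements `n_params` (named vector, millions),
#'   `summary` (data frame of `mean_*`/`sd_*` pairs), `fold_acc` (data
#'   frame, percent), `normalized` (a `normalized_decision_matrix`),
#'   `weights` (a `weight_vector`, user-supplied provenance), and
#'   `rankings` (data frame with `phi`, `q`, `rank_promethee`,
#'   `rank_vikor`).
#' @examples
#' cs <- cnn_case_study()
#' cs$rankings[cs$rankings$rank_promethee == 1, ]
#' @export
cnn_case_study <- function() {
  path <- function(f) system.file("extdata", f, package = "mcdmbench",
                                  mustWork = TRUE)
  params <- utils::read.csv(path("cnn_parameter_counts.csv"),
                            stringsAsFactors = FALSE)
  summary <- utils::read.csv(path("cnn_criterion_summary.csv"),
                             stringsAsFactors = FALSE)
  fold_acc <- utils::read.csv(path("cnn_fold_accuracies.csv"),
                              stringsAsFactors = FALSE)
  norm_df <- utils::read.csv(path("cnn_normalized_matrix.csv"),
                             stringsAsFactors = FALSE)
  weights_df <- utils::read.csv(path("cnn_weights.csv"),
                                stringsAsFactors = FALSE)
  rankings <- utils::read.csv(path("cnn_rankings.csv"),
                              stringsAsFactors = FALSE)

  norm_mat <- as.matrix(norm_df[, -1])
  rownames(norm_mat) <- norm_df$model
  normalized <- structure(
    norm_mat,
    criteria = criterion_spec(colnames(norm_mat), "beneficial"),
    original_criteria = default_criteria(),
    class = c("normalized_decision_matrix", "decision_matrix", "matrix")
  )

  list(
    n_params = stats::setNames(params$n_params, params$model),
    summary = summary,
    fold_acc = fold_acc,
    normalized = normalized,
    weights = load_weights(weights_df$weight, weights_df$criterion),
    rankings = rankings
  )
}

#' Rebuild the case-study decision matrix from criterion means
#'
#' Assembles the raw 19 x 10 decision matrix from the case study's
#' fold-averaged criterion means (percent scale) and parameter counts —
#' the grid the normalized matrix derives from.
#'
#' @param cs A case-study list from [cnn_case_study()]; loaded fresh when
#'   omitted.
#' @return A [decision_matrix] with [default_criteria()] directions.
#' @export
cnn_case_study_matrix <- function(cs = cnn_case_study()) {
  crit <- setdiff(criterion_names(), "n_params")
  grid <- as.matrix(cs$summary[, paste0("mean_", crit)])
  colnames(grid) <- crit
  grid <- cbind(grid, n_params = cs$n_params[cs$summary$model])
  rownames(grid) <- cs$summary$model
  decision_matrix(grid, default_criteria())
}
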