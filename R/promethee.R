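#' Pairwise global preference index
#'
#' For every ordered pair of alternatives (a, b), applies the usual
#' (threshold) preference function to the per-criterion deviations
#' `d_j(a, b) = x_aj - x_bj` and aggregates with the criterion weights:
#' `pi(a, b) = sum_j w_j P_j(a, b)` where `P_j = 1` iff `d_j > 0`. At a tie
#' (`d = 0`) the preference is 0, the standard "usual criterion" convention;
#' it is also what makes `pi(a, a) = 0`.
#'
#' @param matrix A `normalized_decision_matrix` (all columns max-oriented).
#' @param weights A `weight_vector` aligned with the matrix columns.
#' @param weight_signs `"magnitude"` (default) uses `|w_j|`; `"signed"` uses
#'   the weights as stored (for sensitivity analysis only — negative weights
#'   break the usual flow interpretation).
#' @return An m-by-m matrix `pi` with zero diagonal;
#'   `0 <= pi(a,b) <= sum|w|` under magnitudes.
#' @export
pairwise_preference_table <- function(matrix, weights,
                                      weight_signs = c("magnitude", "signed")) {
  weight_signs <- match.arg(weight_signs)
  x <- unclass(matrix)
  attr(x, "criteria") <- NULL
  m <- nrow(x)
  if (m < 2L) stop("need at least two alternatives", call. = FALSE)
  w <- align_weights(weights, colnames(x))
  if (weight_signs == "magnitude") w <- abs(w)
  pi_grid <- base::matrix(0, m, m, dimnames = list(rownames(x), rownames(x)))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a != b) {
        pi_grid[a, b] <- sum(w * (x[a, ] > x[b, ]))
      }
    }
  }
  pi_grid
}

#' PROMETHEE I/II outranking flows and complete ranking
#'
#' Computes the positive flow `phi+(a)` (how strongly a outranks the field),
#' the negative flow `phi-(a)` (how strongly the field outranks a) and the
#' net flow `phi = phi+ - phi-`, then ranks alternatives by descending net
#' flow. Under the `averaged` convention the flows are divided by (m - 1)
#' (the textbook form); `summed` omits the division, so
#' `summed = averaged * (m - 1)` cell-by-cell. Rank ties are broken
#' deterministically by alternative id.
#'
#' @inheritParams pairwise_preference_table
#' @param convention `"averaged"` (default) or `"summed"` flow scaling.
#' @return An object of class `promethee_result`: list with `phi_plus`,
#'   `phi_minus`, `phi`, `rank` (named vectors), `pi` (the preference grid),
#'   `convention`, and `weight_signs`.
#' @examples
#' dm <- decision_matrix(rbind(a = c(x = 2, y = 2), b = c(x = 1, y = 1)))
#' nd <- normalize_decision_matrix(dm)
#' promethee_rank(nd, load_weights(c(x = 0.5, y = 0.5)))
#' @export
promethee_rank <- function(matrix, weights,
                           convention = c("averaged", "summed"),
                           weight_signs = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  weight_signs <- match.arg(weight_signs)
  pi_grid <- pairwise_preference_table(matrix, weights, weight_signs)
  m <- nrow(pi_grid)
  scale <- if (convention == "averaged") m - 1 else 1
  phi_plus <- rowSums(pi_grid) / scale
  phi_minus <- colSums(pi_grid) / scale
  phi <- phi_plus - phi_minus
  ord <- order(-phi, names(phi))
  rk <- stats::setNames(integer(m), names(phi))
  rk[ord] <- seq_len(m)
  structure(
    list(phi_plus = phi_plus, phi_minus = phi_minus, phi = phi,
         rank = rk, pi = pi_grid, convention = convention,
         weight_signs = weight_signs),
    class = "promethee_result"
  )
}

#' @export
print.promethee_result <- function(x, digits = 4, ...) {
  cat("PROMETHEE II ranking (", x$convention, " flows, ",
      x$weight_signs, " weights):\n", sep = "")
  ord <- order(x$rank)
  print(data.frame(
    alternative = names(x$phi)[ord],
    phi_plus = round(x$phi_plus[ord], digits),
    phi_minus = round(x$phi_minus[ord], digits),
    phi = round(x$phi[ord], digits),
    rank = x$rank[ord],
    row.names = NULL
  ))
  invisible(x)
}

# Align a weight vector with a criterion name set; unnamed weights of the
# right length are accepted positionally.
align_weights <- function(weights, criteria) {
  w <- as.numeric(weights)
  if (length(w) != length(criteria)) {
    stop("got ", length(w), " weights for ", length(criteria), " criteria",
         call. = FALSE)
  }
  if (!is.null(names(weights)) && !all(names(weights) == "")) {
    absent <- setdiff(criteria, names(weights))
    if (length(absent)) {
      stop("weights missing for criterion(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    w <- as.numeric(unclass(weights)[criteria])
  }
  stats::setNames(w, criteria)
}
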