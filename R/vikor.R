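#' VIKOR compromise ranking
#'
#' Ranks alternatives by closeness to the per-criterion ideal. For each
#' criterion the best value `x*` and worst value `x-` are found (direction
#' aware on a raw matrix; after normalization every column is max-oriented,
#' so best = max and worst = min). Each alternative accumulates the weighted
#' normalized regrets `w_j (x* - x_ij) / (x* - x-)` into the group utility
#' `S_i` (their sum) and the individual regret `R_i` (their maximum). The
#' compromise index
#' `Q_i = v (S_i - S*) / (S- - S*) + (1 - v) (R_i - R*) / (R- - R*)`
#' mixes the two with the "majority of criteria" weight `v`; alternatives
#' are ranked by ascending Q (ties broken by alternative id).
#'
#' An alternative attaining both the minimum S and minimum R has Q = 0 for
#' every v; the joint maximum has Q = 1. If exactly one of the S- or R-range
#' is degenerate (zero), that Q term is defined as 0; if both are, the input
#' cannot discriminate and an error is raised. A zero-range criterion
#' (best = worst) is an error naming the criterion.
#'
#' @param matrix A [decision_matrix]; raw matrices use their direction
#'   metadata for the best/worst rules, normalized ones are all
#'   max-oriented.
#' @param weights A `weight_vector` aligned with the matrix columns.
#' @param v Mixing weight in \[0, 1\] between group utility and individual
#'   regret; 0.5 balances the two (default).
#' @param weight_signs `"magnitude"` (default) or `"signed"`.
#' @return An object of class `vikor_result`: list with `S`, `R`, `Q`,
#'   `rank` (named vectors), `best`, `worst` (per-criterion), the scalars
#'   `S_star`, `S_minus`, `R_star`, `R_minus`, and `v`.
#' @examples
#' dm <- decision_matrix(rbind(a = c(x = 1, y = 10), b = c(x = 2, y = 20),
#'                             c = c(x = 3, y = 15)))
#' vikor_rank(dm, load_weights(c(x = 0.5, y = 0.5)))
#' @export
vikor_rank <- function(matrix, weights, v = 0.5,
                       weight_signs = c("magnitude", "signed")) {
  weight_signs <- match.arg(weight_signs)
  stopifnot(inherits(matrix, "decision_matrix"))
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
    stop("`v` must be a single number in [0, 1]", call. = FALSE)
  }
  criteria <- attr(matrix, "criteria")
  x <- unclass(matrix)
  attr(x, "criteria") <- NULL
  attr(x, "original_criteria") <- NULL
  m <- nrow(x)
  if (m < 2L) stop("need at least two alternatives", call. = FALSE)
  w <- align_weights(weights, colnames(x))
  if (weight_signs == "magnitude") w <- abs(w)

  benef <- criteria$direction[match(colnames(x), criteria$name)] == "beneficial"
  best <- ifelse(benef, apply(x, 2, max), apply(x, 2, min))
  worst <- ifelse(benef, apply(x, 2, min), apply(x, 2, max))
  names(best) <- names(worst) <- colnames(x)
  rng <- best - worst
  if (any(rng == 0)) {
    stop("zero-range criterion (best = worst): ",
         paste(colnames(x)[rng == 0], collapse = ", "), call. = FALSE)
  }

  terms <- sweep(sweep(-sweep(x, 2, best, "-"), 2, rng, "/"), 2, w, "*")
  S <- rowSums(terms)
  R <- apply(terms, 1, max)
  S_star <- min(S); S_minus <- max(S)
  R_star <- min(R); R_minus <- max(R)
  if (S_minus == S_star && R_minus == R_star) {
    stop("degenerate input: all alternatives have identical S and R",
         call. = FALSE)
  }
  s_term <- if (S_minus > S_star) (S - S_star) / (S_minus - S_star) else 0
  r_term <- if (R_minus > R_star) (R - R_star) / (R_minus - R_star) else 0
  Q <- v * s_term + (1 - v) * r_term

  ord <- order(Q, names(Q))
  rk <- stats::setNames(integer(m), names(Q))
  rk[ord] <- seq_len(m)
  structure(
    list(S = S, R = R, Q = Q, rank = rk, best = best, worst = worst,
         S_star = S_star, S_minus = S_minus, R_star = R_star,
         R_minus = R_minus, v = v, weight_signs = weight_signs),
    class = "vikor_result"
  )
}

#' @export
print.vikor_result <- function(x, digits = 4, ...) {
  cat("VIKOR compromise ranking (v = ", x$v, ", ", x$weight_signs,
      " weights):\n", sep = "")
  ord <- order(x$rank)
  print(data.frame(
    alternative = names(x$Q)[ord],
    S = round(x$S[ord], digits),
    R = round(x$R[ord], digits),
    Q = round(x$Q[ord], digits),
    rank = x$rank[ord],
    row.names = NULL
  ))
  invisible(x)
}
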