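# Independent reference implementations used as oracles. These deliberately
# re-derive everything with naive per-case / per-pair loops and direct
# formula evaluation, sharing no code with the package internals.

oracle_confusion <- function(y_true, y_pred, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    t <- y_true[i] == positive
    p <- y_pred[i] == positive
    if (t && p) tp <- tp + 1L
    else if (!t && !p) tn <- tn + 1L
    else if (!t && p) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(y_true, y_pred, positive) {
  cc <- oracle_confusion(y_true, y_pred, positive)
  tp <- unname(cc["tp"]); tn <- unname(cc["tn"])
  fp <- unname(cc["fp"]); fn <- unname(cc["fn"])
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sen <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spe <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  mcc <- if ((tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0 ||
             (tn + fn) == 0) 0 else {
    (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  }
  c(acc = acc, err = 1 - acc, pre = pre, sen = sen, spe = spe,
    f1 = f1, fpr = 1 - spe, fnr = 1 - sen, mcc = mcc)
}

# Brute-force PROMETHEE: explicit triple loop over pairs and criteria,
# usual preference P(d) = 1 iff d > 0.
oracle_promethee <- function(x, w, averaged = TRUE) {
  m <- nrow(x); k <- ncol(x)
  pi_grid <- matrix(0, m, m)
  for (a in 1:m) for (b in 1:m) if (a != b) {
    s <- 0
    for (j in 1:k) {
      d <- x[a, j] - x[b, j]
      if (d > 0) s <- s + w[j]
    }
    pi_grid[a, b] <- s
  }
  phi_plus <- phi_minus <- numeric(m)
  for (a in 1:m) {
    phi_plus[a] <- sum(pi_grid[a, ])
    phi_minus[a] <- sum(pi_grid[, a])
  }
  if (averaged) {
    phi_plus <- phi_plus / (m - 1)
    phi_minus <- phi_minus / (m - 1)
  }
  list(pi = pi_grid, phi = phi_plus - phi_minus)
}

random_labels <- function(n, p = 0.5) {
  ifelse(stats::runif(n) < p, "pos", "neg")
}
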