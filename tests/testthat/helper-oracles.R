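# Brute-force reference implementations of the evaluation metrics, written
# as explicit per-observation loops so they stay independent of the
# vectorized package code they check.

oracle_logloss <- function(y, P) {
  y <- as.character(y)
  total <- 0
  for (i in seq_along(y)) {
    p <- P[i, y[i]]
    p <- min(max(p, 1e-15), 1 - 1e-15)
    total <- total - log(p)
  }
  total / length(y)
}

oracle_r2_logloss <- function(y, P, prev) {
  B <- matrix(0, length(y), length(prev), dimnames = list(NULL, names(prev)))
  for (i in seq_along(y)) B[i, ] <- prev
  1 - oracle_logloss(y, P) / oracle_logloss(y, B)
}

oracle_binary_logloss <- function(ind, p) {
  total <- 0
  for (i in seq_along(ind)) {
    pi <- min(max(p[i], 1e-15), 1 - 1e-15)
    total <- total - (ind[i] * log(pi) + (1 - ind[i]) * log(1 - pi))
  }
  total / length(ind)
}

oracle_per_class_r2 <- function(y, P, prev) {
  y <- as.character(y)
  out <- numeric(length(prev))
  names(out) <- names(prev)
  for (cl in names(prev)) {
    ind <- as.numeric(y == cl)
    base <- oracle_binary_logloss(ind, rep(prev[[cl]], length(ind)))
    out[cl] <- 1 - oracle_binary_logloss(ind, P[, cl]) / base
  }
  out
}

oracle_tpr_f1 <- function(y, y_hat, classes) {
  y <- as.character(y); y_hat <- as.character(y_hat)
  res <- data.frame(class = classes, tpr = 0, f1 = 0)
  for (j in seq_along(classes)) {
    cl <- classes[j]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y)) {
      if (y[i] == cl && y_hat[i] == cl) tp <- tp + 1
      if (y[i] != cl && y_hat[i] == cl) fp <- fp + 1
      if (y[i] == cl && y_hat[i] != cl) fn <- fn + 1
    }
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    res$tpr[j] <- tpr
    res$f1[j] <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  }
  res
}
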