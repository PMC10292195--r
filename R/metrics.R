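PROB_CLIP <- 1e-15

clip_probs <- function(P) pmin(pmax(P, PROB_CLIP), 1 - PROB_CLIP)

#' Multiclass logarithmic loss
#'
#' Mean over observations of the negative natural log of the probability
#' assigned to the true class, with probabilities clipped to
#' `[1e-15, 1 - 1e-15]` before logging. Units are nats per observation.
#'
#' @param y Factor (or character) of true labels.
#' @param P n x K probability matrix; columns named by class, or ordered as
#'   `levels(y)`. Rows must sum to 1 within 1e-6.
#' @return Logloss in nats per observation.
#' @export
#' @examples
#' multiclass_logloss(factor(c("A", "B")),
#'                    matrix(c(0.8, 0.4, 0.2, 0.6), 2,
#'                           dimnames = list(NULL, c("A", "B"))))
multiclass_logloss <- function(y, P) {
  y <- as.factor(y)
  P <- as.matrix(P)
  if (nrow(P) != length(y)) stop("P must have one row per observation")
  if (is.null(colnames(P))) colnames(P) <- levels(y)
  if (!all(levels(y) %in% colnames(P))) {
    stop("probability columns do not cover the label classes")
  }
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 within 1e-6")
  }
  p_true <- P[cbind(seq_along(y), match(as.character(y), colnames(P)))]
  mean(-log(clip_probs(p_true)))
}

#' Log-loss skill score relative to a prevalence baseline
#'
#' `1 - LL(model) / LL(baseline)`, where the baseline is the constant
#' predictor emitting `baseline_prevalence` for every observation: 1 is a
#' perfect model, 0 no better than predicting prevalences, negative worse
#' than the baseline. The per-class variant (see [per_class_r2_logloss()])
#' uses one-vs-rest binary logloss.
#'
#' @param y Factor of true labels.
#' @param P n x K probability matrix (rows sum to 1).
#' @param baseline_prevalence Strictly positive K-vector summing to 1,
#'   named by class or ordered as `levels(y)`; defaults to the observed
#'   prevalences of `y`. May also be an n x K matrix (per-observation
#'   baseline, as in cross-validation where each point's baseline comes
#'   from its training partition).
#' @return The skill value (at most 1, possibly negative).
#' @export
r2_logloss <- function(y, P, baseline_prevalence = NULL) {
  y <- as.factor(y)
  if (is.null(baseline_prevalence)) {
    baseline_prevalence <- prop.table(table(y))
  }
  if (is.matrix(baseline_prevalence)) {
    B <- baseline_prevalence
    if (is.null(colnames(B))) colnames(B) <- levels(y)
  } else {
    bp <- as.numeric(baseline_prevalence)
    nm <- names(baseline_prevalence)
    if (is.null(nm)) nm <- levels(y)
    if (any(bp <= 0)) stop("baseline prevalences must be strictly positive")
    B <- matrix(bp, length(y), length(bp), byrow = TRUE,
                dimnames = list(NULL, nm))
  }
  ll_base <- multiclass_logloss(y, B)
  if (ll_base == 0) stop("degenerate baseline with zero logloss")
  1 - multiclass_logloss(y, P) / ll_base
}

# One-vs-rest binary logloss of a probability vector against an indicator.
binary_logloss <- function(ind, p) {
  p <- clip_probs(p)
  mean(-(ind * log(p) + (1 - ind) * log(1 - p)))
}

#' Per-class one-vs-rest log-loss skill
#'
#' For each class, the binary logloss of its predicted probability against
#' the class indicator, skill-scored against the constant predictor at the
#' class's baseline prevalence.
#'
#' @inheritParams r2_logloss
#' @param baseline_prevalence Optional named K-vector; defaults to observed
#'   prevalences of `y`.
#' @return Named numeric vector, one skill value per class.
#' @export
per_class_r2_logloss <- function(y, P, baseline_prevalence = NULL) {
  y <- as.factor(y)
  P <- as.matrix(P)
  if (is.null(colnames(P))) colnames(P) <- levels(y)
  if (is.null(baseline_prevalence)) {
    baseline_prevalence <- prop.table(table(y))
  }
  vapply(levels(y), function(cl) {
    ind <- as.numeric(y == cl)
    prev <- clip_probs(as.numeric(baseline_prevalence[[cl]]))
    ll_base <- binary_logloss(ind, rep(prev, length(ind)))
    if (ll_base == 0) return(NA_real_)
    1 - binary_logloss(ind, P[, cl]) / ll_base
  }, numeric(1))
}

#' Per-class true-positive rate and F1 score
#'
#' `TPR = TP / (TP + FN)`; `F1 = 2 * precision * recall /
#' (precision + recall)`. A class never predicted gets precision 0 and hence
#' F1 = 0; a class with no observations gets TPR 0 by the same zero
#' convention.
#'
#' @param y Factor of true labels.
#' @param y_hat Factor of predicted hard labels on the same legend.
#' @return Data frame with columns `class`, `n_obs`, `tpr`, `f1`.
#' @export
per_class_tpr_f1 <- function(y, y_hat) {
  y <- as.factor(y)
  y_hat <- factor(y_hat, levels = levels(y))
  stopifnot(length(y) == length(y_hat))
  res <- lapply(levels(y), function(cl) {
    tp <- sum(y == cl & y_hat == cl)
    fn <- sum(y == cl & y_hat != cl)
    fp <- sum(y != cl & y_hat == cl)
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
    data.frame(class = cl, n_obs = tp + fn, tpr = tpr, f1 = f1)
  })
  do.call(rbind, res)
}

# Stacked out-of-fold prediction with nested meta-learner application:
# for each outer fold, base learners and the meta-learner are trained
# using only the fold's training partition (the meta on that partition's
# inner OOF matrix), then applied to the held-out fold. Returns an n x K
# probability matrix plus the per-point baseline prevalence matrix of each
# point's training partition.
stacked_oof_predict <- function(X, y, blocks, folds, hp, seed,
                                inner_k = NULL) {
  y <- as.factor(y)
  classes <- levels(y)
  n <- length(y)
  P <- matrix(NA_real_, n, length(classes),
              dimnames = list(NULL, classes))
  B <- P
  for (f in sort(unique(folds))) {
    te <- folds == f
    tr <- !te
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    blocks_tr <- blocks[tr, , drop = FALSE]
    class(blocks_tr) <- class(blocks)
    n_blocks <- length(unique(blocks_tr$block_id))
    k_in <- if (is.null(inner_k)) min(5L, n_blocks) else inner_k
    inner_folds <- make_spatial_folds(blocks_tr, k = k_in,
                                      repeat_index = f,
                                      seed = derive_seed(seed, 17L, f))
    base <- fit_base_learners(Xtr, ytr, inner_folds, hp = hp,
                              seed = derive_seed(seed, 23L, f))
    meta <- fit_meta_learner(base$oof, ytr, ridge = hp$meta_ridge)
    base_te <- lapply(base$learners, function(l) {
      l$predict(X[te, , drop = FALSE])
    })
    P[te, ] <- meta$predict(base_te)
    prev <- prop.table(table(factor(ytr, levels = classes)))
    B[te, ] <- matrix(as.numeric(prev), sum(te), length(classes),
                      byrow = TRUE)
  }
  list(prob = P, baseline = B)
}

#' Repeated spatially blocked cross-validation of the stacked ensemble
#'
#' For each repeat, deals the metric blocks into `k` spatial folds and
#' produces stacked out-of-fold predictions for every point --- base
#' learners and meta-learner both applied out-of-fold (the meta-learner is
#' trained on the inner OOF matrix of each fold's training partition only,
#' preventing optimistic bias). Overall accuracy, logloss and log-loss
#' skill (baseline: each point's training-partition class prevalences) are
#' computed per repeat and summarized as mean and SD; per-class TPR, F1 and
#' one-vs-rest skill are averaged across repeats.
#'
#' @param X Point-by-feature matrix.
#' @param y Factor of labels.
#' @param blocks Block assignment from [assign_blocks()].
#' @param k Folds per repeat.
#' @param repeats Number of repeats.
#' @param hp A [hyperparams()] object.
#' @param seed Integer seed.
#' @return Object of class `cv_report`: `$summary` (data frame of overall
#'   metrics, mean and sd), `$per_repeat`, `$per_class` (class, n_obs, TPR,
#'   F1, r2_logloss averaged over repeats) and `$folds` provenance.
#' @export
run_spatial_cv <- function(X, y, blocks, k = 5, repeats = 5,
                           hp = hyperparams(), seed = 1) {
  X <- as.matrix(X)
  y <- as.factor(y)
  classes <- levels(y)
  per_repeat <- vector("list", repeats)
  per_class_acc <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- make_spatial_folds(blocks, k = k, repeat_index = r, seed = seed)
    oofp <- stacked_oof_predict(X, y, blocks, folds, hp,
                                seed = derive_seed(seed, 31L, r))
    hard <- factor(classes[max.col(oofp$prob, ties.method = "first")],
                   levels = classes)
    tab <- per_class_tpr_f1(y, hard)
    tab$r2_logloss <- per_class_r2_logloss(y, oofp$prob)
    per_class_acc[[r]] <- tab
    per_repeat[[r]] <- data.frame(
      repeat_index = r,
      overall_accuracy = mean(hard == y),
      logloss = multiclass_logloss(y, oofp$prob),
      r2_logloss = r2_logloss(y, oofp$prob,
                              baseline_prevalence = oofp$baseline)
    )
  }
  per_repeat <- do.call(rbind, per_repeat)
  per_class <- per_class_acc[[1]][, "class", drop = FALSE]
  per_class$n_obs <- per_class_acc[[1]]$n_obs
  for (col in c("tpr", "f1", "r2_logloss")) {
    per_class[[col]] <- rowMeans(sapply(per_class_acc, `[[`, col))
  }
  summary_df <- data.frame(
    metric = c("overall_accuracy", "logloss", "r2_logloss"),
    mean = vapply(per_repeat[, -1], mean, numeric(1)),
    sd = vapply(per_repeat[, -1], sd, numeric(1)),
    row.names = NULL
  )
  structure(list(summary = summary_df, per_repeat = per_repeat,
                 per_class = per_class, k = k, repeats = repeats,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold spatial CV x %d repeats\n",
              x$k, x$repeats))
  with(x$summary, cat(sprintf("  %-17s %.3f +/- %.3f\n", metric, mean, sd),
                      sep = ""))
  cat("Per-class (mean over repeats):\n")
  pc <- x$per_class
  pc[, c("tpr", "f1", "r2_logloss")] <-
    round(pc[, c("tpr", "f1", "r2_logloss")], 2)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Serialize a cross-validation report
#'
#' Writes the per-repeat raw metrics as CSV and the summary plus per-class
#' table (N.obs, TPR, F1, log-loss skill) as JSON.
#'
#' @param report A [run_spatial_cv()] result.
#' @param csv_path,json_path Output paths; `NULL` skips.
#' @return Invisibly, the written paths.
#' @export
write_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    write.csv(report$per_repeat, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = report$summary, per_class = report$per_class,
           k = report$k, repeats = report$repeats),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    written <- c(written, json_path)
  }
  invisible(written)
}
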