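#' Fit the three base learners with out-of-fold prediction
#'
#' For every spatial fold, each base learner (random forest, gradient-boosted
#' trees, lasso multinomial GLM) is trained on the points outside the fold
#' and predicts class probabilities for the points inside it, filling the
#' out-of-fold (OOF) probability matrices that the meta-learner is trained
#' on. Each learner is then refitted on all points for deployment.
#' Probability columns are aligned to the global class list: classes absent
#' from a training partition contribute an explicit zero column and rows are
#' renormalized, so matrix shapes stay global.
#'
#' @param X Point-by-feature numeric matrix (finite values).
#' @param y Factor of class labels; its levels define the class list.
#' @param folds Fold labels from [make_spatial_folds()].
#' @param hp A [hyperparams()] object.
#' @param seed Integer seed for the stochastic learners.
#' @return List of class `base_fits` with elements `oof` (list `rf`, `gbt`,
#'   `glm` of n x K OOF probability matrices), `learners` (full-data fits),
#'   `classes`, `feature_names` and `folds`.
#' @export
fit_base_learners <- function(X, y, folds, hp = hyperparams(), seed = 1) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nrow(X) == length(folds))
  if (!all(is.finite(X))) stop("non-finite values in the feature matrix")
  if (nlevels(droplevels(y)) < 2) {
    stop("training data contains a single class; at least 2 are required")
  }
  classes <- levels(y)
  n <- nrow(X)
  oof <- lapply(BASE_LEARNERS, function(...) {
    matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  })
  names(oof) <- BASE_LEARNERS
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2) {
      stop("training partition of fold ", f, " contains a single class")
    }
    for (w in BASE_LEARNERS) {
      lf <- fit_one_learner(w, X[tr, , drop = FALSE], y[tr], classes, hp,
                            derive_seed(seed, f, match(w, BASE_LEARNERS)))
      oof[[w]][!tr, ] <- lf$predict(X[!tr, , drop = FALSE])
    }
  }
  learners <- lapply(BASE_LEARNERS, function(w) {
    fit_one_learner(w, X, y, classes, hp,
                    derive_seed(seed, 0L, match(w, BASE_LEARNERS)))
  })
  names(learners) <- BASE_LEARNERS
  structure(list(oof = oof, learners = learners, classes = classes,
                 feature_names = colnames(X), folds = folds),
            class = "base_fits")
}

# 3K stacked meta-feature matrix from per-learner probability matrices.
stack_meta_features <- function(prob_list) {
  mats <- lapply(names(prob_list), function(w) {
    P <- prob_list[[w]]
    colnames(P) <- paste(w, colnames(P), sep = ".")
    P
  })
  do.call(cbind, mats)
}

#' Train the multinomial logistic meta-learner on stacked probabilities
#'
#' Fits a multinomial logistic map (multinomial deviance minimization, with a
#' very small ridge penalty for numerical stability, since stacked
#' probability features are often separable) from the 3K concatenated
#' out-of-fold class probabilities to the K classes.
#'
#' @param oof List of per-learner n x K OOF probability matrices (as in the
#'   `oof` element of [fit_base_learners()]), with no missing rows.
#' @param y Factor of class labels aligned with the OOF rows.
#' @param ridge L2 penalty (overrides `hp$meta_ridge` if given).
#' @return List of class `meta_learner` with a `$predict(prob_list)` closure
#'   emitting normalized K-vectors.
#' @export
fit_meta_learner <- function(oof, y, ridge = 1e-3) {
  y <- as.factor(y)
  M <- stack_meta_features(oof)
  if (anyNA(M)) stop("OOF matrix has missing rows; it must be complete")
  stopifnot(nrow(M) == length(y))
  if (any(apply(M, 2, sd) == 0)) {
    warning("degenerate (constant) stacked features; fit returned anyway")
  }
  yd <- droplevels(y)
  classes <- levels(y)
  fit <- glmnet::glmnet(M, yd, family = "multinomial", alpha = 0,
                        lambda = lambda_path(ridge))
  feature_names <- colnames(M)
  structure(list(
    fit = fit, ridge = ridge, classes = classes,
    feature_names = feature_names,
    predict = function(prob_list) {
      Mnew <- stack_meta_features(prob_list)[, feature_names, drop = FALSE]
      P <- predict(fit, newx = Mnew, s = ridge, type = "response")[, , 1]
      if (is.null(dim(P))) {
        P <- matrix(P, nrow = 1, dimnames = list(NULL, levels(yd)))
      }
      align_probs(P, colnames(P), classes)
    }
  ), class = "meta_learner")
}

#' Fit a stacked-ensemble biome classifier
#'
#' The package's central fitting function. Builds spatially blocked folds,
#' obtains out-of-fold class probabilities from the three base learners,
#' trains the multinomial logistic meta-learner on the stacked 3K
#' probability features, and refits the base learners on all points for
#' deployment. The result predicts per-pixel class probabilities with a
#' base-learner-spread uncertainty layer (see [predict_probabilities()]).
#'
#' @param x Point-by-feature numeric matrix (e.g. from
#'   [extract_features()]).
#' @param y Factor of biome labels; its levels are the canonical class list.
#' @param blocks Metric block assignment from [assign_blocks()]; spatial
#'   blocking is mandatory, plain random folds are deliberately not offered.
#' @param k Number of spatial folds used for the stacking OOF stage.
#' @param hp A [hyperparams()] object.
#' @param seed Integer seed.
#' @return An object of class `biome_stack`: base learners, meta-learner,
#'   class list, feature names, OOF matrices and fold labels.
#' @export
#' @seealso [predict.biome_stack()], [consensus_importance()],
#'   [run_spatial_cv()]
biome_stack <- function(x, y, blocks, k = 5, hp = hyperparams(), seed = 1) {
  y <- as.factor(y)
  folds <- make_spatial_folds(blocks, k = k, repeat_index = 0L, seed = seed)
  base <- fit_base_learners(x, y, folds, hp = hp, seed = seed)
  meta <- fit_meta_learner(base$oof, y, ridge = hp$meta_ridge)
  oof_stack <- meta$predict(base$oof)
  oof_class <- base$classes[max.col(oof_stack, ties.method = "first")]
  structure(list(
    learners = base$learners, meta = meta, classes = base$classes,
    feature_names = base$feature_names, oof = base$oof, folds = folds,
    hp = hp, seed = seed, n_obs = length(y),
    oof_accuracy = mean(oof_class == as.character(y)),
    oof_logloss = multiclass_logloss(y, oof_stack)
  ), class = "biome_stack")
}

#' @export
print.biome_stack <- function(x, ...) {
  cat(sprintf("<biome_stack> %d classes, %d features, %d training points\n",
              length(x$classes), length(x$feature_names), x$n_obs))
  cat(sprintf("  base learners: random forest, gradient-boosted trees, lasso GLM\n"))
  cat(sprintf("  meta-learner : multinomial logistic (ridge %g)\n",
              x$meta$ridge))
  cat(sprintf("  stacked OOF  : accuracy %.3f, logloss %.3f nats\n",
              x$oof_accuracy, x$oof_logloss))
  invisible(x)
}

#' @export
summary.biome_stack <- function(object, ...) {
  oof_stack <- object$meta$predict(object$oof)
  print(object)
  cls <- data.frame(
    class = object$classes,
    mean_oof_prob = colMeans(oof_stack)
  )
  cat("Mean stacked OOF probability per class:\n")
  print(cls, row.names = FALSE)
  invisible(cls)
}

#' @export
coef.biome_stack <- function(object, ...) {
  cf <- coef(object$meta$fit, s = object$meta$ridge)
  sapply(cf, function(b) setNames(as.numeric(b), rownames(b)))
}

#' Predict class probabilities for new points
#'
#' @param object A fitted [biome_stack()].
#' @param newdata Numeric matrix with the model's feature columns.
#' @param type `"prob"` for an n x K probability matrix (fractions summing
#'   to 1), `"class"` for hard labels (ties broken by class-list order),
#'   or `"base"` for the list of per-learner probability matrices.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.biome_stack <- function(object, newdata,
                                type = c("prob", "class", "base"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  base_probs <- lapply(object$learners, function(l) l$predict(newdata))
  if (type == "base") return(base_probs)
  P <- object$meta$predict(base_probs)
  if (type == "class") {
    return(factor(object$classes[max.col(P, ties.method = "first")],
                  levels = object$classes))
  }
  P
}

#' Predict a probability cube and uncertainty layers over a raster stack
#'
#' Runs the fitted ensemble over every unmasked pixel of a covariate stack.
#' The returned cube holds per-pixel per-class probabilities in percent,
#' summing to 100 at every unmasked pixel; the `sd` element holds, per
#' class, the sample standard deviation (n = 3) of the three base learners'
#' probabilities in percent --- the ensemble-spread uncertainty layer.
#' Masked pixels are nodata in every output.
#'
#' @param model A fitted [biome_stack()].
#' @param stack A [covariate_stack()] supplying every model feature as a
#'   layer.
#' @return List with `cube` (a [prob_cube()]) and `sd` (3-D array
#'   rows x cols x K, percent).
#' @export
predict_probabilities <- function(model, stack) {
  miss <- setdiff(model$feature_names, names(stack$layers))
  if (length(miss)) {
    stop("covariate stack is missing layer(s): ", paste(miss, collapse = ", "))
  }
  g <- stack$grid
  open <- which(!stack$mask)
  K <- length(model$classes)
  if (length(open) == 0) {
    vals <- array(NA_real_, c(g$n_rows, g$n_cols, K),
                  dimnames = list(NULL, NULL, model$classes))
    return(list(cube = prob_cube(g, model$classes, vals, stack$mask),
                sd = vals))
  }
  Xpix <- vapply(model$feature_names, function(nm) stack$layers[[nm]][open],
                 numeric(length(open)))
  Xpix <- matrix(Xpix, nrow = length(open),
                 dimnames = list(NULL, model$feature_names))
  base_probs <- lapply(model$learners, function(l) l$predict(Xpix))
  P <- model$meta$predict(base_probs)
  vals <- array(NA_real_, c(g$n_rows, g$n_cols, K),
                dimnames = list(NULL, NULL, model$classes))
  sd_arr <- vals
  for (kk in seq_len(K)) {
    plane <- matrix(NA_real_, g$n_rows, g$n_cols)
    plane[open] <- 100 * P[, kk]
    vals[, , kk] <- plane
    trio <- cbind(base_probs$rf[, kk], base_probs$gbt[, kk],
                  base_probs$glm[, kk])
    sd_plane <- matrix(NA_real_, g$n_rows, g$n_cols)
    sd_plane[open] <- 100 * apply(trio, 1, sd)
    sd_arr[, , kk] <- sd_plane
  }
  list(cube = prob_cube(g, model$classes, vals, stack$mask), sd = sd_arr)
}

#' Consensus variable importance across the three base learners
#'
#' Ranks features per learner (random forest: impurity importance;
#' gradient-boosted trees: total gain; lasso GLM: maximum absolute
#' coefficient over classes at the fitted lambda), takes each learner's
#' top-`top_k` set, and returns the intersection ordered by mean rank ---
#' the variables all component models agree matter.
#'
#' @param model A fitted [biome_stack()].
#' @param top_k Depth of each learner's importance list.
#' @return Character vector of feature names (possibly empty).
#' @export
consensus_importance <- function(model, top_k = 20) {
  stopifnot(top_k >= 1)
  imps <- lapply(model$learners, function(l) l$importance())
  feats <- model$feature_names
  ranks <- sapply(imps, function(im) {
    im <- im[feats]
    im[is.na(im)] <- 0
    rank(-im, ties.method = "first")
  })
  rownames(ranks) <- feats
  tops <- apply(ranks, 2, function(r) feats[r <= top_k], simplify = FALSE)
  common <- Reduce(intersect, tops)
  common[order(rowMeans(ranks[common, , drop = FALSE]))]
}
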