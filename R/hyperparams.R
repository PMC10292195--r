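#' Ensemble hyperparameters
#'
#' Container for the tuned settings of the three base learners. Defaults are
#' the tuned architecture used for the global biome model: a 452-tree random
#' forest with minimum node size 9 and mtry 10; gradient-boosted trees with
#' 20 boosting rounds, maximum tree depth 5, learning rate 0.5, minimum loss
#' reduction 10, full instance subsampling and 0.5 column subsampling; and a
#' lasso-regularized multinomial linear model at lambda = 1.1e-5. Everything
#' not listed stays at the underlying implementation's defaults. `mtry` is
#' capped at the number of available features at fit time.
#'
#' @param rf_trees,rf_min_node,rf_mtry Random-forest trees, minimum node
#'   size, candidate variables per split.
#' @param gbt_rounds,gbt_max_depth,gbt_learning_rate,gbt_min_loss_reduction,gbt_subsample,gbt_colsample
#'   Gradient-boosted-tree rounds, depth, learning rate (eta), minimum loss
#'   reduction to split (gamma), instance and column subsample fractions.
#' @param glm_lambda L1 penalty of the multinomial lasso base learner.
#' @param meta_ridge Small L2 penalty stabilizing the multinomial logistic
#'   meta-learner (stacked probability features are near-separable).
#' @return A list of class `biome_hyperparams`.
#' @export
hyperparams <- function(rf_trees = 452, rf_min_node = 9, rf_mtry = 10,
                        gbt_rounds = 20, gbt_max_depth = 5,
                        gbt_learning_rate = 0.5, gbt_min_loss_reduction = 10,
                        gbt_subsample = 1, gbt_colsample = 0.5,
                        glm_lambda = 1.1e-5, meta_ridge = 1e-3) {
  hp <- list(rf_trees = rf_trees, rf_min_node = rf_min_node,
             rf_mtry = rf_mtry, gbt_rounds = gbt_rounds,
             gbt_max_depth = gbt_max_depth,
             gbt_learning_rate = gbt_learning_rate,
             gbt_min_loss_reduction = gbt_min_loss_reduction,
             gbt_subsample = gbt_subsample, gbt_colsample = gbt_colsample,
             glm_lambda = glm_lambda, meta_ridge = meta_ridge)
  counts <- c("rf_trees", "rf_min_node", "rf_mtry", "gbt_rounds",
              "gbt_max_depth")
  stopifnot(all(vapply(hp[counts], function(v) v >= 1, logical(1))),
            gbt_subsample > 0, gbt_subsample <= 1,
            gbt_colsample > 0, gbt_colsample <= 1,
            gbt_learning_rate > 0, gbt_min_loss_reduction >= 0,
            glm_lambda >= 0, meta_ridge >= 0)
  class(hp) <- "biome_hyperparams"
  hp
}

#' @export
print.biome_hyperparams <- function(x, ...) {
  cat("<biome_hyperparams>\n")
  cat(sprintf("  RF : %d trees, min node %d, mtry %d\n",
              x$rf_trees, x$rf_min_node, x$rf_mtry))
  cat(sprintf("  GBT: %d rounds, depth %d, eta %g, gamma %g, subsample %g, colsample %g\n",
              x$gbt_rounds, x$gbt_max_depth, x$gbt_learning_rate,
              x$gbt_min_loss_reduction, x$gbt_subsample, x$gbt_colsample))
  cat(sprintf("  GLM: lasso lambda %g; meta ridge %g\n",
              x$glm_lambda, x$meta_ridge))
  invisible(x)
}
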