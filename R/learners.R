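# Internal wrappers around the three base learners. Each fit returns a list
# with $predict(newX) emitting an n x K probability matrix aligned to the
# global class list (zero columns for classes absent from the training
# partition, rows renormalized) and $importance(), a named score per feature.

align_probs <- function(P, from_classes, to_classes) {
  out <- matrix(0, nrow(P), length(to_classes),
                dimnames = list(NULL, to_classes))
  out[, from_classes] <- P[, from_classes, drop = FALSE]
  out / rowSums(out)
}

fit_rf <- function(X, y, classes, hp, seed) {
  y <- droplevels(y)
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y,
    probability = TRUE, num.trees = hp$rf_trees,
    min.node.size = hp$rf_min_node, mtry = min(hp$rf_mtry, ncol(X)),
    importance = "impurity", seed = seed, num.threads = 1,
    verbose = FALSE
  )
  present <- levels(y)
  list(
    kind = "rf", fit = fit,
    predict = function(newX) {
      P <- predict(fit, data = as.data.frame(newX),
                   num.threads = 1, verbose = FALSE)$predictions
      align_probs(P, colnames(P), classes)
    },
    importance = function() {
      imp <- fit$variable.importance
      setNames(as.numeric(imp), names(imp))
    }
  )
}

fit_gbt <- function(X, y, classes, hp, seed) {
  y <- droplevels(y)
  present <- levels(y)
  label <- as.integer(y) - 1L
  dtrain <- xgboost::xgb.DMatrix(data = X, label = label)
  params <- list(objective = "multi:softprob", num_class = length(present),
                 max_depth = hp$gbt_max_depth, eta = hp$gbt_learning_rate,
                 gamma = hp$gbt_min_loss_reduction,
                 subsample = hp$gbt_subsample,
                 colsample_bytree = hp$gbt_colsample,
                 nthread = 1, seed = seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = hp$gbt_rounds, verbose = 0)
  list(
    kind = "gbt", fit = fit,
    predict = function(newX) {
      p <- predict(fit, xgboost::xgb.DMatrix(newX))
      P <- if (is.matrix(p)) p else {
        matrix(p, nrow = nrow(newX), ncol = length(present), byrow = TRUE)
      }
      colnames(P) <- present
      align_probs(P, present, classes)
    },
    importance = function() {
      imp <- setNames(rep(0, ncol(X)), colnames(X))
      tab <- tryCatch(xgboost::xgb.importance(model = fit),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab) > 0) imp[tab$Feature] <- tab$Gain
      imp
    }
  )
}

fit_glm_lasso <- function(X, y, classes, hp, seed) {
  y <- droplevels(y)
  present <- levels(y)
  lam <- lambda_path(hp$glm_lambda)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                        lambda = lam)
  list(
    kind = "glm", fit = fit,
    predict = function(newX) {
      P <- predict(fit, newx = newX, s = hp$glm_lambda,
                   type = "response")[, , 1]
      if (is.null(dim(P))) P <- matrix(P, nrow = 1, dimnames = list(NULL, present))
      align_probs(P, colnames(P), classes)
    },
    importance = function() {
      cf <- coef(fit, s = hp$glm_lambda)
      mats <- lapply(cf, function(b) abs(as.numeric(b)[-1]))  # drop intercept
      setNames(do.call(pmax, mats), colnames(X))
    }
  )
}

# Decreasing lambda sequence ending at the target value (glmnet fits a path
# with warm starts; predictions are read off at the target).
lambda_path <- function(lambda, length_out = 25) {
  top <- max(1, lambda * 10)
  exp(seq(log(top), log(max(lambda, 1e-12)), length.out = length_out))
}

BASE_LEARNERS <- c("rf", "gbt", "glm")

fit_one_learner <- function(which, X, y, classes, hp, seed) {
  switch(which,
         rf  = fit_rf(X, y, classes, hp, seed),
         gbt = fit_gbt(X, y, classes, hp, derive_seed(seed, 2L)),
         glm = fit_glm_lasso(X, y, classes, hp, seed))
}
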