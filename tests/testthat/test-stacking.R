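test_that("all base learners separate two linearly separable classes out of fold", {
  set.seed(21)
  n <- 1000
  y <- factor(rep(c("lo", "hi"), each = n / 2))
  X <- cbind(x1 = rnorm(n, ifelse(y == "hi", 4, -4)),
             x2 = rnorm(n))
  pts <- data.frame(point_id = sprintf("p%04d", 1:n),
                    lon = runif(n, -30, 30), lat = runif(n, -30, 30))
  blocks <- assign_blocks(pts)
  folds <- make_spatial_folds(blocks, k = 5, repeat_index = 1, seed = 2)
  fits <- fit_base_learners(X, y, folds, hp = hyperparams(glm_lambda = 1e-8),
                            seed = 3)
  for (w in c("rf", "gbt", "glm")) {
    hard <- colnames(fits$oof[[w]])[max.col(fits$oof[[w]], "first")]
    expect_gte(mean(hard == as.character(y)), 0.95)
  }
  # every OOF probability vector is normalized
  for (w in c("rf", "gbt", "glm")) {
    expect_true(all(abs(rowSums(fits$oof[[w]]) - 1) < 1e-9))
  }
})

test_that("degenerate training inputs are rejected with useful errors", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  folds <- rep(1:2, each = 10)
  expect_error(fit_base_learners(X, factor(rep("only", 20)), folds),
               "single class")
  # fold 2 holds only class "A": fold 1's training partition is pure "A"
  y <- factor(c(rep(c("A", "B"), 5), rep("A", 10)))
  expect_error(fit_base_learners(X, y, folds), "fold 1")
  Xbad <- X; Xbad[3, 1] <- NA
  expect_error(fit_base_learners(Xbad, factor(rep(c("A", "B"), 10)), folds),
               "non-finite")
})

test_that("meta-learner reproduces one-hot base truth and normalizes", {
  set.seed(4)
  n <- 300
  y <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  onehot <- matrix(0, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  onehot[cbind(seq_len(n), as.integer(y))] <- 1
  soft <- (onehot + 0.05) / rowSums(onehot + 0.05)
  oof <- list(rf = soft, gbt = soft, glm = soft)
  meta <- fit_meta_learner(oof, y)
  P <- meta$predict(oof)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  hard <- colnames(P)[max.col(P, "first")]
  expect_identical(hard, as.character(y))

  rand <- list(rf = random_prob_matrix(50, 3),
               gbt = random_prob_matrix(50, 3),
               glm = random_prob_matrix(50, 3))
  expect_true(all(abs(rowSums(meta$predict(rand)) - 1) < 1e-9))

  oof_na <- oof; oof_na$rf[1, 1] <- NA
  expect_error(fit_meta_learner(oof_na, y), "missing")
  oof_const <- oof; oof_const$glm[] <- 1 / 3
  expect_warning(fit_meta_learner(oof_const, y), "degenerate")
})

test_that("the meta-learner agrees with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  set.seed(14)
  n <- 400
  classes <- c("A", "B", "C")
  y <- factor(sample(classes, n, replace = TRUE))
  mk <- function() {
    P <- matrix(rexp(n * 3), n, 3, dimnames = list(NULL, classes))
    P <- 0.5 * P / rowSums(P)
    onehot <- matrix(0, n, 3, dimnames = list(NULL, classes))
    onehot[cbind(seq_len(n), as.integer(y))] <- 0.5
    P + onehot
  }
  oof <- list(rf = mk(), gbt = mk(), glm = mk())
  meta <- fit_meta_learner(oof, y)
  ours <- meta$predict(oof)
  M <- do.call(cbind, oof)
  ref <- nnet::multinom(y ~ M, trace = FALSE, maxit = 500, decay = 1e-3)
  theirs <- predict(ref, type = "probs")
  agree <- mean(colnames(ours)[max.col(ours, "first")] ==
                  colnames(theirs)[max.col(theirs, "first")])
  expect_gte(agree, 0.9)
  expect_lte(abs(multiclass_logloss(y, ours) -
                   multiclass_logloss(y, theirs)), 0.05)
})

test_that("the stack leans on an informative learner over a noise learner", {
  set.seed(6)
  n <- 600
  classes <- c("A", "B", "C")
  y <- factor(sample(classes, n, replace = TRUE))
  truth_soft <- function(yy) {
    onehot <- matrix(0, length(yy), 3, dimnames = list(NULL, classes))
    onehot[cbind(seq_along(yy), as.integer(yy))] <- 1
    (onehot + 0.1) / rowSums(onehot + 0.1)
  }
  tr <- seq_len(400); te <- 401:600
  noise <- random_prob_matrix(n, 3, classes)
  oof_tr <- list(rf = truth_soft(y)[tr, ], gbt = noise[tr, ],
                 glm = noise[tr, ])
  meta <- fit_meta_learner(oof_tr, y[tr])
  stack_te <- meta$predict(list(rf = truth_soft(y)[te, ],
                                gbt = noise[te, ], glm = noise[te, ]))
  ll_stack <- multiclass_logloss(y[te], stack_te)
  ll_noise <- multiclass_logloss(y[te], noise[te, ])
  expect_lte(ll_stack, ll_noise)
})

test_that("prediction over a raster yields normalized percent cubes and spread layers", {
  d <- small_study()
  m <- small_model()
  pred <- predict_probabilities(m, d$stack)
  sums <- apply(pred$cube$values, c(1, 2), sum)
  expect_true(all(abs(sums - 100) < 1e-6))

  # spread layer equals the sample SD (n = 3) of the base learners, percent
  base <- predict(m, d$X[1:5, ], type = "base")
  meta_p <- predict(m, d$X[1:5, ])
  expect_true(all(abs(rowSums(meta_p) - 1) < 1e-9))
  rc <- cbind(d$obs$row[1:5], d$obs$col[1:5])
  for (i in 1:5) {
    for (k in seq_along(m$classes)) {
      trio <- c(base$rf[i, k], base$gbt[i, k], base$glm[i, k])
      expect_equal(unname(pred$sd[rc[i, 1], rc[i, 2], k]), 100 * sd(trio),
                   tolerance = 1e-8)
    }
  }
  # sample SD convention: (20%, 80%, 50%) spread is exactly 30 points
  expect_equal(100 * sd(c(0.2, 0.8, 0.5)), 30)

  # masked pixels are nodata in all outputs
  msk <- matrix(FALSE, d$grid$n_rows, d$grid$n_cols)
  msk[7, ] <- TRUE
  pred_m <- predict_probabilities(m, apply_mask(d$stack, msk))
  expect_true(all(is.na(pred_m$cube$values[7, , ])))
  expect_true(all(is.na(pred_m$sd[7, , ])))

  broken <- d$stack
  broken$layers$prec <- NULL
  expect_error(predict_probabilities(m, broken), "prec")
})

test_that("consensus importance intersects the per-learner top lists", {
  set.seed(8)
  n <- 500
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(ifelse(X[, "f3"] > 0, "pos", "neg"))
  pts <- data.frame(point_id = sprintf("p%04d", 1:n),
                    lon = runif(n, -20, 20), lat = runif(n, -20, 20))
  m <- biome_stack(X, y, assign_blocks(pts), seed = 9)
  expect_true("f3" %in% consensus_importance(m, top_k = 2))
  expect_setequal(consensus_importance(m, top_k = 5), paste0("f", 1:5))
  expect_error(consensus_importance(m, top_k = 0))

  # three learners disagreeing on the single most important feature
  fake <- structure(list(
    feature_names = c("a", "b", "c"),
    learners = list(
      rf = list(importance = function() c(a = 3, b = 2, c = 1)),
      gbt = list(importance = function() c(a = 1, b = 3, c = 2)),
      glm = list(importance = function() c(a = 2, b = 1, c = 3))
    )), class = "biome_stack")
  expect_length(consensus_importance(fake, top_k = 1), 0)
  expect_identical(sort(consensus_importance(fake, top_k = 2)),
                   character(0))
})
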