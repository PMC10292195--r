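test_that("covariate generation is a pure function of its arguments", {
  g <- grid_spec(24, 24, lon_min = 0, lat_min = 0, cell_size = 0.5)
  spec <- data.frame(name = c("t1", "p1"),
                     kind = c("temperature", "precipitation"))
  a <- generate_covariates(g, spec, corr_length = 4, seed = 7)
  b <- generate_covariates(g, spec, corr_length = 4, seed = 7)
  expect_identical(a$layers, b$layers)
  c3 <- generate_covariates(g, spec, corr_length = 4, seed = 8)
  expect_false(identical(a$layers, c3$layers))
  expect_error(generate_covariates(g, data.frame(name = c("x", "x"),
                                                 kind = c("terrain", "terrain"))),
               "duplicate")
  expect_error(generate_covariates(g, data.frame(name = character(),
                                                 kind = character())),
               "empty")
})

test_that("corr_length = 1 reduces the smoother to the identity kernel", {
  set.seed(31)
  f <- biomeshift:::smooth_field(32, 32, 1)
  set.seed(31)
  raw <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(f, raw)
})

test_that("larger correlation lengths increase lag-1 spatial autocorrelation", {
  g <- grid_spec(64, 64, lon_min = 0, lat_min = 0, cell_size = 0.25)
  spec <- data.frame(name = "e", kind = "terrain")
  rough <- generate_covariates(g, spec, corr_length = 1, seed = 5)
  smooth <- generate_covariates(g, spec, corr_length = 16, seed = 5)
  r_rough <- lag1_autocorr(rough$layers$e)
  r_smooth <- lag1_autocorr(smooth$layers$e)
  expect_lt(abs(r_rough), 0.1)
  expect_gt(r_smooth, r_rough)
  expect_gt(r_smooth, 0.8)
})

test_that("temperature layers carry a monotone north-south gradient", {
  g <- grid_spec(48, 32, lon_min = 0, lat_min = -10, cell_size = 0.5)
  spec <- data.frame(name = "tmean", kind = "temperature")
  stk <- generate_covariates(g, spec, corr_length = 6, seed = 3)
  # row 1 is the northern edge: means must increase going south
  rm <- rowMeans(stk$layers$tmean)
  expect_gt(cor(rm, seq_along(rm)), 0.9)
})

test_that("label thresholds hit the requested prevalence structure", {
  g <- grid_spec(64, 64, lon_min = 0, lat_min = 0, cell_size = 0.25)
  spec <- data.frame(name = c("a", "b"), kind = c("temperature", "terrain"))
  stk <- generate_covariates(g, spec, corr_length = 6, seed = 11)

  even <- generate_true_labels(stk, K = 4, rule_seed = 1, prevalence_skew = 1)
  counts <- table(even[!is.na(even)])
  expect_lte(diff(range(counts)), 2)  # equal up to rounding

  two <- generate_true_labels(stk, K = 2, rule_seed = 1, prevalence_skew = 1)
  expect_equal(unname(prop.table(table(two))[1]), 0.5, tolerance = 1e-3)

  g128 <- grid_spec(128, 128, lon_min = 0, lat_min = 0, cell_size = 0.25)
  stk128 <- generate_covariates(g128, spec, corr_length = 10, seed = 12)
  skewed <- generate_true_labels(stk128, K = 6, rule_seed = 2,
                                 prevalence_skew = 3)
  sc <- sort(table(skewed), decreasing = TRUE)
  expect_gte(sc[1] / sc[length(sc)], 50)
})

test_that("the recorded threshold rule reproduces the label raster", {
  d <- small_study()
  rule <- attr(d$labels, "rule")
  lab2 <- matrix(NA_integer_, d$grid$n_rows, d$grid$n_cols)
  remaining <- which(!d$stack$mask)
  for (k in seq_len(nrow(rule))) {
    v <- d$stack$layers[[rule$layer[k]]][remaining]
    take <- if (rule$tail[k] == "high") v >= rule$threshold[k]
            else v <= rule$threshold[k]
    lab2[remaining[take]] <- as.integer(k)
    remaining <- remaining[!take]
  }
  lab2[remaining] <- nrow(rule) + 1L
  expect_identical(lab2, matrix(as.integer(d$labels),
                                d$grid$n_rows, d$grid$n_cols))
})

test_that("observation sampling honours noise, clustering and determinism", {
  d <- small_study()
  # noiseless points carry the raster's class at their cell
  truth <- d$labels[cbind(d$obs$row, d$obs$col)]
  expect_identical(as.integer(d$obs$label), truth)

  # binomial disagreement check at 20% label noise
  g <- d$grid
  noisy <- sample_observations(d$labels, g, n_points = 1500, n_clusters = 10,
                               label_noise = 0.2, seed = 9)
  truth_n <- d$labels[cbind(noisy$row, noisy$col)]
  disagree <- mean(as.integer(noisy$label) != truth_n)
  expect_lt(abs(disagree - 0.2), 0.03)

  # a single cluster keeps all points within the cluster radius (3 sd)
  one <- sample_observations(d$labels, g, n_points = 100, n_clusters = 1,
                             cluster_sd = 3, seed = 10)
  spread <- max(dist(cbind(one$row, one$col)))
  expect_lte(spread, 2 * 3 * 3)

  expect_identical(
    sample_observations(d$labels, g, 50, n_clusters = 3, seed = 12),
    sample_observations(d$labels, g, 50, n_clusters = 3, seed = 12))
  expect_error(sample_observations(d$labels, g, n_points = 1e6), "exceeds")
})

test_that("scenario perturbation shifts temperature, scales precipitation, fixes terrain", {
  d <- small_study()
  idm <- perturb_scenario(d$stack, 0, 1)
  expect_equal(idm$layers, d$stack$layers)

  warm <- perturb_scenario(d$stack, temperature_shift = 5,
                           precipitation_scale = 0.8, scenario_tag = "x")
  expect_equal(warm$layers$tmean, d$stack$layers$tmean + 5)
  expect_equal(warm$layers$prec, d$stack$layers$prec * 0.8)
  expect_equal(mean(warm$layers$prec, na.rm = TRUE),
               0.8 * mean(d$stack$layers$prec, na.rm = TRUE))
  expect_identical(warm$layers$elev, d$stack$layers$elev)
  expect_identical(warm$mask, d$stack$mask)
  expect_error(perturb_scenario(d$stack, precipitation_scale = 0))
})

test_that("masked cells stay nodata through masking and perturbation", {
  d <- small_study()
  m <- matrix(FALSE, d$grid$n_rows, d$grid$n_cols)
  m[1:5, 1:5] <- TRUE
  masked <- apply_mask(d$stack, m)
  for (nm in names(masked$layers)) {
    expect_true(all(is.na(masked$layers[[nm]][m])))
  }
  warm <- perturb_scenario(masked, 3, 1.1)
  for (nm in names(warm$layers)) {
    expect_true(all(is.na(warm$layers[[nm]][m])))
  }
})
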