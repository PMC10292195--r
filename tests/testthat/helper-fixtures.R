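# Shared fixtures, built once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small end-to-end study: 40x40 grid, 3 covariates, K = 3, 300 clustered
# points, no label noise.
small_study <- function() cached("small_study", {
  g <- grid_spec(40, 40, lon_min = 0, lat_min = 10, cell_size = 0.5)
  spec <- data.frame(name = c("tmean", "prec", "elev"),
                     kind = c("temperature", "precipitation", "terrain"))
  stack <- generate_covariates(g, spec, corr_length = 5, seed = 2)
  labels <- generate_true_labels(stack, K = 3, rule_seed = 3,
                                 prevalence_skew = 1.5)
  obs <- sample_observations(labels, g, n_points = 300, n_clusters = 8,
                             label_noise = 0, seed = 4)
  blocks <- assign_blocks(obs)
  list(grid = g, stack = stack, labels = labels, obs = obs,
       blocks = blocks, X = extract_features(stack, obs), y = obs$label)
})

# A fitted stacked model on the small study.
small_model <- function() cached("small_model", {
  d <- small_study()
  biome_stack(d$X, d$y, d$blocks, k = 5, seed = 5)
})

# A uniform-percent probability cube on a tiny grid.
toy_cube <- function(classes = c("A", "B", "C"), n = 4, mask = NULL) {
  g <- grid_spec(n, n, lon_min = 0, lat_min = 0, cell_size = 1)
  vals <- array(100 / length(classes), c(n, n, length(classes)))
  if (!is.null(mask)) for (k in seq_along(classes)) {
    plane <- vals[, , k]; plane[mask] <- NA; vals[, , k] <- plane
  }
  prob_cube(g, classes, vals, mask = if (is.null(mask)) NULL else mask)
}

# Hard/MoV map pair on an n x n grid from explicit matrices.
toy_epoch <- function(hard, mov, classes) {
  attr(hard, "classes") <- classes
  list(hard = hard, mov = mov)
}

# Lag-1 spatial autocorrelation of a field (mean of row- and column-wise
# neighbour correlation) -- independent of the generator internals.
lag1_autocorr <- function(m) {
  rowwise <- cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  colwise <- cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  mean(c(rowwise, colwise))
}

# Evaluate an expression under a local seed without disturbing the
# surrounding RNG stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Random probability matrix with rows summing to 1.
random_prob_matrix <- function(n, K, classes = LETTERS[seq_len(K)]) {
  P <- matrix(rexp(n * K), n, K)
  P <- P / rowSums(P)
  colnames(P) <- classes
  P
}
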