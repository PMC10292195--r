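#' Generate smooth synthetic covariate fields
#'
#' Builds a stack of spatially autocorrelated random fields by convolving
#' white noise with an isotropic Gaussian kernel of scale `corr_length`
#' (circular boundary). Temperature-kind layers additionally carry a monotone
#' north--south gradient, mimicking the latitudinal structure of bioclimatic
#' temperature covariates; precipitation-kind layers are positive (log-normal
#' shaped); terrain-kind layers are elevation-like.
#'
#' With `corr_length = 1` the kernel has width 1 and the field equals the raw
#' noise. Identical arguments (including `seed`) give bit-identical stacks.
#'
#' @param grid A [grid_spec()].
#' @param layer_spec Data frame (or list of two-element vectors) with columns
#'   `name` and `kind`; `kind` is one of `"temperature"`, `"precipitation"`,
#'   `"terrain"`.
#' @param corr_length Kernel scale in cells, >= 1.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A [covariate_stack()].
#' @export
#' @examples
#' g <- grid_spec(32, 32, lon_min = 0, lat_min = 0, cell_size = 0.5)
#' spec <- data.frame(name = c("bio1", "bio12"),
#'                    kind = c("temperature", "precipitation"))
#' stk <- generate_covariates(g, spec, corr_length = 4, seed = 1)
generate_covariates <- function(grid, layer_spec, corr_length = 8, seed = 1) {
  layer_spec <- as.data.frame(layer_spec, stringsAsFactors = FALSE)
  if (nrow(layer_spec) == 0) stop("layer_spec is empty")
  stopifnot(all(c("name", "kind") %in% names(layer_spec)), corr_length >= 1)
  if (anyDuplicated(layer_spec$name)) stop("duplicate layer names")
  kinds <- match.arg(layer_spec$kind,
                     c("temperature", "precipitation", "terrain"),
                     several.ok = TRUE)
  lat <- cell_centre_lat(grid, seq_len(grid$n_rows))
  lat_span <- max(diff(range(lat)), grid$cell_size)
  # warm at the southern edge, cold at the northern: 30 deg C span
  gradient <- 22 - 30 * (lat - min(lat)) / lat_span
  with_seed(seed, {
    layers <- vector("list", nrow(layer_spec))
    for (i in seq_len(nrow(layer_spec))) {
      field <- smooth_field(grid$n_rows, grid$n_cols, corr_length)
      layers[[i]] <- switch(
        kinds[i],
        temperature   = matrix(gradient, grid$n_rows, grid$n_cols) + 6 * field,
        precipitation = 800 * exp(0.9 * field),
        terrain       = 500 + 300 * field
      )
    }
    names(layers) <- layer_spec$name
    covariate_stack(grid, layers, kinds = kinds)
  })
}

# White noise convolved with a separable Gaussian kernel (circular wrap),
# restandardized to zero mean / unit sd. corr_length = 1 -> identity kernel.
smooth_field <- function(n_rows, n_cols, corr_length) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  radius <- ceiling(corr_length) - 1L
  if (radius == 0L) return(z)
  d <- seq(-radius, radius)
  w <- exp(-0.5 * (d / (corr_length / 2))^2)
  w <- w / sum(w)
  sm <- apply(z, 2, conv_circular, w = w)          # down columns
  sm <- t(apply(sm, 1, conv_circular, w = w))      # along rows
  (sm - mean(sm)) / sd(sm)
}

conv_circular <- function(x, w) {
  radius <- (length(w) - 1L) / 2L
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(w)) {
    shift <- j - radius - 1L
    idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
    out <- out + w[j] * x[idx]
  }
  out
}

#' Assign a biome class to every cell by a recorded threshold rule
#'
#' Partitions the unmasked cells into `K` classes by nested quantile
#' thresholds on two designated latent layers: class 1 is carved off the
#' whole domain, class 2 off the remainder, and so on, alternating between
#' the two layers with randomized direction (high or low tail). Threshold
#' placement makes the class prevalences follow a geometric decay with ratio
#' `1/prevalence_skew`, so `prevalence_skew = 1` gives balanced classes and
#' larger values give the heavy imbalance typical of biome point datasets.
#' The applied rule is recorded in the `"rule"` attribute.
#'
#' @param stack A [covariate_stack()] with at least two layers.
#' @param K Number of classes, >= 2.
#' @param rule_seed Seed controlling which layer/tail each split uses.
#' @param prevalence_skew Ratio between consecutive class prevalences, >= 1.
#' @param latent Names of the two layers driving the rule (default: the
#'   first two layers).
#' @param class_names Optional K class labels (default `class_01` ...).
#' @return Integer matrix of class indices (NA on the mask) with attributes
#'   `classes` (labels) and `rule` (data frame of splits).
#' @export
generate_true_labels <- function(stack, K, rule_seed = 1, prevalence_skew = 1,
                                 latent = names(stack$layers)[1:2],
                                 class_names = NULL) {
  stopifnot(K >= 2, length(stack$layers) >= 2, prevalence_skew >= 1,
            length(latent) == 2, all(latent %in% names(stack$layers)))
  if (is.null(class_names)) class_names <- sprintf("class_%02d", seq_len(K))
  stopifnot(length(class_names) == K)
  unmasked <- which(!stack$mask)
  n <- length(unmasked)
  if (K > n) stop("K = ", K, " exceeds the ", n, " unmasked cells")
  r <- 1 / prevalence_skew
  p <- r^(seq_len(K) - 1)
  p <- p / sum(p)
  counts <- diff(c(0, round(cumsum(p) * n)))
  counts[K] <- n - sum(counts[-K])
  if (any(counts < 1)) {
    stop("prevalence_skew = ", prevalence_skew,
         " leaves some of the ", K, " classes without cells on this grid")
  }
  lab <- matrix(NA_integer_, stack$grid$n_rows, stack$grid$n_cols)
  remaining <- unmasked
  rule <- vector("list", K - 1)
  with_seed(rule_seed, {
    for (k in seq_len(K - 1)) {
      layer <- latent[sample.int(2, 1)]
      upper_tail <- runif(1) < 0.5
      v <- stack$layers[[layer]][remaining]
      ord <- order(v, decreasing = upper_tail)
      take <- remaining[ord[seq_len(counts[k])]]
      thr <- stack$layers[[layer]][take[counts[k]]]
      lab[take] <- k
      remaining <- setdiff(remaining, take)
      rule[[k]] <- data.frame(class = class_names[k], layer = layer,
                              tail = if (upper_tail) "high" else "low",
                              threshold = thr, count = counts[k])
    }
  })
  lab[remaining] <- as.integer(K)
  attr(lab, "classes") <- class_names
  attr(lab, "rule") <- do.call(rbind, rule)
  lab
}

#' Sample spatially clustered labelled observation points
#'
#' Two-stage sampling mimicking the clustered geography of pollen-site
#' compilations: cluster centres are drawn uniformly over unmasked cells,
#' then each point scatters around a centre with a truncated Gaussian
#' (within 3 standard deviations, i.e. within the cluster radius), landing
#' on unmasked cells only. Each point takes the label raster's class at its
#' cell with probability `1 - label_noise`, otherwise a uniformly random
#' other class.
#'
#' @param labels Class raster from [generate_true_labels()].
#' @param grid The [grid_spec()] the raster lives on.
#' @param n_points Number of points to draw.
#' @param n_clusters Number of cluster centres.
#' @param label_noise Mislabelling fraction in `[0, 1)`.
#' @param cluster_sd Gaussian scatter, in cells (cluster radius is
#'   `3 * cluster_sd`).
#' @param seed Integer seed.
#' @return Data frame (`point_id`, `lon`, `lat`, `label`, `row`, `col`,
#'   `cluster`) with the legend in attribute `classes`; `label` is a factor
#'   over the full legend.
#' @export
sample_observations <- function(labels, grid, n_points, n_clusters = 10,
                                label_noise = 0, cluster_sd = NULL, seed = 1) {
  stopifnot(n_points >= 1, n_clusters >= 1,
            label_noise >= 0, label_noise < 1)
  classes <- attr(labels, "classes")
  K <- length(classes)
  open <- which(!is.na(labels))
  if (n_points > length(open)) {
    stop("n_points = ", n_points, " exceeds the ", length(open),
         " unmasked cells")
  }
  if (is.null(cluster_sd)) {
    cluster_sd <- max(2, min(grid$n_rows, grid$n_cols) / 12)
  }
  with_seed(seed, {
    centres <- open[sample.int(length(open), n_clusters,
                               replace = n_clusters > length(open))]
    c_row <- ((centres - 1) %% grid$n_rows) + 1
    c_col <- ((centres - 1) %/% grid$n_rows) + 1
    assignment <- sample.int(n_clusters, n_points, replace = TRUE)
    row <- integer(n_points); col <- integer(n_points)
    for (i in seq_len(n_points)) {
      repeat {
        dr <- rnorm(1, 0, cluster_sd); dc <- rnorm(1, 0, cluster_sd)
        if (sqrt(dr^2 + dc^2) > 3 * cluster_sd) next
        ri <- as.integer(round(c_row[assignment[i]] + dr))
        ci <- as.integer(round(c_col[assignment[i]] + dc))
        ok <- ri >= 1 && ri <= grid$n_rows && ci >= 1 && ci <= grid$n_cols &&
          !is.na(labels[ri, ci])
        if (ok) break
      }
      row[i] <- ri; col[i] <- ci
    }
    true_k <- labels[cbind(row, col)]
    flip <- runif(n_points) < label_noise
    obs_k <- true_k
    if (any(flip) && K > 1) {
      obs_k[flip] <- vapply(true_k[flip], function(k) {
        others <- setdiff(seq_len(K), k)
        others[sample.int(length(others), 1)]
      }, integer(1))
    }
    out <- data.frame(
      point_id = sprintf("pt_%05d", seq_len(n_points)),
      lon = cell_centre_lon(grid, col),
      lat = cell_centre_lat(grid, row),
      label = factor(classes[obs_k], levels = classes),
      row = row, col = col, cluster = assignment,
      stringsAsFactors = FALSE
    )
    attr(out, "classes") <- classes
    out
  })
}

#' Apply a climate-scenario perturbation to a covariate stack
#'
#' Emulates a future-scenario covariate stack: temperature-kind layers are
#' shifted additively, precipitation-kind layers are scaled multiplicatively,
#' terrain layers and the mask are untouched.
#'
#' @param stack A [covariate_stack()] whose layers are tagged by kind.
#' @param temperature_shift Degrees added to every temperature layer.
#' @param precipitation_scale Positive multiplier on every precipitation
#'   layer.
#' @param scenario_tag Identifier carried in the result's `"scenario"`
#'   attribute (e.g. `"RCP8.5"`).
#' @return A perturbed [covariate_stack()] on the same grid.
#' @export
perturb_scenario <- function(stack, temperature_shift = 0,
                             precipitation_scale = 1,
                             scenario_tag = "scenario") {
  stopifnot(precipitation_scale > 0)
  out <- stack
  for (nm in names(stack$layers)) {
    out$layers[[nm]] <- switch(
      stack$kinds[[nm]],
      temperature   = stack$layers[[nm]] + temperature_shift,
      precipitation = stack$layers[[nm]] * precipitation_scale,
      terrain       = stack$layers[[nm]]
    )
    out$layers[[nm]][stack$mask] <- NA_real_
  }
  attr(out, "scenario") <- scenario_tag
  out
}

#' The package's standard synthetic study
#'
#' One call building the reference synthetic dataset used throughout the
#' documentation and tests: a 128 x 128 geographic grid, eight covariates
#' (four temperature-like, three precipitation-like, one terrain-like)
#' smoothed at a 12-cell correlation length, six biome classes with
#' geometric prevalence decay (ratio 2.5, most/least prevalent about two
#' orders of magnitude apart), and 2,500 clustered observation points with
#' 10% label noise.
#'
#' @param seed Integer master seed; component seeds are derived from it.
#' @param n_points Number of observation points.
#' @param label_noise Mislabelling fraction.
#' @param prevalence_skew Geometric decay ratio of class prevalences.
#' @return List with `stack`, `labels`, `obs`, `X` (feature matrix), `y`
#'   (factor labels) and `classes`.
#' @export
synthetic_biome_study <- function(seed = 1, n_points = 2500,
                                  label_noise = 0.1, prevalence_skew = 2.5) {
  g <- grid_spec(128, 128, lon_min = -10, lat_min = 10, cell_size = 0.25)
  spec <- data.frame(
    name = c("bio01", "bio02", "bio05", "bio06",
             "bio12", "bio13", "bio14", "elev"),
    kind = c(rep("temperature", 4), rep("precipitation", 3), "terrain")
  )
  stack <- generate_covariates(g, spec, corr_length = 12,
                               seed = derive_seed(seed, 1))
  labels <- generate_true_labels(stack, K = 6,
                                 rule_seed = derive_seed(seed, 2),
                                 prevalence_skew = prevalence_skew,
                                 latent = c("bio01", "bio12"))
  obs <- sample_observations(labels, g, n_points = n_points, n_clusters = 25,
                             label_noise = label_noise,
                             seed = derive_seed(seed, 3))
  list(stack = stack, labels = labels, obs = obs,
       X = extract_features(stack, obs), y = obs$label,
       classes = attr(labels, "classes"))
}
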