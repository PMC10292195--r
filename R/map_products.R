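#' Per-pixel class-probability cube
#'
#' Holds per-pixel per-class probabilities in percent (0--100), summing to
#' 100 within 1e-6 at every unmasked pixel, on a geographic grid.
#'
#' @param grid A [grid_spec()].
#' @param classes Ordered class names (the legend).
#' @param values 3-D array `n_rows x n_cols x K`, percent; `NA` on the mask.
#' @param mask Logical matrix, `TRUE` = excluded.
#' @return An object of class `prob_cube`.
#' @export
prob_cube <- function(grid, classes, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), length(dim(values)) == 3,
            dim(values)[3] == length(classes),
            dim(values)[1] == grid$n_rows, dim(values)[2] == grid$n_cols)
  if (is.null(mask)) mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  sums <- apply(values, c(1, 2), sum)
  open <- !mask
  if (any(is.na(sums[open]))) stop("NA probabilities at unmasked pixels")
  if (any(abs(sums[open] - 100) > 1e-6)) {
    stop("unmasked pixel probabilities must sum to 100 within 1e-6")
  }
  if (!all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 100 + 1e-9) {
      stop("probabilities must lie in [0, 100]")
    }
  }
  dimnames(values)[[3]] <- classes
  structure(list(grid = grid, classes = classes, values = values,
                 mask = mask),
            class = "prob_cube")
}

#' @export
print.prob_cube <- function(x, ...) {
  cat(sprintf("<prob_cube> %d classes on a %d x %d grid (%d masked pixels)\n",
              length(x$classes), x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  invisible(x)
}

#' Margin of victory of a probability cube
#'
#' The difference between the first and second highest class probability at
#' each pixel, in percentage points: 0 means the top two classes tie
#' (maximal confusion), 100 means all mass on one class (full confidence).
#'
#' @param cube A [prob_cube()].
#' @return Matrix of margins in `[0, 100]`; `NA` on the mask.
#' @export
margin_of_victory <- function(cube) {
  K <- length(cube$classes)
  if (K < 2) stop("margin of victory needs at least 2 classes")
  flat <- matrix(cube$values, ncol = K)
  mov <- apply(flat, 1, function(p) {
    if (anyNA(p)) return(NA_real_)
    s <- sort(p, decreasing = TRUE)
    s[1] - s[2]
  })
  matrix(mov, cube$grid$n_rows, cube$grid$n_cols)
}

#' Hard-class map of a probability cube
#'
#' Per-pixel argmax class; ties are broken by the lowest index in the
#' legend order (a documented, deterministic convention --- with continuous
#' probabilities ties are measure-zero).
#'
#' @param cube A [prob_cube()].
#' @return Integer matrix of class indices into `cube$classes` with the
#'   legend in attribute `classes`; `NA` on the mask.
#' @export
hard_classify <- function(cube) {
  K <- length(cube$classes)
  flat <- matrix(cube$values, ncol = K)
  open <- !is.na(flat[, 1])
  idx <- rep(NA_integer_, nrow(flat))
  if (any(open)) {
    idx[open] <- max.col(flat[open, , drop = FALSE], ties.method = "first")
  }
  out <- matrix(idx, cube$grid$n_rows, cube$grid$n_cols)
  attr(out, "classes") <- cube$classes
  out
}

#' The 20-class biome to six-biome IUCN translation scheme
#'
#' The canonical aggregation from the 20-class pollen-based biome legend to
#' the six terrestrial IUCN Global Ecosystem Typology biomes T1--T6
#' (tropical-subtropical forests; temperate-boreal forests and woodlands;
#' shrublands and shrubby woodlands; savannas and grasslands; deserts and
#' semi-deserts; polar/alpine). The intensive land-use biome T7 has no
#' source class and is excluded by construction.
#'
#' @return Named character vector: source class -> target class code.
#' @export
biome_iucn_scheme <- function() {
  c(
    "Tropical deciduous broadleaf forest and woodland" = "T1",
    "Tropical evergreen broadleaf forest"              = "T1",
    "Tropical semi evergreen broadleaf forest"         = "T1",
    "Cold deciduous forest"                            = "T2",
    "Cold evergreen needleleaf forest"                 = "T2",
    "Cool evergreen needleleaf forest"                 = "T2",
    "Cool mixed forest"                                = "T2",
    "Cool temperate rainforest"                        = "T2",
    "Temperate deciduous broadleaf forest"             = "T2",
    "Temperate sclerophyll woodland and shrubland"     = "T2",
    "Temperate evergreen needleleaf open woodland"     = "T3",
    "Warm temperate evergreen and mixed forest"        = "T3",
    "Xerophytic woods scrub"                           = "T3",
    "Tropical savanna"                                 = "T4",
    "Desert"                                           = "T5",
    "Steppe"                                           = "T5",
    "Erect dwarf shrub tundra"                         = "T6",
    "Graminoid and forb tundra"                        = "T6",
    "Low and high shrub tundra"                        = "T6",
    "Prostrate dwarf shrub tundra"                     = "T6"
  )
}

#' Aggregate a probability cube to a coarser legend
#'
#' Sums the per-pixel probabilities of all source classes mapping to each
#' target class. Probability mass is conserved exactly (no renormalization),
#' so the output still sums to 100 per unmasked pixel, and the margin of
#' victory can be recomputed on the aggregated cube.
#'
#' @param cube A [prob_cube()] on the source legend.
#' @param scheme Named character vector source class -> target class (see
#'   [biome_iucn_scheme()]); must cover every class of the cube.
#' @param target_order Optional ordering of the target legend (default:
#'   sorted unique targets).
#' @return A [prob_cube()] on the target legend.
#' @export
translate_probabilities <- function(cube, scheme = biome_iucn_scheme(),
                                    target_order = NULL) {
  miss <- setdiff(cube$classes, names(scheme))
  if (length(miss)) {
    stop("source class(es) absent from the translation scheme: ",
         paste(miss, collapse = ", "))
  }
  targets <- if (is.null(target_order)) {
    sort(unique(unname(scheme[cube$classes])))
  } else target_order
  g <- cube$grid
  vals <- array(0, c(g$n_rows, g$n_cols, length(targets)),
                dimnames = list(NULL, NULL, targets))
  for (src in cube$classes) {
    tgt <- scheme[[src]]
    vals[, , tgt] <- vals[, , tgt] + cube$values[, , src]
  }
  prob_cube(g, targets, vals, cube$mask)
}

#' Write map products as ASCII grids plus a JSON legend
#'
#' Emits one `.asc` per probability band (percent), the margin-of-victory
#' band, the hard-class band, and a JSON legend mapping class indices to
#' names (and, when a scheme is supplied, the translation table).
#'
#' @param cube A [prob_cube()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @param scheme Optional translation scheme echoed into the legend file.
#' @return Character vector of written paths, invisibly.
#' @export
write_map_products <- function(cube, dir, prefix = "biome",
                               scheme = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(cube$classes)) {
    p <- file.path(dir, sprintf("%s_prob_%02d.asc", prefix, i))
    write_asc(cube$values[, , i], cube$grid, p)
    paths <- c(paths, p)
  }
  p_mov <- file.path(dir, paste0(prefix, "_mov.asc"))
  write_asc(margin_of_victory(cube), cube$grid, p_mov)
  p_hard <- file.path(dir, paste0(prefix, "_hardclass.asc"))
  write_asc(hard_classify(cube) * 1.0, cube$grid, p_hard)
  p_leg <- file.path(dir, paste0(prefix, "_legend.json"))
  legend <- list(classes = as.list(setNames(seq_along(cube$classes),
                                            cube$classes)))
  if (!is.null(scheme)) legend$translation <- as.list(scheme)
  jsonlite::write_json(legend, p_leg, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p_mov, p_hard, p_leg))
}
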