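#' Define a geographic raster grid
#'
#' A grid of `n_rows` x `n_cols` square cells in geographic coordinates
#' (longitude/latitude degrees on a sphere). Rows are stored north to south
#' (row 1 is the northernmost band), the usual raster convention.
#'
#' @param n_rows,n_cols Grid dimensions (cells), at least 1.
#' @param lon_min,lat_min Coordinates of the grid's south-west corner, degrees.
#' @param cell_size Cell edge length, degrees.
#' @param crs_tag Identifier of the coordinate convention; only geographic
#'   longitude/latitude is supported.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(64, 64, lon_min = -10, lat_min = 30, cell_size = 0.25)
grid_spec <- function(n_rows, n_cols, lon_min = 0, lat_min = 0,
                      cell_size = 0.5, crs_tag = "lonlat") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  lat_max <- lat_min + n_rows * cell_size
  if (lat_min < -90 || lat_max > 90) {
    stop("grid latitude extent [", lat_min, ", ", lat_max,
         "] leaves [-90, 90]")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         lon_min = lon_min, lat_min = lat_min, cell_size = cell_size,
         crs_tag = crs_tag),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, origin (%g E, %g N)\n",
              x$n_rows, x$n_cols, x$cell_size, x$lon_min, x$lat_min))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "lon_min", "lat_min",
                                "cell_size")],
                   unclass(b)[c("n_rows", "n_cols", "lon_min", "lat_min",
                                "cell_size")]))
}

# Cell-centre coordinates. Row 1 = northernmost band.
cell_centre_lat <- function(grid, row) {
  grid$lat_min + (grid$n_rows - row + 0.5) * grid$cell_size
}
cell_centre_lon <- function(grid, col) {
  grid$lon_min + (col - 0.5) * grid$cell_size
}

# Map lon/lat to (row, col); points must fall inside the extent.
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1
  row_from_bottom <- floor((lat - grid$lat_min) / grid$cell_size) + 1
  row <- grid$n_rows - row_from_bottom + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad)) {
    stop(sum(bad), " point(s) fall outside the grid extent")
  }
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Bundle co-registered covariate layers into a stack
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices (`n_rows` x `n_cols`), one per
#'   covariate. Names must be unique.
#' @param kinds Character vector, one of `"temperature"`, `"precipitation"`,
#'   `"terrain"` per layer; used by scenario perturbation.
#' @param mask Logical matrix, `TRUE` = excluded cell. Excluded cells are set
#'   to `NA` in every layer.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, layers, kinds = NULL, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("layers must carry unique non-empty names")
  }
  if (is.null(mask)) mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (is.null(kinds)) kinds <- rep("terrain", length(layers))
  kinds <- match.arg(kinds, c("temperature", "precipitation", "terrain"),
                     several.ok = TRUE)
  stopifnot(length(kinds) == length(layers))
  dims_ok <- vapply(layers, function(m) {
    is.matrix(m) && nrow(m) == grid$n_rows && ncol(m) == grid$n_cols
  }, logical(1))
  if (!all(dims_ok)) stop("all layers must match the grid dimensions")
  stopifnot(is.matrix(mask), nrow(mask) == grid$n_rows,
            ncol(mask) == grid$n_cols, is.logical(mask))
  layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  structure(list(grid = grid, layers = layers,
                 kinds = setNames(kinds, nm), mask = mask),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on a %d x %d grid (%d masked cells)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  cat("  ", paste0(names(x$layers), " [", x$kinds, "]", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the covariate matrix at observation points
#'
#' Looks up every layer of `stack` at each observation's grid cell, giving the
#' point-by-feature design matrix the learners consume.
#'
#' @param stack A [covariate_stack()].
#' @param obs An observation table (see [sample_observations()]).
#' @return Numeric matrix, one row per point, one column per layer.
#' @export
extract_features <- function(stack, obs) {
  rc <- locate_cells(stack$grid, obs$lon, obs$lat)
  idx <- cbind(rc[, "row"], rc[, "col"])
  X <- vapply(stack$layers, function(m) m[idx], numeric(nrow(obs)))
  X <- matrix(X, nrow = nrow(obs),
              dimnames = list(obs$point_id, names(stack$layers)))
  X
}

# ---- plain-text raster and point writers --------------------------------

#' Write a matrix as an ESRI ASCII grid
#'
#' One band per file; `NA` cells are written as the nodata value.
#'
#' @param m Numeric matrix (rows north to south).
#' @param grid The [grid_spec()] georeferencing the matrix.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(m, grid, path, nodata = -9999) {
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$lon_min, digits = 15)),
    paste("yllcorner", format(grid$lat_min, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  m[is.na(m)] <- nodata
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_asc()] (or any conforming `.asc`).
#' @return List with elements `grid` ([grid_spec()]) and `values` (matrix,
#'   nodata as `NA`).
#' @export
read_asc <- function(path) {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "[[:space:]]+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  tolower(vapply(kv, `[`, "", 1)))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  grid <- grid_spec(hdr[["nrows"]], hdr[["ncols"]],
                    lon_min = hdr[["xllcorner"]], lat_min = hdr[["yllcorner"]],
                    cell_size = hdr[["cellsize"]])
  list(grid = grid, values = m)
}

#' Write a covariate stack as one ASCII grid per layer
#'
#' @param stack A [covariate_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_stack_asc <- function(stack, dir, prefix = "cov") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(prefix, "_", gsub("[^A-Za-z0-9_.-]", "_", nm),
                               ".asc"))
    write_asc(stack$layers[[nm]], stack$grid, p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Write an observation table as CSV and GeoJSON
#'
#' @param obs Observation table with columns `point_id`, `lon`, `lat`, `label`.
#' @param csv_path,geojson_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_observations <- function(obs, csv_path = NULL, geojson_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    write.csv(obs[, c("point_id", "lon", "lat", "label")], csv_path,
              row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(geojson_path)) {
    feats <- lapply(seq_len(nrow(obs)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(obs$lon[i], obs$lat[i])),
           properties = list(point_id = obs$point_id[i],
                             label = as.character(obs$label[i])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, geojson_path)
  }
  invisible(written)
}
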