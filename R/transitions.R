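#' Exact per-pixel areas on the authalic sphere
#'
#' Every pixel in a latitude band of a geographic grid has the same area,
#' given exactly by the spherical zone formula
#' `R^2 * d_lambda * (sin(lat_top) - sin(lat_bottom))` with
#' `R = 6371.0072` km the authalic Earth radius. This is the analytic
#' equivalent of measuring areas in an equal-area projection, with no
#' resampling step.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_rows` (row 1 = northernmost band),
#'   km^2 per pixel.
#' @export
#' @examples
#' g <- grid_spec(1, 1, lon_min = 0, lat_min = 0, cell_size = 1)
#' pixel_areas(g)  # ~1.236e4 km^2 for a 1x1 degree pixel on the equator
pixel_areas <- function(grid) {
  rows <- seq_len(grid$n_rows)
  lat_top <- grid$lat_min + (grid$n_rows - rows + 1) * grid$cell_size
  lat_bottom <- lat_top - grid$cell_size
  if (any(lat_bottom > lat_top)) stop("inverted latitude bounds")
  dlam <- grid$cell_size * pi / 180
  EARTH_RADIUS_KM^2 * dlam *
    (sin(lat_top * pi / 180) - sin(lat_bottom * pi / 180))
}

#' Detect confident class transitions between two epochs
#'
#' Compares the hard-class maps of a current and a future epoch. A pixel is
#' `changed` when its class differs, and `confident` when the margin of
#' victory passes `threshold` (inclusive, `>=`) on both maps
#' (`filter_mode = "both"`, the conservative default) or on the chosen one.
#' Only confident changed pixels enter downstream tallies.
#'
#' @param current,future Lists with elements `hard` (a [hard_classify()]
#'   map) and `mov` (a [margin_of_victory()] matrix), co-registered and on
#'   the same legend.
#' @param threshold Margin-of-victory confidence threshold, percentage
#'   points.
#' @param filter_mode Which epoch's margin the filter applies to.
#' @return Object of class `change_map`: `from`, `to` (class-index
#'   matrices), `changed`, `confident` (logical matrices, `NA` on the
#'   mask), `classes`, `threshold`, `filter_mode`.
#' @export
detect_transitions <- function(current, future, threshold = 50,
                               filter_mode = c("both", "current", "future")) {
  filter_mode <- match.arg(filter_mode)
  cl_cur <- attr(current$hard, "classes")
  cl_fut <- attr(future$hard, "classes")
  if (!identical(dim(current$hard), dim(future$hard))) {
    stop("current and future maps are not co-registered")
  }
  if (!identical(cl_cur, cl_fut)) stop("class legends differ")
  changed <- current$hard != future$hard
  conf <- switch(filter_mode,
                 both = current$mov >= threshold & future$mov >= threshold,
                 current = current$mov >= threshold,
                 future = future$mov >= threshold)
  structure(list(from = current$hard, to = future$hard,
                 changed = changed, confident = conf,
                 classes = cl_cur, threshold = threshold,
                 filter_mode = filter_mode),
            class = "change_map")
}

#' Count scenario agreement on confident transitions
#'
#' Per pixel, how many of the supplied change maps flag a confident change:
#' 1 = only one scenario sees the pixel transitioning, S = complete
#' agreement across the S scenarios.
#'
#' @param changes Non-empty list of co-registered [detect_transitions()]
#'   results.
#' @return Integer matrix of counts in `0..length(changes)`; `NA` where all
#'   maps are masked.
#' @export
scenario_agreement <- function(changes) {
  if (length(changes) == 0) stop("no change maps supplied")
  flags <- lapply(changes, function(ch) {
    f <- ch$changed & ch$confident
    mode(f) <- "integer"
    f
  })
  out <- Reduce(function(a, b) {
    s <- ifelse(is.na(a) & is.na(b), NA_integer_, 0L)
    s + ifelse(is.na(a), 0L, a) + ifelse(is.na(b), 0L, b)
  }, flags)
  out
}

#' Tally equal-area transition totals per class pair
#'
#' For each confident changed pixel, adds its spherical pixel area to the
#' (from, to) cell of the transition table. The diagonal is zero by
#' construction (only transitions are counted) and the grand total equals
#' the summed area of confident changed pixels exactly.
#'
#' @param change A [detect_transitions()] result.
#' @param areas Per-row pixel areas from [pixel_areas()] (or a full matrix
#'   co-registered with the maps).
#' @return Object of class `transition_table`: `$table` (K x K km^2
#'   matrix), `$total_km2`, plus the threshold/filter provenance.
#' @export
transition_areas <- function(change, areas) {
  K <- length(change$classes)
  nr <- nrow(change$from); nc <- ncol(change$from)
  A <- if (is.matrix(areas)) areas else matrix(areas, nr, nc)
  stopifnot(nrow(A) == nr, ncol(A) == nc)
  sel <- which(!is.na(change$changed) & change$changed &
                 !is.na(change$confident) & change$confident)
  tab <- matrix(0, K, K, dimnames = list(from = change$classes,
                                         to = change$classes))
  if (length(sel)) {
    cell <- (change$to[sel] - 1L) * K + change$from[sel]
    sums <- rowsum(A[sel], group = cell)
    tab[as.integer(rownames(sums))] <- sums[, 1]
  }
  structure(list(table = tab, total_km2 = sum(tab),
                 threshold = change$threshold,
                 filter_mode = change$filter_mode),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> total confident changed area %.4g km^2 (MoV >= %g, filter %s)\n",
              x$total_km2, x$threshold, x$filter_mode))
  print(signif(x$table, 4))
  invisible(x)
}

#' Write a transition table as long-format CSV and JSON summary
#'
#' The CSV holds one `(from, to, km2)` row per non-zero cell --- a
#' Sankey-ready two-column-plus-weight export; the JSON carries the total
#' and the filter provenance.
#'
#' @param tt A [transition_areas()] result.
#' @param csv_path,json_path Output paths; `NULL` skips.
#' @return Invisibly, the written paths.
#' @export
write_transition_table <- function(tt, csv_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    nz <- which(tt$table > 0, arr.ind = TRUE)
    df <- data.frame(from = rownames(tt$table)[nz[, 1]],
                     to = colnames(tt$table)[nz[, 2]],
                     km2 = tt$table[nz])
    write.csv(df[order(df$from, df$to), ], csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(total_km2 = tt$total_km2,
                              threshold = tt$threshold,
                              filter_mode = tt$filter_mode),
                         json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
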