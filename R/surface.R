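#' PMC surface matrix
#'
#' The nine first-level dimension scores of a policy arranged row-major into a
#' 3 x 3 grid: row 1 = (X1, X2, X3), row 2 = (X4, X5, X6), row 3 =
#' (X7, X8, X9). Rendered as a 3D surface, convex regions mark strong
#' dimensions and concave regions weak ones.
#'
#' @param x either a named numeric vector of the nine dimension scores, or a
#'   `pmc_evaluation` together with `policy` naming one scorecard.
#' @param policy policy id selecting one scorecard when `x` is an evaluation.
#' @return a `pmc_surface`: a 3 x 3 numeric matrix with dimension codes as
#'   cell names (stored in attribute `codes`).
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' ev <- evaluate_from_first_level(fx$scores)
#' surface_matrix(ev, policy = "P11")
surface_matrix <- function(x, policy = NULL) {
  if (inherits(x, "pmc_evaluation")) {
    dims <- x$dimension_averages$dimension
    if (is.null(policy)) {
      abort("supply `policy` to pick one scorecard, or use average_surface()",
            class = "pmcindex_input_error")
    }
    row <- filter(x$scorecards, .data$policy_id == policy)
    if (nrow(row) != 1) {
      abort(sprintf("policy '%s' not found", policy), class = "pmcindex_input_error")
    }
    vals <- as.numeric(row[1, dims])
    names(vals) <- dims
    x <- vals
  }
  if (length(x) != 9) {
    abort("a PMC surface needs exactly nine dimension scores", class = "pmcindex_input_error")
  }
  codes <- names(x) %||% paste0("X", 1:9)
  m <- matrix(as.numeric(x), nrow = 3, ncol = 3, byrow = TRUE)
  structure(m, codes = matrix(codes, 3, 3, byrow = TRUE), class = c("pmc_surface", "matrix"))
}

#' @rdname surface_matrix
#' @param result a `pmc_evaluation`.
#' @return `average_surface()`: the surface of the corpus dimension averages.
#' @export
average_surface <- function(result) {
  vals <- result$dimension_averages$average
  names(vals) <- result$dimension_averages$dimension
  surface_matrix(vals)
}

#' Interpolate a PMC surface onto a fine grid
#'
#' Expands the 3 x 3 control grid to `resolution` x `resolution` points for
#' plotting. `"interpolate"` uses tensor-product monotone Hermite splines
#' (rows then columns), which reproduce the control values exactly at the
#' nodes and never overshoot the range of the control grid; `"tile"` repeats
#' each control value over its cell (nearest-neighbour), for readers who want
#' the raw matrix without smoothing.
#'
#' @param surface a `pmc_surface`.
#' @param resolution number of grid points per axis, >= 3.
#' @param mode `"interpolate"` (default) or `"tile"`.
#' @return tibble with `row`, `col` (continuous positions in `[1, 3]`) and
#'   `value`.
#' @export
surface_grid <- function(surface, resolution = 30, mode = c("interpolate", "tile")) {
  mode <- match.arg(mode)
  if (resolution < 3) {
    abort("resolution must be >= 3", class = "pmcindex_input_error")
  }
  m <- unclass(surface)
  xs <- seq(1, 3, length.out = resolution)
  if (mode == "tile") {
    idx <- pmin(3, pmax(1, round(xs)))
    grid <- m[idx, idx, drop = FALSE]
  } else if (resolution == 3) {
    grid <- m
  } else {
    # rows first: 3 x resolution, then columns: resolution x resolution
    step1 <- t(apply(m, 1, function(v) splinefun(1:3, v, method = "monoH.FC")(xs)))
    grid <- apply(step1, 2, function(v) splinefun(1:3, v, method = "monoH.FC")(xs))
  }
  tibble(
    row = rep(xs, times = resolution),
    col = rep(xs, each = resolution),
    value = as.vector(grid)
  )
}

#' Export a surface grid (and optional image)
#'
#' @inheritParams surface_grid
#' @param file CSV destination for the gridded height field.
#' @param image optional PNG/SVG path; rendered with ggplot2 as a filled
#'   raster (the package does not attempt 3D perspective output).
#' @return the grid tibble, invisibly.
#' @export
export_surface_grid <- function(surface, file, resolution = 30,
                                mode = c("interpolate", "tile"), image = NULL) {
  grid <- surface_grid(surface, resolution = resolution, mode = mode)
  readr::write_csv(grid, file)
  if (!is.null(image)) {
    ggplot2::ggsave(image, plot = autoplot(surface, resolution = resolution),
                    width = 5, height = 4, dpi = 150)
  }
  invisible(grid)
}

#' @export
print.pmc_surface <- function(x, ...) {
  cat("PMC surface (rows: X1-X3 / X4-X6 / X7-X9):\n")
  print(matrix(fmt2(unclass(x)), 3, 3), quote = FALSE)
  invisible(x)
}

#' Heatmap rendering of a PMC surface
#'
#' @param object a `pmc_surface`.
#' @param resolution interpolation resolution (see [surface_grid()]).
#' @param ... passed to [surface_grid()].
#' @return a ggplot object.
#' @method autoplot pmc_surface
#' @export
autoplot.pmc_surface <- function(object, resolution = 30, ...) {
  grid <- surface_grid(object, resolution = resolution, ...)
  ggplot(grid, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score")
}

#' Radar data: dimension averages with low-score flags
#'
#' @param result a `pmc_evaluation`.
#' @param threshold flag dimensions with average strictly below this value
#'   (default 0.6, the conventional cut separating adequately covered
#'   dimensions from improvement targets).
#' @return tibble with `dimension`, `average`, `display`, `flagged`.
#' @export
#' @examples
#' fx <- mqimp_fixture()
#' radar_data(evaluate_from_first_level(fx$scores))
radar_data <- function(result, threshold = 0.6) {
  result$dimension_averages |>
    mutate(flagged = .data$average < threshold) |>
    select("dimension", "average", "display", "flagged")
}
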