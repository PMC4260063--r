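#' Construct a comparison surface
#'
#' A raster derived from one or two density surfaces by map algebra.
#'
#' @param grid A [grid_spec()].
#' @param values Value matrix (row 1 = top); `NA` marks NODATA.
#' @param kind One of `"difference"`, `"ratio"`,
#'   `"indicator_difference"`, `"mask"`.
#' @param parent_stats For indicator kinds, list of the two parent
#'   [surface_stats()] objects.
#' @return A `comparison_surface` object.
#' @export
comparison_surface <- function(grid, values,
                               kind = c("difference", "ratio",
                                        "indicator_difference", "mask"),
                               parent_stats = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols) {
    abort_appdens("values matrix does not match grid dimensions",
                  "invalid_parameter")
  }
  finite <- values[!is.na(values)]
  if (kind == "indicator_difference" && !all(finite %in% c(-1, 0, 1))) {
    abort_appdens("indicator_difference values must be in {-1, 0, 1}",
                  "invalid_parameter")
  }
  if (kind == "mask" && !all(finite %in% c(0, 1))) {
    abort_appdens("mask values must be in {0, 1}", "invalid_parameter")
  }
  if (kind == "ratio" && any(finite < 0)) {
    abort_appdens("ratio values must be >= 0", "invalid_parameter")
  }
  structure(list(grid = grid, values = values, kind = kind,
                 parent_stats = parent_stats),
            class = "comparison_surface")
}

#' @export
print.comparison_surface <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<comparison_surface> kind=%s %dx%d cells, values %.4g-%.4g\n",
              x$kind, x$grid$nrows, x$grid$ncols, rng[1L], rng[2L]))
  invisible(x)
}

#' Cellwise statistics of a density surface
#'
#' Mean and population (divide-by-N) standard deviation over all
#' non-NODATA cells — the "entire sample space" — and the derived
#' high-density threshold `mean + n_sd * sd`.
#'
#' @param surface A `density_surface`.
#' @param n_sd Standard-deviation multiplier (default 2).
#' @return A `surface_stats` list: `mean`, `sd`, `threshold`, `n_sd`,
#'   `n_cells`.
#' @examples
#' # a surface with cell mean 14 and sd 7 yields threshold 28
#' g <- grid_spec(0, 0, 1, 2, 1)
#' s <- density_surface(g, matrix(c(7, 21), 1))
#' surface_stats(s)$threshold
#' @export
surface_stats <- function(surface, n_sd = 2) {
  v <- surface$values[!is.na(surface$values)]
  if (length(v) == 0L) {
    abort_appdens("surface has no non-NODATA cells", "empty_surface")
  }
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population sd
  structure(list(mean = m, sd = s, threshold = m + n_sd * s,
                 n_sd = n_sd, n_cells = length(v)),
            class = "surface_stats")
}

#' @export
print.surface_stats <- function(x, ...) {
  cat(sprintf(
    "<surface_stats> mean %.4g, sd %.4g over %d cells; mean + %g sd = %.4g\n",
    x$mean, x$sd, x$n_cells, x$n_sd, x$threshold))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!grids_identical(a$grid, b$grid)) {
    abort_appdens("surfaces are on incompatible grids", "incompatible_grids")
  }
}

#' Cellwise difference of two density surfaces
#'
#' `a - b`: zero means no difference; positive cells have higher
#' density in `a` (an absolute excess of users of stratum `a`).
#' NODATA in either operand propagates.
#'
#' @param a,b `density_surface`s on the same grid.
#' @return A [comparison_surface()] of kind `"difference"`.
#' @export
surface_difference <- function(a, b) {
  check_same_grid(a, b)
  comparison_surface(a$grid, a$values - b$values, kind = "difference")
}

#' Cellwise ratio of two density surfaces
#'
#' `a / b`: one means no difference; values above one mark relative
#' excess of stratum `a` even where both densities are small.  Cells
#' where `b` is zero become NODATA (the ratio is undefined there, and
#' an ASCII raster has no infinity).
#'
#' @param a,b `density_surface`s on the same grid.
#' @return A [comparison_surface()] of kind `"ratio"`.
#' @export
surface_ratio <- function(a, b) {
  check_same_grid(a, b)
  vals <- a$values / b$values
  vals[!is.na(b$values) & b$values == 0] <- NA_real_
  comparison_surface(a$grid, vals, kind = "ratio")
}

#' Mask of extreme-density cells
#'
#' Cells strictly exceeding the surface's own `mean + n_sd * sd`
#' threshold are 1, others 0; NODATA propagates.  With the default
#' `n_sd = 2` this flags the highest-density areas of the map.
#'
#' @param surface A `density_surface`.
#' @param n_sd Standard-deviation multiplier (default 2).
#' @return A [comparison_surface()] of kind `"mask"` with the
#'   [surface_stats()] used attached as `parent_stats`.
#' @export
extreme_mask <- function(surface, n_sd = 2) {
  st <- surface_stats(surface, n_sd = n_sd)
  vals <- ifelse(surface$values > st$threshold, 1, 0)
  vals[is.na(surface$values)] <- NA_real_
  comparison_surface(surface$grid, vals, kind = "mask",
                     parent_stats = list(st))
}

#' Indicator-difference of two surfaces' extreme areas
#'
#' Computes `I(a > mean_a + n_sd * sd_a) - I(b > mean_b + n_sd * sd_b)`
#' cellwise, each surface thresholded against its OWN statistics.
#' The result takes only three values: 1 where only `a` is extreme,
#' -1 where only `b` is extreme, and 0 where both or neither are.
#' This contrasts where each stratum's density is highest, regardless
#' of which stratum is larger in absolute terms.
#'
#' @param a,b `density_surface`s on the same grid.
#' @param n_sd Standard-deviation multiplier (default 2).
#' @return A [comparison_surface()] of kind `"indicator_difference"`
#'   with both parents' [surface_stats()] attached.
#' @export
indicator_difference <- function(a, b, n_sd = 2) {
  check_same_grid(a, b)
  ma <- extreme_mask(a, n_sd = n_sd)
  mb <- extreme_mask(b, n_sd = n_sd)
  comparison_surface(a$grid, ma$values - mb$values,
                     kind = "indicator_difference",
                     parent_stats = c(ma$parent_stats, mb$parent_stats))
}
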