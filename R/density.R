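#' Raster grid geometry
#'
#' ESRI ASCII grid convention: `xll`/`yll` name the lower-left corner
#' of the grid, `cell_size` the square cell edge, and the value matrix
#' stores row 1 as the TOP row.
#'
#' @param xll,yll Lower-left corner in miles.
#' @param cell_size Cell edge in miles (> 0).
#' @param ncols,nrows Grid dimensions (positive integers).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(xll, yll, cell_size, ncols, nrows) {
  check_positive(cell_size, "cell_size")
  if (ncols < 1L || nrows < 1L) {
    abort_appdens("grid must have at least one row and column",
                  "invalid_parameter")
  }
  structure(list(xll = as.numeric(xll), yll = as.numeric(yll),
                 cell_size = as.numeric(cell_size),
                 ncols = as.integer(ncols), nrows = as.integer(nrows)),
            class = "grid_spec")
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with vectors `x` (length `ncols`, left to right) and
#'   `y` (length `nrows`, TOP to bottom, matching matrix row order).
#' @export
grid_cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cell_size,
       y = grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cell_size)
}

#' Grid covering a study region
#'
#' @param region A [study_region()].
#' @param cell_size Cell edge in miles (default 0.1).
#' @param pad Extra margin in miles around the region's bounding box.
#' @return A [grid_spec()] whose bounding box contains the region.
#' @export
region_grid <- function(region, cell_size = 0.1, pad = 0) {
  stopifnot(inherits(region, "study_region"))
  check_positive(cell_size, "cell_size")
  bb <- region_bbox(region)
  xll <- bb["xmin"] - pad
  yll <- bb["ymin"] - pad
  ncols <- ceiling((bb["xmax"] + pad - xll) / cell_size)
  nrows <- ceiling((bb["ymax"] + pad - yll) / cell_size)
  grid_spec(xll, yll, cell_size, ncols, nrows)
}

#' Standardize a capture count to a reference area
#'
#' Stops observe different radii, so raw counts are not comparable.
#' Rescaling by area gives `per_sqmi = count / (pi * r^2)` users per
#' square mile and `per_circle = count / r^2` users per 1-mile-radius
#' reference circle (area pi square miles).
#'
#' @param count Non-negative integer capture count (vectorized).
#' @param radius_mi Observed radius in miles (> 0, vectorized).
#' @return List with numeric vectors `per_circle` and `per_sqmi`.
#' @examples
#' standardize_count(12, 2)  # per_circle 3, per_sqmi 12 / (4 * pi)
#' @export
standardize_count <- function(count, radius_mi) {
  if (any(radius_mi <= 0) || anyNA(radius_mi)) {
    abort_appdens("radius_mi must be > 0", "invalid_radius")
  }
  if (any(count < 0)) abort_appdens("count must be >= 0", "invalid_parameter")
  list(per_circle = count / radius_mi^2,
       per_sqmi = count / (pi * radius_mi^2))
}

# Truncated-gaussian mass inside 3 bandwidths (Rayleigh CDF at 3).
GAUSS_TRUNC_MASS <- 1 - exp(-4.5)

# Radial kernel profile evaluated at distance d, bandwidth h;
# integrates to 1 over the plane (within its support).
kernel_profile <- function(d, h, kernel) {
  if (kernel == "gaussian") {
    ifelse(d <= 3 * h,
           exp(-d^2 / (2 * h^2)) / (2 * pi * h^2 * GAUSS_TRUNC_MASS),
           0)
  } else {  # quartic, support = one bandwidth
    u2 <- pmin((d / h)^2, 1)
    3 / (pi * h^2) * (1 - u2)^2
  }
}

kernel_support <- function(h, kernel) if (kernel == "gaussian") 3 * h else h

#' Weighted kernel density surface of app users
#'
#' Each sampling stop contributes a radially symmetric kernel centered
#' at its location, scaled so that its integrated volume equals the
#' stop's weight for the requested stratum; cell values are the sum of
#' kernel contributions at cell centers, in users per square mile.
#' The default weight is the standardized per-1-mile-circle count
#' (`count / radius^2`); `weight_mode = "raw"` weights by the raw
#' capture count instead.
#'
#' The default kernel is a bivariate gaussian truncated at 3 bandwidths
#' and renormalized to unit mass; `"quartic"` gives the compact-support
#' kernel classically used by GIS kernel-density tools (support = one
#' bandwidth).
#'
#' @param samples Stop-level data frame (from [sample_points_table()]
#'   or [read_sample_points_csv()]) with `x_mi`, `y_mi`, `radius_mi`
#'   and count columns `n_<stratum>`.
#' @param stratum Stratum name: `"total"`, `"white"`, `"black"`,
#'   `"other"`, an age group such as `"age_18_24"`, or any custom
#'   column suffix present in `samples`.
#' @param bandwidth_mi Kernel bandwidth in miles (> 0); the field
#'   protocol used 1 and 2 miles.
#' @param grid A [grid_spec()]; defaults to [region_grid()] of
#'   `region` when supplied.
#' @param kernel `"gaussian"` (truncated, default) or `"quartic"`.
#' @param region Optional [study_region()]; cells outside it become
#'   `NODATA` (`NA`).
#' @param weight_mode `"standardized"` (default) or `"raw"`.
#' @param counts Optional numeric vector overriding the stratum count
#'   column (one value per stop).
#' @return A `density_surface`: list with `grid`, `values` matrix
#'   (users per square mile, row 1 = top), `stratum`, `bandwidth_mi`,
#'   `kernel`.
#' @export
kernel_density <- function(samples, stratum = "total", bandwidth_mi = 2,
                           grid = NULL, kernel = c("gaussian", "quartic"),
                           region = NULL,
                           weight_mode = c("standardized", "raw"),
                           counts = NULL) {
  kernel <- match.arg(kernel)
  weight_mode <- match.arg(weight_mode)
  check_positive(bandwidth_mi, "bandwidth_mi")
  if (is.null(grid)) {
    if (is.null(region)) {
      abort_appdens("supply `grid` or `region`", "invalid_parameter")
    }
    grid <- region_grid(region)
  }
  if (is.null(counts)) {
    col <- paste0("n_", stratum)
    if (!col %in% names(samples)) {
      abort_appdens(sprintf("samples has no column '%s'", col),
                    "invalid_parameter")
    }
    counts <- samples[[col]]
  }
  w <- switch(weight_mode,
              standardized = standardize_count(counts, samples$radius_mi)$per_circle,
              raw = as.numeric(counts))
  cc <- grid_cell_centers(grid)
  vals <- matrix(0, nrow = grid$nrows, ncol = grid$ncols)
  supp <- kernel_support(bandwidth_mi, kernel)
  for (i in seq_len(nrow(samples))) {
    if (w[i] == 0) next
    x0 <- samples$x_mi[i]; y0 <- samples$y_mi[i]
    jx <- which(abs(cc$x - x0) <= supp)
    jy <- which(abs(cc$y - y0) <= supp)
    if (!length(jx) || !length(jy)) next
    d <- sqrt(outer((cc$y[jy] - y0)^2, (cc$x[jx] - x0)^2, `+`))
    vals[jy, jx] <- vals[jy, jx] + w[i] * kernel_profile(d, bandwidth_mi, kernel)
  }
  if (!is.null(region)) {
    mask <- outer(cc$y, cc$x, function(y, x) in_region(region, x, y))
    vals[!mask] <- NA_real_
  }
  density_surface(grid, vals, stratum = stratum,
                  bandwidth_mi = bandwidth_mi, kernel = kernel)
}

#' Construct a density surface
#'
#' @param grid A [grid_spec()].
#' @param values `nrows x ncols` numeric matrix (row 1 = top) of users
#'   per square mile; `NA` marks NODATA cells.
#' @param stratum Stratum label.
#' @param bandwidth_mi,kernel Smoothing metadata.
#' @return A `density_surface` object.
#' @export
density_surface <- function(grid, values, stratum = "total",
                            bandwidth_mi = NA_real_, kernel = "gaussian") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols) {
    abort_appdens("values matrix does not match grid dimensions",
                  "invalid_parameter")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort_appdens("density values must be >= 0", "invalid_parameter")
  }
  structure(list(grid = grid, values = values, stratum = stratum,
                 bandwidth_mi = bandwidth_mi, kernel = kernel),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf(
    "<density_surface> stratum=%s %dx%d cells of %g mi, bandwidth %g mi (%s)\n",
    x$stratum, x$grid$nrows, x$grid$ncols, x$grid$cell_size,
    x$bandwidth_mi, x$kernel))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values %.4g-%.4g users/sq mi, %d NODATA cells\n",
              rng[1L], rng[2L], sum(is.na(x$values))))
  invisible(x)
}

#' Summarize standardized per-stop densities
#'
#' Order statistics and a histogram of the standardized density
#' observed at each stop, the stop-level view of spatial heterogeneity
#' (field data are typically strongly right-skewed: mean well above
#' median).
#'
#' @param samples Stop-level data frame.
#' @param stratum Stratum name (count column suffix).
#' @param measure `"per_sqmi"` (users per square mile, default) or
#'   `"per_circle"` (users per 1-mile-radius circle).
#' @param breaks Histogram bin specification passed to [graphics::hist]
#'   semantics via [base::cut]; either a number of bins or a vector of
#'   edges.
#' @return List with `n`, `mean`, `median`, `min`, `max`, `densities`,
#'   and `histogram` (data frame of bin intervals and counts).
#' @export
per_point_density_summary <- function(samples, stratum = "total",
                                      measure = c("per_sqmi", "per_circle"),
                                      breaks = 10) {
  measure <- match.arg(measure)
  if (is.null(samples) || nrow(samples) == 0L) {
    abort_appdens("no sample points to summarize", "empty_input")
  }
  col <- paste0("n_", stratum)
  if (!col %in% names(samples)) {
    abort_appdens(sprintf("samples has no column '%s'", col), "invalid_parameter")
  }
  dens <- standardize_count(samples[[col]], samples$radius_mi)[[measure]]
  h <- graphics::hist(dens, breaks = breaks, plot = FALSE)
  list(n = length(dens), mean = mean(dens), median = stats::median(dens),
       min = min(dens), max = max(dens), densities = dens,
       histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                              upper = h$breaks[-1L], count = h$counts))
}

ASC_NODATA <- -9999

#' ESRI ASCII grid round-trip
#'
#' Header lines `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` followed by rows top-to-bottom, space-delimited,
#' numbers in `%g` style with 6 significant digits.  Write -> read ->
#' write is byte-identical.
#'
#' @param surface A `density_surface` or `comparison_surface`.
#' @param path Output `.asc` path.
#' @export
write_asc <- function(surface, path) {
  grid <- surface$grid
  vals <- surface$values
  vals[is.na(vals)] <- ASC_NODATA
  rows <- apply(vals, 1L, function(r) paste(fmt_num(r), collapse = " "))
  header <- c(paste("ncols", grid$ncols),
              paste("nrows", grid$nrows),
              paste("xllcorner", fmt_num(grid$xll)),
              paste("yllcorner", fmt_num(grid$yll)),
              paste("cellsize", fmt_num(grid$cell_size)),
              paste("NODATA_value", ASC_NODATA))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @param stratum,bandwidth_mi,kernel Metadata to attach to the read
#'   surface (the ASC format itself carries none).
#' @param kind Force interpretation as a [comparison_surface()] of the
#'   given kind; by default non-negative rasters read as densities and
#'   rasters with negative cells as comparison surfaces.
#' @return `read_asc`: a [density_surface()] or [comparison_surface()].
#' @export
read_asc <- function(path, stratum = "unknown", bandwidth_mi = NA_real_,
                     kernel = "gaussian", kind = NULL) {
  lines <- readLines(path)
  if (length(lines) < 7L) {
    abort_appdens(sprintf("%s: truncated ASC file", path), "parse_error")
  }
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L) {
      abort_appdens(sprintf("%s:%d: malformed header line", path, i),
                    "parse_error")
    }
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    abort_appdens(sprintf("%s: incomplete ASC header", path), "parse_error")
  }
  nrows <- as.integer(hdr$nrows)
  if (length(lines) != 6L + nrows) {
    abort_appdens(sprintf("%s:%d: expected %d data rows", path,
                          length(lines), nrows), "parse_error")
  }
  vals <- matrix(NA_real_, nrow = nrows, ncol = as.integer(hdr$ncols))
  for (i in seq_len(nrows)) {
    row <- as.numeric(strsplit(trimws(lines[6L + i]), "\\s+")[[1L]])
    if (length(row) != hdr$ncols || anyNA(row)) {
      abort_appdens(sprintf("%s:%d: malformed data row", path, 6L + i),
                    "parse_error")
    }
    vals[i, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$ncols, nrows)
  if (!is.null(kind)) {
    comparison_surface(grid, vals, kind = kind)
  } else if (any(vals < 0, na.rm = TRUE)) {
    # negative cells cannot be a density; read as a difference raster
    # (or an indicator raster if only -1/0/1 appear)
    k <- if (all(vals %in% c(-1, 0, 1) | is.na(vals)))
      "indicator_difference" else "difference"
    comparison_surface(grid, vals, kind = k)
  } else {
    density_surface(grid, vals, stratum = stratum,
                    bandwidth_mi = bandwidth_mi, kernel = kernel)
  }
}
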