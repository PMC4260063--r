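#' Render a surface as a PNG heatmap
#'
#' Cosmetic output: density surfaces get a sequential color ramp,
#' indicator surfaces a three-color categorical scheme (-1 green,
#' 0 white, 1 red), NODATA light gray.  Optional overlay points (for
#' example recruitment venues or sampling stops) are drawn as small
#' dark markers.  Rendering failures warn and continue; they never
#' abort an analysis.
#'
#' @param surface A `density_surface` or `comparison_surface`.
#' @param path Output PNG path.
#' @param overlay_points Optional data frame with `x_mi`, `y_mi`.
#' @param upscale Integer pixel replication factor per cell (default
#'   chosen to give roughly 400-px-wide images).
#' @return Invisibly, `path` (or `NULL` if rendering failed).
#' @export
render_surface <- function(surface, path, overlay_points = NULL,
                           upscale = NULL) {
  tryCatch({
    grid <- surface$grid
    vals <- surface$values
    indicator <- inherits(surface, "comparison_surface") &&
      surface$kind %in% c("indicator_difference", "mask")
    if (indicator) {
      cols <- matrix("#FFFFFF", nrow(vals), ncol(vals))
      cols[!is.na(vals) & vals > 0] <- "#C0392B"
      cols[!is.na(vals) & vals < 0] <- "#1E8449"
    } else {
      pal <- grDevices::hcl.colors(256L, "YlGnBu", rev = TRUE)
      rng <- range(vals, na.rm = TRUE)
      idx <- if (diff(rng) > 0) {
        pmin(256L, 1L + floor(255 * (vals - rng[1L]) / diff(rng)))
      } else matrix(1L, nrow(vals), ncol(vals))
      cols <- matrix(pal[idx], nrow(vals), ncol(vals))
    }
    cols[is.na(vals)] <- "#DDDDDD"
    if (!is.null(overlay_points) && nrow(overlay_points) > 0L) {
      col_i <- pmax(1L, pmin(grid$ncols,
        ceiling((overlay_points$x_mi - grid$xll) / grid$cell_size)))
      row_i <- pmax(1L, pmin(grid$nrows,
        grid$nrows - floor((overlay_points$y_mi - grid$yll) / grid$cell_size)))
      for (k in seq_along(col_i)) {
        rr <- pmax(1L, pmin(grid$nrows, row_i[k] + (-1L:1L)))
        cc <- pmax(1L, pmin(grid$ncols, col_i[k] + (-1L:1L)))
        cols[rr, cc] <- "#111111"
      }
    }
    rgb <- grDevices::col2rgb(cols) / 255
    img <- array(0, dim = c(nrow(cols), ncol(cols), 3L))
    img[, , 1L] <- matrix(rgb[1L, ], nrow(cols), ncol(cols))
    img[, , 2L] <- matrix(rgb[2L, ], nrow(cols), ncol(cols))
    img[, , 3L] <- matrix(rgb[3L, ], nrow(cols), ncol(cols))
    if (is.null(upscale)) upscale <- max(1L, floor(400 / ncol(cols)))
    if (upscale > 1L) {
      ones <- matrix(1, upscale, upscale)
      big <- array(0, dim = c(nrow(cols) * upscale, ncol(cols) * upscale, 3L))
      for (ch in 1:3) big[, , ch] <- kronecker(img[, , ch], ones)
      img <- big
    }
    png::writePNG(img, path)
    invisible(path)
  }, error = function(e) {
    warning("rendering failed: ", conditionMessage(e))
    invisible(NULL)
  })
}
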