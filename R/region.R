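#' Define a polygonal study region
#'
#' A study region is the analysis extent: a simple (non-self-intersecting)
#' polygon in planar coordinates measured in miles.  All sampling,
#' density estimation and raster masking happen inside this polygon.
#'
#' @param vertices Two-column matrix or data frame of `(x, y)` vertex
#'   coordinates in miles, in order around the boundary.  The polygon is
#'   closed automatically (the first vertex is appended if the last
#'   differs from it).
#' @param name Label for the region.
#' @return An object of class `study_region` with elements `vertices`
#'   (closed polygon matrix), `name`, and `area` in square miles.
#' @examples
#' sq <- study_region(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), "square")
#' region_area(sq)  # 100
#' @export
study_region <- function(vertices, name = "region") {
  v <- as.matrix(vertices)
  if (is.null(v) || nrow(v) < 3L || ncol(v) != 2L || anyNA(v)) {
    abort_appdens("region polygon needs at least 3 finite (x, y) vertices",
                  "invalid_region")
  }
  storage.mode(v) <- "double"
  # normalize: drop a duplicated closing vertex, then close explicitly
  if (all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) {
    abort_appdens("region polygon needs at least 3 distinct vertices",
                  "invalid_region")
  }
  closed <- rbind(v, v[1L, ])
  if (polygon_self_intersects(v)) {
    abort_appdens("region polygon is self-intersecting", "invalid_region")
  }
  area <- shoelace_area(v)
  if (area <= 0) {
    abort_appdens("region polygon has zero area", "invalid_region")
  }
  structure(list(vertices = closed, name = as.character(name)[1L],
                 area = area),
            class = "study_region")
}

# Shoelace formula; absolute value so vertex orientation does not matter.
shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# O(n^2) proper-crossing test between non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]))
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      denom <- cross(r[1L], r[2L], s[1L], s[2L])
      if (abs(denom) < 1e-14) next
      t <- cross(q[1L] - p[1L], q[2L] - p[2L], s[1L], s[2L]) / denom
      u <- cross(q[1L] - p[1L], q[2L] - p[2L], r[1L], r[2L]) / denom
      if (t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12) return(TRUE)
    }
  }
  FALSE
}

#' @rdname study_region
#' @param region A `study_region`.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "study_region"))
  region$area
}

#' Bounding box of a study region
#'
#' @param region A `study_region`.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)` in miles.
#' @export
region_bbox <- function(region) {
  stopifnot(inherits(region, "study_region"))
  v <- region$vertices
  c(xmin = min(v[, 1L]), ymin = min(v[, 2L]),
    xmax = max(v[, 1L]), ymax = max(v[, 2L]))
}

#' Test points for membership in a study region
#'
#' @param region A `study_region`.
#' @param x,y Numeric vectors of coordinates in miles.
#' @return Logical vector, `TRUE` for points inside the polygon.
#' @export
in_region <- function(region, x, y) {
  stopifnot(inherits(region, "study_region"))
  if (length(x) == 0L) return(logical(0L))
  bnd <- region$vertices
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("<study_region> %s: %d vertices, %.4g sq mi\n",
              x$name, nrow(x$vertices) - 1L, x$area))
  invisible(x)
}

#' Read or write a study region as GeoJSON
#'
#' The GeoJSON `Polygon` coordinates are interpreted as planar miles
#' (no geographic projection is applied).  Only the exterior ring is
#' used; holes are not supported.
#'
#' @param path Path to a GeoJSON file containing a Polygon geometry
#'   (bare geometry, Feature, or single-feature FeatureCollection).
#' @return `read_region_geojson`: a [study_region()].
#' @export
read_region_geojson <- function(path) {
  g <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  abort_appdens(sprintf("cannot parse GeoJSON '%s': %s",
                                        path, conditionMessage(e)),
                                "parse_error")
                })
  name <- "region"
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) < 1L) abort_appdens("empty FeatureCollection", "parse_error")
    feat <- if (is.data.frame(g$features)) {
      list(geometry = list(type = g$features$geometry$type[1L],
                           coordinates = g$features$geometry$coordinates[[1L]]),
           properties = as.list(g$features$properties[1L, , drop = FALSE]))
    } else g$features[[1L]]
    if (!is.null(feat$properties$name)) name <- feat$properties$name
    g <- feat$geometry
  } else if (identical(g$type, "Feature")) {
    if (!is.null(g$properties$name)) name <- g$properties$name
    g <- g$geometry
  }
  if (!identical(g$type, "Polygon")) {
    abort_appdens("GeoJSON geometry is not a Polygon", "parse_error")
  }
  ring <- g$coordinates
  if (is.list(ring)) ring <- ring[[1L]]
  if (length(dim(ring)) == 3L) ring <- ring[1L, , ]
  study_region(ring, name = name)
}

#' @rdname read_region_geojson
#' @param region A `study_region` to serialize.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "study_region"))
  coords <- unname(lapply(seq_len(nrow(region$vertices)), function(i) {
    as.numeric(region$vertices[i, ])
  }))
  obj <- list(type = "Feature",
              properties = list(name = region$name),
              geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Demo study region
#'
#' A rectangular analysis extent of 13.24 x 10 miles (132.4 square
#' miles, the area of the city the method was piloted in), used by the
#' bundled demo scenario.
#'
#' @return A [study_region()].
#' @export
demo_region <- function() {
  study_region(cbind(c(0, 13.24, 13.24, 0), c(0, 0, 10, 10)), name = "demo-city")
}
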