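#' Profile categorization rules
#'
#' Field protocol: missing race is analysed as `"other"`; missing age
#' goes to an `unknown` group; reported ages fall into right-open bins
#' defined by `age_breaks`.  The default breaks `c(18, 25, 31, Inf)`
#' give groups 18-24 / 25-30 / >30; an alternative convention with
#' breaks `c(18, 26, 31, Inf)` (18-25 / 26-30 / >30) is equally valid —
#' both appear in field reports.
#'
#' @param race_map Named character vector mapping raw race values to
#'   analysis categories; raw `"missing"` maps to `"other"`.
#' @param age_breaks Increasing numeric vector of bin edges starting at
#'   18 and ending at `Inf`; bins are `[e_i, e_{i+1})`.
#' @param unknown_label Age-group label for missing ages.
#' @return A `categorization_rules` object with derived `age_labels`.
#' @export
categorization_rules <- function(race_map = c(white = "white", black = "black",
                                              other = "other",
                                              missing = "other"),
                                 age_breaks = c(18, 25, 31, Inf),
                                 unknown_label = "unknown") {
  if (length(age_breaks) < 2L || is.unsorted(age_breaks, strictly = TRUE) ||
      age_breaks[1L] != 18 || !is.infinite(age_breaks[length(age_breaks)])) {
    abort_appdens("age_breaks must increase strictly from 18 to Inf",
                  "invalid_parameter")
  }
  k <- length(age_breaks) - 1L
  labels <- character(k)
  for (i in seq_len(k)) {
    labels[i] <- if (is.infinite(age_breaks[i + 1L])) {
      paste0(">", age_breaks[i] - 1L)
    } else {
      paste0(age_breaks[i], "-", age_breaks[i + 1L] - 1L)
    }
  }
  structure(list(race_map = race_map, age_breaks = age_breaks,
                 age_labels = labels, unknown_label = unknown_label),
            class = "categorization_rules")
}

age_group <- function(age, rules) {
  out <- rep(rules$unknown_label, length(age))
  known <- !is.na(age)
  if (any(known)) {
    idx <- findInterval(age[known], rules$age_breaks, rightmost.closed = FALSE)
    out[known] <- rules$age_labels[idx]
  }
  out
}

#' Categorize one or more raw profiles
#'
#' @param raw_race Character vector of raw race values (`white`,
#'   `black`, `other`, `missing`).
#' @param raw_age Numeric vector of ages (`NA` for missing).
#' @param rules A [categorization_rules()].
#' @return Data frame with columns `race` (analysis category) and
#'   `age_group`.  Errors with class `out_of_domain` on ages below 18:
#'   the sampled population is adult by construction.
#' @examples
#' categorize_profile("missing", 25)   # other, 25-30
#' categorize_profile("black", NA)     # black, unknown
#' @export
categorize_profile <- function(raw_race, raw_age, rules = categorization_rules()) {
  stopifnot(inherits(rules, "categorization_rules"))
  if (any(!is.na(raw_age) & raw_age < 18)) {
    abort_appdens("age below 18 is outside the sampled population",
                  "out_of_domain")
  }
  unknown_race <- !raw_race %in% names(rules$race_map)
  if (any(unknown_race)) {
    abort_appdens(sprintf("unknown raw race value '%s'",
                          raw_race[unknown_race][1L]), "invalid_parameter")
  }
  data.frame(race = unname(rules$race_map[raw_race]),
             age_group = age_group(raw_age, rules),
             stringsAsFactors = FALSE)
}

# Optional distance quantization emulating the app's display: feet
# below one mile, hundredths of a mile above.
quantize_distance <- function(d) {
  ifelse(d < 1, round(d * 5280) / 5280, round(d * 100) / 100)
}

#' Observe profiles at one sampling point
#'
#' Implements the adaptive capture rule: if at least `k` profiles lie
#' within `r_max` miles, capture the `k` nearest and set the observed
#' radius to the distance of the k-th nearest (ties at that distance
#' are all included, so captures may exceed `k`); otherwise capture
#' every profile within `r_max` and set the radius to `r_max`.
#'
#' @param point Numeric `(x, y)` location in miles.
#' @param profiles Population data frame (`x_mi`, `y_mi`, plus marks).
#' @param k Capture cap (default 50 profiles).
#' @param r_max Maximum search radius in miles (default 2).
#' @param quantize If `TRUE`, distances are rounded the way the app
#'   displays them (feet under 1 mile, 0.01 mile above) before the
#'   capture rule is applied.  Default exact Euclidean distances.
#' @param id Identifier for the resulting sample point.
#' @return A `sample_point`: list with `id`, `x`, `y`, `radius_mi`, and
#'   `captured` (data frame `id`, `distance_mi`, `race`, `age` sorted
#'   by distance).
#' @export
observe <- function(point, profiles, k = 50L, r_max = 2.0,
                    quantize = FALSE, id = "p001") {
  if (k < 1L) abort_appdens("k must be >= 1", "invalid_parameter")
  check_positive(r_max, "r_max")
  d <- if (nrow(profiles) > 0L) {
    euclid(point[1L], point[2L], profiles$x_mi, profiles$y_mi)
  } else numeric(0L)
  if (quantize) d <- quantize_distance(d)
  within <- which(d <= r_max)
  if (length(within) >= k) {
    ds <- sort(d[within])
    dk <- ds[k]
    take <- within[d[within] <= dk]
    radius <- dk
  } else {
    take <- within
    radius <- r_max
  }
  ord <- take[order(d[take], profiles$id[take])]
  captured <- data.frame(id = profiles$id[ord],
                         distance_mi = d[ord],
                         race = profiles$race[ord],
                         age = profiles$age[ord],
                         stringsAsFactors = FALSE)
  structure(list(id = id, x = as.numeric(point[1L]), y = as.numeric(point[2L]),
                 radius_mi = radius, captured = captured),
            class = "sample_point")
}

#' @export
print.sample_point <- function(x, ...) {
  cat(sprintf("<sample_point> %s at (%.3f, %.3f): %d captured, radius %.3f mi\n",
              x$id, x$x, x$y, nrow(x$captured), x$radius_mi))
  invisible(x)
}

#' Define a sampling route
#'
#' A polyline along which sampling stops are placed by arc length.
#'
#' @param polyline Two-column matrix/data frame of `(x, y)` vertices in
#'   miles; consecutive vertices must be distinct.
#' @param start_offset Arc length (miles, >= 0) of the first stop.
#' @return A `route` with cumulative segment lengths precomputed.
#' @export
route <- function(polyline, start_offset = 0) {
  v <- as.matrix(polyline)
  if (nrow(v) < 2L || ncol(v) != 2L || anyNA(v)) {
    abort_appdens("route polyline needs at least 2 finite vertices",
                  "invalid_parameter")
  }
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  seg <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(seg == 0)) {
    abort_appdens("route has coincident consecutive vertices", "invalid_parameter")
  }
  if (start_offset < 0) abort_appdens("start_offset must be >= 0",
                                      "invalid_parameter")
  structure(list(polyline = v, cumlen = c(0, cumsum(seg)),
                 length = sum(seg), start_offset = as.numeric(start_offset)),
            class = "route")
}

# Point on the polyline at arc length s (clamped to [0, length]).
route_point <- function(rt, s) {
  s <- min(max(s, 0), rt$length)
  i <- findInterval(s, rt$cumlen, rightmost.closed = TRUE)
  i <- min(i, nrow(rt$polyline) - 1L)
  t <- (s - rt$cumlen[i]) / (rt$cumlen[i + 1L] - rt$cumlen[i])
  rt$polyline[i, ] + t * (rt$polyline[i + 1L, ] - rt$polyline[i, ])
}

#' Run the adaptive protocol along a route
#'
#' The first stop sits at `start_offset` along the polyline.  After
#' each observation the protocol advances along the route by that
#' stop's observed radius (the distance to the k-th nearest user, or
#' `r_max` in sparse areas), so stops pack closer together where users
#' are dense.  The traversal ends when the route is exhausted.
#'
#' @param rt A [route()].
#' @param profiles Population data frame (frozen for the traversal).
#' @inheritParams observe
#' @param min_step Smallest allowed advance in miles, guarding against
#'   a zero radius when k users sit exactly at the stop.
#' @return List of [observe()] results (class `sample_run`), with the
#'   arc-length position of each stop attached as attribute `arc`.
#' @export
run_route <- function(rt, profiles, k = 50L, r_max = 2.0,
                      quantize = FALSE, min_step = 1e-6) {
  stopifnot(inherits(rt, "route"))
  if (rt$start_offset > rt$length + 1e-9) {
    warning("route is shorter than start_offset; no stops taken")
    return(structure(list(), class = "sample_run", arc = numeric(0L)))
  }
  stops <- list()
  arcs <- numeric(0L)
  s <- rt$start_offset
  i <- 0L
  while (s <= rt$length + 1e-9) {
    i <- i + 1L
    p <- route_point(rt, s)
    sp <- observe(p, profiles, k = k, r_max = r_max, quantize = quantize,
                  id = sprintf("p%03d", i))
    stops[[i]] <- sp
    arcs[i] <- s
    s <- s + max(sp$radius_mi, min_step)
  }
  structure(stops, class = "sample_run", arc = arcs)
}

#' @export
print.sample_run <- function(x, ...) {
  cat(sprintf("<sample_run> %d stops, %d captures\n", length(x),
              sum(vapply(x, function(s) nrow(s$captured), 0L))))
  invisible(x)
}

#' Tabulate a sample run as a stop-level data frame
#'
#' One row per stop with the stratified counts used downstream:
#' captures by race category (after [categorize_profile()], so missing
#' race counts as other) and by age group using the default
#' 18-24 / 25-30 / >30 / unknown bins.
#'
#' @param run A `sample_run` (or list of `sample_point`s).
#' @param rules A [categorization_rules()] (the age columns of the
#'   fixed CSV schema always use the default bins; pass custom rules
#'   only for matching custom strata).
#' @param extra_strata Optional named list of predicates
#'   `function(race, age_group, age)` returning a logical capture
#'   filter; each adds a count column `n_<name>` (e.g. a young-black
#'   stratum).  Extra columns are not part of the CSV schema.
#' @return Data frame with columns `id, x_mi, y_mi, radius_mi, n_total,
#'   n_white, n_black, n_other, n_age_18_24, n_age_25_30, n_age_gt30,
#'   n_age_unknown, timestamp`.
#' @export
sample_points_table <- function(run, rules = categorization_rules(),
                                extra_strata = NULL) {
  rows <- lapply(run, function(sp) {
    cap <- sp$captured
    cat_df <- if (nrow(cap) > 0L) {
      categorize_profile(cap$race, cap$age, rules)
    } else data.frame(race = character(0L), age_group = character(0L))
    base <- data.frame(
      id = sp$id, x_mi = sp$x, y_mi = sp$y, radius_mi = sp$radius_mi,
      n_total = nrow(cap),
      n_white = sum(cat_df$race == "white"),
      n_black = sum(cat_df$race == "black"),
      n_other = sum(cat_df$race == "other"),
      n_age_18_24 = sum(cat_df$age_group == rules$age_labels[1L]),
      n_age_25_30 = sum(cat_df$age_group == rules$age_labels[2L]),
      n_age_gt30 = sum(cat_df$age_group == rules$age_labels[3L]),
      n_age_unknown = sum(cat_df$age_group == rules$unknown_label),
      timestamp = "", stringsAsFactors = FALSE)
    for (nm in names(extra_strata)) {
      base[[paste0("n_", nm)]] <-
        sum(extra_strata[[nm]](cat_df$race, cat_df$age_group, cap$age))
    }
    base
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

sample_csv_header <- paste("id,x_mi,y_mi,radius_mi,n_total,n_white,n_black",
                           "n_other,n_age_18_24,n_age_25_30,n_age_gt30",
                           "n_age_unknown,timestamp", sep = ",")

#' Sample-point CSV round-trip
#'
#' Fixed schema `id,x_mi,y_mi,radius_mi,n_total,n_white,n_black,
#' n_other,n_age_18_24,n_age_25_30,n_age_gt30,n_age_unknown,timestamp`;
#' numbers with 6 significant digits.  Write -> read -> write is
#' byte-identical.
#'
#' @param tab Data frame from [sample_points_table()] (extra stratum
#'   columns are dropped: the schema is fixed).
#' @param path Output file path.
#' @export
write_sample_points_csv <- function(tab, path) {
  cols <- strsplit(sample_csv_header, ",", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    abort_appdens(paste("sample table lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "invalid_parameter")
  }
  body <- if (nrow(tab) > 0L) {
    paste(tab$id, fmt_num(tab$x_mi), fmt_num(tab$y_mi), fmt_num(tab$radius_mi),
          tab$n_total, tab$n_white, tab$n_black, tab$n_other,
          tab$n_age_18_24, tab$n_age_25_30, tab$n_age_gt30, tab$n_age_unknown,
          ifelse(is.na(tab$timestamp), "", tab$timestamp), sep = ",")
  }
  writeLines(c(sample_csv_header, body), path)
  invisible(path)
}

#' @rdname write_sample_points_csv
#' @return `read_sample_points_csv`: the stop-level data frame.
#' @export
read_sample_points_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, sample_csv_header)) {
    abort_appdens(sprintf("%s:1: unexpected sample CSV header", path),
                  "parse_error")
  }
  df <- utils::read.csv(path, colClasses = c(
    "character", "numeric", "numeric", "numeric", rep("integer", 8L),
    "character"))
  if (nrow(df) > 0L) {
    race_sum <- df$n_white + df$n_black + df$n_other
    bad <- which(race_sum != df$n_total)
    if (length(bad)) {
      abort_appdens(sprintf("%s:%d: race counts do not sum to n_total",
                            path, bad[1L] + 1L), "parse_error")
    }
  }
  df$timestamp[is.na(df$timestamp)] <- ""
  df
}

#' Read a route from GeoJSON
#'
#' LineString coordinates are interpreted as planar miles.
#'
#' @param path GeoJSON file with a LineString geometry (bare geometry,
#'   Feature, or single-feature FeatureCollection).
#' @param start_offset Arc length of the first stop (miles).
#' @return A [route()].
#' @export
read_route_geojson <- function(path, start_offset = 0) {
  g <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  abort_appdens(sprintf("cannot parse GeoJSON '%s': %s",
                                        path, conditionMessage(e)),
                                "parse_error")
                })
  if (identical(g$type, "FeatureCollection")) {
    g <- if (is.data.frame(g$features)) {
      list(type = g$features$geometry$type[1L],
           coordinates = g$features$geometry$coordinates[[1L]])
    } else g$features[[1L]]$geometry
  } else if (identical(g$type, "Feature")) {
    g <- g$geometry
  }
  if (!identical(g$type, "LineString")) {
    abort_appdens("GeoJSON geometry is not a LineString", "parse_error")
  }
  coords <- g$coordinates
  if (is.list(coords)) coords <- do.call(rbind, lapply(coords, as.numeric))
  route(coords, start_offset = start_offset)
}

#' @rdname read_route_geojson
#' @param rt A [route()] to serialize.
#' @export
write_route_geojson <- function(rt, path) {
  stopifnot(inherits(rt, "route"))
  coords <- unname(lapply(seq_len(nrow(rt$polyline)), function(i) {
    as.numeric(rt$polyline[i, ])
  }))
  obj <- list(type = "Feature", properties = list(),
              geometry = list(type = "LineString", coordinates = coords))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Demo sampling route
#'
#' A boustrophedon (serpentine) drive across [demo_region()] with rows
#' 1.8 miles apart.  Every point of the region lies within one mile of
#' the polyline, and stops are never more than one arc-mile from any
#' path point, so in sparse areas (2-mile radii) the observation
#' circles are guaranteed to cover the whole region.
#'
#' @param row_spacing Distance between serpentine rows in miles.
#' @return A [route()].
#' @export
demo_route <- function(row_spacing = 1.8) {
  bb <- region_bbox(demo_region())
  margin <- row_spacing / 2
  ys <- seq(bb["ymin"] + margin, bb["ymax"] - margin, by = row_spacing)
  top <- bb["ymax"] - margin
  if (top - ys[length(ys)] > 1e-9) ys <- c(ys, top)
  xs <- c(bb["xmin"], bb["xmax"])
  verts <- matrix(numeric(0L), ncol = 2L)
  for (i in seq_along(ys)) {
    xrow <- if (i %% 2L == 1L) xs else rev(xs)
    verts <- rbind(verts, cbind(xrow, ys[i]))
  }
  route(verts)
}

#' Fraction of the region covered by the sampling circles
#'
#' Grid approximation: the share of region-interior cell centers (at
#' the given resolution) that fall inside at least one observation
#' circle.  Monotone non-decreasing as circles are added.
#'
#' @param run A `sample_run`, or a stop-level data frame with columns
#'   `x_mi`, `y_mi`, `radius_mi`.
#' @param region A [study_region()].
#' @param resolution Grid spacing in miles (> 0).
#' @return Fraction in `[0, 1]`; 0 for an empty sample list.
#' @export
coverage_fraction <- function(run, region, resolution = 0.05) {
  check_positive(resolution, "resolution")
  stopifnot(inherits(region, "study_region"))
  tab <- if (is.data.frame(run)) run else {
    data.frame(x_mi = vapply(run, `[[`, 0, "x"),
               y_mi = vapply(run, `[[`, 0, "y"),
               radius_mi = vapply(run, `[[`, 0, "radius_mi"))
  }
  bb <- region_bbox(region)
  gx <- seq(bb["xmin"] + resolution / 2, bb["xmax"], by = resolution)
  gy <- seq(bb["ymin"] + resolution / 2, bb["ymax"], by = resolution)
  pts <- expand.grid(x = gx, y = gy)
  pts <- pts[in_region(region, pts$x, pts$y), , drop = FALSE]
  if (nrow(pts) == 0L) return(0)
  if (nrow(tab) == 0L) return(0)
  covered <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(tab))) {
    todo <- which(!covered)
    if (length(todo) == 0L) break
    r2 <- tab$radius_mi[i]^2
    d2 <- (pts$x[todo] - tab$x_mi[i])^2 + (pts$y[todo] - tab$y_mi[i])^2
    covered[todo[d2 <= r2]] <- TRUE
  }
  mean(covered)
}
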