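# Independent oracles, deliberately coded with none of the package's
# internals: naive double-loop KDE, exhaustive distance-sort capture,
# and small builders for hand-made inputs.

# Naive KDE: loop over every cell and every point.
naive_kde_values <- function(x, y, w, h, grid, kernel = "gaussian") {
  vals <- matrix(0, grid$nrows, grid$ncols)
  for (i in seq_len(grid$nrows)) {
    cy <- grid$yll + (grid$nrows - i + 0.5) * grid$cell_size
    for (j in seq_len(grid$ncols)) {
      cx <- grid$xll + (j - 0.5) * grid$cell_size
      tot <- 0
      for (p in seq_along(x)) {
        d <- sqrt((cx - x[p])^2 + (cy - y[p])^2)
        if (kernel == "gaussian") {
          if (d <= 3 * h) {
            tot <- tot + w[p] * exp(-d^2 / (2 * h^2)) /
              (2 * pi * h^2 * (1 - exp(-4.5)))
          }
        } else {
          if (d < h) tot <- tot + w[p] * 3 / (pi * h^2) * (1 - (d / h)^2)^2
        }
      }
      vals[i, j] <- tot
    }
  }
  vals
}

# Exhaustive capture oracle: sort ALL distances, apply the k-or-radius
# rule with the all-ties-at-rank-k inclusion.
brute_observe <- function(point, profiles, k = 50, r_max = 2) {
  d <- sqrt((profiles$x_mi - point[1])^2 + (profiles$y_mi - point[2])^2)
  ord <- order(d)
  d_sorted <- d[ord]
  within <- which(d_sorted <= r_max)
  if (length(within) >= k) {
    dk <- d_sorted[k]
    keep <- ord[d_sorted <= dk]
    list(ids = sort(profiles$id[keep]), radius = dk)
  } else {
    keep <- ord[d_sorted <= r_max]
    list(ids = sort(profiles$id[keep]), radius = r_max)
  }
}

# Minimal stop-level table for density functions.
make_samples <- function(x, y, radius, counts, stratum = "total") {
  df <- data.frame(id = sprintf("p%03d", seq_along(x)),
                   x_mi = x, y_mi = y, radius_mi = radius,
                   stringsAsFactors = FALSE)
  df[[paste0("n_", stratum)]] <- counts
  df
}

# Surface wrapping a bare matrix on a unit grid.
make_surface <- function(values, cell_size = 1) {
  values <- as.matrix(values)
  density_surface(grid_spec(0, 0, cell_size, ncol(values), nrow(values)),
                  values)
}

random_population <- function(n, xlim = c(0, 10), ylim = c(0, 10)) {
  data.frame(id = sprintf("u%06d", seq_len(n)),
             x_mi = runif(n, xlim[1], xlim[2]),
             y_mi = runif(n, ylim[1], ylim[2]),
             race = sample(c("white", "black", "other"), n, replace = TRUE),
             age = sample(18:60, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
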