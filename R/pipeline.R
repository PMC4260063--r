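#' Default pipeline configuration
#'
#' Mirrors the field protocol's choices: capture cap `k = 50`, maximum
#' radius 2 miles, smoothing bandwidth 2 miles (1 mile available via
#' config), 0.1-mile raster cells, gaussian kernel, mean + 2 SD
#' extreme threshold, standardized kernel weights.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_total = 2666,
    k = 50L,
    r_max_mi = 2.0,
    bandwidth_mi = 2.0,
    cell_size_mi = 0.1,
    kernel = "gaussian",
    n_sd = 2,
    age_breaks = c(18, 25, 31, Inf),
    weight_mode = "standardized",
    p_missing_race = 0.0551,
    p_missing_age = 0.2224,
    region_geojson = NULL,   # NULL -> demo_region()
    route_geojson = NULL,    # NULL -> demo_route()
    out_dir = "appdens-out",
    strata = c("total", "white", "black")
  )
}

#' Read a pipeline configuration file
#'
#' YAML document whose keys are a subset of [default_config()]'s;
#' unknown keys are rejected, missing keys take the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path), error = function(e) {
      abort_appdens(sprintf("cannot parse config '%s': %s", path,
                            conditionMessage(e)), "parse_error")
    })
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      abort_appdens(paste("unknown config keys:",
                          paste(unknown, collapse = ", ")),
                    "invalid_parameter")
    }
    if (!is.null(user$age_breaks)) {
      user$age_breaks <- as.numeric(
        ifelse(user$age_breaks %in% c("Inf", ".inf"), Inf, user$age_breaks))
    }
    cfg[names(user)] <- user
  }
  check_positive(cfg$r_max_mi, "r_max_mi")
  check_positive(cfg$bandwidth_mi, "bandwidth_mi")
  check_positive(cfg$cell_size_mi, "cell_size_mi")
  if (cfg$k < 1L) abort_appdens("k must be >= 1", "invalid_parameter")
  if (!cfg$kernel %in% c("gaussian", "quartic")) {
    abort_appdens("kernel must be gaussian or quartic", "invalid_parameter")
  }
  if (!cfg$weight_mode %in% c("standardized", "raw")) {
    abort_appdens("weight_mode must be standardized or raw", "invalid_parameter")
  }
  check_prob(cfg$p_missing_race, "p_missing_race")
  check_prob(cfg$p_missing_age, "p_missing_age")
  cfg
}

config_region <- function(cfg) {
  if (is.null(cfg$region_geojson)) demo_region()
  else read_region_geojson(cfg$region_geojson)
}

config_route <- function(cfg) {
  if (is.null(cfg$route_geojson)) demo_route()
  else read_route_geojson(cfg$route_geojson)
}

log_info <- function(fmt, ...) message(sprintf(paste0("[appdens] ", fmt), ...))

path_in <- function(cfg, file) file.path(cfg$out_dir, file)

#' Pipeline stages
#'
#' Each stage reads its inputs from and writes its outputs under
#' `config$out_dir`, so the stages chain into a reproducible pipeline:
#' `simulate-population` generates the synthetic user population
#' (`population.csv`), `sample` runs the adaptive route protocol over
#' it (`samples.csv`), `density` fits one kernel surface per configured
#' stratum (`density_<stratum>.asc`), `compare` derives the
#' black-vs-white difference, ratio and indicator-difference rasters,
#' and `report` writes a text summary plus PNG renderings.
#'
#' @param config Configuration list from [read_config()].
#' @return Invisibly, the paths written.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  region <- config_region(config)
  pop <- generate_population(region, demo_intensity(config$n_total),
                             seed = config$seed)
  pop <- assign_missingness(pop, config$p_missing_race, config$p_missing_age,
                            seed = config$seed + 1L)
  out <- path_in(config, "population.csv")
  write_population_csv(pop, out)
  log_info("simulate-population: %d users in %.4g sq mi (seed %d) -> %s",
           nrow(pop), region_area(region), config$seed, out)
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_sample <- function(config = default_config()) {
  pop_path <- path_in(config, "population.csv")
  if (!file.exists(pop_path)) {
    abort_appdens(sprintf("missing input file '%s' (run simulate-population)",
                          pop_path), "missing_input")
  }
  pop <- read_population_csv(pop_path)
  rt <- config_route(config)
  run <- run_route(rt, pop, k = config$k, r_max = config$r_max_mi)
  rules <- categorization_rules(age_breaks = config$age_breaks)
  tab <- sample_points_table(run, rules = rules)
  out <- path_in(config, "samples.csv")
  write_sample_points_csv(tab, out)
  log_info("sample: %d stops, %d captures, mean radius %.3g mi -> %s",
           nrow(tab), sum(tab$n_total), mean(tab$radius_mi), out)
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_density <- function(config = default_config()) {
  smp_path <- path_in(config, "samples.csv")
  if (!file.exists(smp_path)) {
    abort_appdens(sprintf("missing input file '%s' (run sample)", smp_path),
                  "missing_input")
  }
  tab <- read_sample_points_csv(smp_path)
  region <- config_region(config)
  grid <- region_grid(region, cell_size = config$cell_size_mi)
  outs <- character(0L)
  for (stratum in config$strata) {
    surf <- kernel_density(tab, stratum = stratum,
                           bandwidth_mi = config$bandwidth_mi, grid = grid,
                           kernel = config$kernel, region = region,
                           weight_mode = config$weight_mode)
    st <- surface_stats(surf, n_sd = config$n_sd)
    out <- path_in(config, sprintf("density_%s.asc", stratum))
    write_asc(surf, out)
    log_info("density[%s]: mean %.4g sd %.4g users/sq mi over %d cells -> %s",
             stratum, st$mean, st$sd, st$n_cells, out)
    outs <- c(outs, out)
  }
  invisible(outs)
}

#' @rdname pipeline
#' @param a_stratum,b_stratum Strata compared by the `compare` stage
#'   (defaults: black vs white).
#' @export
pipeline_compare <- function(config = default_config(),
                             a_stratum = "black", b_stratum = "white") {
  pa <- path_in(config, sprintf("density_%s.asc", a_stratum))
  pb <- path_in(config, sprintf("density_%s.asc", b_stratum))
  for (p in c(pa, pb)) {
    if (!file.exists(p)) {
      abort_appdens(sprintf("missing input file '%s' (run density)", p),
                    "missing_input")
    }
  }
  a <- read_asc(pa, stratum = a_stratum, bandwidth_mi = config$bandwidth_mi,
                kernel = config$kernel)
  b <- read_asc(pb, stratum = b_stratum, bandwidth_mi = config$bandwidth_mi,
                kernel = config$kernel)
  outs <- c(diff = path_in(config, sprintf("diff_%s_%s.asc", a_stratum, b_stratum)),
            ratio = path_in(config, sprintf("ratio_%s_%s.asc", a_stratum, b_stratum)),
            ind = path_in(config, sprintf("indicator_%s_%s.asc", a_stratum,
                                          b_stratum)))
  write_asc(surface_difference(a, b), outs[["diff"]])
  write_asc(surface_ratio(a, b), outs[["ratio"]])
  ind <- indicator_difference(a, b, n_sd = config$n_sd)
  write_asc(ind, outs[["ind"]])
  st <- ind$parent_stats
  log_info("compare %s vs %s: thresholds %.4g / %.4g users/sq mi",
           a_stratum, b_stratum, st[[1L]]$threshold, st[[2L]]$threshold)
  invisible(outs)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(config = default_config()) {
  smp_path <- path_in(config, "samples.csv")
  if (!file.exists(smp_path)) {
    abort_appdens(sprintf("missing input file '%s'", smp_path), "missing_input")
  }
  tab <- read_sample_points_csv(smp_path)
  sm <- per_point_density_summary(tab, "total")
  lines <- c(
    sprintf("stops: %d", sm$n),
    sprintf("captures: %d", sum(tab$n_total)),
    sprintf("mean radius (mi): %s", fmt_num(mean(tab$radius_mi))),
    sprintf("per-point density (users/sq mi): mean %s median %s range %s-%s",
            fmt_num(sm$mean), fmt_num(sm$median), fmt_num(sm$min),
            fmt_num(sm$max)),
    "histogram (lower upper count):",
    sprintf("  %s %s %d", fmt_num(sm$histogram$lower),
            fmt_num(sm$histogram$upper), sm$histogram$count))
  out <- path_in(config, "report.txt")
  writeLines(lines, out)
  outs <- out
  for (stratum in config$strata) {
    asc <- path_in(config, sprintf("density_%s.asc", stratum))
    if (file.exists(asc)) {
      png <- path_in(config, sprintf("density_%s.png", stratum))
      render_surface(read_asc(asc, stratum = stratum), png)
      outs <- c(outs, png)
    }
  }
  ind <- path_in(config, "indicator_black_white.asc")
  if (file.exists(ind)) {
    png <- path_in(config, "indicator_black_white.png")
    render_surface(read_asc(ind), png)
    outs <- c(outs, png)
  }
  log_info("report: median per-point density %.4g users/sq mi -> %s",
           sm$median, out)
  invisible(outs)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands; used by the bundled
#' `inst/cli/appdens.R` wrapper as
#' `Rscript appdens.R <subcommand> [--config file.yaml] [--seed N]`.
#'
#' Subcommands: `simulate-population`, `sample`, `density`, `compare`,
#' `report`.  Outputs are deterministic given the config and seed.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success); error
#'   messages go to stderr.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: appdens <simulate-population|sample|density|",
                 "compare|report> [--config file.yaml] [--seed N]", sep = "")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  sub <- args[1L]
  opts <- args[-1L]
  get_opt <- function(flag) {
    i <- which(opts == flag)
    if (length(i) == 1L && i < length(opts)) opts[i + 1L] else NULL
  }
  status <- tryCatch({
    cfg <- read_config(get_opt("--config"))
    seed_opt <- get_opt("--seed")
    if (!is.null(seed_opt)) cfg$seed <- as.integer(seed_opt)
    log_info("subcommand=%s seed=%d k=%d r_max=%g bandwidth=%g kernel=%s (appdens %s, R %s)",
             sub, cfg$seed, cfg$k, cfg$r_max_mi, cfg$bandwidth_mi, cfg$kernel,
             as.character(utils::packageVersion("appdens")),
             paste(R.version$major, R.version$minor, sep = "."))
    switch(sub,
           "simulate-population" = pipeline_simulate(cfg),
           "sample" = pipeline_sample(cfg),
           "density" = pipeline_density(cfg),
           "compare" = pipeline_compare(cfg),
           "report" = pipeline_report(cfg),
           abort_appdens(paste0("unknown subcommand '", sub, "'\n", usage),
                         "invalid_parameter"))
    0L
  }, error = function(e) {
    message("appdens error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
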