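# Shared demo scenario at pilot scale (n about 2500 users, about 80
# adaptive stops), generated once per test run and memoized: several
# tests and all surface-level checks reuse it.
.scenario_cache <- new.env(parent = emptyenv())

demo_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    region <- demo_region()
    spec <- demo_intensity(2500)
    pop <- generate_population(region, spec, seed = 42L)
    pop <- assign_missingness(pop, 0.0551, 0.2224, seed = 43L)
    run <- run_route(demo_route(), pop)
    tab <- sample_points_table(run)
    .scenario_cache$sc <- list(region = region, spec = spec, pop = pop,
                               run = run, tab = tab)
  }
  .scenario_cache$sc
}
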