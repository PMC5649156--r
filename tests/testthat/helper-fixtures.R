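# Shared small fixtures, built once per test run.

small_array <- build_sensor_array(n_chan = 36, helmet_radius = 0.11,
                                  baseline = 0.05, seed = 1L)
small_grid <- build_source_grid(spacing = 0.018)
small_leadfield <- compute_leadfield(small_array, small_grid)

# compact simulation settings used across tests (short, low-rate versions
# of the default acquisition; the full-scale defaults are exercised in the
# acceptance tests)
quick_sim_config <- function(...) {
  args <- utils::modifyList(list(n_chan = 24, sfreq = 200, duration = 120,
                                 grid_spacing = 0.02), list(...))
  do.call(bro_sim_config, args)
}

quick_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- quick_sim_config()
      hm <- build_headmodel(cfg, seed = 2L)
      cache <<- c(generate_recording(cfg, seed = 11L, headmodel = hm),
                  list(headmodel = hm, config = cfg))
    }
    cache
  }
})

expect_partition <- function(regions, n) {
  expect_s3_class(regions, "factor")
  expect_length(regions, n)
  expect_false(anyNA(regions))
}
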