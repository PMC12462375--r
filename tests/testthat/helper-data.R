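# Shared study-scale synthetic dataset, generated once per test run and
# memoised; several end-to-end properties are checked against it.
study_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(generator_config(seed = 20260925))
      dm <- heterodimer_dist_matrix(ds$records)
      cache <<- list(ds = ds, dm = dm)
    }
    cache
  }
})
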