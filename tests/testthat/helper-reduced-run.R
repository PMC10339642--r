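# One reduced-replication run of the full design grid (400 conditions x 100
# replications, both settings), shared by the acceptance tests. Computed on
# first use and cached for the session; Rubin's total variance is dominated
# by W + B, which is nearly invariant in the number of replications, so the
# per-condition classifications are stable between 100 and 1 000 replications.
reduced_grid_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        run_experiment(default_config(reps = 100, seed = 1), progress = 0))
    }
    cache
  }
})
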