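# The default calibrated cohort used by the cohort-level checks.  Built once
# per test run and cached (it takes about a minute at n = 500).
.prl_test_cache <- new.env(parent = emptyenv())

calibrated_metrics <- function(n = 500, seed = 7) {
  key <- sprintf("metrics_%d_%d", n, seed)
  if (is.null(.prl_test_cache[[key]])) {
    cohort <- simulate_cohort(cohort_config(n_participants = n, seed = seed))
    .prl_test_cache[[key]] <- compute_participant_metrics(cohort)
  }
  .prl_test_cache[[key]]
}
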