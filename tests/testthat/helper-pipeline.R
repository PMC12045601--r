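# Shared end-to-end phantom pipeline, computed once per test run and reused
# by the integration tests: a 4-stage x 5-specimen cohort on a 96^3 grid at
# the package's default study conditions.
acceptance_env <- new.env(parent = emptyenv())

acceptance_pipeline <- function() {
  if (is.null(acceptance_env$res)) {
    spec <- phantom_spec(grid_shape = 96, n_per_group = 5, seed = 11)
    ch <- generate_cohort(spec)
    acceptance_env$spec <- spec
    acceptance_env$cohort <- ch
    acceptance_env$res <- run_pipeline(ch, R_null = 100, n_perm = 199,
                                       seed = 3)
  }
  acceptance_env
}
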