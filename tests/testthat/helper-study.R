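# The reduced simulation study shared by the acceptance tests.  Run once,
# lazily, and cached for the session: 30 replicates per block-variance
# ratio for the fixed LOD-2.5 rule, permutation thresholds (100
# permutations, alpha = 0.05) on the first 25 replicates.
.acc_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.acc_cache$res)) {
    cfg <- study_config(n_replicates = 30, n_perm = 100,
                        perm_replicates = 25, seed = 4242)
    .acc_cache$res <- run_study(cfg)
  }
  .acc_cache$res
}

study_cell <- function(res, method, rule, delta, field = "power") {
  p <- res$power
  p[[field]][p$method == method & p$rule == rule & p$delta == delta]
}
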