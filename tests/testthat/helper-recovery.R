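# the 20-replicate parameter-recovery experiment is the most expensive
# shared fixture; compute it once per test run
.recovery_cache <- new.env(parent = emptyenv())

recovery_experiment_fixture <- function() {
  if (is.null(.recovery_cache$out)) {
    truth <- default_truth(seed = 101)
    .recovery_cache$out <- list(
      truth = truth,
      res = parameter_recovery_experiment(
        truth, n_replicates = 20,
        mcmc = mcmc_config(n_chains = 3, n_iter = 2000, n_burnin = 1000,
                           seed = 101))
    )
  }
  .recovery_cache$out
}
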