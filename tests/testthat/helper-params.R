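# small parameter sets used across tests; Table-1-style defaults come from
# trap_params() itself

# a desk-scale configuration: small host populations, short runs
small_params <- function(...) {
  args <- utils::modifyList(list(K1 = 100, K2 = 100, n1 = 4, n2 = 4,
                                 P0 = 20, generations = 5), list(...))
  do.call(trap_params, args)
}

# build a host cohort of given total size spread uniformly over patches,
# bypassing the Ricker draw (for engine tests that control density)
fixed_hosts <- function(n1_hosts, n2_hosts, p) {
  rbind(
    sample_maturation_times(
      stats::rmultinom(1, n1_hosts, rep(1, p$n1))[, 1],
      p$tau_dH1, 1L, seq_len(p$n1)),
    sample_maturation_times(
      stats::rmultinom(1, n2_hosts, rep(1, p$n2))[, 1],
      p$tau_dH2, 2L, p$n1 + seq_len(p$n2)))
}

# monoclonal parasitoid population
fixed_parasitoids <- function(n, q = 0, S = 1L) {
  data.frame(q = rep(q, n), S = rep(as.integer(S), n))
}
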