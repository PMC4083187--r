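# Shared fixtures: small parameter sets and an independent brute-force
# implementation of the modified Thompson tau rule used as an oracle.

linear_params <- function(m, n_cells = 50L, n_wells = 9L, seed = NULL) {
  sim_params(m = m, S = 200L, d = 0.9, lambda0 = 0, sigma = 0,
             kappa = 20000, n_cells = n_cells, n_wells = n_wells,
             seed = seed)
}

# Brute-force modified Thompson tau: explicit loop, explicit critical
# value, no shared code with the package implementation.
tau_filter_oracle <- function(x, alpha = 0.05) {
  removed <- integer(0)
  idx <- seq_along(x)
  while (length(idx) >= 3L) {
    cur <- x[idx]
    mu <- sum(cur) / length(cur)
    sdev <- sqrt(sum((cur - mu)^2) / (length(cur) - 1))
    if (sdev == 0) break
    deviations <- abs(cur - mu)
    worst <- which(deviations == max(deviations))[1L]
    n <- length(cur)
    t_crit <- qt(1 - alpha / 2, df = n - 2)
    tau <- (t_crit * (n - 1)) / (sqrt(n) * sqrt(n - 2 + t_crit^2))
    if (deviations[worst] > tau * sdev) {
      removed <- c(removed, idx[worst])
      idx <- idx[-worst]
    } else break
  }
  list(retained = x[idx], removed_idx = removed)
}

toy_groups <- function() {
  comet_groups(control = c(1, 2, 1.5, 2.5),
               hpaii = c(18, 22, 20, 21),
               mspi = c(38, 42, 40, 39),
               sample_id = "toy", condition = "untreated")
}
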