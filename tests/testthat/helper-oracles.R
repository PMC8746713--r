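# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Forward Wright-Fisher fixation frequency: diploid population of N
# individuals (2N gene copies), genic selection with per-copy advantage s/2,
# binomial resampling each generation. Vectorized over runs.
wf_fixation_fraction <- function(N, s, p, n_runs, seed) {
  withr::with_seed(seed, {
    copies <- 2L * N
    sel <- s / 2
    count <- rep(round(p * copies), n_runs)
    fixed <- logical(n_runs)
    active <- count > 0 & count < copies
    while (any(active)) {
      pp <- count[active] / copies
      padj <- pp * (1 + sel) / (1 + pp * sel)
      count[active] <- rbinom(sum(active), copies, padj)
      fixed[count == copies] <- TRUE
      active <- count > 0 & count < copies
    }
    mean(fixed)
  })
}

# brute-force excess heterozygosity from a dosage matrix, one individual at
# a time (independent of the package's vectorized computation)
brute_excess <- function(d) {
  apply(d, 1, function(row) {
    row <- row[!is.na(row)]
    p_ab <- mean(row == 1)
    h <- sum(row) / (2 * length(row))
    p_ab - 2 * h * (1 - h)
  })
}
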