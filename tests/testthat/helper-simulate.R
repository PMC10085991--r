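# Shared fixtures: small generators independent of the package's own
# simulators, used as oracles for the fitting machinery.

# Two-state Markov efficiency traces built directly (independent of
# simulate_traces): per-frame stay probability `stay`, Gaussian emission.
make_efficiency_traces <- function(n_traces, len, means, sds, stay, seed) {
  set.seed(seed)
  lapply(seq_len(n_traces), function(i) {
    s <- integer(len)
    s[1] <- sample(1:2, 1)
    for (t in 2:len)
      s[t] <- if (runif(1) < stay) s[t - 1] else 3L - s[t - 1]
    pmin(1, pmax(0, rnorm(len, means[s], sds[s])))
  })
}

# Exhaustive least-squares change-point: the brute-force oracle for
# detect_photobleach.
oracle_changepoint <- function(total) {
  n <- length(total)
  sse <- vapply(1:(n - 1), function(k) {
    pre <- total[1:k]; post <- total[(k + 1):n]
    sum((pre - mean(pre))^2) + sum((post - mean(post))^2)
  }, 1.0)
  which.min(sse)
}

# Half-log concentration grid between two molar bounds (inclusive).
halflog_grid <- function(lo, hi) 10^seq(log10(lo), log10(hi), by = 0.5)
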