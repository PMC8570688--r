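# Exhaustive-summation information oracles, written independently of the
# package implementation: direct loops over the joint count table.
oracle_mi <- function(tab) {
  n <- sum(tab)
  acc <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / n
    if (p > 0)
      acc <- acc + p * log2(p / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  acc
}

oracle_specific <- function(tab) {
  n <- sum(tab)
  out <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ns <- sum(tab[i, ])
    for (j in seq_len(ncol(tab))) {
      prk <- tab[i, j] / ns
      pr <- sum(tab[, j]) / n
      if (prk > 0) out[i] <- out[i] + prk * log2(prk / pr)
    }
  }
  out
}
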