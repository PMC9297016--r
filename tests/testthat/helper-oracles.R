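## Brute-force oracle for the equal-informativeness plurality curve:
## enumerate all K^k per-whoop vote sequences under the symmetric
## likelihood (correct w.p. p, each wrong class w.p. (1-p)/(K-1)), award
## fractional credit on plurality ties.
bruteForcePlurality <- function(p, K, k) {
  probs <- c(p, rep((1 - p) / (K - 1), K - 1))
  grids <- do.call(expand.grid, rep(list(seq_len(K)), k))
  total <- 0
  for (r in seq_len(nrow(grids))) {
    seqc <- as.integer(grids[r, ])
    pr <- prod(probs[seqc])
    counts <- tabulate(seqc, K)
    mx <- max(counts)
    tied <- which(counts == mx)
    total <- total + pr * (if (1 %in% tied) 1 / length(tied) else 0)
  }
  total
}
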