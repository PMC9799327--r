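# shared fixtures: random frequency vectors and small model objects

random_genotype_freqs <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    p <- as.numeric(rmultinom(1, 1000, runif(10)) / 1000)
    genotype_freqs(p)
  })
}

# per-locus heterozygosities implied by a genotype vector
locus_het <- function(G) {
  c(A = sum(G[c("G13", "G14", "G23", "G24")]),
    B = sum(G[c("G12", "G14", "G23", "G34")]))
}
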