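# Independent oracles used across the suite.  These deliberately use the
# slow, obviously-correct formulation and stay independent of the code paths
# they check.

# Brute-force recombination: O(G^2 * 16) double sum over ordered parent
# pairs, each of the 16 inheritance masks with weight 1/16.
brute_force_recombine <- function(freqs, space) {
  G <- space$G
  dec <- decode_genotype(space, seq_len(G))
  out <- numeric(G)
  for (p1 in seq_len(G)) for (p2 in seq_len(G)) {
    w <- freqs[p1] * freqs[p2]
    if (w == 0) next
    for (m in 0:15) {
      inA <- as.logical(bitwAnd(m, c(1L, 2L, 4L, 8L)))
      k <- encode_genotype(space,
        if (inA[1]) dec$resist[p1] else dec$resist[p2],
        if (inA[2]) dec$neutral[p1] else dec$neutral[p2],
        if (inA[3]) dec$choice[p1] else dec$choice[p2],
        if (inA[4]) dec$trait[p1] else dec$trait[p2])
      out[k] <- out[k] + w / 16
    }
  }
  out
}

# Pairwise linkage disequilibrium matrix D[i, j] = freq(allele i at locus a,
# allele j at locus b) - marginal product, for a named locus pair.
pairwise_ld <- function(freqs, space, locus_a, locus_b) {
  ga <- space[[locus_a]]; gb <- space[[locus_b]]
  na <- max(ga); nb <- max(gb)
  joint <- matrix(0, na, nb)
  for (k in seq_along(freqs))
    joint[ga[k], gb[k]] <- joint[ga[k], gb[k]] + freqs[k]
  joint - outer(rowSums(joint), colSums(joint))
}

# A seeded random point on the genotype simplex.
random_simplex <- function(space, seed) {
  set.seed(seed)
  x <- stats::runif(space$G)
  x / sum(x)
}

# A linkage-equilibrium (product-measure) state from seeded random marginals.
random_product_state <- function(space, seed) {
  set.seed(seed)
  rmarg <- function(n) { x <- stats::runif(n) + 0.1; x / sum(x) }
  mr <- rmarg(space$L_resist); mn <- rmarg(space$L_neutral)
  mc <- rmarg(2L); mt <- rmarg(2L)
  mr[space$resist] * mn[space$neutral] * mc[space$choice] * mt[space$trait]
}

LOCUS_PAIRS <- combn(c("resist", "neutral", "choice", "trait"), 2)
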