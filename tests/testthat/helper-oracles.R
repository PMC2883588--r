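# Independent oracles used across the suite. Each is a deliberately naive
# computation (enumeration, simulation, nested loops) kept separate from
# the package's own code paths.

# Monte-Carlo gene-dropping estimate of 2*Phi between two pedigree members:
# drop unique founder alleles down the pedigree many times and count shared
# alleles identical by descent.
oracle_kinship2_mc <- function(pedigree, id_a, id_b, n_drops = 1e5,
                               seed = 404) {
  set.seed(seed)
  n <- nrow(pedigree)
  idx <- seq_len(n); names(idx) <- pedigree$iid
  founder <- is.na(pedigree$father)
  a1 <- matrix(0L, n, n_drops); a2 <- matrix(0L, n, n_drops)
  lab <- 0L
  for (i in which(founder)) {
    a1[i, ] <- lab <- lab + 1L
    a2[i, ] <- lab <- lab + 1L
  }
  # process in pedigree order (parents precede children by construction)
  for (i in which(!founder)) {
    fi <- idx[[pedigree$father[i]]]; mi <- idx[[pedigree$mother[i]]]
    pf <- runif(n_drops) < 0.5; pm <- runif(n_drops) < 0.5
    a1[i, ] <- ifelse(pf, a1[fi, ], a2[fi, ])
    a2[i, ] <- ifelse(pm, a1[mi, ], a2[mi, ])
  }
  i <- idx[[id_a]]; j <- idx[[id_b]]
  # kinship: P(random allele from i IBD to random allele from j); 2*Phi
  2 * mean((  (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
              (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4)
}

# Nested-loop count of qualifying PTH/vehicle replicate comparisons.
oracle_pth_pairs <- function(pth, vehicle, fold = 1.5) {
  up <- mean(pth) / mean(vehicle) >= 1
  count <- 0L
  for (i in 1:3) for (j in 1:3) {
    r <- pth[i] / vehicle[j]
    if (up && r >= fold) count <- count + 1L
    if (!up && r <= 1 / fold) count <- count + 1L
  }
  count
}

# Exhaustive hypergeometric upper tail by enumeration over overlap counts.
oracle_hyper_upper <- function(k, term_size, universe_size, set_size) {
  kk <- k:min(term_size, set_size)
  sum(choose(term_size, kk) * choose(universe_size - term_size,
                                     set_size - kk)) /
    choose(universe_size, set_size)
}

# Brute-force FDR threshold: scan every candidate p as threshold.
oracle_fdr_threshold <- function(p, budget, pi0) {
  ps <- sort(p)
  ok <- ps[pi0 * length(p) * ps <= budget]
  if (length(ok)) max(ok) else ps[1]
}
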