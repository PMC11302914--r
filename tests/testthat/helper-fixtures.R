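# Shared fixtures and independent brute-force oracles.

tiny_a3m <- ">q\nACDE\n>s1 OX=9606\nAC-E\n>s2\nACDF\n"

# Brute-force per-column tally of class frequencies, independent of
# computeProfile's vectorized tabulation.
brute_profile <- function(rows) {
  ab <- profileAlphabet()
  L <- nchar(rows[1])
  m <- matrix(0, L, length(ab))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    for (l in seq_len(L)) m[l, match(ch[l], ab)] <- m[l, match(ch[l], ab)] + 1
  }
  m / length(rows)
}

# Pairwise-concordance ROC-AUC: count wins and half-ties over all
# positive-negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Central finite difference of the surrogate confidence at one coordinate.
fd_confidence <- function(problem, features, i, j, h = 1e-5,
                          nRecycles = 0L, seed = 0L, stochastic = FALSE) {
  up <- features; up[i, j] <- up[i, j] + h
  dn <- features; dn[i, j] <- dn[i, j] - h
  (surrogateForward(problem, up, nRecycles, seed, stochastic)@confidence -
     surrogateForward(problem, dn, nRecycles, seed, stochastic)@confidence) / (2 * h)
}

# A small deterministic surrogate problem reused across files.
demo_problem <- function(L = 20L, nRows = 120L, sigma = 0.1, seed = 42L) {
  makeSurrogateProblem(L, nRows, sigma, seed)
}

# Observed-profile starting features of a problem under the optimizer's own
# iteration-0 sampling, mirroring what a deterministic run starts from.
start_profile <- function(problem, cfg) {
  msa <- observedMSA(problem)
  rows0 <- sampleClusters(msa, cfg@nClusters,
                          msaDenoise:::.derive_seed(cfg@masterSeed, 0L, 1L))
  computeProfile(msa, rows0)
}
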