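test_that("computeProfile matches a brute-force tally and sums to one", {
  msa <- parseAlignedFasta(">q\nAC\n")
  m <- profileMatrix(computeProfile(msa))
  expect_equal(unname(m[1, "A"]), 1.0)
  expect_equal(unname(m[2, "C"]), 1.0)

  msa2 <- MSA(c("A", "C"))
  expect_equal(profileMatrix(computeProfile(msa2))[1, c("A", "C")],
               c(A = 0.5, C = 0.5))
  msa3 <- MSA(c("A", "-"))
  expect_equal(profileMatrix(computeProfile(msa3))[1, c("A", "-")],
               c("A" = 0.5, "-" = 0.5))

  # property: random small MSAs agree with the brute-force oracle
  ab <- profileAlphabet()
  set.seed(11)
  for (rep in 1:10) {
    rows <- vapply(1:8, function(i)
      paste(sample(ab, 9, replace = TRUE), collapse = ""), "")
    rows[1] <- gsub("-", "A", rows[1])
    msa <- MSA(rows)
    p <- computeProfile(msa)
    expect_equal(unname(profileMatrix(p)), brute_profile(rows))
    expect_true(all(abs(rowSums(profileMatrix(p)) - 1) < 1e-9))
  }
  expect_error(computeProfile(msa, integer(0)), "empty")
})

test_that("sampleClusters keeps the query first, caps at row count, is seeded", {
  one <- MSA("ACD")
  expect_equal(sampleClusters(one, 8L, seed = 1), 1L)
  msa <- demo_problem(L = 6L, nRows = 100L)@observedMSA
  all_idx <- sampleClusters(msa, 100L, seed = 3)
  expect_equal(sort(all_idx), 1:100)
  expect_equal(all_idx[1], 1L)
  a <- sampleClusters(msa, 32L, seed = 7)
  b <- sampleClusters(msa, 32L, seed = 7)
  expect_identical(a, b)
  expect_equal(length(a), 32L)
  expect_false(anyDuplicated(a) > 0)
  expect_error(sampleClusters(msa, 0L), "nClusters")
})

test_that("makeFeatures bundles profile, cluster rows and deletion means", {
  msa <- parseA3M(">q\nACD\n>s1\nAaC-\n>s2\nACD\n")
  fb <- makeFeatures(msa, nClusters = 3L, seed = 0)
  expect_s4_class(fb, "FeatureBundle")
  expect_equal(sort(fb@clusterRows), 1:3)
  expect_equal(fb@deletionMean, c(0, 1 / 3, 0))
  expect_false(fb@biasApplied)
})

test_that("pairBySpecies pairs per shared species by best identity", {
  chainA <- parseA3M(paste0(">qa\nACDEFG\n",
                            ">a1 OX=S1\nACDEFG\n",
                            ">a2 OX=S1\nAAAAFG\n",
                            ">a3 OX=S1\nACDEYG\n",
                            ">a4 OX=S2\nACNEFG\n"))
  chainB <- parseA3M(paste0(">qb\nKLMN\n",
                            ">b1 OX=S1\nKLMQ\n",
                            ">b2 OX=S1\nKIII\n",
                            ">b3 OX=S3\nKLNN\n"))
  paired <- pairBySpecies(list(chainA, chainB))
  # only S1 is shared: query row + exactly one paired row
  expect_equal(nrow(paired), 2L)
  expect_equal(msaRows(paired)[1], "ACDEFGKLMN")
  # best-identity representatives: a1 (identity 1.0) and b1 (0.75)
  expect_equal(msaRows(paired)[2], "ACDEFGKLMQ")
  expect_equal(msaSpecies(paired)[2], "S1")
  expect_equal(chainLengths(paired), c(6L, 4L))

  # full overlap: one paired row per common species
  cA <- parseA3M(">q\nAC\n>x OX=S1\nAC\n>y OX=S2\nA-\n")
  cB <- parseA3M(">q\nDE\n>x OX=S1\nDE\n>y OX=S2\nD-\n")
  expect_equal(nrow(pairBySpecies(list(cA, cB))), 3L)

  # disjoint species: query only
  cC <- parseA3M(">q\nDE\n>x OX=S9\nDE\n")
  expect_equal(nrow(pairBySpecies(list(cA, cC))), 1L)

  expect_error(pairBySpecies(list(cA)), "two chains")
})

test_that("paired query columns always carry the query residue with positive mass", {
  cA <- parseA3M(">q\nACDE\n>x OX=S1\nAC-E\n>y OX=S2\nGCDE\n")
  cB <- parseA3M(">q\nKL\n>x OX=S1\nKI\n>y OX=S2\nKL\n")
  paired <- pairBySpecies(list(cA, cB))
  p <- profileMatrix(computeProfile(paired))
  qchars <- strsplit(msaRows(paired)[1], "")[[1]]
  for (l in seq_along(qchars)) expect_gt(p[l, qchars[l]], 0)
})

test_that("blockDiagonalize pads each chain's rows with all-gap off-chain spans", {
  cA <- parseA3M(">qa\nACD\n>a1\nAC-\n>a2\nA-D\n")
  cB <- parseA3M(">qb\nKL\n>b1\nKI\n")
  bd <- blockDiagonalize(list(cA, cB))
  expect_equal(ncol(bd), 5L)
  expect_equal(msaRows(bd)[1], "ACDKL")          # concatenated query first
  expect_equal(msaRows(bd)[2], "AC---")
  expect_equal(msaRows(bd)[3], "A-D--")
  expect_equal(msaRows(bd)[4], "---KI")
  expect_equal(chainLengths(bd), c(3L, 2L))
  # off-chain gap fraction is exactly 1
  offchain <- substr(msaRows(bd)[4], 1, 3)
  expect_equal(offchain, "---")

  # single chain: identity (query + its rows, no padding)
  solo <- blockDiagonalize(list(cA))
  expect_equal(msaRows(solo), msaRows(cA))
})

test_that("blockDiagonalize preserves per-chain column profiles on that chain's rows", {
  cA <- demo_problem(L = 5L, nRows = 30L, seed = 3L)@observedMSA
  cB <- demo_problem(L = 4L, nRows = 20L, seed = 4L)@observedMSA
  bd <- blockDiagonalize(list(cA, cB))
  rowsA <- 2:30                      # chain A block rows in the output
  pA <- profileMatrix(computeProfile(bd, rowsA))[1:5, ]
  pAref <- profileMatrix(computeProfile(cA, 2:30))
  expect_equal(unname(pA), unname(pAref))
})

test_that("mergeChains stacks paired rows above the block-diagonal rows", {
  cA <- parseA3M(">qa\nACD\n>a1 OX=S1\nACD\n>a2 OX=S9\nAC-\n")
  cB <- parseA3M(">qb\nKL\n>b1 OX=S1\nKL\n")
  merged <- mergeChains(list(cA, cB))
  expect_equal(msaRows(merged)[1], "ACDKL")
  expect_equal(msaRows(merged)[2], "ACDKL")      # S1 paired row
  expect_equal(nrow(merged), 2L + 3L)            # + 3 block rows
  expect_equal(chainLengths(merged), c(3L, 2L))
})

test_that("randomizeProfile draws valid simplex columns deterministically", {
  pr <- demo_problem(L = 30L)
  p <- computeProfile(observedMSA(pr))
  r1 <- randomizeProfile(p, seed = 5)
  r2 <- randomizeProfile(p, seed = 5)
  expect_identical(profileMatrix(r1), profileMatrix(r2))
  expect_true(all(abs(rowSums(profileMatrix(r1)) - 1) < 1e-9))
  expect_true(all(profileMatrix(r1) >= 0 & profileMatrix(r1) <= 1))
  expect_false(identical(profileMatrix(randomizeProfile(p, seed = 6)),
                         profileMatrix(r1)))
})

test_that("randomized columns sit far from a sharply peaked profile", {
  # Monte-Carlo estimate of the expected per-column total-variation
  # distance between a near-one-hot profile and uniform simplex draws
  peaked <- ClusterProfile(matrix(rep(c(0.99, rep(0.01 / 21, 21)), 10),
                                  nrow = 10, byrow = TRUE))
  tvs <- vapply(1:100, function(s) {
    r <- profileMatrix(randomizeProfile(peaked, seed = s))
    mean(0.5 * rowSums(abs(r - profileMatrix(peaked))))
  }, 0)
  expect_gt(mean(tvs), 0.3)
})

test_that("profile TSV and JSON serialization round-trips at 12 significant digits", {
  pr <- demo_problem(L = 15L)
  p <- computeProfile(observedMSA(pr))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  writeProfileTSV(p, tmp)
  back <- readProfileTSV(tmp)
  expect_equal(profileMatrix(back), profileMatrix(p), tolerance = 1e-11)

  tmpj <- tempfile(fileext = ".json")
  on.exit(unlink(tmpj), add = TRUE)
  writeProfileJSON(p, tmpj)
  backj <- readProfileJSON(tmpj)
  expect_equal(profileMatrix(backj), profileMatrix(p), tolerance = 1e-12)

  # bias dialect: unconstrained values survive
  b <- initBias(15L)
  bm <- profileMatrix(b)
  bm[3, 5] <- -0.25
  b2 <- new("ProfileBias", matrix = bm, complexId = "t")
  writeProfileTSV(b2, tmp)
  expect_equal(unname(profileMatrix(readProfileTSV(tmp, what = "bias"))),
               unname(bm), tolerance = 1e-11)
})
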