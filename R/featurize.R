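# Featurization: cluster sampling, the cluster profile, multimer species
# pairing and block diagonalization, profile corruption, and the profile
# TSV/JSON serialization dialect.

.char_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, ""))
}

#' Compute the cluster profile of an MSA
#'
#' Entry (l, a) is the relative frequency of alphabet class a at alignment
#' column l over the selected rows — the per-column categorical
#' distribution the optimizer learns a residual for.
#'
#' @param msa an [MSA-class].
#' @param rows optional integer subset of row indices (1-based); defaults to
#'   all rows.
#' @return A [ClusterProfile-class] (L x 22, rows summing to 1).
#' @export
#' @examples
#' msa <- parseAlignedFasta(">q\nA\n>s\nC\n")
#' profileMatrix(computeProfile(msa))[1, c("A", "C")]
computeProfile <- function(msa, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(msa))
  if (length(rows) == 0) .stopf("computeProfile: empty row selection")
  if (any(rows < 1) || any(rows > nrow(msa))) .stopf("computeProfile: row index out of range")
  L <- ncol(msa)
  cm <- .char_matrix(msaRows(msa)[rows])
  cls <- match(cm, .ALPHABET)              # n x L, class index per cell
  col <- rep(seq_len(L), each = length(rows))
  counts <- matrix(tabulate((col - 1L) * .NCLASS + cls, nbins = L * .NCLASS),
                   nrow = .NCLASS, ncol = L)
  ClusterProfile(t(counts) / length(rows))
}

#' Sample cluster-center rows from an MSA
#'
#' Returns `min(nClusters, nrow(msa))` unique row indices; the query (index
#' 1) is always included and first, the remainder drawn uniformly without
#' replacement. Deterministic given the seed. This emulates the predictor's
#' sampling of the MSA into a fixed number of cluster centers (the full MSA
#' never fits in the network).
#'
#' @param msa an [MSA-class].
#' @param nClusters number of cluster rows (>= 1); silently capped at the
#'   row count.
#' @param seed integer seed.
#' @return Integer vector of row indices, query first.
#' @export
sampleClusters <- function(msa, nClusters = 128L, seed = 0L) {
  if (nClusters < 1) .stopf("sampleClusters: nClusters must be >= 1")
  n <- nrow(msa)
  k <- min(as.integer(nClusters), n)
  if (k == 1L || n == 1L) return(1L)
  rest <- .with_seed(seed, sample(seq.int(2L, n), k - 1L, replace = FALSE))
  c(1L, rest)
}

#' Build the featurized view of an MSA
#'
#' Samples cluster rows, computes the cluster profile over them, and carries
#' the per-column deletion mean as pass-through context. Only the profile is
#' ever biased.
#'
#' @inheritParams sampleClusters
#' @return A [FeatureBundle-class].
#' @export
makeFeatures <- function(msa, nClusters = 128L, seed = 0L) {
  cr <- sampleClusters(msa, nClusters, seed)
  new("FeatureBundle",
      profile = computeProfile(msa, cr),
      clusterRows = cr,
      deletionMean = colMeans(msaDeletions(msa)[cr, , drop = FALSE]),
      msa = msa, biasApplied = FALSE)
}

#' Pair chain MSAs by species
#'
#' For a multimer, rows from different chains are paired when they share a
#' taxon: for every species present in all chains, the highest
#' query-identity row of that species is taken from each chain and the rows
#' are concatenated. Row 1 of the result is the concatenated query. Rows
#' without a parsable taxon are unpairable. Deletion counts are concatenated
#' and `chainLengths` records the per-chain column spans.
#'
#' @param chainMsas list of two or more [MSA-class] objects, each with a
#'   gap-free query row.
#' @return An [MSA-class] of paired rows (possibly just the query when no
#'   species is shared).
#' @export
pairBySpecies <- function(chainMsas) {
  if (length(chainMsas) < 2) .stopf("pairBySpecies: need at least two chains")
  for (m in chainMsas) {
    if (nrow(m) < 1) .stopf("pairBySpecies: empty chain MSA")
    if (grepl("-", msaRows(m)[1], fixed = TRUE))
      .stopf("pairBySpecies: chain query row must be gap-free")
  }
  common <- Reduce(intersect, lapply(chainMsas, function(m) {
    sp <- msaSpecies(m)[-1]
    unique(sp[!is.na(sp)])
  }))
  common <- sort(common)
  pick <- function(m, s) {
    cand <- which(msaSpecies(m) == s & seq_len(nrow(m)) != 1L)
    ident <- vapply(cand, function(i) sequenceIdentity(msaRows(m)[i], msaRows(m)[1]), 0)
    cand[which.max(ident)]
  }
  idx <- lapply(chainMsas, function(m) vapply(common, pick, 0L, m = m))
  rows <- paste0(vapply(chainMsas, function(m) msaRows(m)[1], ""), collapse = "")
  dels <- list(do.call(cbind, lapply(chainMsas, function(m) msaDeletions(m)[1, , drop = FALSE])))
  headers <- paste(vapply(chainMsas, function(m) msaHeaders(m)[1], ""), collapse = " ")
  species <- NA_character_
  for (j in seq_along(common)) {
    rows <- c(rows, paste0(vapply(seq_along(chainMsas),
                                  function(c) msaRows(chainMsas[[c]])[idx[[c]][j]], ""),
                           collapse = ""))
    dels[[j + 1L]] <- do.call(cbind, lapply(seq_along(chainMsas), function(c)
      msaDeletions(chainMsas[[c]])[idx[[c]][j], , drop = FALSE]))
    headers <- c(headers, paste(vapply(seq_along(chainMsas), function(c)
      msaHeaders(chainMsas[[c]])[idx[[c]][j]], ""), collapse = " "))
    species <- c(species, common[j])
  }
  MSA(rows = rows, deletions = do.call(rbind, dels), species = species,
      headers = headers,
      chainLengths = vapply(chainMsas, ncol, 0L))
}

#' Block-diagonalize chain MSAs
#'
#' Places every non-query row of each chain in that chain's column span with
#' gaps everywhere else, preserving intra-chain covariation without implying
#' any inter-chain pairing. Row 1 of the result is the concatenated query;
#' total width is the sum of chain lengths.
#'
#' @param chainMsas list of one or more [MSA-class] objects.
#' @return An [MSA-class]: concatenated query first, then one padded row per
#'   non-query input row, chains in order.
#' @export
blockDiagonalize <- function(chainMsas) {
  if (length(chainMsas) < 1) .stopf("blockDiagonalize: need at least one chain")
  for (m in chainMsas) if (nrow(m) < 1) .stopf("blockDiagonalize: empty chain MSA")
  lens <- vapply(chainMsas, ncol, 0L)
  L <- sum(lens)
  offsets <- c(0L, cumsum(lens))
  rows <- paste0(vapply(chainMsas, function(m) msaRows(m)[1], ""), collapse = "")
  dels <- list(matrix(unlist(lapply(chainMsas, function(m) msaDeletions(m)[1, ])), 1L, L))
  headers <- paste(vapply(chainMsas, function(m) msaHeaders(m)[1], ""), collapse = " ")
  species <- NA_character_
  for (c in seq_along(chainMsas)) {
    m <- chainMsas[[c]]
    if (nrow(m) < 2) next
    left <- strrep("-", offsets[c])
    right <- strrep("-", L - offsets[c] - lens[c])
    for (i in seq.int(2L, nrow(m))) {
      rows <- c(rows, paste0(left, msaRows(m)[i], right))
      d <- integer(L)
      d[(offsets[c] + 1L):(offsets[c] + lens[c])] <- msaDeletions(m)[i, ]
      dels[[length(dels) + 1L]] <- matrix(d, 1L, L)
      headers <- c(headers, msaHeaders(m)[i])
      species <- c(species, msaSpecies(m)[i])
    }
  }
  MSA(rows = rows, deletions = do.call(rbind, dels), species = species,
      headers = headers, chainLengths = lens)
}

#' Merge chain MSAs the way a multimer pipeline does
#'
#' Species-paired rows first (query included), then the block-diagonalized
#' unpaired representation of every chain's non-query rows.
#'
#' @param chainMsas list of [MSA-class] objects, one per chain.
#' @return An [MSA-class] covering all chains.
#' @export
mergeChains <- function(chainMsas) {
  if (length(chainMsas) == 1) return(chainMsas[[1]])
  paired <- pairBySpecies(chainMsas)
  block <- blockDiagonalize(chainMsas)
  keep <- seq.int(2L, nrow(block))
  MSA(rows = c(msaRows(paired), msaRows(block)[keep]),
      deletions = rbind(msaDeletions(paired), msaDeletions(block)[keep, , drop = FALSE]),
      species = c(msaSpecies(paired), msaSpecies(block)[keep]),
      headers = c(msaHeaders(paired), msaHeaders(block)[keep]),
      chainLengths = chainLengths(paired))
}

#' Replace every profile column by a uniform simplex draw
#'
#' The destructive control for the whole approach: a random profile (with
#' all other features intact) carries no evolutionary signal, and a
#' predictor driven by it collapses to low confidence. Each alignment
#' column is replaced by an independent uniform draw from the 22-class
#' probability simplex.
#'
#' @param profile a [ClusterProfile-class].
#' @param seed integer seed; the corruption is deterministic given it.
#' @return A valid [ClusterProfile-class] with i.i.d. uniform-simplex rows.
#' @export
randomizeProfile <- function(profile, seed = 0L) {
  m <- profileMatrix(profile)
  rnd <- .with_seed(seed, t(vapply(seq_len(nrow(m)),
                                   function(i) .runif_simplex(ncol(m)),
                                   numeric(ncol(m)))))
  ClusterProfile(rnd)
}

#' Write / read a profile (or bias) matrix as TSV
#'
#' L rows by 22 columns, header line = the alphabet, values printed with 12
#' significant digits so a write/read round trip is bit-exact at that
#' precision.
#'
#' @param x a [ClusterProfile-class], [ProfileBias-class], or plain matrix.
#' @param path file path.
#' @return `writeProfileTSV` returns `path` invisibly.
#' @export
writeProfileTSV <- function(x, path) {
  m <- if (is.matrix(x)) x else profileMatrix(x)
  lines <- c(paste(.ALPHABET, collapse = "\t"),
             apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @param what "profile" validates and returns a [ClusterProfile-class];
#'   "bias" returns a [ProfileBias-class]; "matrix" returns the raw matrix.
#' @param complexId identifier attached when reading a bias.
#' @export
readProfileTSV <- function(path, what = c("profile", "bias", "matrix"),
                           complexId = "unknown") {
  what <- match.arg(what)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE, comment.char = ""))
  dimnames(m) <- list(NULL, .ALPHABET)
  switch(what,
         profile = ClusterProfile(m / rowSums(m)),
         bias = new("ProfileBias", matrix = m, complexId = complexId),
         matrix = m)
}

#' @rdname writeProfileTSV
#' @export
writeProfileJSON <- function(x, path) {
  m <- if (is.matrix(x)) x else profileMatrix(x)
  jsonlite::write_json(
    list(L = nrow(m), A = ncol(m), alphabet = paste(.ALPHABET, collapse = ""),
         matrix = unname(m)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @export
readProfileJSON <- function(path, what = c("profile", "bias", "matrix"),
                            complexId = "unknown") {
  what <- match.arg(what)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(obj$matrix, nrow = obj$L, ncol = obj$A)
  dimnames(m) <- list(NULL, .ALPHABET)
  switch(what,
         profile = ClusterProfile(m / rowSums(m)),
         bias = new("ProfileBias", matrix = m, complexId = complexId),
         matrix = m)
}
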