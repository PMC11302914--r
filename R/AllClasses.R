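# Central S4 classes. All matrices are L x A with A = 22 (profileAlphabet()).

#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MSA: a multiple sequence alignment with deletion counts
#'
#' Aligned rows over the 22-letter alphabet (20 amino acids, 'X', '-'), all of
#' equal length L. Row 1 is always the query. `deletions[i, l]` counts the
#' lowercase (inserted) residues that preceded match column `l` in row `i` of
#' the source A3M; it is all-zero for plain aligned FASTA. `species` carries a
#' best-effort per-row taxon label (`NA` = unpairable). `chainLengths` splits
#' the columns into per-chain spans for multimers (a single entry for
#' monomers) and must sum to L.
#'
#' @slot rows character vector of aligned sequences.
#' @slot deletions integer matrix, `length(rows)` x L.
#' @slot species character vector, one label per row (`NA` allowed).
#' @slot headers character vector, FASTA/A3M header lines without the ">".
#' @slot chainLengths integer vector of per-chain column counts.
#' @export
setClass("MSA", representation(
  rows = "character",
  deletions = "matrix",
  species = "character",
  headers = "character",
  chainLengths = "integer"
))

setValidity("MSA", function(object) {
  n <- length(object@rows)
  if (n < 1) return("MSA must contain at least one row (the query)")
  L <- nchar(object@rows[1])
  if (L < 1) return("alignment width must be >= 1")
  if (any(nchar(object@rows) != L)) return("all rows must have identical length")
  bad <- setdiff(unique(strsplit(paste(object@rows, collapse = ""), "")[[1]]), .ALPHABET)
  if (length(bad)) return(sprintf("characters outside alphabet: %s", paste(bad, collapse = "")))
  if (!identical(dim(object@deletions), c(n, L))) return("deletions must be rows x L")
  if (any(object@deletions < 0)) return("deletion counts must be >= 0")
  if (length(object@species) != n) return("species must have one entry per row")
  if (length(object@headers) != n) return("headers must have one entry per row")
  if (sum(object@chainLengths) != L) return("chainLengths must sum to alignment width")
  if (any(object@chainLengths < 1)) return("chainLengths must be positive")
  TRUE
})

#' Construct an MSA object
#'
#' @param rows character vector of aligned rows (query first).
#' @param deletions optional integer matrix of insertion counts; defaults to
#'   all zeros.
#' @param species optional per-row taxon labels; defaults to `NA`.
#' @param headers optional header lines; defaults to `row1`, `row2`, ...
#' @param chainLengths optional per-chain column spans; defaults to a single
#'   chain covering all columns.
#' @return An [MSA-class] object.
#' @export
MSA <- function(rows, deletions = NULL, species = NULL, headers = NULL,
                chainLengths = NULL) {
  rows <- unname(as.character(rows))
  n <- length(rows)
  L <- if (n) nchar(rows[1]) else 0L
  if (is.null(deletions)) deletions <- matrix(0L, n, L)
  deletions <- unname(as.matrix(deletions))
  storage.mode(deletions) <- "integer"
  if (is.null(species)) species <- rep(NA_character_, n)
  if (is.null(headers)) headers <- paste0("row", seq_len(n))
  if (is.null(chainLengths)) chainLengths <- as.integer(L)
  new("MSA", rows = rows, deletions = deletions,
      species = unname(as.character(species)), headers = unname(headers),
      chainLengths = unname(as.integer(chainLengths)))
}

#' ClusterProfile: per-column residue frequency matrix
#'
#' The "cluster profile": row l is the categorical distribution of the 22
#' residue classes at alignment column l, computed over a sampled subset of
#' MSA rows. Each row sums to 1 (tolerance 1e-9). This is the feature the
#' optimizer biases.
#'
#' @slot matrix numeric L x 22 matrix with columns named by
#'   [profileAlphabet()].
#' @export
setClass("ClusterProfile", representation(matrix = "matrix"))

setValidity("ClusterProfile", function(object) {
  m <- object@matrix
  if (ncol(m) != .NCLASS) return(sprintf("profile must have %d columns", .NCLASS))
  if (nrow(m) < 1) return("profile must have at least one column position")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) return("profile entries must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-9)) return("each profile row must sum to 1 (tol 1e-9)")
  TRUE
})

#' Construct a ClusterProfile from a numeric matrix
#' @param matrix numeric L x 22 matrix of per-column class frequencies.
#' @return A [ClusterProfile-class] object.
#' @export
ClusterProfile <- function(matrix) {
  colnames(matrix) <- .ALPHABET
  new("ClusterProfile", matrix = matrix)
}

#' ProfileBias: the learned additive residual to a cluster profile
#'
#' Unconstrained L x 22 real matrix, zero-initialized, added elementwise to
#' the cluster profile before the backend forward pass. A bias is specific to
#' one complex and never shared.
#'
#' @slot matrix numeric L x 22 matrix.
#' @slot complexId identifier of the complex the bias was trained for.
#' @export
setClass("ProfileBias", representation(matrix = "matrix", complexId = "character"))

setValidity("ProfileBias", function(object) {
  if (ncol(object@matrix) != .NCLASS) return(sprintf("bias must have %d columns", .NCLASS))
  if (nrow(object@matrix) < 1) return("bias must have at least one row")
  if (any(!is.finite(object@matrix))) return("bias entries must be finite")
  TRUE
})

#' OptConfig: optimizer and run configuration
#'
#' Defaults follow the preferred published setting: Adam with learning rate
#' 1e-4, at most 100 steps, 20 recycles per forward pass, stochastic
#' resampling on.
#'
#' @slot learningRate positive step size (default 1e-4).
#' @slot beta1,beta2 Adam moment decay rates (0.9, 0.999).
#' @slot epsilon Adam denominator fuzz (1e-8).
#' @slot maxIters iteration budget (default 100).
#' @slot nRecycles internal recycles per forward pass (default 20).
#' @slot stochastic logical; resample clusters and enable backend noise each
#'   iteration.
#' @slot masterSeed integer master seed; all per-iteration seeds derive from
#'   it.
#' @slot nClusters number of cluster rows sampled per profile (default 128,
#'   silently capped at the MSA row count).
#' @export
setClass("OptConfig", representation(
  learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
  epsilon = "numeric", maxIters = "integer", nRecycles = "integer",
  stochastic = "logical", masterSeed = "integer", nClusters = "integer"
))

setValidity("OptConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@beta1 < 0 || object@beta1 >= 1) return("beta1 must be in [0, 1)")
  if (object@beta2 < 0 || object@beta2 >= 1) return("beta2 must be in [0, 1)")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  if (object@maxIters < 1) return("maxIters must be >= 1")
  if (object@nRecycles < 0) return("nRecycles must be >= 0")
  if (object@nClusters < 1) return("nClusters must be >= 1")
  TRUE
})

#' Construct an OptConfig
#' @param learningRate,beta1,beta2,epsilon Adam hyperparameters.
#' @param maxIters iteration budget.
#' @param nRecycles recycles per forward pass.
#' @param stochastic enable per-iteration resampling and backend noise.
#' @param masterSeed master seed for all randomness of the run.
#' @param nClusters cluster rows sampled per profile.
#' @return An [OptConfig-class] object.
#' @export
optConfig <- function(learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, maxIters = 100L, nRecycles = 20L,
                      stochastic = TRUE, masterSeed = 0L, nClusters = 128L) {
  new("OptConfig", learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      epsilon = epsilon, maxIters = as.integer(maxIters),
      nRecycles = as.integer(nRecycles), stochastic = stochastic,
      masterSeed = as.integer(masterSeed), nClusters = as.integer(nClusters))
}

#' AdamState: first/second moment estimates and step counter
#' @slot m,v numeric matrices, same shape as the bias.
#' @slot t integer step counter.
#' @export
setClass("AdamState", representation(m = "matrix", v = "matrix", t = "integer"))

setValidity("AdamState", function(object) {
  if (!identical(dim(object@m), dim(object@v))) return("m and v must have identical shape")
  if (any(object@v < 0)) return("second moments must be >= 0")
  if (object@t < 0) return("step counter must be >= 0")
  TRUE
})

#' Trajectory: per-iteration records of one optimization run
#'
#' `records` has one row per completed iteration with columns `iteration`
#' (0-based), `iptm`, `ptm`, `confidence`, `loss`, `bias_l2`,
#' `accuracy_proxy`. Invariants: `confidence = 0.8*iptm + 0.2*ptm` and
#' `loss = 1/confidence` hold rowwise; `bestIndex` points at the
#' maximum-confidence row (earliest on ties).
#'
#' @slot records data.frame of per-iteration records.
#' @slot config the [OptConfig-class] the run used.
#' @slot bestIndex integer row index of the best record.
#' @export
setClass("Trajectory", representation(
  records = "data.frame", config = "OptConfig", bestIndex = "integer"
))

setValidity("Trajectory", function(object) {
  r <- object@records
  need <- c("iteration", "iptm", "ptm", "confidence", "loss", "bias_l2", "accuracy_proxy")
  if (!all(need %in% names(r))) return("records is missing required columns")
  if (nrow(r) > object@config@maxIters) return("more records than maxIters")
  if (nrow(r) > 0) {
    if (any(abs(r$confidence - (0.8 * r$iptm + 0.2 * r$ptm)) > 1e-12))
      return("confidence must equal 0.8*iptm + 0.2*ptm (tol 1e-12)")
    if (any(abs(r$loss - 1 / r$confidence) > 1e-9))
      return("loss must equal 1/confidence (tol 1e-9)")
    if (object@bestIndex < 1 || object@bestIndex > nrow(r)) return("bestIndex out of range")
    if (r$confidence[object@bestIndex] < max(r$confidence) - 1e-15)
      return("bestIndex must point at the maximum-confidence record")
  }
  TRUE
})

#' FeatureBundle: featurized view of an MSA
#'
#' The cluster profile over the sampled rows plus per-column deletion means,
#' with a back-reference to the source MSA. Only the profile is ever biased;
#' the deletion means are pass-through context for a backend.
#'
#' @slot profile the [ClusterProfile-class] over `clusterRows`.
#' @slot clusterRows integer row indices (query, index 1, always first).
#' @slot deletionMean numeric per-column mean deletion count over
#'   `clusterRows`.
#' @slot msa the source [MSA-class].
#' @slot biasApplied logical flag.
#' @export
setClass("FeatureBundle", representation(
  profile = "ClusterProfile", clusterRows = "integer",
  deletionMean = "numeric", msa = "MSA", biasApplied = "logical"
))

setValidity("FeatureBundle", function(object) {
  cr <- object@clusterRows
  if (length(cr) < 1 || cr[1] != 1L) return("clusterRows must start with the query (index 1)")
  if (anyDuplicated(cr)) return("clusterRows must be unique")
  if (any(cr < 1) || any(cr > length(object@msa@rows))) return("clusterRows out of range")
  if (length(object@deletionMean) != nrow(object@profile@matrix))
    return("deletionMean must have one entry per column position")
  TRUE
})

#' FoldConfidenceBackend: the predictor adapter contract
#'
#' Virtual class for differentiable fold-confidence predictors. A backend
#' must implement [backendForward()] (iptm/ptm/accuracy proxy from an L x 22
#' feature matrix, with `nRecycles` internal passes and optional internal
#' noise) and [backendGradient()] (d(confidence)/d(features) evaluated at the
#' final pass only — gradients never flow across recycles). A backend must be
#' pure given (features, seed).
#'
#' @export
setClass("FoldConfidenceBackend", representation("VIRTUAL"))

#' SurrogateProblem: a planted-profile synthetic fold-confidence problem
#'
#' Holds a planted "true" profile P*, an observed MSA sampled from a
#' noise-blurred copy of P*, and the sharpness constants of the synthetic
#' confidence function `iptm = exp(-kIptm * d)`, `ptm = exp(-kPtm * d)` where
#' d is the mean squared column distance between the input features and P*.
#' Confidence is maximized exactly when profile + bias recovers P*.
#'
#' @slot plantedProfile the ground-truth [ClusterProfile-class] (P*).
#' @slot observedMSA [MSA-class] sampled from the blurred profile.
#' @slot blurredProfile the noise-blurred [ClusterProfile-class] rows were
#'   drawn from.
#' @slot noiseSigma Gaussian blur level applied to P*.
#' @slot sharpnessIptm,sharpnessPtm positive decay constants (defaults 5, 3).
#' @slot seed integer seed the problem was built from.
#' @export
setClass("SurrogateProblem", representation(
  plantedProfile = "ClusterProfile", observedMSA = "MSA",
  blurredProfile = "ClusterProfile", noiseSigma = "numeric",
  sharpnessIptm = "numeric", sharpnessPtm = "numeric", seed = "integer"
))

setValidity("SurrogateProblem", function(object) {
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@sharpnessIptm <= 0 || object@sharpnessPtm <= 0)
    return("sharpness constants must be > 0")
  if (nrow(object@plantedProfile@matrix) != nchar(object@observedMSA@rows[1]))
    return("planted profile width must match the observed MSA")
  TRUE
})

#' SurrogateBackend: FoldConfidenceBackend over a SurrogateProblem
#'
#' @slot problem the [SurrogateProblem-class] defining the confidence
#'   surface.
#' @export
setClass("SurrogateBackend", contains = "FoldConfidenceBackend",
         representation(problem = "SurrogateProblem"))

#' Wrap a SurrogateProblem as an optimization backend
#' @param problem a [SurrogateProblem-class].
#' @return A [SurrogateBackend-class].
#' @export
SurrogateBackend <- function(problem) new("SurrogateBackend", problem = problem)

#' FoldPrediction: one backend forward-pass result
#'
#' @slot iptm,ptm predicted TM-scores (interface / whole complex), in [0,1].
#' @slot confidence ranking confidence `0.8*iptm + 0.2*ptm`.
#' @slot accuracyProxy backend-specific accuracy stand-in (surrogate:
#'   negative mean squared distance to the planted profile over all columns).
#' @export
setClass("FoldPrediction", representation(
  iptm = "numeric", ptm = "numeric", confidence = "numeric",
  accuracyProxy = "numeric"
))
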