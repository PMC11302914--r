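# Accessor and show methods.

#' @rdname MSA-class
#' @export
setMethod("msaRows", "MSA", function(x) x@rows)

#' @rdname MSA-class
#' @export
setMethod("msaDeletions", "MSA", function(x) x@deletions)

#' @rdname MSA-class
#' @export
setMethod("msaSpecies", "MSA", function(x) x@species)

#' @rdname MSA-class
#' @export
setMethod("msaHeaders", "MSA", function(x) x@headers)

#' @rdname MSA-class
#' @export
setMethod("chainLengths", "MSA", function(x) x@chainLengths)

#' @rdname MSA-class
#' @export
setMethod("nrow", "MSA", function(x) length(x@rows))

#' @rdname MSA-class
#' @export
setMethod("ncol", "MSA", function(x) nchar(x@rows[1]))

setMethod("show", "MSA", function(object) {
  cat(sprintf("MSA: %d rows x %d columns, %d chain(s)\n",
              nrow(object), ncol(object), length(object@chainLengths)))
  nsp <- sum(!is.na(object@species))
  cat(sprintf("  species labels: %d/%d rows; total deletions: %d\n",
              nsp, nrow(object), sum(object@deletions)))
  q <- object@rows[1]
  if (nchar(q) > 60) q <- paste0(substr(q, 1, 57), "...")
  cat("  query: ", q, "\n", sep = "")
})

#' @rdname ClusterProfile-class
#' @export
setMethod("profileMatrix", "ClusterProfile", function(x) x@matrix)

#' @rdname ProfileBias-class
#' @export
setMethod("profileMatrix", "ProfileBias", function(x) x@matrix)

setMethod("show", "ClusterProfile", function(object) {
  m <- object@matrix
  cat(sprintf("ClusterProfile: %d positions x %d classes\n", nrow(m), ncol(m)))
  ent <- -rowSums(ifelse(m > 0, m * log(m), 0))
  cat(sprintf("  mean column entropy: %.3f nats\n", mean(ent)))
})

setMethod("show", "ProfileBias", function(object) {
  cat(sprintf("ProfileBias for '%s': %d x %d, L2 norm %.4g\n",
              object@complexId, nrow(object@matrix), ncol(object@matrix),
              sqrt(sum(object@matrix^2))))
})

setMethod("show", "OptConfig", function(object) {
  cat(sprintf(
    "OptConfig: lr %g, Adam(%g, %g, eps %g), %d iters, %d recycles, stochastic %s, seed %d, %d clusters\n",
    object@learningRate, object@beta1, object@beta2, object@epsilon,
    object@maxIters, object@nRecycles, object@stochastic, object@masterSeed,
    object@nClusters))
})

#' @rdname Trajectory-class
#' @export
setMethod("records", "Trajectory", function(x) x@records)

#' @rdname Trajectory-class
#' @export
setMethod("length", "Trajectory", function(x) nrow(x@records))

#' @rdname selectBest
#' @export
setMethod("selectBest", "Trajectory", function(x) {
  if (nrow(x@records) == 0) .stopf("cannot select from an empty trajectory")
  x@records[x@bestIndex, , drop = FALSE]
})

setMethod("show", "Trajectory", function(object) {
  r <- object@records
  cat(sprintf("Trajectory: %d iterations\n", nrow(r)))
  if (nrow(r)) {
    b <- r[object@bestIndex, ]
    cat(sprintf("  confidence: %.4f (start) -> %.4f (best, iteration %d)\n",
                r$confidence[1], b$confidence, b$iteration))
  }
})

setMethod("show", "SurrogateProblem", function(object) {
  cat(sprintf(
    "SurrogateProblem: L = %d, %d observed rows, noise sigma %.3g, sharpness (%.3g, %.3g), seed %d\n",
    nrow(object@plantedProfile@matrix), nrow(object@observedMSA),
    object@noiseSigma, object@sharpnessIptm, object@sharpnessPtm, object@seed))
})

#' @rdname SurrogateProblem-class
#' @export
setMethod("plantedProfile", "SurrogateProblem", function(x) x@plantedProfile)

#' @rdname SurrogateProblem-class
#' @export
setMethod("observedMSA", "SurrogateProblem", function(x) x@observedMSA)

setMethod("show", "FoldPrediction", function(object) {
  cat(sprintf("FoldPrediction: iptm %.4f, ptm %.4f, confidence %.4f, accuracy proxy %.4g\n",
              object@iptm, object@ptm, object@confidence, object@accuracyProxy))
})

setMethod("show", "FeatureBundle", function(object) {
  cat(sprintf("FeatureBundle: %d cluster rows over a %d-column MSA, bias applied: %s\n",
              length(object@clusterRows), nrow(object@profile@matrix),
              object@biasApplied))
})
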