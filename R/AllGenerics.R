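# Generics. Accessors are preferred over @-slot access everywhere.

#' @rdname MSA-class
#' @param x,object an object.
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname MSA-class
#' @export
setGeneric("msaDeletions", function(x) standardGeneric("msaDeletions"))

#' @rdname MSA-class
#' @export
setGeneric("msaSpecies", function(x) standardGeneric("msaSpecies"))

#' @rdname MSA-class
#' @export
setGeneric("msaHeaders", function(x) standardGeneric("msaHeaders"))

#' @rdname MSA-class
#' @export
setGeneric("chainLengths", function(x) standardGeneric("chainLengths"))

#' @rdname ClusterProfile-class
#' @param x an object with an underlying profile/bias matrix.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname Trajectory-class
#' @param x a [Trajectory-class].
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Select the best record of a trajectory
#'
#' Returns the maximum-confidence record; ties are broken by the earliest
#' iteration. This is the model-selection rule of the whole method: the
#' highest-confidence model is the one reported.
#'
#' @param x a [Trajectory-class].
#' @return A one-row data.frame (iteration, iptm, ptm, confidence, loss,
#'   bias_l2, accuracy_proxy).
#' @export
setGeneric("selectBest", function(x) standardGeneric("selectBest"))

#' Run a backend forward pass
#'
#' @param backend a [FoldConfidenceBackend-class].
#' @param features numeric L x 22 feature matrix (profile + bias, raw).
#' @param nRecycles number of internal recycles; the pass averages
#'   `nRecycles + 1` internal evaluations.
#' @param seed integer seed making the pass reproducible.
#' @param stochastic logical; enable backend-internal noise (the stand-in
#'   for dropout and MSA resampling).
#' @return A [FoldPrediction-class].
#' @export
setGeneric("backendForward", function(backend, features, nRecycles = 20L,
                                      seed = 0L, stochastic = TRUE)
  standardGeneric("backendForward"))

#' Gradient of the confidence with respect to the input features
#'
#' Evaluated at the final internal pass only: gradients are never taken
#' across recycles. Given the same seed as [backendForward()], the final pass
#' is the same one the forward evaluation ended on.
#'
#' @inheritParams backendForward
#' @return A list with `grad` (L x 22 matrix, d(confidence)/d(features)) and
#'   `confidence` (the final-pass confidence the gradient belongs to).
#' @export
setGeneric("backendGradient", function(backend, features, nRecycles = 20L,
                                       seed = 0L, stochastic = TRUE)
  standardGeneric("backendGradient"))

#' @rdname SurrogateProblem-class
#' @param x a [SurrogateProblem-class].
#' @export
setGeneric("plantedProfile", function(x) standardGeneric("plantedProfile"))

#' @rdname SurrogateProblem-class
#' @export
setGeneric("observedMSA", function(x) standardGeneric("observedMSA"))
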