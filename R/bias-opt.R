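# The core loop: learn an additive bias to the cluster profile by Adam
# gradient descent through a frozen fold-confidence backend, minimizing
# 1/confidence. Per iteration the clusters are resampled (stochastic mode),
# the biased features go through the backend, and gradients are taken at the
# final internal pass only.

#' Initialize a zero profile bias
#'
#' @param L number of alignment columns (>= 1).
#' @param A number of residue classes (must be 22).
#' @param complexId identifier of the complex the bias belongs to.
#' @return A [ProfileBias-class] of zeros: `applyBias(p, initBias(...))`
#'   equals `p` for any profile.
#' @export
initBias <- function(L, A = 22L, complexId = "unknown") {
  if (L < 1 || A < 1) .stopf("initBias: dimensions must be positive")
  if (A != .NCLASS) .stopf("initBias: A must be %d", .NCLASS)
  new("ProfileBias", matrix = matrix(0, L, A, dimnames = list(NULL, .ALPHABET)),
      complexId = complexId)
}

#' Add a bias to a cluster profile
#'
#' Plain elementwise sum in raw feature space: no clamping and no
#' renormalization. The backend consumes possibly non-simplex features —
#' the bias is a free residual, not a distribution.
#'
#' @param profile a [ClusterProfile-class] or L x 22 matrix.
#' @param bias a [ProfileBias-class] of the same shape.
#' @return The biased L x 22 feature matrix.
#' @export
applyBias <- function(profile, bias) {
  p <- if (is.matrix(profile)) profile else profileMatrix(profile)
  b <- profileMatrix(bias)
  if (!identical(dim(p), dim(b))) .stopf("applyBias: shape mismatch")
  p + b
}

#' Inverse-confidence loss
#'
#' The optimization objective: minimizing `1/confidence` maximizes the
#' ranking confidence.
#'
#' @param confidence a confidence value in (0, 1].
#' @return `1/confidence`.
#' @export
confidenceLoss <- function(confidence) {
  if (any(confidence <= 0))
    .stopf("confidenceLoss: confidence must be > 0 (degenerate backend output)")
  1 / confidence
}

#' Fresh Adam state matching a bias shape
#' @param bias a [ProfileBias-class].
#' @return An [AdamState-class] with zero moments and t = 0.
#' @export
adamInit <- function(bias) {
  d <- dim(profileMatrix(bias))
  new("AdamState", m = matrix(0, d[1], d[2]), v = matrix(0, d[1], d[2]), t = 0L)
}

#' One Adam update of the profile bias
#'
#' Standard Adam with bias-corrected moments:
#' `m <- b1*m + (1-b1)*g`, `v <- b2*v + (1-b2)*g^2`, `t <- t + 1`,
#' `bias <- bias - lr * (m/(1-b1^t)) / (sqrt(v/(1-b2^t)) + eps)`.
#'
#' @param bias current [ProfileBias-class].
#' @param grad gradient of the loss with respect to the bias (L x 22).
#' @param state current [AdamState-class].
#' @param config an [OptConfig-class] (learning rate and moment decays).
#' @return A list with updated `bias` and `state`.
#' @export
adamUpdate <- function(bias, grad, state, config) {
  b <- profileMatrix(bias)
  if (!identical(dim(b), dim(grad))) .stopf("adamUpdate: shape mismatch")
  m <- config@beta1 * state@m + (1 - config@beta1) * grad
  v <- config@beta2 * state@v + (1 - config@beta2) * grad^2
  t <- state@t + 1L
  mhat <- m / (1 - config@beta1^t)
  vhat <- v / (1 - config@beta2^t)
  bnew <- b - config@learningRate * mhat / (sqrt(vhat) + config@epsilon)
  list(bias = new("ProfileBias", matrix = bnew, complexId = bias@complexId),
       state = new("AdamState", m = m, v = v, t = t))
}

#' Optimize a profile bias against a fold-confidence backend
#'
#' Runs up to `maxIters` iterations. Each iteration i (0-based in the
#' records): derives its seeds from `(masterSeed, i)`; resamples cluster
#' rows and recomputes the profile when `stochastic` is on (otherwise a
#' fixed profile computed once is reused); adds the current bias; runs the
#' backend forward with `nRecycles` internal recycles; takes the gradient
#' of `1/confidence` with respect to the bias at the final pass only
#' (chain rule: `-confidence^-2 * d(confidence)/d(bias)`); applies one Adam
#' update; and appends a trajectory record. Adam state persists across
#' iterations. The learned bias is specific to this complex.
#'
#' A backend error or a non-finite gradient aborts with a condition of
#' class `"biasOptError"` carrying the partial trajectory (fields
#' `trajectory` and `iteration`) — failures are recorded, never silently
#' skipped.
#'
#' @param backend a [FoldConfidenceBackend-class].
#' @param msa the [MSA-class] to featurize and denoise.
#' @param config an [OptConfig-class].
#' @param complexId identifier stored in the returned bias.
#' @return A list with `trajectory` ([Trajectory-class]) and `bias` (the
#'   final [ProfileBias-class]).
#' @export
optimizeBias <- function(backend, msa, config = optConfig(),
                         complexId = "complex") {
  L <- ncol(msa)
  bias <- initBias(L, .NCLASS, complexId)
  state <- adamInit(bias)
  fixed_profile <- NULL
  if (!config@stochastic) {
    rows0 <- sampleClusters(msa, config@nClusters, .derive_seed(config@masterSeed, 0L, 1L))
    fixed_profile <- computeProfile(msa, rows0)
  }
  rec <- vector("list", config@maxIters)
  abort <- function(i, msg) {
    done <- do.call(rbind, rec[seq_len(i - 1L)])
    cond <- structure(
      class = c("biasOptError", "error", "condition"),
      list(message = sprintf("optimization aborted at iteration %d: %s", i - 1L, msg),
           call = sys.call(-1), trajectory = done, iteration = i - 1L))
    stop(cond)
  }
  for (i in seq_len(config@maxIters)) {
    seed_cluster <- .derive_seed(config@masterSeed, i, 1L)
    seed_backend <- .derive_seed(config@masterSeed, i, 2L)
    profile <- if (config@stochastic) {
      computeProfile(msa, sampleClusters(msa, config@nClusters, seed_cluster))
    } else fixed_profile
    features <- applyBias(profile, bias)
    res <- tryCatch({
      pred <- backendForward(backend, features, config@nRecycles,
                             seed_backend, config@stochastic)
      g <- backendGradient(backend, features, config@nRecycles,
                           seed_backend, config@stochastic)
      list(pred = pred, g = g)
    }, error = function(e) e)
    if (inherits(res, "error")) abort(i, conditionMessage(res))
    pred <- res$pred
    # d(1/C)/d(bias) = -C^-2 dC/d(bias), with C the final-pass confidence
    # the gradient was evaluated at; features are linear in the bias.
    grad_loss <- -res$g$grad / res$g$confidence^2
    if (any(!is.finite(grad_loss))) abort(i, "non-finite gradient")
    upd <- adamUpdate(bias, grad_loss, state, config)
    bias <- upd$bias
    state <- upd$state
    conf <- 0.8 * pred@iptm + 0.2 * pred@ptm
    rec[[i]] <- data.frame(
      iteration = i - 1L, iptm = pred@iptm, ptm = pred@ptm,
      confidence = conf, loss = 1 / conf,
      bias_l2 = sqrt(sum(profileMatrix(bias)^2)),
      accuracy_proxy = pred@accuracyProxy)
  }
  records <- do.call(rbind, rec)
  traj <- new("Trajectory", records = records, config = config,
              bestIndex = which.max(records$confidence))
  list(trajectory = traj, bias = bias)
}
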