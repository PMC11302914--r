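# Synthetic differentiable fold-confidence backend with a planted optimum.
# The confidence surface is smooth and convex in the features (squared
# distance through exp), so optimizer correctness — parameter recovery,
# gradient checks, confidence/accuracy coupling — is testable at desk scale.
# No claim of landscape fidelity to a real structure predictor is made.

#' Build a planted-profile surrogate problem
#'
#' Draws a ground-truth profile P* column-wise from a Dirichlet concentrated
#' on one (uniformly chosen) amino acid per column, blurs it with Gaussian
#' noise of sd `noiseSigma` followed by Euclidean projection back onto the
#' simplex, and samples the observed MSA rows i.i.d. per column from the
#' blurred profile. The query row carries the concentrated residue of each
#' column (gap-free by construction). Everything is deterministic given
#' `seed`.
#'
#' @param L number of alignment columns (>= 1).
#' @param nRows number of observed MSA rows including the query (>= 2).
#' @param noiseSigma blur level (>= 0); 0 means the observed rows are drawn
#'   from P* itself.
#' @param seed integer seed.
#' @param sharpnessIptm,sharpnessPtm decay constants of the synthetic
#'   confidence (defaults 5 and 3, so iptm < ptm at moderate distance,
#'   loosely echoing interface vs global score behavior).
#' @return A [SurrogateProblem-class].
#' @export
makeSurrogateProblem <- function(L, nRows, noiseSigma = 0.1, seed = 0L,
                                 sharpnessIptm = 5, sharpnessPtm = 3) {
  if (L < 1) .stopf("makeSurrogateProblem: L must be >= 1")
  if (nRows < 2) .stopf("makeSurrogateProblem: nRows must be >= 2")
  if (noiseSigma < 0) .stopf("makeSurrogateProblem: noiseSigma must be >= 0")
  n_aa <- 20L  # concentrate on real residues, never on 'X' or the gap
  out <- .with_seed(seed, {
    peak <- sample.int(n_aa, L, replace = TRUE)
    planted <- t(vapply(seq_len(L), function(l) {
      alpha <- rep(0.2, .NCLASS)
      alpha[c(.NCLASS - 1L, .NCLASS)] <- 0.02   # X and gap stay rare
      alpha[peak[l]] <- 20
      g <- stats::rgamma(.NCLASS, shape = alpha)
      g / sum(g)
    }, numeric(.NCLASS)))
    blurred <- t(vapply(seq_len(L), function(l)
      .project_simplex(planted[l, ] + stats::rnorm(.NCLASS, 0, noiseSigma)),
      numeric(.NCLASS)))
    rows <- vapply(seq_len(nRows - 1L), function(i)
      paste(.ALPHABET[vapply(seq_len(L), function(l)
        sample.int(.NCLASS, 1L, prob = blurred[l, ]), 0L)], collapse = ""),
      "")
    list(planted = planted, blurred = blurred, rows = rows, peak = peak)
  })
  query <- paste(.ALPHABET[out$peak], collapse = "")
  msa <- MSA(rows = c(query, out$rows),
             headers = c("query", sprintf("synthetic_row%03d", seq_len(nRows - 1L))))
  new("SurrogateProblem",
      plantedProfile = ClusterProfile(out$planted),
      observedMSA = msa,
      blurredProfile = ClusterProfile(out$blurred),
      noiseSigma = noiseSigma,
      sharpnessIptm = sharpnessIptm, sharpnessPtm = sharpnessPtm,
      seed = as.integer(seed))
}

# Shared internal machinery: the (nRecycles + 1) evaluation passes of one
# forward call. In stochastic mode each pass scores a fresh random 80%
# column subset (the joint stand-in for dropout and MSA-resampling noise);
# deterministic mode scores all columns. Pure given (features, seed).
.surrogate_passes <- function(problem, features, nRecycles, seed, stochastic) {
  pm <- profileMatrix(plantedProfile(problem))
  if (!identical(dim(features), dim(pm)))
    .stopf("surrogate: feature shape %s does not match planted profile %s",
           paste(dim(features), collapse = "x"), paste(dim(pm), collapse = "x"))
  L <- nrow(pm)
  sqdist <- rowSums((features - pm)^2)   # per-column squared distance
  npass <- nRecycles + 1L
  subsets <- if (stochastic) {
    k <- max(1L, round(0.8 * L))
    .with_seed(seed, lapply(seq_len(npass), function(j) sort(sample.int(L, k))))
  } else {
    rep(list(seq_len(L)), npass)
  }
  d <- vapply(subsets, function(cols) mean(sqdist[cols]), 0)
  iptm <- exp(-problem@sharpnessIptm * d)
  ptm <- exp(-problem@sharpnessPtm * d)
  list(iptm_mean = mean(iptm), ptm_mean = mean(ptm),
       final_cols = subsets[[npass]], final_d = d[npass],
       final_iptm = iptm[npass], final_ptm = ptm[npass],
       d_all = mean(sqdist))
}

#' Surrogate forward pass
#'
#' Let d be the mean over evaluated columns of the squared Euclidean
#' distance between each feature column and the corresponding planted
#' profile column. Then `iptm = exp(-kIptm * d)` and `ptm = exp(-kPtm * d)`;
#' the reported scores average `nRecycles + 1` internal evaluations (the
#' recycles reduce subset-sampling variance), and the accuracy proxy is
#' `-d` computed over ALL columns. With `stochastic = TRUE` each internal
#' evaluation scores a random 80% column subset.
#'
#' @param problem a [SurrogateProblem-class].
#' @param features numeric L x 22 matrix (profile + bias, raw).
#' @param nRecycles internal recycles (>= 0).
#' @param seed integer seed.
#' @param stochastic enable the column-subset noise.
#' @return A [FoldPrediction-class]; confidence is exactly
#'   `0.8*iptm + 0.2*ptm` of the averaged scores.
#' @export
surrogateForward <- function(problem, features, nRecycles = 20L, seed = 0L,
                             stochastic = TRUE) {
  p <- .surrogate_passes(problem, features, nRecycles, seed, stochastic)
  new("FoldPrediction", iptm = p$iptm_mean, ptm = p$ptm_mean,
      confidence = 0.8 * p$iptm_mean + 0.2 * p$ptm_mean,
      accuracyProxy = -p$d_all)
}

#' Surrogate confidence gradient (final pass only)
#'
#' Analytic d(confidence)/d(features) at the final internal evaluation:
#' `(0.8*kIptm*iptm + 0.2*kPtm*ptm) * (-2/L') * (features - P*)` on the L'
#' evaluated columns of the final pass, zero elsewhere, with iptm/ptm taken
#' at that pass. Mirrors a predictor whose gradients can only be taken at
#' the last recycle.
#'
#' @inheritParams surrogateForward
#' @return A list with `grad` (L x 22 matrix) and `confidence` (final-pass
#'   confidence).
#' @export
surrogateGradient <- function(problem, features, nRecycles = 20L, seed = 0L,
                              stochastic = TRUE) {
  p <- .surrogate_passes(problem, features, nRecycles, seed, stochastic)
  pm <- profileMatrix(plantedProfile(problem))
  coef <- 0.8 * problem@sharpnessIptm * p$final_iptm +
    0.2 * problem@sharpnessPtm * p$final_ptm
  grad <- matrix(0, nrow(pm), ncol(pm))
  cols <- p$final_cols
  grad[cols, ] <- coef * (-2 / length(cols)) * (features[cols, , drop = FALSE] -
                                                  pm[cols, , drop = FALSE])
  list(grad = grad, confidence = 0.8 * p$final_iptm + 0.2 * p$final_ptm)
}

#' @rdname backendForward
#' @export
setMethod("backendForward", "SurrogateBackend",
          function(backend, features, nRecycles = 20L, seed = 0L, stochastic = TRUE)
            surrogateForward(backend@problem, features, nRecycles, seed, stochastic))

#' @rdname backendGradient
#' @export
setMethod("backendGradient", "SurrogateBackend",
          function(backend, features, nRecycles = 20L, seed = 0L, stochastic = TRUE)
            surrogateGradient(backend@problem, features, nRecycles, seed, stochastic))

#' Write a surrogate problem to disk
#'
#' Observed MSA as A3M, planted and blurred profiles as TSV, parameters as
#' JSON — everything needed to reload or inspect the problem, in plain
#' text.
#'
#' @param problem a [SurrogateProblem-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSurrogateProblem <- function(problem, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeA3M(observedMSA(problem), file.path(dir, "observed.a3m"))
  writeProfileTSV(plantedProfile(problem), file.path(dir, "planted_profile.tsv"))
  writeProfileTSV(problem@blurredProfile, file.path(dir, "blurred_profile.tsv"))
  jsonlite::write_json(
    list(L = nrow(profileMatrix(plantedProfile(problem))),
         n_rows = nrow(observedMSA(problem)),
         noise_sigma = problem@noiseSigma,
         sharpness_iptm = problem@sharpnessIptm,
         sharpness_ptm = problem@sharpnessPtm,
         seed = problem@seed),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSurrogateProblem
#' @export
readSurrogateProblem <- function(dir) {
  par <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  new("SurrogateProblem",
      plantedProfile = readProfileTSV(file.path(dir, "planted_profile.tsv")),
      observedMSA = readMSA(file.path(dir, "observed.a3m")),
      blurredProfile = readProfileTSV(file.path(dir, "blurred_profile.tsv")),
      noiseSigma = par$noise_sigma,
      sharpnessIptm = par$sharpness_iptm, sharpnessPtm = par$sharpness_ptm,
      seed = as.integer(par$seed))
}
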