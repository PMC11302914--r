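# msaDenoise

Confidence-guided denoising of MSA cluster profiles by gradient descent.

## The problem

Structure predictors for protein complexes read the multiple sequence
alignment (MSA) through a *cluster profile* — an L x 22 matrix giving, for
each alignment column, the frequency of the 20 amino acids plus unknown
and gap over a sampled subset of rows. A noisy or shallow MSA yields a
blurred profile and a failed, low-confidence prediction. Resampling
protocols rescue such targets by drawing thousands of predictions and
keeping the most confident one, at a matching computational price.

`msaDenoise` implements the gradient alternative for anyone studying
confidence-guided input optimization: learn an additive residual
("bias") to the cluster profile that maximizes the predictor's ranking
confidence

    RC = 0.8 * iptm + 0.2 * ptm

by minimizing `1/RC` with Adam (default learning rate 1e-4, at most 100
steps, 20 recycles per forward pass, gradients taken at the final pass
only). At 100 iterations the budget undercuts a 6000-sample resampling
protocol 60-fold. The bias is zero-initialized, added in raw feature
space without renormalization, and specific to one complex.

The predictor is abstracted behind a backend contract
(`backendForward` / `backendGradient`); the package ships a
**planted-ground-truth surrogate** — a differentiable confidence function
maximized exactly when profile + bias recovers a known planted profile —
so the full loop, model selection and evaluation statistics are testable
on a laptop, with parameter recovery as the sharp correctness criterion.
No GPU, no network weights, no structural data required.

Also included: A3M/FASTA alignment I/O with insertion (deletion-count)
bookkeeping and species labels, multimer featurization (species pairing,
block diagonalization, cluster sampling, profile corruption), and the
evaluation statistics for confidence as a model selector (strict-threshold
success / hidden-failure classification, Spearman correlation, ROC-AUC,
running-mean curves).

## A worked example

```r
library(msaDenoise)

# a planted problem: L = 50 columns, 200 MSA rows drawn from a
# noise-blurred copy of the hidden true profile
pr <- makeSurrogateProblem(L = 50, nRows = 200, noiseSigma = 0.1, seed = 1)
pr
#> SurrogateProblem: L = 50, 200 observed rows, noise sigma 0.1, sharpness (5, 3), seed 1

cfg <- optConfig(learningRate = 1e-2, maxIters = 100,
                 stochastic = FALSE, masterSeed = 1, nRecycles = 0)
res <- optimizeBias(SurrogateBackend(pr), observedMSA(pr), cfg)
res$trajectory
#> Trajectory: 100 iterations
#>   confidence: 0.8439 (start) -> 1.0000 (best, iteration 99)

selectBest(res$trajectory)
#>     iteration      iptm       ptm confidence     loss  bias_l2 accuracy_proxy
#> 100        99 0.9999974 0.9999984  0.9999976 1.000002 1.359307  -5.194466e-07
```

The starting confidence 0.8439 reflects the blur: the observed profile
sits at squared distance ~0.03 per column from the planted optimum.
Gradient descent on the bias drives the confidence to 1.0000 and the
accuracy proxy (negative mean squared distance to the planted profile) to
~-5e-7 — the learned residual has removed essentially all of the planted
noise, which is the method's denoising claim in miniature.

Score tables are summarized with `evaluateScores()`; batches of targets
run through `runBatch()`, which isolates per-target failures and accounts
for every completed iteration. A thin CLI wrapping these functions is in
`inst/scripts/msadenoise` (subcommands `simulate`, `optimize`, `evaluate`,
`fixtures`).

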