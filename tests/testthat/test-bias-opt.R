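test_that("initBias is an additive identity of the right shape", {
  b <- initBias(4L)
  expect_equal(dim(profileMatrix(b)), c(4L, 22L))
  expect_true(all(profileMatrix(b) == 0))
  pr <- demo_problem(L = 4L, nRows = 10L)
  p <- computeProfile(observedMSA(pr))
  expect_equal(applyBias(p, b), profileMatrix(p), ignore_attr = TRUE)
  expect_error(initBias(0L), "positive")
  expect_error(initBias(4L, A = 21L), "must be 22")
})

test_that("applyBias is a raw elementwise sum without renormalization", {
  pr <- demo_problem(L = 6L, nRows = 10L)
  p <- computeProfile(observedMSA(pr))
  neg <- new("ProfileBias", matrix = -profileMatrix(p), complexId = "t")
  expect_true(all(applyBias(p, neg) == 0))
  b <- initBias(6L)
  bm <- profileMatrix(b); bm[] <- 0.5
  b@matrix <- bm
  out <- applyBias(p, b)
  expect_false(all(abs(rowSums(out) - 1) < 1e-9))  # deliberately non-simplex
  expect_identical(applyBias(p, b), applyBias(p, b))
  expect_error(applyBias(p, initBias(5L)), "shape")
})

test_that("confidenceLoss inverts the confidence and rejects degenerate values", {
  expect_equal(confidenceLoss(1.0), 1.0)
  expect_equal(confidenceLoss(0.5), 2.0)
  expect_error(confidenceLoss(0.0), "degenerate")
  expect_error(confidenceLoss(-0.1), "degenerate")
})

test_that("adamUpdate reproduces the hand-evaluated scalar recurrence", {
  # 1x1 bias so the Adam formulas can be traced by hand; the reference is
  # computed with plain scalar arithmetic, independent of adamUpdate
  cfg <- optConfig(learningRate = 1e-4)
  bias1 <- new("ProfileBias",
               matrix = matrix(0, 1, 22, dimnames = list(NULL, profileAlphabet())),
               complexId = "scalar")
  st <- adamInit(bias1)
  g <- matrix(0, 1, 22); g[1, 1] <- 0.5

  lr <- 1e-4; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- 0; v <- 0; x <- 0
  for (t in 1:2) {
    m <- b1 * m + (1 - b1) * 0.5
    v <- b2 * v + (1 - b2) * 0.25
    x <- x - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  }
  u1 <- adamUpdate(bias1, g, st, cfg)
  # first step moves by ~ -lr * g/(|g| + eps)
  expect_equal(unname(profileMatrix(u1$bias)[1, 1]),
               -lr * 0.5 / (0.5 + eps), tolerance = 1e-12)
  u2 <- adamUpdate(u1$bias, g, u1$state, cfg)
  expect_equal(unname(profileMatrix(u2$bias)[1, 1]), x, tolerance = 1e-12)
  expect_equal(u2$state@t, 2L)

  # zero gradient on a fresh state leaves the bias untouched
  u0 <- adamUpdate(bias1, 0 * g, st, cfg)
  expect_true(all(profileMatrix(u0$bias) == 0))
  expect_error(adamUpdate(bias1, matrix(0, 2, 22), st, cfg), "shape")
})

test_that("loss gradient obeys the chain rule against finite differences", {
  pr <- demo_problem(L = 12L, nRows = 60L)
  p <- profileMatrix(computeProfile(observedMSA(pr)))
  g <- surrogateGradient(pr, p, nRecycles = 0L, seed = 0L, stochastic = FALSE)
  conf <- g$confidence
  set.seed(21)
  for (k in 1:20) {
    i <- sample.int(nrow(p), 1); j <- sample.int(22, 1)
    fd_conf <- fd_confidence(pr, p, i, j)
    fd_loss <- local({
      h <- 1e-5
      up <- p; up[i, j] <- up[i, j] + h
      dn <- p; dn[i, j] <- dn[i, j] - h
      (1 / surrogateForward(pr, up, 0L, 0L, FALSE)@confidence -
         1 / surrogateForward(pr, dn, 0L, 0L, FALSE)@confidence) / (2 * h)
    })
    analytic_loss <- -g$grad[i, j] / conf^2
    if (abs(fd_loss) > 1e-5)
      expect_lt(abs(analytic_loss - fd_loss) / abs(fd_loss), 1e-5)
    if (abs(fd_conf) > 1e-5)
      expect_lt(abs(g$grad[i, j] - fd_conf) / abs(fd_conf), 1e-5)
  }
})

test_that("a single optimization step moves the bias and records one entry", {
  pr <- demo_problem()
  cfg <- optConfig(maxIters = 1L, masterSeed = 5L)
  res <- optimizeBias(SurrogateBackend(pr), observedMSA(pr), cfg)
  expect_equal(length(res$trajectory), 1L)
  expect_gt(records(res$trajectory)$bias_l2[1], 0)
})

test_that("deterministic runs are bit-identical and stochastic runs reproduce by seed", {
  pr <- demo_problem()
  msa <- observedMSA(pr)
  cfg <- optConfig(maxIters = 5L, stochastic = FALSE, masterSeed = 9L)
  r1 <- optimizeBias(SurrogateBackend(pr), msa, cfg)
  r2 <- optimizeBias(SurrogateBackend(pr), msa, cfg)
  expect_identical(records(r1$trajectory), records(r2$trajectory))
  expect_identical(profileMatrix(r1$bias), profileMatrix(r2$bias))

  cfgS <- optConfig(maxIters = 5L, stochastic = TRUE, masterSeed = 9L, nRecycles = 2L)
  s1 <- optimizeBias(SurrogateBackend(pr), msa, cfgS)
  s2 <- optimizeBias(SurrogateBackend(pr), msa, cfgS)
  expect_identical(records(s1$trajectory), records(s2$trajectory))
})

test_that("trajectory records satisfy the confidence and loss identities", {
  pr <- demo_problem()
  cfg <- optConfig(maxIters = 20L, learningRate = 1e-3, masterSeed = 2L,
                   nRecycles = 3L)
  res <- optimizeBias(SurrogateBackend(pr), observedMSA(pr), cfg)
  r <- records(res$trajectory)
  expect_equal(nrow(r), 20L)
  expect_true(all(abs(r$confidence - (0.8 * r$iptm + 0.2 * r$ptm)) <= 1e-12))
  expect_true(all(abs(r$loss - 1 / r$confidence) <= 1e-9))
  expect_equal(r$iteration, 0:19)
})

test_that("deterministic descent is monotone for small learning rates", {
  for (s in c(1L, 2L)) {
    pr <- demo_problem(seed = s)
    cfg <- optConfig(learningRate = 1e-3, maxIters = 60L, stochastic = FALSE,
                     masterSeed = s, nRecycles = 0L)
    r <- records(optimizeBias(SurrogateBackend(pr), observedMSA(pr), cfg)$trajectory)
    expect_true(all(diff(r$loss) <= 1e-12))
  }
})

test_that("the selected best record dominates the starting confidence", {
  pr <- demo_problem()
  cfg <- optConfig(learningRate = 1e-2, maxIters = 40L, stochastic = FALSE,
                   masterSeed = 3L, nRecycles = 0L)
  traj <- optimizeBias(SurrogateBackend(pr), observedMSA(pr), cfg)$trajectory
  best <- selectBest(traj)
  r <- records(traj)
  expect_gte(best$confidence, r$confidence[1])
  expect_gt(r$confidence[nrow(r)], r$confidence[1])
})

test_that("selectBest picks the maximum confidence with earliest-iteration ties", {
  mk <- function(conf) {
    rec <- data.frame(iteration = seq_along(conf) - 1L, iptm = conf, ptm = conf,
                      confidence = conf, loss = 1 / conf,
                      bias_l2 = 0, accuracy_proxy = 0)
    new("Trajectory", records = rec, config = optConfig(maxIters = length(conf)),
        bestIndex = which.max(conf))
  }
  expect_equal(selectBest(mk(c(0.3, 0.9, 0.5)))$iteration, 1L)
  expect_equal(selectBest(mk(c(0.7, 0.7)))$iteration, 0L)
  empty <- new("Trajectory",
               records = data.frame(iteration = integer(), iptm = numeric(),
                                    ptm = numeric(), confidence = numeric(),
                                    loss = numeric(), bias_l2 = numeric(),
                                    accuracy_proxy = numeric()),
               config = optConfig(), bestIndex = 1L)
  expect_error(selectBest(empty), "empty")
})

test_that("backend failure aborts with the partial trajectory attached", {
  setClass("FailingBackend", contains = "FoldConfidenceBackend",
           representation(fail_at = "integer", inner = "SurrogateBackend"),
           where = environment())
  counter <- new.env(); counter$n <- 0L
  setMethod("backendForward", "FailingBackend",
            function(backend, features, nRecycles = 20L, seed = 0L, stochastic = TRUE) {
              counter$n <- counter$n + 1L
              if (counter$n > backend@fail_at) stop("synthetic backend failure")
              backendForward(backend@inner, features, nRecycles, seed, stochastic)
            }, where = environment())
  setMethod("backendGradient", "FailingBackend",
            function(backend, features, nRecycles = 20L, seed = 0L, stochastic = TRUE)
              backendGradient(backend@inner, features, nRecycles, seed, stochastic),
            where = environment())
  pr <- demo_problem()
  fb <- new("FailingBackend", fail_at = 3L, inner = SurrogateBackend(pr))
  cfg <- optConfig(maxIters = 10L, stochastic = FALSE, masterSeed = 1L)
  err <- tryCatch(optimizeBias(fb, observedMSA(pr), cfg), biasOptError = function(e) e)
  expect_s3_class(err, "biasOptError")
  expect_equal(err$iteration, 3L)
  expect_equal(nrow(err$trajectory), 3L)
})
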