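# Batch orchestration: run optimize -> select over many targets with
# per-target isolation, trajectory/bias serialization, the deterministic
# fixture generator, and the iteration-budget comparison.

#' Write / read a trajectory as TSV
#'
#' One row per iteration with columns iteration, iptm, ptm, confidence,
#' loss, bias_l2, accuracy_proxy, at 12 significant digits.
#'
#' @param trajectory a [Trajectory-class] (or its records data.frame).
#' @param path file path.
#' @return `writeTrajectoryTSV` returns `path` invisibly;
#'   `readTrajectoryTSV` returns the records data.frame.
#' @export
writeTrajectoryTSV <- function(trajectory, path) {
  r <- if (is.data.frame(trajectory)) trajectory else records(trajectory)
  lines <- c(paste(names(r), collapse = "\t"),
             vapply(seq_len(nrow(r)), function(i)
               paste(c(sprintf("%d", r$iteration[i]),
                       sprintf("%.12g", unlist(r[i, -1]))), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTrajectoryTSV
#' @export
readTrajectoryTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Run the optimization over a batch of targets
#'
#' Applies [optimizeBias()] per target and collects the batch accounting:
#' per-target completed iteration counts, best (maximum-confidence) record,
#' and an explicit failure list. One target failing — an unreadable MSA, a
#' backend error mid-run — never aborts the batch; the failure is recorded
#' and the remaining targets proceed.
#'
#' Targets are given as a named list. Each element is either a
#' [SurrogateProblem-class] (its observed MSA is optimized against its own
#' [SurrogateBackend()]) or a list with fields `msa` (an [MSA-class] or a
#' file path readable by [readMSA()]) and `backend` (a
#' [FoldConfidenceBackend-class]).
#'
#' @param targets named list of targets (see Details).
#' @param config an [OptConfig-class]; per-target master seeds are derived
#'   from `masterSeed` and the target index so runs are independent but
#'   reproducible.
#' @param outDir optional directory; when given, each target writes
#'   `trajectory.tsv`, `bias.tsv` and `meta.json` under `outDir/<id>/`.
#' @return A list with `perTarget` (data.frame: target_id, records,
#'   best_iteration, best_confidence, status), `failures` (character),
#'   `totalRecords`, and `runs` (per-target [optimizeBias()] results for
#'   completed targets).
#' @export
runBatch <- function(targets, config = optConfig(), outDir = NULL) {
  if (length(targets) == 0) .stopf("runBatch: no targets")
  ids <- names(targets)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("target%02d", seq_along(targets))
  rows <- vector("list", length(targets))
  runs <- list()
  failures <- character()
  for (i in seq_along(targets)) {
    id <- ids[i]
    cfg <- config
    cfg@masterSeed <- .derive_seed(config@masterSeed, i, 3L)
    res <- tryCatch({
      tgt <- targets[[i]]
      if (is(tgt, "SurrogateProblem")) {
        backend <- SurrogateBackend(tgt)
        msa <- observedMSA(tgt)
      } else {
        msa <- tgt$msa
        if (is.character(msa)) msa <- readMSA(msa)
        backend <- tgt$backend
        if (!is(backend, "FoldConfidenceBackend"))
          .stopf("target '%s' has no FoldConfidenceBackend", id)
      }
      optimizeBias(backend, msa, cfg, complexId = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      rows[[i]] <- data.frame(target_id = id, records = 0L,
                              best_iteration = NA_integer_,
                              best_confidence = NA_real_, status = "failed")
      next
    }
    best <- selectBest(res$trajectory)
    rows[[i]] <- data.frame(target_id = id, records = length(res$trajectory),
                            best_iteration = best$iteration,
                            best_confidence = best$confidence, status = "ok")
    runs[[id]] <- res
    if (!is.null(outDir)) {
      tdir <- file.path(outDir, id)
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      writeTrajectoryTSV(res$trajectory, file.path(tdir, "trajectory.tsv"))
      writeProfileTSV(res$bias, file.path(tdir, "bias.tsv"))
      jsonlite::write_json(
        list(target_id = id, master_seed = cfg@masterSeed,
             learning_rate = cfg@learningRate, max_iters = cfg@maxIters,
             n_recycles = cfg@nRecycles, stochastic = cfg@stochastic,
             n_clusters = cfg@nClusters,
             best_iteration = best$iteration,
             best_confidence = best$confidence),
        file.path(tdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  perTarget <- do.call(rbind, rows)
  list(perTarget = perTarget, failures = failures,
       totalRecords = sum(perTarget$records), runs = runs)
}

#' Iteration-budget ratio against a sampling baseline
#'
#' How many predictions a brute-force sampling protocol spends for each
#' gradient-descent iteration spent here: `nSamplesBaseline / nIters`. With
#' the published numbers (6000 samples for the sampling protocol vs the
#' default 100-iteration budget) the ratio is 60.
#'
#' @param nSamplesBaseline predictions drawn by the sampling baseline
#'   (default 6000).
#' @param nIters this method's iteration budget (default: the
#'   [optConfig()] default).
#' @return The ratio, a single number.
#' @export
speedupFactor <- function(nSamplesBaseline = 6000, nIters = optConfig()@maxIters) {
  if (nIters < 1) .stopf("speedupFactor: nIters must be >= 1")
  nSamplesBaseline / nIters
}

#' Generate the deterministic fixture suite
#'
#' Writes, under `out`: three surrogate problems (`surrogate_L10`,
#' `surrogate_L50`, `surrogate_L200`), a two-chain species-pairing fixture
#' (`pairing/chainA.a3m`, `pairing/chainB.a3m` with overlapping OX= taxa), a
#' clean/corrupted profile pair (`corruption/`), and a synthetic per-target
#' score table (`scores.tsv`). Everything is plain text, derived from
#' `seed`, and byte-identical across runs with the same seed.
#'
#' @param seed integer master seed.
#' @param out output directory (created if missing).
#' @return `out`, invisibly.
#' @export
makeFixtures <- function(seed = 0L, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (L in c(10L, 50L, 200L)) {
    pr <- makeSurrogateProblem(L = L, nRows = 200L, noiseSigma = 0.1,
                               seed = .derive_seed(seed, L, 4L))
    writeSurrogateProblem(pr, file.path(out, sprintf("surrogate_L%d", L)))
  }
  # two-chain pairing fixture: taxa 9606/10090 shared, one unshared each
  pdir <- file.path(out, "pairing")
  dir.create(pdir, showWarnings = FALSE)
  writeLines(c(">chainA_query", "ACDEFG",
               ">a1 OX=9606", "ACDEFG",
               ">a2 OX=9606", "ACDDFG",
               ">a3 OX=10090", "ACDEYG",
               ">a4 OX=7227", "ACNEFG"),
             file.path(pdir, "chainA.a3m"))
  writeLines(c(">chainB_query", "KLMN",
               ">b1 OX=9606", "KLMQ",
               ">b2 OX=10090", "KIMN",
               ">b3 OX=4932", "KLNN"),
             file.path(pdir, "chainB.a3m"))
  # clean vs corrupted profile pair
  cdir <- file.path(out, "corruption")
  dir.create(cdir, showWarnings = FALSE)
  pr <- makeSurrogateProblem(L = 25L, nRows = 100L, noiseSigma = 0.05,
                             seed = .derive_seed(seed, 1L, 5L))
  clean <- computeProfile(observedMSA(pr))
  writeProfileTSV(clean, file.path(cdir, "clean_profile.tsv"))
  writeProfileTSV(randomizeProfile(clean, seed = .derive_seed(seed, 2L, 5L)),
                  file.path(cdir, "random_profile.tsv"))
  # synthetic score table for the evaluation statistics
  n <- 60L
  tab <- .with_seed(.derive_seed(seed, 3L, 5L), {
    mm0 <- round(stats::runif(n, 0.2, 0.75), 4)
    dmm <- round(pmax(stats::rnorm(n, 0.1, 0.15), -0.1), 4)
    mm1 <- pmin(pmax(mm0 + dmm, 0), 1)
    iptm <- round(pmin(pmax(mm1 + stats::rnorm(n, 0, 0.12), 0), 1), 4)
    ptm <- round(pmin(pmax(iptm + stats::runif(n, 0, 0.1), 0), 1), 4)
    data.frame(target_id = sprintf("synthetic_t%03d", seq_len(n)),
               mmscore_initial = mm0, mmscore_final = round(mm1, 4),
               iptm = iptm, ptm = ptm,
               msa_depth = sample.int(5000L, n))
  })
  utils::write.table(tab, file.path(out, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}
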