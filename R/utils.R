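# Shared internal helpers: alphabet, seeding, simplex geometry.

.ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYVX-", "")[[1]]
.NCLASS <- length(.ALPHABET)

#' Residue alphabet used by all profiles
#'
#' Twenty amino acids in the AlphaFold ordering, followed by 'X' (unknown)
#' and '-' (gap). The position of a character in this vector is the canonical
#' column index of every profile and bias matrix in the package.
#'
#' @return Character vector of length 22.
#' @export
#' @examples
#' profileAlphabet()
profileAlphabet <- function() .ALPHABET

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps all package randomness local.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic per-iteration seed: Lehmer-style hash of (master, iteration)
# with a stream salt so e.g. cluster resampling and backend noise draw from
# decoupled streams. Stays below 2^31 - 1 (R integers are 32-bit) and all
# intermediates stay well below 2^53 so double arithmetic is exact.
.derive_seed <- function(master, iteration, stream = 0L) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m)
  h <- (h * 48271 + as.numeric(iteration) * 1009 + as.numeric(stream) * 7919) %% m
  as.integer(h)
}

# Euclidean projection of a vector onto the probability simplex.
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  w <- pmax(v - theta, 0)
  w / sum(w)
}

# Uniform draw from the (n-1)-simplex: normalized Exp(1) variates.
.runif_simplex <- function(n) {
  e <- stats::rexp(n)
  e / sum(e)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
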