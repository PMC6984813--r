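# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' `(spec, seed)` and never perturb the caller's RNG stream.
#'
#' @param seed integer scalar, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# seconds -> sample index (1-based, half-open window convention [start, end))
.t2i <- function(t, fs, n = Inf, t0 = 0) {
  i <- floor((t - t0) * fs + 1e-9) + 1L
  pmin(pmax(i, 1L), n)
}

# sample index -> time at sample (t = 0 at first sample)
.i2t <- function(i, fs, t0 = 0) (i - 1L) / fs + t0

# indices of a half-open time window [start, end) within a sweep of n samples
.window_idx <- function(start, end, fs, n, t0 = 0) {
  i0 <- floor((start - t0) * fs + 1e-9) + 1L
  i1 <- ceiling((end - t0) * fs - 1e-9)
  if (i1 < i0 || i1 < 1L || i0 > n) return(integer(0))
  seq.int(max(i0, 1L), min(i1, n))
}

# raw (unscaled) median absolute deviation
.raw_mad <- function(x, scale = 1) scale * stats::median(abs(x - stats::median(x)))

# linear interpolation of the time at which y crosses `level` between
# samples i and i+1 (assumes y[i], y[i+1] bracket level)
.cross_time <- function(t, y, i, level) {
  if (y[i + 1L] == y[i]) return(t[i])
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
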