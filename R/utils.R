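# Internal helpers shared across modules.

#' Derive a deterministic substream seed
#'
#' All stochastic stages draw their seed from a single root seed plus a stage
#' label, so that an identical configuration reproduces every stage
#' bit-for-bit while stages remain statistically independent.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return an integer in [0, 2^31 - 1].
#' @keywords internal
substream_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded from (seed, stage);
# restores the caller's RNG afterwards.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  expr
}

#' Mean-zero bounded residual draws
#'
#' Draws from a scaled beta distribution with exact mean zero, variance
#' \code{v} (shrunk if the support cannot carry it) and support
#' \code{[lo, hi]} with \code{lo < 0 < hi}. Used by the synthetic-data
#' generator so that residuals on the percentage scale never push responses
#' outside [0, 100]; hard clamping would attenuate planted coefficients,
#' whereas a bounded mean-zero draw leaves conditional means untouched.
#'
#' @param n number of draws.
#' @param v target variance.
#' @param lo,hi support bounds (vectors recycled against n).
#' @return numeric vector of length n.
#' @keywords internal
rbeta_bounded <- function(n, v, lo, hi) {
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  if (any(lo >= 0) || any(hi <= 0)) {
    stop("bounded residual support must contain zero (lo < 0 < hi)")
  }
  v <- pmin(v, 0.9 * (-lo) * hi)  # shrink variance where support is narrow
  t <- -lo / (hi - lo)
  s <- (hi - lo)^2 * t * (1 - t) / v - 1
  lo + (hi - lo) * stats::rbeta(n, s * t, s * (1 - t))
}

# Separable gaussian smoothing of a matrix with reflecting edges. Length
# scale in cells; returns a matrix of the same shape. Used for spatially
# correlated isoscape noise and mask blobs.
smooth_matrix <- function(m, scale) {
  if (scale <= 0) return(m)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  pad_reflect <- function(x, h) c(rev(x[seq_len(h)]), x, rev(x)[seq_len(h)])
  conv1 <- function(x) {
    xp <- pad_reflect(x, half)
    stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

# Stop unless all named columns exist.
check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
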