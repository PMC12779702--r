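#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic derived seed for stage k of a run seeded with `seed`.
# Kept strictly below 2^31 so it is always a valid R integer.
child_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 1103 + 7919 * as.numeric(k)) %% 2147483587) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero; base round() uses banker's rounding which would
# make BARC values depend on floating parity.
round_half_up <- function(x) floor(x + 0.5)

# One 3x3 box-blur pass with replicate padding.
box_blur <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
    p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
    p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
}

# Smooth random field scaled to [0, 1]; spatial correlation length grows with
# the number of blur passes.
smooth_field <- function(nr, nc, passes = 8) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) f <- box_blur(f)
  rng <- range(f)
  (f - rng[1]) / max(rng[2] - rng[1], 1e-12)
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Standard Gumbel(0, 1) draws; argmax of eta + Gumbel is a softmax sample.
rgumbel <- function(n) -log(-log(runif(n)))
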