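#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom median mad sd cor lm coef predict
#'   quantile spline splinefun runmed complete.cases setNames
#' @importFrom utils write.csv read.csv modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline are seeded from one master seed via
#' this deterministic scheme, so a whole study run is reproducible from a
#' single integer.  The returned value is always a valid 32-bit seed.
#'
#' @param seed master seed (single number).
#' @param k child index (single non-negative number).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k), length(k) == 1L)
  s <- abs(as.numeric(seed)) %% 1000003
  as.integer((s * 1021 + as.numeric(k) * 2017 + 12347) %% 2147483629)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state;
# seed = NULL leaves the current state in charge
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# rolling maximum of |x| over a centred window of half-width w samples
running_max <- function(x, w) {
  ax <- abs(x)
  out <- ax
  n <- length(ax)
  if (n == 0L || w < 1L) return(out)
  for (s in seq_len(min(w, n - 1L))) {
    out <- pmax(out,
                c(ax[-seq_len(s)], rep(0, s)),
                c(rep(0, s), ax[seq_len(n - s)]))
  }
  out
}

# scalar argument checks with readable errors ------------------------------

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("configuration error: '%s' must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lo = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x != floor(x)) {
    stop(sprintf("configuration error: '%s' must be an integer >= %s", name, lo),
         call. = FALSE)
  }
  invisible(x)
}

# fast slope/intercept of y ~ x (least squares), avoids lm() overhead in
# per-pulse inner loops
ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / vx
  c(intercept = my - b * mx, slope = b)
}
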