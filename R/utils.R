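#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Derive a sequence of child seeds from one master seed without disturbing
## the caller's RNG stream more than once.  Children stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is_count(n) || n == 0)
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

## moving-average smoother (centered, reflecting edges), used for optional
## smoothing of power time courses
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  w <- min(width, n)
  pad <- c(rev(x[seq_len(w)]), x, rev(x[n + 1 - seq_len(w)]))
  cs <- cumsum(pad)
  half <- w %/% 2
  idx <- (w + seq_len(n))
  (cs[idx + (w - half - 1)] - cs[idx - half - 1]) / w
}
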