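# Small internal helpers shared across modules.

# Shift a matrix by (di, dj), filling vacated entries with `fill`.
# shiftm(M, 1, 0)[i, j] == M[i - 1, j] (values move in +i direction).
shiftm <- function(M, di, dj, fill = 0) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(fill, n, m)
  si <- max(1L, 1L + di):min(n, n + di)
  sj <- max(1L, 1L + dj):min(m, m + dj)
  out[si, sj] <- M[si - di, sj - dj, drop = FALSE]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stopf("'%s' must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}
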