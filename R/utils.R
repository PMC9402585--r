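`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All seeded entry points go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_fmt("'%s' must be numeric without NA", name)
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad)) {
    stop_fmt("'%s' must lie in %s%g, %g%s (offending value: %g)",
             name, if (lo_open) "(" else "[", lo, hi,
             if (hi_open) ")" else "]", x[which(bad)[1L]])
  }
  invisible(x)
}

## Row variances of a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

## Vectorized two-sample Welch t-test p-values across rows of `x`;
## `grp` is a logical vector over columns. Matches stats::t.test.
row_welch_p <- function(x, grp) {
  x1 <- x[, grp, drop = FALSE]
  x2 <- x[, !grp, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop_fmt("Welch t-test needs >= 2 samples per group")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(tt)] <- NA_real_   # zero variance in both groups
  p
}
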