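`%||%` <- function(x, y) if (is.null(x)) y else x

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside the admissible range", name, x),
         call. = FALSE)
  invisible(x)
}

# Resolve a seed-vector-like argument to a plain numeric vector aligned to
# `nodes` (when given). Accepts seed_vector objects and named/plain numerics.
.as_x0 <- function(x0, nodes = NULL) {
  if (inherits(x0, "seed_vector")) x0 <- x0$x0
  if (!is.numeric(x0)) stop("`x0` must be numeric or a seed_vector", call. = FALSE)
  if (!is.null(nodes)) {
    if (!is.null(names(x0))) {
      out <- stats::setNames(numeric(length(nodes)), nodes)
      common <- intersect(names(x0), nodes)
      out[common] <- x0[common]
      x0 <- out
    } else if (length(x0) != length(nodes)) {
      stop("unnamed `x0` must have one entry per network node", call. = FALSE)
    } else {
      names(x0) <- nodes
    }
  }
  if (any(x0 < 0)) stop("seed scores must be nonnegative", call. = FALSE)
  x0
}
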