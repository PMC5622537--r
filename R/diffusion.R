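#' Network diffusion of seed scores
#'
#' Propagates a nonnegative seed vector `X0` over the symmetrically
#' normalized network `W` with the recurrence
#' \deqn{X_{t+1} = \alpha W X_t + (1 - \alpha) X_0,}
#' whose limit `X*` blends the initial scores with network topology. The
#' retention parameter `alpha` in (0, 1) controls how far the initial
#' information spreads: small values keep `X*` close to `X0`, values near
#' 1 weight the network structure. Because the spectral radius of `W` is
#' at most 1, the iteration contracts and the limit solves the linear
#' system `(I - alpha W) X* = (1 - alpha) X0`.
#'
#' `diffuse_iterative()` runs the recurrence from `X0` until the max-norm
#' of successive updates falls below `tol`; `diffuse_closed_form()` solves
#' the linear system directly (sparse Cholesky) and serves both as the
#' fast path for permutation nulls and as an independent oracle for the
#' iterative solver.
#'
#' @param W normalized adjacency matrix (from a [gene_network()]), or a
#'   `gene_network` itself.
#' @param x0 seed scores: a [build_seed_vector()] result, a named numeric
#'   vector, or a plain numeric vector aligned to the node order.
#' @param alpha retention parameter in (0, 1); default 0.7.
#' @param tol convergence tolerance on `max |X_{t+1} - X_t|`.
#' @param max_iter iteration cap; exceeding it raises an error that
#'   carries the last residual (condition class
#'   `ndprio_no_convergence`).
#' @return an object of class `diffusion_result`: list with `x_star`
#'   (named numeric), `alpha`, `iterations`, `residual`, `method`.
#' @seealso [nsi_score()] for the full smoothing-index pipeline.
#' @export
diffuse_iterative <- function(W, x0, alpha = 0.7, tol = 1e-6,
                              max_iter = 10000L) {
  W <- .as_W(W)
  x0 <- .as_x0(x0, rownames(W))
  .assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  .assert_scalar_number(tol, "tol", 0, Inf, strict_lower = TRUE)

  x <- x0
  b <- (1 - alpha) * x0
  resid <- Inf
  for (t in seq_len(max_iter)) {
    x_new <- as.numeric(alpha * (W %*% x)) + b
    resid <- max(abs(x_new - x))
    x <- x_new
    if (resid < tol) {
      names(x) <- names(x0)
      return(.diffusion_result(x, alpha, t, resid, "iterative"))
    }
  }
  cond <- structure(
    class = c("ndprio_no_convergence", "error", "condition"),
    list(message = sprintf(
      "diffusion did not converge in %d iterations (residual %.3g, tol %.3g)",
      max_iter, resid, tol),
      call = sys.call(-1), residual = resid))
  stop(cond)
}

#' @rdname diffuse_iterative
#' @export
diffuse_closed_form <- function(W, x0, alpha = 0.7) {
  W <- .as_W(W)
  x0 <- .as_x0(x0, rownames(W))
  .assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  op <- .diffusion_operator(W, alpha)
  x <- as.numeric(op(x0))
  names(x) <- names(x0)
  .diffusion_result(x, alpha, NA_integer_, 0, "closed_form")
}

# Factorize (I - alpha W) once; returns a solver usable with vector or
# matrix right-hand sides. I - alpha*W is symmetric positive definite for
# alpha < 1 (spectral radius of W <= 1), so sparse Cholesky applies.
.diffusion_operator <- function(W, alpha) {
  n <- nrow(W)
  M <- Matrix::Diagonal(n) - alpha * W
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE),
    error = function(e)
      stop("diffusion system could not be factorized; is W symmetrically normalized?",
           call. = FALSE))
  function(b) (1 - alpha) * Matrix::solve(ch, b, system = "A")
}

.as_W <- function(W) {
  if (inherits(W, "gene_network")) W <- W$W
  if (is.null(rownames(W))) rownames(W) <- colnames(W) <- as.character(seq_len(nrow(W)))
  methods::as(W, "CsparseMatrix")
}

.diffusion_result <- function(x_star, alpha, iterations, residual, method) {
  structure(list(x_star = x_star, alpha = alpha, iterations = iterations,
                 residual = residual, method = method),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("diffusion_result (%s): %d genes, alpha = %g",
              x$method, length(x$x_star), x$alpha))
  if (x$method == "iterative")
    cat(sprintf(", %d iterations, residual %.3g", x$iterations, x$residual))
  cat("\n")
  invisible(x)
}
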