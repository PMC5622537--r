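#' Network smoothing index
#'
#' The smoothing index of gene `g` is the ratio of its score after and
#' before diffusion,
#' \deqn{S(g) = \frac{X^*(g)}{X_0(g) + \varepsilon},}
#' where `epsilon > 0` weights the importance of the initial scores: large
#' values favour the seed genes themselves, small values favour non-seed
#' genes that received diffused mass (network proximity to the seeds).
#'
#' @param x_star post-diffusion scores.
#' @param x0 pre-diffusion (seed) scores.
#' @param epsilon positive regularizer.
#' @return numeric vector `S`, same length and names as `x_star`.
#' @export
smoothing_index <- function(x_star, x0, epsilon) {
  .assert_scalar_number(epsilon, "epsilon", 0, Inf, strict_lower = TRUE)
  if (length(x_star) != length(x0))
    stop("x_star and x0 must have equal length", call. = FALSE)
  as.numeric(x_star) / (as.numeric(x0) + epsilon)
}

#' Permutation-adjusted smoothing index
#'
#' `Sp(g) = -log10(pS(g)) * S(g)`. Genes that reach a high `S` merely
#' because they are hubs tend to score high under random seed placements
#' as well, so their empirical p-value is large and `Sp` shrinks towards
#' zero; `Sp = 0` exactly when `pS = 1`.
#'
#' @param S smoothing-index vector.
#' @param pS empirical p-values in (0, 1].
#' @return numeric vector `Sp`.
#' @export
adjusted_index <- function(S, pS) {
  if (any(pS <= 0 | pS > 1))
    stop("pS must lie in (0, 1]", call. = FALSE)
  -log10(pS) * as.numeric(S)
}

# K column-permutations of x0 (values reassigned uniformly over all node
# labels), drawn under the current RNG state.
.perm_matrix <- function(x0, K) {
  vapply(seq_len(K), function(k) sample(x0), numeric(length(x0)))
}

# Exceedance counts and pS for observed S against null S^k.
# Xn: n x K matrix of null x_star columns; X0perm: matching permuted seeds.
# Ties count as exceedances; the comparison carries a small relative
# tolerance so that mathematically exact ties (e.g. on symmetric graphs)
# are not split arbitrarily by rounding in the linear solves.
.empirical_ps <- function(S, Xn, X0perm, epsilon, K) {
  Sk <- Xn / (X0perm + epsilon)
  thr <- S - (1e-9 * abs(S) + 1e-12)
  exceed <- rowSums(Sk >= thr)
  list(exceed = exceed, pS = (1 + exceed) / (K + 1))
}

#' Empirical p-values from seed-label permutations
#'
#' Re-diffuses `K` random reassignments of the multiset of seed values
#' over all node labels, computes the null smoothing index `S^k` for each,
#' and returns `pS(g) = (1 + #\{S^k(g) >= S(g)\}) / (K + 1)`. Ties count
#' as exceedances; the pseudocount bounds `pS` in `[1/(K+1), 1]`.
#'
#' All `K` null diffusions are solved in one factorized linear solve, so
#' the cost is one sparse Cholesky factorization plus `K` triangular
#' solves.
#'
#' @inheritParams diffuse_iterative
#' @param K number of permutations (default 999).
#' @param rng_seed integer seed controlling the permutations.
#' @param epsilon smoothing-index regularizer.
#' @return list with `S`, `exceed` (per-gene null exceedance counts),
#'   `pS`, `x_star`, and the parameters used.
#' @export
permutation_null <- function(W, x0, K = 999L, rng_seed = 1L, epsilon,
                             alpha = 0.7) {
  W <- .as_W(W)
  x0 <- .as_x0(x0, rownames(W))
  stopifnot(K >= 1)
  .assert_scalar_number(epsilon, "epsilon", 0, Inf, strict_lower = TRUE)
  op <- .diffusion_operator(W, alpha)
  x_star <- as.numeric(op(x0))
  set.seed(rng_seed)
  X0perm <- .perm_matrix(x0, K)
  Xn <- as.matrix(op(X0perm))
  S <- smoothing_index(x_star, x0, epsilon)
  ps <- .empirical_ps(S, Xn, X0perm, epsilon, K)
  list(S = S, exceed = ps$exceed, pS = ps$pS, x_star = x_star,
       K = K, epsilon = epsilon, alpha = alpha, rng_seed = rng_seed)
}

#' Score all genes with the permutation-adjusted smoothing index
#'
#' End-to-end scoring stage: diffuses the seed vector, computes `S`,
#' the permutation p-values `pS` (seed labels reassigned over all nodes,
#' `K` permutations), and `Sp = -log10(pS) * S`; ranks all genes by
#' decreasing `Sp` (ties broken by decreasing `S`, then lexicographic gene
#' ID). With `epsilon = "auto"` the regularizer is calibrated so that the
#' top `2n` ranks hold input and non-input genes in a 1:1 ratio (see
#' [calibrate_epsilon()]); the permutation null is shared across
#' calibration candidates since the null diffusions do not depend on
#' `epsilon`.
#'
#' @param net a `gene_network`.
#' @param seeds a `seed_vector` (or gene ID vector, taken as one
#'   weight-1 list).
#' @param alpha diffusion retention parameter (default 0.7).
#' @param epsilon positive value, or `"auto"` for 1:1 calibration.
#' @param K permutation count (default 999).
#' @param rng_seed integer seed for the permutations.
#' @param target_window ranking window used by the calibration; default
#'   `2 * n_seeds`.
#' @return object of class `smoothing_result`: list with `table`
#'   (data.frame: gene, x0, x_star, S, pS, Sp, exceed, rank, is_input,
#'   source_lists; ordered by rank), `epsilon`, `K`, `alpha`, `rng_seed`,
#'   `n_input`.
#' @export
nsi_score <- function(net, seeds, alpha = 0.7, epsilon = "auto", K = 999L,
                      rng_seed = 1L, target_window = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (!inherits(seeds, "seed_vector"))
    seeds <- build_seed_vector(seeds, net = net)
  x0 <- seeds$x0
  op <- .diffusion_operator(net$W, alpha)
  x_star <- as.numeric(op(x0))
  set.seed(rng_seed)
  X0perm <- .perm_matrix(x0, K)
  Xn <- as.matrix(op(X0perm))

  is_input <- x0 > 0
  if (identical(epsilon, "auto")) {
    epsilon <- .calibrate_core(net$nodes, x0, x_star, Xn, X0perm, K,
                               is_input, target_window)
  }
  .assert_scalar_number(epsilon, "epsilon", 0, Inf, strict_lower = TRUE)

  S <- smoothing_index(x_star, x0, epsilon)
  ps <- .empirical_ps(S, Xn, X0perm, epsilon, K)
  Sp <- adjusted_index(S, ps$pS)

  src <- vapply(net$nodes, function(g) {
    m <- seeds$membership[[g]]
    if (is.null(m)) "" else paste(sort(m), collapse = ",")
  }, character(1))

  tab <- data.frame(gene = net$nodes, x0 = unname(x0), x_star = x_star,
                    S = S, pS = ps$pS, Sp = Sp, exceed = ps$exceed,
                    is_input = unname(is_input), source_lists = unname(src),
                    stringsAsFactors = FALSE)
  o <- order(-tab$Sp, -tab$S, tab$gene)
  tab <- tab[o, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("gene", "x0", "x_star", "S", "pS", "Sp", "exceed", "rank",
                 "is_input", "source_lists")]

  structure(list(table = tab, epsilon = epsilon, K = K, alpha = alpha,
                 rng_seed = rng_seed, n_input = sum(is_input)),
            class = "smoothing_result")
}

# Count input genes among the top `window` ranks at a candidate epsilon.
.inputs_in_top <- function(nodes, x0, x_star, Xn, X0perm, K, is_input,
                           epsilon, window) {
  S <- x_star / (x0 + epsilon)
  pS <- .empirical_ps(S, Xn, X0perm, epsilon, K)$pS
  Sp <- -log10(pS) * S
  o <- order(-Sp, -S, nodes)
  sum(is_input[o[seq_len(window)]])
}

.calibrate_core <- function(nodes, x0, x_star, Xn, X0perm, K, is_input,
                            target_window = NULL,
                            eps_range = c(1e-4, 100), max_steps = 60L) {
  n_in <- sum(is_input)
  window <- as.integer(target_window %||% (2L * n_in))
  if (window > length(nodes))
    stop("target window exceeds network size", call. = FALSE)
  target <- window / 2
  if (n_in < target - 1)
    stop("fewer input genes than the calibration target: balance unattainable",
         call. = FALSE)

  cnt <- function(e) .inputs_in_top(nodes, x0, x_star, Xn, X0perm, K,
                                    is_input, e, window)
  lo <- log10(eps_range[1]); hi <- log10(eps_range[2])
  c_lo <- cnt(10^lo); c_hi <- cnt(10^hi)
  if (abs(c_lo - target) <= 1) return(10^lo)
  if (abs(c_hi - target) <= 1) return(10^hi)
  if (c_lo > target || c_hi < target)
    stop(sprintf(paste0("1:1 calibration unattainable: %d input genes in the ",
                        "top %d at epsilon = %.2g and %d at epsilon = %.2g ",
                        "(target %g)"),
                 c_lo, window, 10^lo, c_hi, window, 10^hi, target),
         call. = FALSE)
  # input count in the top window increases with epsilon: bisect
  for (i in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    c_mid <- cnt(10^mid)
    if (abs(c_mid - target) <= 1) return(10^mid)
    if (c_mid < target) lo <- mid else hi <- mid
  }
  stop(sprintf(paste0("epsilon calibration did not reach a 1:1 balance: ",
                      "closest counts %d / %d input genes in the top %d ",
                      "(target %g)"),
               cnt(10^lo), cnt(10^hi), window, target), call. = FALSE)
}

#' Calibrate the smoothing-index regularizer
#'
#' Searches (bisection on a log grid) for the `epsilon` at which the top
#' `target_window` genes ranked by `Sp` contain input and non-input genes
#' in a 1:1 ratio (within one gene). Larger `epsilon` promotes input genes
#' in the ranking — for a seed gene `S = x*/(1 + epsilon)` while for a
#' non-seed gene `S = x*/epsilon` — so the input count in the window is
#' monotone in `epsilon` and bisection is valid. The same permutation null
#' is reused for every candidate, because the null diffusions do not
#' depend on `epsilon`.
#'
#' @inheritParams nsi_score
#' @param eps_range search interval (default `[1e-4, 100]`).
#' @return the calibrated `epsilon`.
#' @export
calibrate_epsilon <- function(net, seeds, alpha = 0.7, K = 999L,
                              rng_seed = 1L, target_window = NULL,
                              eps_range = c(1e-4, 100)) {
  stopifnot(inherits(net, "gene_network"))
  if (!inherits(seeds, "seed_vector"))
    seeds <- build_seed_vector(seeds, net = net)
  x0 <- seeds$x0
  op <- .diffusion_operator(net$W, alpha)
  x_star <- as.numeric(op(x0))
  set.seed(rng_seed)
  X0perm <- .perm_matrix(x0, K)
  Xn <- as.matrix(op(X0perm))
  .calibrate_core(net$nodes, x0, x_star, Xn, X0perm, K, x0 > 0,
                  target_window, eps_range)
}

#' Ranked gene table of a smoothing result
#'
#' @param result a `smoothing_result`.
#' @return the ranked data.frame (descending `Sp`; ties by descending
#'   `S`, then gene ID).
#' @export
rank_genes <- function(result) {
  stopifnot(inherits(result, "smoothing_result"))
  result$table
}

#' Select the top multiplier-times-n genes
#'
#' Returns the first `multiplier * n` ranked genes, where `n` is the
#' number of input genes, labelled input vs predicted — the "n*" list of
#' a single-list analysis (default multiplier 2).
#'
#' @param result a `smoothing_result`.
#' @param multiplier integer rank multiplier (default 2).
#' @return data.frame subset of the ranked table.
#' @export
select_top <- function(result, multiplier = 2L) {
  stopifnot(inherits(result, "smoothing_result"))
  m <- multiplier * result$n_input
  if (m > nrow(result$table)) {
    warning(sprintf("requested top %d genes but the network has only %d; truncating",
                    m, nrow(result$table)), call. = FALSE)
    m <- nrow(result$table)
  }
  utils::head(result$table, m)
}

#' Write a smoothing result to TSV
#' @param result a `smoothing_result`.
#' @param path output file.
#' @export
write_scores <- function(result, path) {
  stopifnot(inherits(result, "smoothing_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.smoothing_result <- function(x, ...) {
  cat(sprintf(paste0("smoothing_result: %d genes, %d input; alpha = %g, ",
                     "epsilon = %.4g, K = %d, seed = %d\n"),
              nrow(x$table), x$n_input, x$alpha, x$epsilon, x$K, x$rng_seed))
  cat(sprintf("  genes with pS <= 0.05: %d\n", sum(x$table$pS <= 0.05)))
  print(utils::head(x$table[, c("gene", "S", "pS", "Sp", "rank", "is_input")], 5))
  invisible(x)
}
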