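#' Build a weighted seed vector from one or more gene lists
#'
#' Encodes one or several (already network-restricted) disease-gene lists
#' as the initial diffusion vector `X0`. Each list carries a weight in
#' (0, 1]; a gene occurring in several lists takes the maximum weight over
#' the lists containing it, so that genes from high-confidence sources
#' keep their full priority. The typical joint setting weights the
#' strongest-evidence list 1 and all others 0.5.
#'
#' @param lists named list of character vectors (gene IDs). A single
#'   unnamed character vector is treated as one list named `"list1"`.
#' @param weights named numeric vector of per-list weights in (0, 1];
#'   default 1 for every list.
#' @param net the `gene_network` providing the node index.
#' @param restrict drop genes absent from the network (default TRUE, with
#'   a message); with FALSE, absent genes raise an error.
#' @return an object of class `seed_vector`: list with `x0` (named
#'   numeric over all network nodes), `support` (genes with `x0 > 0`),
#'   `membership` (gene -> source list names), `weights`, `lists`.
#' @export
build_seed_vector <- function(lists, weights = NULL, net, restrict = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  if (is.character(lists)) lists <- list(list1 = lists)
  if (is.null(names(lists)) || any(names(lists) == ""))
    names(lists) <- paste0("list", seq_along(lists))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(lists)), names(lists))
  if (is.null(names(weights))) names(weights) <- names(lists)
  if (!all(names(lists) %in% names(weights)))
    stop("every list needs a weight", call. = FALSE)
  w <- weights[names(lists)]
  if (any(w <= 0 | w > 1))
    stop("list weights must lie in (0, 1]", call. = FALSE)

  lists <- lapply(lists, function(g) unique(as.character(g)))
  in_net <- lapply(lists, function(g) g[g %in% net$nodes])
  n_dropped <- sum(lengths(lists)) - sum(lengths(in_net))
  if (n_dropped > 0) {
    if (!restrict)
      stop(sprintf("%d seed gene(s) absent from the network", n_dropped),
           call. = FALSE)
    message(sprintf("dropped %d seed gene(s) absent from the network", n_dropped))
  }
  lists <- in_net

  support <- unique(unlist(lists, use.names = FALSE))
  if (length(support) == 0L)
    stop("empty seed set: no input gene occurs in the network", call. = FALSE)

  x0 <- stats::setNames(numeric(net$n), net$nodes)
  membership <- stats::setNames(vector("list", length(support)), support)
  for (nm in names(lists)) {
    g <- lists[[nm]]
    x0[g] <- pmax(x0[g], w[[nm]])
    for (gi in g) membership[[gi]] <- c(membership[[gi]], nm)
  }

  structure(list(x0 = x0, support = support, membership = membership,
                 weights = w, lists = lists),
            class = "seed_vector")
}

#' @export
print.seed_vector <- function(x, ...) {
  cat(sprintf("seed_vector: %d seed genes over %d nodes, %d source list(s)\n",
              length(x$support), length(x$x0), length(x$lists)))
  tw <- table(x$x0[x$support])
  cat("  weights:", paste(sprintf("%s x %d", names(tw), as.integer(tw)),
                          collapse = ", "), "\n")
  invisible(x)
}
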