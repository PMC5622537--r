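#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing at least `k` annotated genes when
#' drawing `n_q` genes from a background of `N_b` genes of which `K_p`
#' are annotated: `P(X >= k)` computed by direct summation of the
#' hypergeometric mass (no normal approximation).
#'
#' @param k observed overlap.
#' @param K_p number of annotated genes in the background.
#' @param n_q number of drawn (query) genes.
#' @param N_b background size.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(k, K_p, n_q, N_b) {
  if (any(c(k, K_p, n_q, N_b) < 0) || K_p > N_b || n_q > N_b ||
      k > min(K_p, n_q))
    stop("infeasible hypergeometric configuration", call. = FALSE)
  if (k == 0) return(1)
  sum(stats::dhyper(k:min(K_p, n_q), K_p, N_b - K_p, n_q))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1, input order
#' preserved). Thin wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Overlap coefficient between two gene sets
#'
#' `o = |A intersect B| / min(|A|, |B|)`, in \[0, 1\].
#'
#' @param set_a,set_b nonempty gene sets (character vectors).
#' @return the coefficient.
#' @export
overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("overlap coefficient is undefined for empty sets", call. = FALSE)
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Read pathway gene sets in GMT format
#'
#' @param path GMT file (name, description, genes...; tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write pathway gene sets in GMT format
#'
#' @param pathways named list of gene sets.
#' @param path output file.
#' @param descriptions optional per-pathway description column (defaults
#'   to the pathway name).
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(pathways)
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter pathways by gene-set size
#'
#' @param pathways named list of gene sets.
#' @param min_size,max_size inclusive size range (default 10–200).
#' @param background optional background; when given, sizes are counted
#'   after intersecting each set with the background.
#' @return filtered pathway list.
#' @export
filter_pathways <- function(pathways, min_size = 10L, max_size = 200L,
                            background = NULL) {
  if (!is.null(background))
    pathways <- lapply(pathways, intersect, y = background)
  sizes <- lengths(pathways)
  pathways[sizes >= min_size & sizes <= max_size]
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation in the query list against
#' a background gene universe, with Benjamini-Hochberg correction across
#' the tested pathways. Pathways are first intersected with the
#' background and filtered to the size range; query genes outside the
#' background are ignored.
#'
#' @param query character vector of query genes.
#' @param pathways named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector defining the gene universe (e.g.
#'   all network genes, or the union of the original input lists).
#' @param min_size,max_size pathway size range after background
#'   intersection (default 10–200).
#' @param background_label free-text label recorded in the result.
#' @return object of class `ora_result`: data.frame with columns
#'   pathway, size, overlap, expected, p, p_adj (sorted by p), plus
#'   attributes `background_label`, `n_query`, `n_background`.
#' @export
ora <- function(query, pathways, background, min_size = 10L,
                max_size = 200L, background_label = "background") {
  background <- unique(as.character(background))
  query <- intersect(unique(as.character(query)), background)
  if (length(query) == 0L)
    stop("no query gene occurs in the background", call. = FALSE)
  pathways <- filter_pathways(pathways, min_size, max_size, background)
  if (length(pathways) == 0L)
    stop("no pathway within the size range after background intersection",
         call. = FALSE)
  N_b <- length(background); n_q <- length(query)
  K_p <- lengths(pathways)
  k <- vapply(pathways, function(p) length(intersect(p, query)), integer(1))
  p <- mapply(hypergeom_tail, k, K_p, MoreArgs = list(n_q = n_q, N_b = N_b))
  res <- data.frame(pathway = names(pathways), size = unname(K_p),
                    overlap = unname(k),
                    expected = unname(K_p) * n_q / N_b,
                    p = unname(p), p_adj = unname(bh_adjust(p)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$pathway), ]
  rownames(res) <- NULL
  attr(res, "background_label") <- background_label
  attr(res, "n_query") <- n_q
  attr(res, "n_background") <- N_b
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Module-annotation overlap test
#'
#' Tests whether a gene module overlaps an annotation set (e.g. a
#' weaker-evidence disease gene class) more than expected by chance in a
#' given background. The expected overlap is
#' `E = |module| * |annotation| / |background|` and the p-value is the
#' upper hypergeometric tail of the observed overlap. Annotation genes
#' absent from the background are dropped with a warning; module genes
#' outside the background are likewise ignored.
#'
#' @param module_genes character vector (the module).
#' @param annotation character vector (the annotation set).
#' @param background character vector (gene universe).
#' @return object of class `overlap_test`: list with `observed`,
#'   `expected`, `p`, `module_size`, `complement_size`,
#'   `annotation_size`, `background_size`.
#' @export
module_overlap_test <- function(module_genes, annotation, background) {
  background <- unique(as.character(background))
  module_genes <- intersect(unique(as.character(module_genes)), background)
  ann0 <- unique(as.character(annotation))
  annotation <- intersect(ann0, background)
  if (length(annotation) == 0L)
    stop("annotation set is disjoint from the background", call. = FALSE)
  if (length(annotation) < length(ann0))
    warning(sprintf("%d annotation gene(s) absent from the background dropped",
                    length(ann0) - length(annotation)), call. = FALSE)
  obs <- length(intersect(module_genes, annotation))
  M <- length(module_genes); A <- length(annotation); N <- length(background)
  structure(list(observed = obs, expected = M * A / N,
                 p = hypergeom_tail(obs, A, M, N),
                 module_size = M, complement_size = N - M,
                 annotation_size = A, background_size = N),
            class = "overlap_test")
}

#' Interaction-excess test for a single gene
#'
#' Tests whether a gene's direct interactors contain more risk genes than
#' expected: draws = the gene's interactor count, successes = risk genes
#' in the background, observed = risk genes among the interactors, upper
#' hypergeometric tail. An isolated gene returns p = 1 with overlap 0.
#'
#' @param gene gene ID (must occur in the network).
#' @param net a `gene_network`.
#' @param risk_genes character vector of risk genes.
#' @param background_size gene universe size (default: network size).
#' @return an `overlap_test` (module slot = the interactor set).
#' @export
interaction_excess_test <- function(gene, net, risk_genes,
                                    background_size = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (!gene %in% net$nodes) stop("gene not in network", call. = FALSE)
  N <- as.integer(background_size %||% net$n)
  e <- net$edges
  nb <- unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene]))
  risk <- setdiff(unique(intersect(risk_genes, net$nodes)), gene)
  obs <- length(intersect(nb, risk))
  I <- length(nb)
  p <- if (I == 0L) 1 else hypergeom_tail(obs, length(risk), I, N)
  structure(list(observed = obs, expected = I * length(risk) / N, p = p,
                 module_size = I, complement_size = N - I,
                 annotation_size = length(risk), background_size = N),
            class = "overlap_test")
}

#' Build an enrichment map from significant pathways
#'
#' Nodes are the pathways significant at `padj_threshold`, weighted by
#' `-log10(p_adj)`; candidate edges link pathway pairs whose overlap
#' coefficient exceeds `o_threshold`, and each pathway keeps only the
#' edges to its `top_k` most similar pathways (ties broken by pathway
#' name). The retained edge set is the union over pathways, so it is
#' invariant to the input ordering.
#'
#' @param results an `ora_result`.
#' @param pathways the gene-set list the ORA was run on.
#' @param padj_threshold significance cut on adjusted p (default 0.01).
#' @param o_threshold minimum overlap coefficient for an edge
#'   (default 0.5, strict).
#' @param top_k maximum edges kept per pathway (default 5).
#' @return object of class `enrichment_map`: list with `nodes`
#'   (data.frame: pathway, neg_log10_padj) and `edges` (data.frame:
#'   pathway_a, pathway_b, o).
#' @export
build_enrichment_map <- function(results, pathways, padj_threshold = 0.01,
                                 o_threshold = 0.5, top_k = 5L) {
  stopifnot(inherits(results, "ora_result"))
  sig <- results[results$p_adj < padj_threshold, ]
  nodes <- data.frame(pathway = sig$pathway,
                      neg_log10_padj = -log10(sig$p_adj),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$pathway), ]
  rownames(nodes) <- NULL
  empty <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      o = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) < 2L)
    return(structure(list(nodes = nodes, edges = empty),
                     class = "enrichment_map"))

  nm <- nodes$pathway
  pairs <- utils::combn(nm, 2L)
  o <- apply(pairs, 2L, function(p)
    overlap_coefficient(pathways[[p[1L]]], pathways[[p[2L]]]))
  cand <- data.frame(pathway_a = pairs[1L, ], pathway_b = pairs[2L, ],
                     o = o, stringsAsFactors = FALSE)
  cand <- cand[cand$o > o_threshold, ]
  if (nrow(cand) == 0L)
    return(structure(list(nodes = nodes, edges = empty),
                     class = "enrichment_map"))

  # per pathway keep the top_k most similar partners; union of kept edges
  keep <- logical(nrow(cand))
  for (p in nm) {
    inc <- which(cand$pathway_a == p | cand$pathway_b == p)
    if (length(inc) == 0L) next
    partner <- ifelse(cand$pathway_a[inc] == p, cand$pathway_b[inc],
                      cand$pathway_a[inc])
    o_inc <- cand$o[inc]
    keep[inc[order(-o_inc, partner)[seq_len(min(top_k, length(inc)))]]] <- TRUE
  }
  edges <- cand[keep, ]
  edges <- edges[order(edges$pathway_a, edges$pathway_b), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "enrichment_map")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap_test: observed %d, expected %.3g ",
                     "(module %d, annotation %d, background %d), p = %.3g\n"),
              x$observed, x$expected, x$module_size, x$annotation_size,
              x$background_size, x$p))
  invisible(x)
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %d pathways, %d links\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
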