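#' Build a gene network from an edge table
#'
#' Constructs an undirected, simple gene network from a three-column edge
#' table (gene A, gene B, confidence score in \[0, 1000\]). Edges below the
#' confidence threshold are dropped, self-pairs are removed, and duplicate
#' gene pairs are collapsed keeping the highest score. Nodes are ordered
#' lexicographically so that matrix layouts are deterministic across runs.
#'
#' The adjacency matrix `A` is binary by default; with `weighted = TRUE`
#' entries are `score / 1000`, for sensitivity analyses where interaction
#' confidence should modulate diffusion. The symmetrically normalized
#' matrix is `W[i, j] = A[i, j] / sqrt(d_i * d_j)` with `d` the (weighted)
#' degree; isolated nodes get all-zero rows and columns. The spectral
#' radius of `W` is at most 1, which guarantees convergence of the
#' diffusion recurrence for any retention parameter `alpha < 1`.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`.
#' @param nodes optional character vector of node IDs to retain in the
#'   index even when they have no surviving edge (kept as isolated nodes).
#' @param score_threshold minimum confidence score; edges with
#'   `score >= score_threshold` are kept.
#' @param weighted logical; use `score / 1000` as edge weight in `A`
#'   instead of 1.
#' @return An object of class `gene_network`: a list with elements
#'   `nodes`, `n`, `edges` (canonical edge table), `A`, `W` (sparse
#'   symmetric matrices), `degree` (weighted row sums of `A`),
#'   `score_threshold` and `weighted`.
#' @export
gene_network <- function(edges, nodes = NULL, score_threshold = 0,
                         weighted = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene_a", "gene_b", "score") %in% names(edges)))
    stop("`edges` needs columns gene_a, gene_b, score", call. = FALSE)
  .assert_scalar_number(score_threshold, "score_threshold", 0, 1000)

  ga <- as.character(edges$gene_a)
  gb <- as.character(edges$gene_b)
  sc <- as.numeric(edges$score)
  if (anyNA(sc)) stop("non-numeric confidence score in edge table", call. = FALSE)

  keep <- sc >= score_threshold & ga != gb
  ga <- ga[keep]; gb <- gb[keep]; sc <- sc[keep]

  # canonical unordered pair, then collapse duplicates by maximum score
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    o <- order(key, -sc)
    first <- !duplicated(key[o])
    lo <- lo[o][first]; hi <- hi[o][first]; sc <- sc[o][first]
  }

  all_nodes <- sort(unique(c(lo, hi, as.character(nodes))))
  if (length(all_nodes) == 0L)
    stop("network is empty after filtering", call. = FALSE)

  n <- length(all_nodes)
  i <- match(lo, all_nodes)
  j <- match(hi, all_nodes)
  w <- if (weighted) sc / 1000 else rep(1, length(sc))
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n),
                            dimnames = list(all_nodes, all_nodes))
  deg <- Matrix::rowSums(A)
  structure(list(
    nodes = all_nodes,
    n = n,
    edges = data.frame(gene_a = lo, gene_b = hi, score = sc,
                       stringsAsFactors = FALSE),
    A = A,
    W = .normalize_adjacency(A, deg),
    degree = deg,
    score_threshold = score_threshold,
    weighted = weighted
  ), class = "gene_network")
}

.normalize_adjacency <- function(A, deg = Matrix::rowSums(A)) {
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  D <- Matrix::Diagonal(x = inv)
  W <- D %*% A %*% D
  dimnames(W) <- dimnames(A)
  W
}

#' Symmetrically normalize an adjacency matrix
#'
#' Returns `W` with `W[i, j] = A[i, j] / sqrt(d_i * d_j)`, where `d` is the
#' vector of row sums of `A`. Rows and columns of isolated nodes (zero
#' degree) are left at zero rather than producing `NaN`.
#'
#' @param net a `gene_network`, or a symmetric (sparse) adjacency matrix.
#' @return sparse normalized matrix `W`.
#' @export
normalize_adjacency <- function(net) {
  if (inherits(net, "gene_network")) return(net$W)
  .normalize_adjacency(methods::as(net, "CsparseMatrix"))
}

#' Read a gene network from an edge-list file
#'
#' Parses a STRING-style TSV edge list (`geneA geneB score`, `#` comment
#' lines ignored), optionally maps native identifiers to gene identifiers,
#' applies the confidence-score threshold and builds a [gene_network()].
#' When several identifier pairs map to the same gene pair, only the pair
#' with the highest confidence score is retained; pairs that collapse onto
#' a single gene after mapping are dropped.
#'
#' @param path edge-list file.
#' @param score_threshold minimum confidence score (default 700, the
#'   conventional "high confidence" cut for STRING-like scores).
#' @param mapping optional ID map: a two-column data.frame
#'   (`source_id`, `gene_id`), a named character vector
#'   (`names = source`), or the path of a two-column TSV. Identifiers
#'   without a mapping are dropped with a warning.
#' @param weighted see [gene_network()].
#' @return a `gene_network`.
#' @export
load_edge_list <- function(path, score_threshold = 700, mapping = NULL,
                           weighted = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop(sprintf("malformed row at line %d of %s: expected 3 fields, found %d",
                 idx[which(nf != 3L)[1L]], path, nf[nf != 3L][1L]),
         call. = FALSE)
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  sc <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(sc))
    stop(sprintf("malformed row at line %d of %s: non-numeric score '%s'",
                 idx[which(is.na(sc))[1L]], path, m[is.na(sc), 3L][1L]),
         call. = FALSE)
  ga <- m[, 1L]; gb <- m[, 2L]

  if (!is.null(mapping)) {
    map <- .as_id_map(mapping)
    ma <- map[ga]; mb <- map[gb]
    unmapped <- is.na(ma) | is.na(mb)
    if (any(unmapped)) {
      warning(sprintf("%d edge(s) dropped: identifier(s) missing from ID map",
                      sum(unmapped)), call. = FALSE)
      ma <- ma[!unmapped]; mb <- mb[!unmapped]; sc <- sc[!unmapped]
    }
    ga <- unname(ma); gb <- unname(mb)
  }

  edges <- data.frame(gene_a = ga, gene_b = gb, score = sc,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$score >= score_threshold & edges$gene_a != edges$gene_b, ]
  if (nrow(edges) == 0L)
    stop(sprintf("no edges left after applying score threshold %g",
                 score_threshold), call. = FALSE)
  gene_network(edges, score_threshold = score_threshold, weighted = weighted)
}

.as_id_map <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- utils::read.table(mapping, header = FALSE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE)
  if (is.data.frame(mapping)) {
    if (ncol(mapping) < 2L) stop("ID map needs two columns", call. = FALSE)
    mapping <- stats::setNames(as.character(mapping[[2L]]),
                               as.character(mapping[[1L]]))
  }
  if (is.null(names(mapping)))
    stop("ID map must be named (source_id -> gene_id)", call. = FALSE)
  mapping
}

#' Write a network back to an edge-list TSV
#'
#' Inverse of [load_edge_list()]: reloading the written file with the same
#' threshold reproduces the identical node set, edge set and `W`.
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict a gene list to network genes
#'
#' @param gene_list character vector of gene IDs.
#' @param net a `gene_network`.
#' @return list with `kept` (deduplicated, input order preserved,
#'   intersected with the network) and `dropped` (IDs absent from the
#'   network, for logging).
#' @export
restrict_to_network <- function(gene_list, net) {
  stopifnot(inherits(net, "gene_network"))
  gene_list <- unique(as.character(gene_list))
  kept <- gene_list[gene_list %in% net$nodes]
  dropped <- setdiff(gene_list, kept)
  if (length(kept) == 0L)
    stop("no input gene occurs in the network: nothing to diffuse",
         call. = FALSE)
  list(kept = kept, dropped = dropped)
}

#' Read a plain-text gene list (one ID per line, '#' comments ignored)
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[!grepl("^(#|$)", x)]
}

#' Write a plain-text gene list
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

# igraph view of the network (used for induced subgraphs / rewiring)
.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (score >= %g, %s adjacency)\n",
              x$n, nrow(x$edges), x$score_threshold,
              if (x$weighted) "score-weighted" else "binary"))
  cat(sprintf("  degree: median %g, max %g; isolated nodes: %d\n",
              stats::median(x$degree), max(x$degree), sum(x$degree == 0)))
  invisible(x)
}
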