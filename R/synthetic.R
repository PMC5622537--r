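#' Synthetic planted-module scenario parameters
#'
#' Bundles the parameters of the synthetic data generator. The generator
#' emulates the statistical structure of a high-confidence protein
#' interaction network and of heterogeneous disease-gene screens: a
#' sparse undirected network with heavy-tailed degrees, one connected
#' "disease module" planted into it, several noisy gene lists drawn from
#' the module with low pairwise overlap, and pathway gene sets partially
#' enriched in the module.
#'
#' Defaults describe the reference scenario used throughout the test
#' suite: a 2000-node network (power-law degree exponent 2.5, minimum
#' degree 2), a 100-gene module wired at internal edge density 0.1, six
#' lists each covering 30% of the module with 5% off-module
#' contamination, and pathway sets of 10–200 genes of which a quarter
#' draw 80% of their genes from the module.
#'
#' @param n_nodes number of genes.
#' @param degree_exponent power-law exponent of the degree tail.
#' @param min_degree,max_degree degree bounds.
#' @param module_size planted module size.
#' @param module_density internal edge density of the planted module
#'   (fraction of the `choose(module_size, 2)` pairs realized).
#' @param n_lists number of seed gene lists.
#' @param list_coverage fraction of module genes drawn into each list.
#' @param contamination fraction of each list drawn off-module.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size_range inclusive gene-set size range.
#' @param pathway_module_fraction fraction of an enriched pathway's genes
#'   drawn from the module.
#' @param pathway_enriched_fraction fraction of pathways that are
#'   module-enriched (the rest are uniform null draws).
#' @param score_range confidence scores assigned to synthetic edges.
#' @param rng_seed integer seed; the full scenario is deterministic
#'   given the seed.
#' @return a `synthetic_scenario` parameter list.
#' @export
synthetic_scenario <- function(n_nodes = 2000L, degree_exponent = 2.5,
                               min_degree = 2L, max_degree = 100L,
                               module_size = 100L, module_density = 0.1,
                               n_lists = 6L, list_coverage = 0.3,
                               contamination = 0.05, n_pathways = 60L,
                               pathway_size_range = c(10L, 200L),
                               pathway_module_fraction = 0.8,
                               pathway_enriched_fraction = 0.25,
                               score_range = c(700L, 999L),
                               rng_seed = 42L) {
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Generate a heavy-tailed random gene network
#'
#' Samples a power-law degree sequence (discretized Pareto with the
#' scenario's exponent, truncated to the degree bounds), realizes it as a
#' simple undirected graph, and assigns synthetic confidence scores to
#' the edges. Gene IDs are `G000001`, `G000002`, ... and the result is
#' deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param rng_seed overrides the scenario seed when given.
#' @return a `gene_network`.
#' @export
generate_network <- function(scenario = synthetic_scenario(),
                             rng_seed = NULL) {
  sc <- scenario
  n <- as.integer(sc$n_nodes)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  set.seed(rng_seed %||% sc$rng_seed)
  deg <- .powerlaw_degrees(n, sc$degree_exponent, sc$min_degree,
                           min(sc$max_degree, n - 1L))
  g <- .realize_degseq(deg)
  ends <- igraph::as_edgelist(g, names = FALSE)
  nodes <- sprintf("G%06d", seq_len(n))
  edges <- data.frame(
    gene_a = nodes[ends[, 1L]], gene_b = nodes[ends[, 2L]],
    score = sample(sc$score_range[1L]:sc$score_range[2L], nrow(ends),
                   replace = TRUE),
    stringsAsFactors = FALSE)
  gene_network(edges, nodes = nodes, score_threshold = sc$score_range[1L])
}

.powerlaw_degrees <- function(n, exponent, dmin, dmax) {
  # discretized truncated Pareto: P(D >= d) ~ d^-(exponent - 1)
  u <- stats::runif(n)
  d <- floor(dmin * (1 - u)^(-1 / (exponent - 1)))
  d <- pmin(pmax(d, dmin), dmax)
  if (sum(d) %% 2 == 1) d[which.max(d)] <- d[which.max(d)] + 1L
  as.integer(d)
}

.realize_degseq <- function(deg) {
  g <- tryCatch(suppressWarnings(igraph::sample_degseq(deg, method = "vl")),
                error = function(e) NULL)
  if (is.null(g))
    g <- igraph::simplify(igraph::sample_degseq(deg, method = "fast.heur.simple"))
  g
}

#' Plant a connected module into a network
#'
#' Selects `module_size` genes and adds edges among them (none are
#' removed, so the degree structure outside the module is preserved)
#' until the requested internal edge density is reached and the module's
#' induced subgraph is connected. Densities below the connectivity
#' threshold (`module_size - 1` edges) are rejected.
#'
#' @param net a `gene_network`.
#' @param module_size number of module genes.
#' @param density target internal edge density in (0, 1].
#' @param rng_seed integer seed.
#' @param score_range confidence scores for the added edges.
#' @return list with `net` (augmented network) and `module` (the planted
#'   gene set, sorted).
#' @export
plant_module <- function(net, module_size, density, rng_seed = 1L,
                         score_range = c(700L, 999L)) {
  stopifnot(inherits(net, "gene_network"))
  module_size <- as.integer(module_size)
  if (module_size > net$n) stop("module larger than network", call. = FALSE)
  .assert_scalar_number(density, "density", 0, 1, strict_lower = TRUE)
  n_pairs <- choose(module_size, 2)
  target <- round(density * n_pairs)
  if (target < module_size - 1L)
    stop(sprintf(paste0("density %g yields %d edges, below the %d needed ",
                        "for a connected module"),
                 density, target, module_size - 1L), call. = FALSE)

  set.seed(rng_seed)
  members <- sort(sample(net$nodes, module_size))
  pairs <- utils::combn(members, 2L)
  key <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
  have <- paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")
  present <- key %in% have
  n_new <- target - sum(present)
  add_idx <- integer(0)
  if (n_new > 0)
    add_idx <- sample(which(!present), n_new)

  sel <- present
  sel[add_idx] <- TRUE
  # ensure connectivity by bridging components with extra edges
  repeat {
    g <- igraph::graph_from_edgelist(t(pairs[, sel, drop = FALSE]),
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(members, igraph::V(g)$name))
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    cm <- comp$membership[members]
    a <- sample(members[cm == 1L], 1L)
    b <- sample(members[cm != 1L], 1L)
    bridge <- which(key == paste(min(a, b), max(a, b), sep = "\r"))
    sel[bridge] <- TRUE
  }

  new_pairs <- which(sel & !present)
  if (length(new_pairs)) {
    add <- data.frame(gene_a = pairs[1L, new_pairs],
                      gene_b = pairs[2L, new_pairs],
                      score = sample(score_range[1L]:score_range[2L],
                                     length(new_pairs), replace = TRUE),
                      stringsAsFactors = FALSE)
    net <- gene_network(rbind(net$edges, add), nodes = net$nodes,
                        score_threshold = net$score_threshold,
                        weighted = net$weighted)
  }
  list(net = net, module = members)
}

#' Sample noisy seed lists from a planted module
#'
#' Each list draws a `coverage` fraction of the module genes plus
#' off-module contaminant genes making up a `contamination` fraction of
#' the list. Independent draws at low coverage reproduce the low pairwise
#' overlap typical of disease-gene screens (expected pairwise module
#' overlap is roughly `coverage^2`).
#'
#' @param planted character vector of module genes.
#' @param net the `gene_network`.
#' @param n_lists number of lists.
#' @param coverage fraction of module genes per list, in \[0, 1\].
#' @param contamination fraction of each list drawn off-module, in
#'   \[0, 1).
#' @param rng_seed integer seed.
#' @return named list of gene ID vectors, with a `jaccard` attribute
#'   holding the pairwise Jaccard matrix.
#' @export
sample_gene_lists <- function(planted, net, n_lists = 6L, coverage = 0.3,
                              contamination = 0.05, rng_seed = 1L) {
  stopifnot(inherits(net, "gene_network"))
  .assert_scalar_number(coverage, "coverage", 0, 1)
  .assert_scalar_number(contamination, "contamination", 0, 1)
  set.seed(rng_seed)
  off_pool <- setdiff(net$nodes, planted)
  n_mod <- round(coverage * length(planted))
  n_off <- if (contamination >= 1) length(off_pool)
           else round(contamination * n_mod / (1 - contamination))
  lists <- lapply(seq_len(n_lists), function(i) {
    sort(c(sample(planted, n_mod),
           sample(off_pool, min(n_off, length(off_pool)))))
  })
  names(lists) <- sprintf("list%02d", seq_len(n_lists))
  jac <- outer(seq_len(n_lists), seq_len(n_lists),
               Vectorize(function(i, j) {
                 u <- union(lists[[i]], lists[[j]])
                 if (length(u) == 0) return(0)
                 length(intersect(lists[[i]], lists[[j]])) / length(u)
               }))
  dimnames(jac) <- list(names(lists), names(lists))
  attr(lists, "jaccard") <- jac
  lists
}

#' Generate synthetic pathway gene sets
#'
#' A configured fraction of the pathways are "true positives" drawing
#' `module_fraction` of their genes from the planted module (the rest of
#' their genes, and all genes of the remaining null pathways, are uniform
#' draws from the network). Pathway sizes are uniform over `size_range`.
#'
#' @param net the `gene_network`.
#' @param planted module gene set.
#' @param n_pathways number of gene sets.
#' @param size_range inclusive size range (default 10–200).
#' @param module_fraction fraction of an enriched pathway drawn from the
#'   module.
#' @param enriched_fraction fraction of pathways that are enriched.
#' @param rng_seed integer seed.
#' @return named list of gene sets with attribute `enriched` naming the
#'   true-positive pathways.
#' @export
generate_pathways <- function(net, planted, n_pathways = 60L,
                              size_range = c(10L, 200L),
                              module_fraction = 0.8,
                              enriched_fraction = 0.25, rng_seed = 1L) {
  stopifnot(inherits(net, "gene_network"))
  set.seed(rng_seed)
  n_enr <- round(enriched_fraction * n_pathways)
  sizes <- sample(size_range[1L]:size_range[2L], n_pathways, replace = TRUE)
  off_pool <- setdiff(net$nodes, planted)
  pw <- lapply(seq_len(n_pathways), function(i) {
    s <- sizes[i]
    if (i <= n_enr && module_fraction > 0) {
      n_mod <- min(round(module_fraction * s), length(planted))
      sort(c(sample(planted, n_mod), sample(off_pool, s - n_mod)))
    } else {
      sort(sample(net$nodes, s))
    }
  })
  names(pw) <- sprintf("PW%04d", seq_len(n_pathways))
  attr(pw, "enriched") <- if (n_enr > 0 && module_fraction > 0)
    names(pw)[seq_len(n_enr)] else character(0)
  pw
}

#' Generate a full synthetic scenario
#'
#' Runs the whole generator: network, planted module, seed lists and
#' pathways, all deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `network`, `module` (planted genes), `lists`,
#'   `pathways`, `scenario`; class `scenario_data`.
#' @export
generate_scenario <- function(scenario = synthetic_scenario()) {
  sc <- scenario
  net0 <- generate_network(sc)
  planted <- plant_module(net0, sc$module_size, sc$module_density,
                          rng_seed = sc$rng_seed + 1L,
                          score_range = sc$score_range)
  lists <- sample_gene_lists(planted$module, planted$net, sc$n_lists,
                             sc$list_coverage, sc$contamination,
                             rng_seed = sc$rng_seed + 2L)
  pathways <- generate_pathways(planted$net, planted$module, sc$n_pathways,
                                sc$pathway_size_range,
                                sc$pathway_module_fraction,
                                sc$pathway_enriched_fraction,
                                rng_seed = sc$rng_seed + 3L)
  structure(list(network = planted$net, module = planted$module,
                 lists = lists, pathways = pathways, scenario = sc),
            class = "scenario_data")
}

#' Write a synthetic scenario to disk
#'
#' Emits `edges.tsv`, one `listNN.txt` per seed list, `pathways.gmt` and
#' `truth.json` (planted members and generator parameters) into a
#' directory.
#'
#' @param sim a `scenario_data` object from [generate_scenario()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  stopifnot(inherits(sim, "scenario_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(sim$network, file.path(dir, "edges.tsv"))
  for (nm in names(sim$lists))
    write_gene_list(sim$lists[[nm]], file.path(dir, paste0(nm, ".txt")))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing truth.json requires the jsonlite package", call. = FALSE)
  jsonlite::write_json(
    list(module = sim$module,
         enriched_pathways = attr(sim$pathways, "enriched"),
         scenario = unclass(sim$scenario)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
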