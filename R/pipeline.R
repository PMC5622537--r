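#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its conventional
#' default: diffusion retention `alpha = 0.7`, `K = 999` seed
#' permutations, `q = 200` network resamplings, module significance 0.05,
#' pathway size filter 10–200, ORA significance at adjusted p < 0.01,
#' enrichment-map overlap threshold 0.5 with top 5 links per pathway, and
#' the top-`2n` selection rule.
#'
#' @param alpha diffusion retention parameter.
#' @param K seed-permutation count.
#' @param epsilon `"auto"` (1:1 calibration) or a positive value.
#' @param q resamplings per rank cutoff.
#' @param nr_significance p_NR threshold for module extraction.
#' @param nr_window consecutive significant grid points required.
#' @param nr_rule module selection rule, `"onset"` or `"largest"`
#'   (see [extract_module()]).
#' @param m_grid optional explicit rank grid.
#' @param swaps_per_edge swap attempts per edge when rewiring.
#' @param multiplier top-`multiplier * n` selection.
#' @param min_pathway_size,max_pathway_size ORA size filter.
#' @param padj_threshold ORA significance cut on adjusted p.
#' @param o_threshold,top_k enrichment-map parameters.
#' @param rng_seed integer seed driving all randomized stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.7, K = 999L, epsilon = "auto",
                            q = 200L, nr_significance = 0.05,
                            nr_window = 3L, nr_rule = "onset",
                            m_grid = NULL,
                            swaps_per_edge = 10L, multiplier = 2L,
                            min_pathway_size = 10L, max_pathway_size = 200L,
                            padj_threshold = 0.01, o_threshold = 0.5,
                            top_k = 5L, rng_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Single-list analysis: scoring, top-2n selection, module, ORA
#'
#' Runs the full pipeline for one gene list: restriction to network
#' genes, unit-weight seeding, epsilon calibration (1:1 rule) unless a
#' fixed value is configured, permutation-adjusted smoothing-index
#' scoring, selection of the top `2n` genes (the "n*" list of input plus
#' predicted genes), the network-resampling connectivity profile with
#' module extraction and, when pathway sets are supplied,
#' over-representation analysis of the n* list.
#'
#' @param net a `gene_network`.
#' @param gene_list character vector of input genes.
#' @param pathways optional named list of pathway gene sets.
#' @param config a [pipeline_config()].
#' @param list_name label used in reporting.
#' @param ora_background background for the ORA: `"network"` (all network
#'   genes, default) or a character vector.
#' @return list with `restricted`, `scores` (`smoothing_result`),
#'   `top` (n* table), `profile` (`nr_profile`), `module`
#'   (`gene_module`), `ora` (`ora_result` or NULL), `config`.
#' @export
run_single_list <- function(net, gene_list, pathways = NULL,
                            config = pipeline_config(),
                            list_name = "list", ora_background = "network") {
  stopifnot(inherits(net, "gene_network"))
  cfg <- config
  restricted <- restrict_to_network(gene_list, net)
  if (length(restricted$dropped))
    message(sprintf("%s: %d of %d genes not in network (kept %d)",
                    list_name, length(restricted$dropped),
                    length(restricted$dropped) + length(restricted$kept),
                    length(restricted$kept)))
  seeds <- build_seed_vector(stats::setNames(list(restricted$kept), list_name),
                             net = net)
  scores <- nsi_score(net, seeds, alpha = cfg$alpha, epsilon = cfg$epsilon,
                      K = cfg$K, rng_seed = cfg$rng_seed)
  top <- select_top(scores, cfg$multiplier)
  profile <- nr_profile(scores, net, m_grid = cfg$m_grid, q = cfg$q,
                        rng_seed = cfg$rng_seed,
                        swaps_per_edge = cfg$swaps_per_edge)
  module <- extract_module(profile, scores, net,
                           significance = cfg$nr_significance,
                           window = cfg$nr_window, rule = cfg$nr_rule)
  ora_res <- NULL
  if (!is.null(pathways)) {
    bg <- if (identical(ora_background, "network")) net$nodes else ora_background
    ora_res <- ora(top$gene, pathways, bg,
                   min_size = cfg$min_pathway_size,
                   max_size = cfg$max_pathway_size,
                   background_label = if (identical(ora_background, "network"))
                     "network" else "custom")
  }
  list(list_name = list_name, restricted = restricted, scores = scores,
       top = top, profile = profile, module = module, ora = ora_res,
       config = cfg)
}

#' Joint analysis of several weighted gene lists
#'
#' Builds the joint seed vector by the max-weight rule (a gene's initial
#' score is the largest weight over the lists containing it), scores all
#' genes, and extracts the significantly connected module with its
#' per-source membership breakdown. The default `epsilon = 1` reflects
#' that a joint run mainly prioritizes the input genes themselves rather
#' than predicting new ones; pass `epsilon = "auto"` to calibrate.
#'
#' @param net a `gene_network`.
#' @param lists named list of gene ID vectors (each restricted to the
#'   network automatically).
#' @param weights named per-list weights in (0, 1]; default 1 for all.
#' @param pathways optional pathway sets for ORA on the module.
#' @param config a [pipeline_config()].
#' @param epsilon joint-analysis regularizer (default 1).
#' @return list with `seeds`, `scores`, `profile`, `module`, `ora`
#'   (or NULL), `config`.
#' @export
run_joint <- function(net, lists, weights = NULL, pathways = NULL,
                      config = pipeline_config(), epsilon = 1) {
  stopifnot(inherits(net, "gene_network"))
  if (length(lists) < 2L) stop("joint analysis needs >= 2 lists", call. = FALSE)
  cfg <- config
  seeds <- build_seed_vector(lists, weights, net)
  scores <- nsi_score(net, seeds, alpha = cfg$alpha, epsilon = epsilon,
                      K = cfg$K, rng_seed = cfg$rng_seed)
  profile <- nr_profile(scores, net, m_grid = cfg$m_grid, q = cfg$q,
                        rng_seed = cfg$rng_seed,
                        swaps_per_edge = cfg$swaps_per_edge)
  module <- extract_module(profile, scores, net,
                           significance = cfg$nr_significance,
                           window = cfg$nr_window, rule = cfg$nr_rule)
  ora_res <- NULL
  if (!is.null(pathways) && module$m_star > 0)
    ora_res <- ora(module$genes, pathways, net$nodes,
                   min_size = cfg$min_pathway_size,
                   max_size = cfg$max_pathway_size,
                   background_label = "network")
  list(seeds = seeds, scores = scores, profile = profile, module = module,
       ora = ora_res, config = cfg)
}

#' Co-occurrence summary across single-list analyses
#'
#' Cross-tabulates, for every gene appearing in at least one top-`2n`
#' selection, the number of lists where it was an input gene against the
#' number of lists where it was predicted (non-input among the top
#' ranks) — a compact view of how often independent screens and their
#' network neighborhoods point at the same genes.
#'
#' @param runs list of [run_single_list()] results.
#' @return data.frame with columns `gene`, `n_input`, `n_predicted`,
#'   plus a `counts` attribute holding the contingency table of
#'   (`n_predicted`, `n_input`).
#' @export
cooccurrence_summary <- function(runs) {
  recs <- lapply(runs, function(r) {
    data.frame(gene = r$top$gene, is_input = r$top$is_input,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, recs)
  n_input <- tapply(all$is_input, all$gene, sum)
  n_pred <- tapply(!all$is_input, all$gene, sum)
  out <- data.frame(gene = names(n_input),
                    n_input = as.integer(n_input),
                    n_predicted = as.integer(n_pred),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_predicted, -out$n_input, out$gene), ]
  rownames(out) <- NULL
  attr(out, "counts") <- table(predicted = out$n_predicted,
                               input = out$n_input)
  out
}
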