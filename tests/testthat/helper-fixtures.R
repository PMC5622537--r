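# Small deterministic fixtures used across the test files.

edges_df <- function(a, b, score = 900) {
  data.frame(gene_a = a, gene_b = b, score = score, stringsAsFactors = FALSE)
}

# linear path g01 - g02 - ... - gNN
path_net <- function(n = 3) {
  ids <- sprintf("g%02d", seq_len(n))
  gene_network(edges_df(ids[-n], ids[-1]))
}

# star: center connected to k leaves
star_net <- function(k = 4) {
  gene_network(edges_df(rep("center", k), sprintf("leaf%d", seq_len(k))))
}

complete_net <- function(n = 6) {
  ids <- sprintf("g%02d", seq_len(n))
  pr <- t(utils::combn(ids, 2))
  gene_network(edges_df(pr[, 1], pr[, 2]))
}

ring_net <- function(n = 6) {
  ids <- sprintf("g%02d", seq_len(n))
  gene_network(edges_df(ids, ids[c(2:n, 1)]))
}

# Erdos-Renyi background network, deterministic given seed
random_net <- function(n, p = 4 / n, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  ends <- igraph::as_edgelist(g)
  ids <- sprintf("g%03d", seq_len(n))
  gene_network(edges_df(ids[ends[, 1]], ids[ends[, 2]]), nodes = ids)
}

# sparse background plus a seeded clique with one extra gene attached to
# most clique members: that gene sits in an exceptionally strong seed
# neighborhood and should reach the minimal permutation p-value
clique_scenario <- function(n_background = 200, clique_size = 10,
                            n_attach = 6, seed = 5) {
  net <- random_net(n_background, p = 3 / n_background, seed = seed)
  clique <- sprintf("g%03d", seq_len(clique_size))
  pr <- t(utils::combn(clique, 2))
  probe <- "probe"
  extra <- rbind(edges_df(pr[, 1], pr[, 2]),
                 edges_df(rep(probe, n_attach), clique[seq_len(n_attach)]))
  list(net = gene_network(rbind(net$edges, extra), nodes = c(net$nodes, probe)),
       seeds = clique, probe = probe)
}

# small planted-module scenario for calibration / recovery smoke tests
small_scenario <- function(seed = 42) {
  synthetic_scenario(n_nodes = 200L, module_size = 30L, module_density = 0.3,
                     n_lists = 2L, list_coverage = 0.5, contamination = 0.05,
                     n_pathways = 20L, pathway_size_range = c(10L, 30L),
                     rng_seed = seed)
}

expect_same_network <- function(a, b) {
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_equal(as.matrix(a$W), as.matrix(b$W))
}
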