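test_that("omega: edgeless zero, single-edge arithmetic, quadratic scaling", {
  expect_equal(omega(c(2, 3), matrix(0, 2, 2)), 0)
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(omega(c(2, 3), a), 12)  # each edge counted twice
  sp <- c(1, 2, 3)
  am <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(omega(2 * sp, am), 4 * omega(sp, am))
  expect_error(omega(c(1, 2), am), "dimensions")
})

test_that("rewiring preserves the degree sequence and simplicity on every draw", {
  net <- random_net(60, seed = 21)
  a <- net$A
  d0 <- Matrix::rowSums(a)
  for (s in 1:20) {
    r <- degree_preserving_rewire(a, swaps_per_edge = 10, rng_seed = s)
    expect_equal(Matrix::rowSums(r), d0)
    expect_equal(r, Matrix::t(r))
    expect_true(all(Matrix::diag(r) == 0))
    expect_true(all(r@x %in% c(0, 1)))
  }
})

test_that("a triangle is rigid under rewiring", {
  tri <- gene_network(edges_df(c("a", "a", "b"), c("b", "c", "c")))
  r <- degree_preserving_rewire(tri$A, swaps_per_edge = 50, rng_seed = 1)
  expect_equal(as.matrix(r), as.matrix(tri$A))
})

test_that("a 4-cycle rewires onto a labeled 2-regular graph, reproducibly", {
  cyc <- ring_net(4)
  # the three labeled 2-regular graphs on 4 nodes are the three 4-cycles
  valid <- list(c("g01g02", "g01g04", "g02g03", "g03g04"),
                c("g01g02", "g01g03", "g02g04", "g03g04"),
                c("g01g03", "g01g04", "g02g03", "g02g04"))
  r1 <- degree_preserving_rewire(cyc$A, swaps_per_edge = 10, rng_seed = 7)
  r2 <- degree_preserving_rewire(cyc$A, swaps_per_edge = 10, rng_seed = 7)
  expect_equal(r1, r2)
  m <- as.matrix(r1)
  got <- unname(sort(apply(which(upper.tri(m) & m == 1, arr.ind = TRUE), 1,
                    function(ij) paste0(rownames(m)[ij[1]], colnames(m)[ij[2]]))))
  expect_true(any(vapply(valid, identical, logical(1), y = got)))
  expect_equal(Matrix::rowSums(r1), Matrix::rowSums(cyc$A))
})

test_that("empirical p_nr matches exhaustive degree-sequence enumeration", {
  # 6 nodes, 6 edges, heterogeneous degrees and scores
  ids <- sprintf("n%d", 1:6)
  ed <- edgeD <- edges_df(c("n1", "n1", "n1", "n2", "n4", "n5"),
                          c("n2", "n3", "n4", "n3", "n5", "n6"))
  net <- gene_network(ed)
  sp <- c(n1 = 3, n2 = 2.5, n3 = 2, n4 = 1, n5 = 0.5, n6 = 0.1)
  a <- as.matrix(net$A)[ids, ids]
  obs <- omega(sp[ids], a)

  # oracle: enumerate every simple graph with the same degree sequence
  pairs <- utils::combn(ids, 2)
  deg0 <- sort(colSums(a))
  combos <- utils::combn(ncol(pairs), 6)
  omegas <- c()
  for (j in seq_len(ncol(combos))) {
    am <- matrix(0, 6, 6, dimnames = list(ids, ids))
    for (k in combos[, j]) {
      am[pairs[1, k], pairs[2, k]] <- 1
      am[pairs[2, k], pairs[1, k]] <- 1
    }
    if (identical(sort(colSums(am)), deg0) &&
        identical(sort(rowSums(am)), deg0) &&
        all(vapply(ids, function(i) sum(am[i, ]), numeric(1)) ==
            colSums(a)[ids]))
      omegas <- c(omegas, omega(sp[ids], am))
  }
  p_exact <- mean(omegas >= obs - 1e-9)

  set.seed(99)
  null_om <- vapply(1:1500, function(k) {
    r <- degree_preserving_rewire(a, swaps_per_edge = 20)
    omega(sp[ids], as.matrix(r))
  }, numeric(1))
  p_emp <- mean(null_om >= obs - 1e-9)
  expect_lt(abs(p_emp - p_exact), 0.07)
})

test_that("omega is non-decreasing along the rank grid and p_nr in bounds", {
  sc <- clique_scenario()
  res <- nsi_score(sc$net, sc$seeds, epsilon = 0.2, K = 99L, rng_seed = 2L)
  prof <- nr_profile(res, sc$net, m_grid = seq(10, 80, by = 10), q = 49L,
                     rng_seed = 5L)
  expect_true(all(diff(prof$profile$omega) >= 0))
  expect_true(all(prof$profile$p_nr >= 1 / 50 & prof$profile$p_nr <= 1))
  prof2 <- nr_profile(res, sc$net, m_grid = seq(10, 80, by = 10), q = 49L,
                      rng_seed = 5L)
  expect_identical(prof$profile, prof2$profile)
})

test_that("constant scores make the statistic degenerate (p_nr = 1)", {
  net <- random_net(80, seed = 31)
  fake <- structure(list(
    table = data.frame(gene = net$nodes, x0 = 0, x_star = 0,
                       S = 0, pS = 1, Sp = 1, exceed = 0,
                       rank = seq_len(net$n), is_input = FALSE,
                       source_lists = "", stringsAsFactors = FALSE),
    epsilon = 1, K = 0L, alpha = 0.7, rng_seed = 1L, n_input = 10L),
    class = "smoothing_result")
  prof <- nr_profile(fake, net, m_grid = seq(20, 80, by = 20), q = 49L,
                     rng_seed = 1L)
  expect_true(all(prof$profile$p_nr == 1))
})

test_that("module selection rules map the profile to the documented cutoffs", {
  net <- random_net(300, seed = 41)
  fake <- structure(list(
    table = data.frame(gene = net$nodes, x0 = 0, x_star = 0, S = 0, pS = 1,
                       Sp = 0, exceed = 0, rank = seq_len(net$n),
                       is_input = FALSE, source_lists = "",
                       stringsAsFactors = FALSE),
    epsilon = 1, K = 0L, alpha = 0.7, rng_seed = 1L, n_input = 50L),
    class = "smoothing_result")
  grid <- seq(50, 300, by = 50)
  mk_prof <- function(p) structure(
    list(profile = data.frame(m = grid, omega = 1, p_nr = p),
         q = 200L, swaps_per_edge = 10L, rng_seed = 1L, m_grid = grid,
         pseudocount = TRUE), class = "nr_profile")

  # significant only on {100..250}: largest rule ends the run at 250
  p <- c(0.5, 0.01, 0.01, 0.01, 0.01, 0.5)
  mod_l <- extract_module(mk_prof(p), fake, net, rule = "largest")
  expect_equal(mod_l$m_star, 250)
  # onset rule opens the run at 100 (refinement off to test the raw rule)
  mod_o <- extract_module(mk_prof(p), fake, net, rule = "onset",
                          refine = FALSE)
  expect_equal(mod_o$m_star, 100)

  # nothing significant: empty module is a valid outcome
  mod_e <- extract_module(mk_prof(rep(0.4, 6)), fake, net)
  expect_equal(mod_e$m_star, 0L)
  expect_match(mod_e$status, "no significantly connected")
})

test_that("a planted module is recovered by the onset rule", {
  sim <- generate_scenario(small_scenario(seed = 7))
  res <- run_joint(sim$network, sim$lists,
                   config = pipeline_config(K = 199L, q = 99L, rng_seed = 3L))
  expect_equal(res$module$status, "ok")
  got <- res$module$genes
  expect_gte(length(intersect(got, sim$module)) / length(got), 0.8)
  expect_gte(length(intersect(got, sim$module)) / length(sim$module), 0.8)
  # breakdown partitions the module
  expect_equal(sum(res$module$breakdown$n), res$module$m_star)
})
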