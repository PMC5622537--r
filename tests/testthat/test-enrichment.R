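test_that("hypergeometric tail: trivial and derived configurations", {
  expect_equal(hypergeom_tail(0, 5, 4, 20), 1)
  expect_equal(hypergeom_tail(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_tail(2, 216, 10, 11381), 1.46e-2, tolerance = 5e-3)
  expect_error(hypergeom_tail(6, 5, 4, 20), "infeasible")
  expect_error(hypergeom_tail(1, 25, 4, 20), "infeasible")
})

test_that("hypergeometric tail matches draw-by-draw enumeration", {
  # enumerate every possible draw for small universes
  for (cfg in list(c(N = 8, K = 3, n = 4), c(N = 10, K = 5, n = 3),
                   c(N = 9, K = 4, n = 6))) {
    N <- cfg[["N"]]; K <- cfg[["K"]]; n <- cfg[["n"]]
    draws <- utils::combn(N, n)
    overlaps <- colSums(draws <= K)  # items 1..K are the annotated ones
    for (k in 0:min(K, n))
      expect_equal(hypergeom_tail(k, K, n, N), mean(overlaps >= k),
                   tolerance = 1e-12)
  }
})

test_that("hypergeometric tail matches binomial-coefficient summation everywhere", {
  oracle <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(1)
  for (rep in 1:300) {
    N <- sample(2:25, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    if (k == 0) next
    expect_equal(hypergeom_tail(k, K, n, N), oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("module-annotation overlap reproduces the reference contingency rows", {
  bg <- sprintf("g%05d", 1:11381)
  ann <- bg[1:216]
  # |M| = 10 with overlap 2
  mod10 <- c(ann[1:2], bg[10000:10007])
  t10 <- module_overlap_test(mod10, ann, bg)
  expect_equal(t10$observed, 2)
  expect_equal(t10$expected, 0.190, tolerance = 1e-2)
  expect_equal(t10$p, 1.46e-2, tolerance = 5e-3)
  expect_equal(t10$module_size + t10$complement_size, 11381)

  # |M| = 300 with overlap 20
  mod300 <- c(ann[1:20], bg[10000:10279])
  t300 <- module_overlap_test(mod300, ann, bg)
  expect_equal(t300$expected, 5.69, tolerance = 1e-2)
  expect_equal(t300$p, 1.07e-6, tolerance = 5e-3)

  # module equal to annotation: maximal overlap, minimal p
  tid <- module_overlap_test(ann, ann, bg)
  expect_equal(tid$observed, 216)
  expect_lt(tid$p, 1e-100)

  expect_error(module_overlap_test(mod10, c("zzz"), bg), "disjoint")
  expect_warning(module_overlap_test(mod10, c(ann[1:5], "zzz"), bg), "dropped")
})

test_that("interaction-excess test uses the neighborhood as the draw", {
  st <- star_net(10)
  risk <- sprintf("leaf%d", 1:6)
  t1 <- interaction_excess_test("center", st, risk)
  expect_equal(t1$observed, 6)
  expect_equal(t1$p, hypergeom_tail(6, 6, 10, st$n), tolerance = 1e-12)
  # gene with zero risk-gene neighbors
  t2 <- interaction_excess_test("leaf1", st, c("leaf2", "leaf3"))
  expect_equal(t2$observed, 0)
  expect_equal(t2$p, 1)
})

test_that("BH adjustment: equal p unchanged, step-up example, monotone", {
  expect_equal(bh_adjust(c(0.02, 0.02, 0.02)), rep(0.02, 3))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.07), 0.07)
  set.seed(2)
  p <- stats::runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # order preserved: adjusting sorted input sorts the adjusted values
  expect_equal(bh_adjust(sort(p)), sort(adj))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("overlap coefficient handles nesting, disjointness and arithmetic", {
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(overlap_coefficient(c("a"), c("b")), 0)
  expect_equal(overlap_coefficient(c("a", "b", "x", "y"),
                                   c(letters[1:2], LETTERS[1:8])), 0.5)
  expect_error(overlap_coefficient(character(0), "a"), "empty")
})

test_that("GMT files round-trip through write and read", {
  pw <- list(PW1 = c("g1", "g2", "g3"), PW2 = c("g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pw, f)
  back <- read_gmt(f)
  expect_equal(back, pw)
})

test_that("ORA computes exact tails with BH correction over filtered sets", {
  bg <- sprintf("g%03d", 1:100)
  pw <- list(hit = bg[1:20], miss = bg[41:60], small = bg[1:3])
  query <- bg[1:10]
  res <- ora(query, pw, bg, min_size = 10, max_size = 200)
  expect_false("small" %in% res$pathway)  # size filter
  hit <- res[res$pathway == "hit", ]
  expect_equal(hit$overlap, 10)
  expect_equal(hit$p, hypergeom_tail(10, 20, 10, 100), tolerance = 1e-12)
  expect_equal(res$p_adj, bh_adjust(res$p))
  expect_true(all(res$p_adj >= res$p))
})

test_that("enrichment map applies the threshold, top-k and ordering rules", {
  bg <- sprintf("g%03d", 1:200)
  pw <- list(A = bg[1:20], B = bg[1:22], C = c(bg[1:18], bg[100:103]),
             D = bg[150:170])
  res <- structure(data.frame(pathway = c("A", "B", "C", "D"),
                              size = lengths(pw)[c("A", "B", "C", "D")],
                              overlap = 5, expected = 1,
                              p = c(1e-6, 1e-5, 1e-4, 1e-3),
                              p_adj = c(4e-6, 2e-5, 1.33e-4, 1e-3),
                              stringsAsFactors = FALSE),
                   class = c("ora_result", "data.frame"))
  em <- build_enrichment_map(res, pw, padj_threshold = 0.01,
                             o_threshold = 0.5, top_k = 5)
  expect_setequal(em$nodes$pathway, c("A", "B", "C", "D"))
  # D shares nothing: no incident edge; A-B-C mutually above 0.5
  expect_false("D" %in% c(em$edges$pathway_a, em$edges$pathway_b))
  expect_equal(nrow(em$edges), 3)

  # top_k = 1: each pathway keeps one edge, union of kept edges <= 3
  em1 <- build_enrichment_map(res, pw, padj_threshold = 0.01,
                              o_threshold = 0.5, top_k = 1)
  expect_lte(nrow(em1$edges), 3)
  expect_gte(nrow(em1$edges), 1)

  # permuting the input row order leaves the edge set unchanged
  res2 <- res[c(3, 1, 4, 2), ]
  class(res2) <- c("ora_result", "data.frame")
  em2 <- build_enrichment_map(res2, pw, padj_threshold = 0.01,
                              o_threshold = 0.5, top_k = 5)
  expect_equal(em2$edges, em$edges)

  # o = 0.4 stays below the strict threshold
  pwx <- list(X = bg[1:10], Y = c(bg[1:4], bg[50:55]))
  resx <- structure(data.frame(pathway = c("X", "Y"), size = c(10, 10),
                               overlap = 3, expected = 1, p = c(1e-4, 1e-4),
                               p_adj = c(2e-4, 2e-4), stringsAsFactors = FALSE),
                    class = c("ora_result", "data.frame"))
  emx <- build_enrichment_map(resx, pwx, o_threshold = 0.5)
  expect_equal(nrow(emx$edges), 0)

  # a single significant pathway yields one node and no edges
  em_single <- build_enrichment_map(resx[1, ], pwx)
  expect_equal(nrow(em_single$nodes), 1)
  expect_equal(nrow(em_single$edges), 0)
})
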