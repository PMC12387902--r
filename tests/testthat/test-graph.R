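test_that("associationToDistance reverses order and zeroes the diagonal", {
  m <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  a <- methods::new("AssociationMatrix", m)
  d <- associationToDistance(a)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d["a", "b"], 0.1, tolerance = 1e-12)
})

test_that("MST matches igraph on random distance matrices", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    d <- randomDistanceMatrix(n)
    g <- minimumSpanningTree(d)
    expect_equal(nrow(graphEdges(g)), n - 1)
    ig <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(ig))$weight)
    expect_equal(graphDistanceWeight(g, d), ref, tolerance = 1e-10)
  }
})

test_that("MST output is acyclic and spans all nodes", {
  set.seed(42)
  d <- randomDistanceMatrix(9)
  g <- minimumSpanningTree(d)
  e <- graphEdges(g)
  expect_setequal(unique(c(e$u, e$v)), graphNodes(g))
  ig <- asIgraph(g)
  expect_true(igraph::is_connected(ig))
  expect_equal(igraph::gsize(ig), 8)
  expect_equal(sum(nodeDegrees(g)), 2 * nrow(e))
})

test_that("tie-breaking is deterministic under node permutation", {
  # all-equal weights: every spanning tree is minimal, so the result is
  # decided purely by the documented (weight, u, v) ordering
  n <- 5
  d <- matrix(0.5, n, n); diag(d) <- 0
  dimnames(d) <- list(letters[1:n], letters[1:n])
  g1 <- minimumSpanningTree(d)
  perm <- c(3, 5, 1, 4, 2)
  d2 <- d[perm, perm]
  g2 <- minimumSpanningTree(d2)
  key <- function(g) {
    e <- graphEdges(g)
    sort(paste(e$u, e$v))
  }
  expect_identical(key(g1), key(g2))
  # the lexicographically first star: a-b, a-c, a-d, a-e
  expect_identical(key(g1), c("a b", "a c", "a d", "a e"))
})

test_that("edges are canonical (u < v) and sorted by strength", {
  set.seed(43)
  g <- minimumSpanningTree(randomDistanceMatrix(8))
  e <- graphEdges(g)
  expect_true(all(e$u < e$v))
  expect_true(all(diff(e$strength) <= 1e-12))
})

test_that("mrgAugment defaults to the tree relabelled as MRG", {
  co <- scaleCohort(toyCohort())
  a <- associationMatrix(suppressWarnings(
    trainAutoCM(co, autoCMConfig(maxEpochs = 200))))
  tree <- minimumSpanningTree(a)
  mrg <- mrgAugment(tree, a)
  expect_identical(graphKind(mrg), "MRG")
  expect_identical(graphEdges(mrg), graphEdges(tree))
})

test_that("mrgAugment adds edges only when regularity strictly improves", {
  co <- scaleCohort(toyCohort())
  a <- associationMatrix(suppressWarnings(
    trainAutoCM(co, autoCMConfig(maxEpochs = 200))))
  tree <- minimumSpanningTree(a)
  # a functional that rewards edge count: every candidate improves it
  mrg <- mrgAugment(tree, a, regularity = function(g) nrow(graphEdges(g)),
                    budget = 2)
  expect_equal(nrow(graphEdges(mrg)), nrow(graphEdges(tree)) + 2)
  # a constant functional accepts nothing
  mrg0 <- mrgAugment(tree, a, regularity = function(g) 0)
  expect_equal(nrow(graphEdges(mrg0)), nrow(graphEdges(tree)))
  expect_error(mrgAugment(tree, a, budget = -1), "non-negative")
})

test_that("GraphML and CSV exports round-trip the graph", {
  set.seed(44)
  g <- minimumSpanningTree(randomDistanceMatrix(7))
  for (fmt in c("graphml", "csv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    exportGraph(g, f, fmt)
    g2 <- importGraph(f, fmt)
    expect_setequal(graphNodes(g2), graphNodes(g))
    key <- function(x) {
      e <- graphEdges(x)
      e <- e[order(e$u, e$v), ]
      paste(e$u, e$v, signif(e$strength, 10))
    }
    expect_setequal(key(g2), key(g))
    expect_identical(graphKind(g2), "MST")
    unlink(f)
  }
})

test_that("DOT export writes a readable graphviz file", {
  set.seed(45)
  g <- minimumSpanningTree(randomDistanceMatrix(5))
  f <- tempfile(fileext = ".dot")
  exportGraph(g, f, "dot")
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})

test_that("asIgraph categorizes indicator nodes", {
  d <- matrix(0.5, 3, 3); diag(d) <- 0
  dimnames(d) <- list(c("A", "INPH", "DEMENZA"), c("A", "INPH", "DEMENZA"))
  ig <- asIgraph(minimumSpanningTree(d))
  cat_ <- igraph::vertex_attr(ig, "category")
  names(cat_) <- igraph::vertex_attr(ig, "name")
  expect_identical(unname(cat_[c("A", "INPH", "DEMENZA")]),
                   c("coding", "indicator", "indicator"))
})

test_that("malformed distance input is rejected", {
  expect_error(minimumSpanningTree(matrix(1:6, 2, 3)), "square")
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(minimumSpanningTree(d), "symmetric")
  d <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(minimumSpanningTree(d), "finite|symmetric")
})
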