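test_that("distance_map gives BFS hop counts and drops absent sources", {
  p5 <- make_path5()
  D <- distance_map(p5, "1")
  expect_equal(unname(D[1, as.character(1:5)]), 0:4)
  expect_warning(D2 <- distance_map(p5, c("1", "ZZ")), "absent")
  expect_equal(nrow(D2), 1)
  # disconnected component: Inf
  g2 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g2)$name <- c("a", "b")
  expect_equal(unname(distance_map(g2, "a")[1, "b"]), Inf)
})

test_that("BFS distances agree with the Floyd-Warshall oracle", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    A <- random_adjacency(n, p = 0.15)
    g <- graph_from_adjacency(A)
    D <- distance_map(g, rownames(A))
    expect_equal(unname(D[rownames(A), colnames(A)]),
                 unname(floyd_warshall(A)))
  }
})

test_that("triangle inequality holds on sampled triples", {
  set.seed(52)
  g <- simulate_interactome(300, 2, seed = 6)$network
  D <- distance_map(g, igraph::V(g)$name)
  for (i in 1:200) {
    t3 <- sample(igraph::V(g)$name, 3)
    expect_lte(D[t3[1], t3[3]], D[t3[1], t3[2]] + D[t3[2], t3[3]])
  }
})

test_that("set distances match the hand oracle on P5", {
  p5 <- make_path5()
  expect_equal(cross_set_distance(p5, c("1", "2"), c("4", "5")), 3.0)
  expect_equal(cross_set_distance(p5, "3", "3"), 0)      # self-pair
  expect_equal(within_set_distance(p5, c("1", "2")), 1.0)
  expect_equal(within_set_distance(p5, "2"), 0)          # singleton
  res <- separation_score(p5, c("1", "2"), c("4", "5"))
  expect_equal(res$d_ab, 3.0)
  expect_equal(res$d_aa, 1.0)
  expect_equal(res$d_bb, 1.0)
  expect_equal(res$s_ab, 2.0)
  expect_equal(res$classification, "separated")
})

test_that("overlapping sets use self-pairs in d_AB only", {
  # adjacent u, v with A = B = {u, v}: d_AB = (0+1+1+0)/4 = 0.5,
  # d_AA = d_BB = 1, S = -0.5 proximal
  g <- igraph::make_graph(~ u - v)
  res <- separation_score(g, c("u", "v"), c("u", "v"))
  expect_equal(res$d_ab, 0.5)
  expect_equal(res$s_ab, -0.5)
  expect_equal(res$classification, "proximal")
})

test_that("singleton-vs-singleton scores are never proximal", {
  p5 <- make_path5()
  res <- separation_score(p5, "2", "4")
  expect_equal(res$s_ab, 2)
  expect_equal(res$classification, "separated")
  res0 <- separation_score(p5, "3", "3")
  expect_equal(res0$s_ab, 0)               # S_AB = 0 classified separated
  expect_equal(res0$classification, "separated")
})

test_that("S_AB is symmetric and matches the matrix oracle on random instances", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    A <- random_adjacency(n, p = 0.25)
    g <- graph_from_adjacency(A)
    D <- floyd_warshall(A)
    a <- sample(rownames(A), sample(2:4, 1))
    b <- sample(rownames(A), sample(2:5, 1))
    r1 <- suppressWarnings(tryCatch(separation_score(g, a, b),
                                    error = function(e) NULL))
    if (is.null(r1)) next
    r2 <- separation_score(g, b, a)
    expect_identical(r1$s_ab, r2$s_ab)
    expect_equal(r1$s_ab, oracle_separation(D, a, b), tolerance = 1e-12)
  }
})

test_that("adding an edge never increases the cross-set distance", {
  set.seed(62)
  for (i in 1:10) {
    g <- simulate_interactome(100, 1, seed = i)$network  # tree: room to add
    nodes <- igraph::V(g)$name
    a <- sample(nodes, 3); b <- sample(nodes, 3)
    d0 <- cross_set_distance(g, a, b)
    new <- sample(nodes, 2)
    g2 <- igraph::add_edges(g, new)
    g2 <- igraph::simplify(g2)
    expect_lte(cross_set_distance(g2, a, b), d0 + 1e-12)
  }
})

test_that("results are invariant under node relabelling", {
  set.seed(63)
  A <- random_adjacency(15, 0.3)
  g <- graph_from_adjacency(A)
  a <- rownames(A)[1:3]; b <- rownames(A)[10:12]
  r1 <- separation_score(g, a, b)
  perm <- sample(15)
  A2 <- A[perm, perm]   # same topology, rows carry their names along
  r2 <- separation_score(graph_from_adjacency(A2), a, b)
  expect_equal(r1$s_ab, r2$s_ab)
})

test_that("indirect targets reproduce the 22-target difference", {
  fx <- load_fixtures()
  ind <- indirect_targets(fx$dioscin4, fx$clinical23)
  expect_length(ind, 22)
  expect_false("IL2" %in% ind)
  expect_length(indirect_targets(c("A", "B"), "A"), 0)
  expect_equal(indirect_targets("x", c("y", "z")),
               sort(setdiff(toupper(c("y", "z")), "X")))
})

test_that("intermediary nodes cover all geodesic interiors", {
  p5 <- make_path5()
  expect_equal(intermediary_nodes(p5, "1", "5"), c("2", "3", "4"))
  expect_length(intermediary_nodes(p5, "1", "2"), 0)   # adjacent
  # diamond: both 2-hop routes counted
  dia <- igraph::make_graph(~ a - x, x - b, a - y, y - b)
  expect_equal(intermediary_nodes(dia, "a", "b"), c("x", "y"))
})

test_that("batch scoring equals individual calls and preserves order", {
  p5 <- make_path5()
  pairs <- list(one = list(a = c("1", "2"), b = c("4", "5")),
                two = list(a = "1", b = "5"),
                bad = list(a = "NOPE", b = "5"))
  expect_warning(bat <- batch_separation(p5, pairs), "absent")
  expect_equal(bat$summary$id, c("one", "two", "bad"))
  solo <- separation_score(p5, c("1", "2"), c("4", "5"))
  expect_equal(bat$results$one$s_ab, solo$s_ab)
  expect_equal(bat$results$two$s_ab, 4)
  expect_null(bat$results$bad)                      # error collected
  expect_match(bat$summary$error[3], "restriction")
  # permuted input order gives permuted identical outputs
  expect_warning(bat2 <- batch_separation(p5, rev(pairs)))
  expect_equal(bat2$summary$s_ab, rev(bat$summary$s_ab))
})
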