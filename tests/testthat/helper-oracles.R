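# Brute-force oracles, independent of the implementation paths (and of
# igraph's clique/shortest-path routines) that they check.

# adjacency matrix of a random simple graph on n named nodes
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  A
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  dimnames(D) <- dimnames(A)
  D
}

# exhaustive MCC: enumerate every vertex subset, keep cliques that are
# maximal, score sum (|C|-1)! per member. Feasible to ~12 nodes.
brute_force_mcc <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 14)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    sub <- A[idx, idx]
    all(sub[upper.tri(sub)] == 1)
  }
  subsets <- lapply(1:(2^n - 1), function(mask) which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
  cliques <- Filter(is_clique, subsets)
  keys <- vapply(cliques, function(s) paste(s, collapse = ","), "")
  maximal <- Filter(function(s) {
    ext <- setdiff(1:n, s)
    !any(vapply(ext, function(v) is_clique(c(s, v)), TRUE))
  }, cliques)
  scores <- setNames(numeric(n), rownames(A))
  for (C in maximal) scores[C] <- scores[C] + factorial(length(C) - 1)
  scores
}

# hand-rolled separation score from a precomputed distance matrix
# (ordered cross pairs incl. self-pairs; distinct unordered within pairs)
oracle_separation <- function(D, a, b) {
  dab <- as.vector(D[a, b, drop = FALSE])
  dab <- mean(dab[is.finite(dab)])
  wd <- function(s) {
    if (length(s) < 2) return(0)
    v <- D[s, s][upper.tri(D[s, s])]
    mean(v[is.finite(v)])
  }
  dab - (wd(a) + wd(b)) / 2
}

make_path5 <- function() {
  g <- igraph::make_ring(5, circular = FALSE)
  igraph::V(g)$name <- as.character(1:5)
  g
}

toy_expression <- function() {
  m <- matrix(c(5, 5.2, 4.9, 7, 7.1, 6.8,
                3, 3.1, 2.9, 3, 3.2, 3.1,
                9, 8.8, 9.1, 6.9, 7.2, 7.0,
                5, 5, 5, 5, 5, 5,
                4, 4.5, 4.2, 4.3, 4.1, 4.6),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("G", 1:5),
                              c(paste0("c", 1:3), paste0("n", 1:3))))
  expression_dataset(m, c(rep("case", 3), rep("control", 3)))
}
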