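# Synthetic-data generators: two-group log2 expression with planted
# fold-changes, scale-free interactomes, and planted proximal/separated
# target-set pairs. Every generator is a pure function of its arguments
# including the seed.

#' Simulate a two-group log2 expression matrix with planted DE genes
#'
#' Baseline per-gene means are drawn uniformly on log2 intensities
#' typical of processed microarrays (4 to 12); i.i.d. Gaussian noise of
#' SD \code{sigma} is added on the log2 scale. The first \code{n_de}
#' genes carry a planted case-mean shift of +/- \code{lfc} with signs
#' alternating deterministically (1st, 3rd, ... planted gene up; 2nd,
#' 4th, ... down), so up/down counts are exactly predictable.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group (>= 2 each).
#' @param n_de Number of planted differentially expressed genes
#'   (<= n_genes; 0 gives a pure null matrix).
#' @param lfc Planted absolute log2 fold-change (case minus control).
#' @param sigma Noise SD on the log2 scale (> 0).
#' @param seed Integer RNG seed; same seed, same matrix, bit for bit.
#' @return Object of classes \code{simulated_expression} and
#'   \code{expression_dataset}: fields \code{matrix}, \code{groups},
#'   plus \code{truth} (data.frame gene, planted_lfc) and \code{seed}.
#' @examples
#' sim <- simulate_expression(500, 10, 10, n_de = 50, lfc = 2,
#'                            sigma = 0.5, seed = 7)
#' table(sign(sim$truth$planted_lfc))
#' @export
simulate_expression <- function(n_genes, n_case, n_control, n_de,
                                lfc = 2, sigma = 0.5, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_case <- assert_count(n_case, "n_case", min = 2L)
  n_control <- assert_count(n_control, "n_control", min = 2L)
  n_de <- assert_count(n_de, "n_de", min = 0L)
  if (n_de > n_genes) stopf("n_de (%d) exceeds n_genes (%d)", n_de, n_genes)
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0")
  set.seed(seed)

  genes <- sprintf("GENE%05d", seq_len(n_genes))
  n <- n_case + n_control
  base <- runif(n_genes, 4, 12)
  m <- matrix(rnorm(n_genes * n, mean = 0, sd = sigma),
              nrow = n_genes, ncol = n) + base
  planted_lfc <- numeric(0)
  if (n_de > 0L) {
    sign_vec <- rep_len(c(1, -1), n_de)   # odd planted index up, even down
    planted_lfc <- lfc * sign_vec
    m[seq_len(n_de), seq_len(n_case)] <-
      m[seq_len(n_de), seq_len(n_case)] + planted_lfc
  }
  dimnames(m) <- list(genes,
                      c(sprintf("case_%02d", seq_len(n_case)),
                        sprintf("control_%02d", seq_len(n_control))))
  out <- expression_dataset(m, c(rep("case", n_case),
                                 rep("control", n_control)))
  out$truth <- data.frame(gene = genes[seq_len(n_de)],
                          planted_lfc = planted_lfc,
                          stringsAsFactors = FALSE)
  out$seed <- as.integer(seed)
  class(out) <- c("simulated_expression", class(out))
  out
}

#' Simulate a scale-free interactome
#'
#' Preferential-attachment (Barabasi-Albert) growth: each new node
#' attaches to \code{attachment} existing nodes with probability
#' proportional to degree. The result is a connected simple undirected
#' graph with the heavy-tailed, hub-dominated degree distribution of
#' the human protein-protein interactome. \code{attachment = 1} yields
#' a tree with \code{n_nodes - 1} edges.
#'
#' @param n_nodes Number of nodes (> attachment).
#' @param attachment Edges added per new node (>= 1).
#' @param seed Integer RNG seed.
#' @return Object of class \code{simulated_interactome}: fields
#'   \code{network} (an igraph with uppercase node names N0001...),
#'   \code{planted_pairs} (empty list, see [plant_target_sets()]) and
#'   \code{seed}.
#' @export
simulate_interactome <- function(n_nodes, attachment = 2L, seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  attachment <- assert_count(attachment, "attachment", min = 1L)
  if (n_nodes <= attachment)
    stopf("n_nodes (%d) must exceed attachment (%d)", n_nodes, attachment)
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("N%05d", seq_len(n_nodes))
  structure(list(network = g, planted_pairs = list(),
                 seed = as.integer(seed)),
            class = "simulated_interactome")
}

as_igraph <- function(net) {
  if (inherits(net, "simulated_interactome")) return(net$network)
  if (igraph::is_igraph(net)) return(net)
  stopf("`net` must be an igraph or simulated_interactome")
}

#' Plant a target-set pair of known proximity class
#'
#' Constructs two node sets A and B whose separation score
#' \eqn{S_{AB}} has a known intended sign:
#' \describe{
#'   \item{proximal}{A is a uniform sample of nodes; B is drawn from the
#'     closed 2-hop neighbourhood of A, with roughly half of B taken
#'     from A itself (overlapping target sets, as when a drug hits a
#'     member of the disease target set directly). Shared members and
#'     short cross distances pull \eqn{\langle d_{AB}\rangle} below the
#'     within-set averages, so \eqn{S_{AB} < 0}.}
#'   \item{separated}{A is a compact cluster (a low-degree centre plus
#'     its BFS-nearest nodes); B is sampled from nodes at distance >= 4
#'     from every member of A (falling back to the maximal-distance
#'     nodes with a warning when no such nodes exist), so cross
#'     distances dominate and \eqn{S_{AB} \ge 0}.}
#' }
#'
#' @param net igraph or [simulate_interactome()] result.
#' @param size_a,size_b Target-set sizes (\code{size_a + size_b} at most
#'   the node count).
#' @param cls \code{"proximal"} or \code{"separated"}.
#' @param seed Integer RNG seed.
#' @return List with character vectors \code{a}, \code{b} and the
#'   intended class \code{cls}.
#' @export
plant_target_sets <- function(net, size_a = 4L, size_b = 8L,
                              cls = c("proximal", "separated"),
                              seed = 1L) {
  g <- as_igraph(net)
  cls <- match.arg(cls)
  size_a <- assert_count(size_a, "size_a")
  size_b <- assert_count(size_b, "size_b")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) stopf("network nodes must be named")
  if (size_a + size_b > length(nodes))
    stopf("size_a + size_b exceeds the node count")
  set.seed(seed)

  if (cls == "proximal") {
    a <- sample(nodes, size_a)
    ball <- unique(unlist(lapply(igraph::ego(g, order = 2, nodes = a),
                                 function(v) v$name)))
    n_from_a <- min(size_a, max(1L, size_b %/% 2L))
    b_core <- sample(a, n_from_a)
    pool <- setdiff(ball, b_core)
    if (length(pool) < size_b - n_from_a)
      stopf("2-hop neighbourhood too small to plant a proximal pair")
    b <- c(b_core, sample(pool, size_b - n_from_a))
  } else {
    deg <- igraph::degree(g)
    centre <- sample(nodes[deg <= stats::median(deg)], 1L)
    d_centre <- igraph::distances(g, v = centre)[1L, ]
    a <- nodes[order(d_centre, runif(length(nodes)))][seq_len(size_a)]
    d_a <- igraph::distances(g, v = a)
    min_d <- apply(d_a, 2L, min)
    far <- nodes[is.finite(min_d) & min_d >= 4]
    far <- setdiff(far, a)
    if (length(far) < size_b) {
      warnf("no/few nodes >= 4 hops from A; falling back to maximal-distance nodes")
      cand <- setdiff(nodes, a)
      far <- cand[order(-min_d[match(cand, nodes)])][seq_len(size_b)]
      b <- far
    } else {
      b <- sample(far, size_b)
    }
  }
  list(a = sort(a), b = sort(b), cls = cls)
}
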