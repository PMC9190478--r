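# PPI subnetwork construction from scored edge lists and hub
# identification by maximal clique centrality (MCC).

#' Build an interaction network from an edge data.frame
#'
#' @param edges data.frame whose first two columns are node symbols;
#'   an optional \code{score} column carries edge confidence in [0, 1].
#' @return Simple undirected igraph with uppercase node names (self
#'   loops and duplicate edges removed; duplicate scores keep the max).
#' @export
interaction_network <- function(edges) {
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stopf("`edges` must be a data.frame with at least two columns")
  df <- data.frame(from = toupper(trimws(as.character(edges[[1]]))),
                   to = toupper(trimws(as.character(edges[[2]]))),
                   stringsAsFactors = FALSE)
  if ("score" %in% names(edges)) df$score <- as.numeric(edges$score)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(score = "max", "ignore"))
}

#' Load a scored PPI edge list and apply a confidence threshold
#'
#' Accepts the STRING links dialect (whitespace-separated columns
#' \code{protein1 protein2 combined_score} with scores 0-1000) or a
#' plain 2/3-column TSV with scores already in [0, 1]. Integer scores
#' larger than 1 are normalised by 1/1000 (the STRING file convention);
#' edges with normalised score >= \code{threshold} are retained
#' (inclusive, so STRING's "0.7" keeps combined scores of exactly 700).
#' Files with only two columns are read as unscored edge lists and not
#' filtered.
#'
#' @param path Edge-list file.
#' @param threshold Minimum combined score in [0, 1] (default 0.7).
#' @return Simple undirected igraph; edges keep a \code{score}
#'   attribute when the input was scored. An empty result triggers a
#'   warning, not an error.
#' @export
load_scored_edges <- function(path, threshold = 0.7) {
  threshold <- assert_prob(threshold, "threshold")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty edge file: %s", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  has_header <- grepl("protein|node|score|from|to", lines[1], ignore.case = TRUE)
  if (has_header) toks <- toks[-1]
  ncols <- lengths(toks)
  bad <- which(ncols < 2L)
  if (length(bad))
    stopf("edge file line %d: fewer than 2 fields",
          bad[1] + has_header)
  scored <- all(ncols >= 3L)
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  if (scored) {
    score <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    if (anyNA(score))
      stopf("edge file line %d: unparseable score",
            which(is.na(score))[1] + has_header)
    if (any(score > 1)) score <- score / 1000   # STRING stores 0-1000
    keep <- score >= threshold
    df <- data.frame(from = from[keep], to = to[keep],
                     score = score[keep], stringsAsFactors = FALSE)
  } else {
    df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) {
    warnf("no edges pass threshold %.3g in %s", threshold, path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  interaction_network(df)
}

#' Maximal clique centrality (MCC) scores
#'
#' For each node v, MCC(v) is the sum over all maximal cliques C
#' containing v of (|C| - 1)!. Maximal cliques are enumerated exactly
#' (Bron-Kerbosch with pivoting); an isolated node is its own maximal
#' clique and scores (1-1)! = 1. On a triangle-free graph every edge is
#' a maximal clique, so MCC reduces to degree (plus nothing); on the
#' complete graph K_n every node scores (n-1)!.
#'
#' Clique enumeration is worst-case exponential, so the computation is
#' guarded by node- and clique-count budgets.
#'
#' @param net igraph (simple, undirected).
#' @param max_nodes,max_cliques Budgets; exceeding either aborts with
#'   an error rather than running unbounded.
#' @return Named numeric vector of MCC scores (named by node).
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- LETTERS[1:4]
#' mcc_scores(g)   # all 3! = 6
#' @export
mcc_scores <- function(net, max_nodes = 5000L, max_cliques = 1e6) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  if (n > max_nodes)
    stopf("network has %d nodes, over the clique-enumeration budget (%d)",
          n, max_nodes)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  cl <- igraph::max_cliques(g)
  if (length(cl) > max_cliques)
    stopf("%d maximal cliques exceed the budget (%g)", length(cl), max_cliques)
  scores <- setNames(numeric(n), nodes)
  for (C in cl) {
    w <- factorial(length(C) - 1L)
    idx <- as.integer(C)
    scores[idx] <- scores[idx] + w
  }
  scores
}

#' Node degrees of a simple network
#'
#' @param net igraph.
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(net) {
  g <- as_igraph(net)
  igraph::degree(g, loops = FALSE)
}

#' Select hub nodes by top MCC fraction and decompose into submodules
#'
#' Retains the top \code{ceiling(fraction * n)} nodes ranked by MCC
#' (descending), breaking ties by degree (descending) then symbol
#' (ascending). Submodules are the connected components of size >= 2 of
#' the subgraph induced by the selected hubs, numbered by decreasing
#' size.
#'
#' @param scores Named MCC score vector from [mcc_scores()].
#' @param fraction Top fraction to keep, in (0, 1] (default 0.10; a
#'   267-node network yields ceiling(26.7) = 27 hubs).
#' @param net The scored network the MCC came from (for degrees and
#'   submodule induction).
#' @return Object of class \code{hub_result}: \code{table} (data.frame
#'   node, mcc, degree, rank, submodule), \code{hubs} (ordered symbol
#'   vector) and \code{submodules} (list of symbol vectors).
#' @export
select_hubs <- function(scores, fraction = 0.10, net) {
  if (!length(scores)) stopf("empty score map")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stopf("`fraction` must be in (0, 1]")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  deg <- deg[names(scores)]
  deg[is.na(deg)] <- 0L
  n_sel <- as.integer(ceiling(fraction * length(scores)))
  ord <- order(-scores, -deg, names(scores))
  hubs <- names(scores)[ord][seq_len(n_sel)]

  sub <- igraph::induced_subgraph(g, intersect(hubs, igraph::V(g)$name))
  comp <- igraph::components(sub)
  members <- split(names(comp$membership), comp$membership)
  members <- members[order(-vapply(members, length, 1L))]
  members <- members[vapply(members, length, 1L) >= 2L]
  submodules <- lapply(unname(members), sort)

  modid <- rep(NA_integer_, n_sel)
  for (i in seq_along(submodules))
    modid[hubs %in% submodules[[i]]] <- i
  tab <- data.frame(node = hubs,
                    mcc = unname(scores[hubs]),
                    degree = as.integer(deg[hubs]),
                    rank = seq_len(n_sel),
                    submodule = modid,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, hubs = hubs, submodules = submodules),
            class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("hub_result: %d hubs, %d submodule(s)\n",
              length(x$hubs), length(x$submodules)))
  print(head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("...\n")
  invisible(x)
}
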