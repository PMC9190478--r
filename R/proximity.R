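# Interactome proximity: average shortest-path set distances, the
# separation score S_AB = <d_AB> - (<d_AA> + <d_BB>)/2, its sign-based
# proximal/separated call, indirect targets, intermediary proteins and
# batch scoring.
#
# Conventions (stated loudly because they change the numbers):
# * <d_AB> averages d(a, b) over ALL ordered pairs a in A, b in B.
#   When A and B share members the self-pairs contribute d(a, a) = 0 --
#   overlapping target sets genuinely occur (a drug can hit a disease
#   treatment target directly) and the zeros materially lower <d_AB>.
# * <d_AA> and <d_BB> average over unordered DISTINCT pairs; a
#   singleton set has within-set distance 0 by convention. Consequently
#   singleton A, B give S_AB = d(a, b) >= 0: singletons can never be
#   called proximal.
# * Distances are unweighted hops (edge confidence is ignored).
# * Pairs in different components are excluded from numerator and
#   denominator, with the count reported.

# match query symbols to node names case-insensitively, returning the
# node names as spelled in the graph
restrict_to_net <- function(g, x, label) {
  x <- unique(norm_symbols(x))
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) stopf("network nodes must be named")
  idx <- match(x, toupper(nodes))
  found <- nodes[idx[!is.na(idx)]]
  dropped <- x[is.na(idx)]
  if (length(dropped))
    warnf("%d %s symbol(s) absent from the network: %s", length(dropped),
          label, paste(dropped, collapse = ", "))
  list(found = found, dropped = dropped)
}

#' Per-source shortest-path distance map
#'
#' Unweighted breadth-first shortest-path lengths from each source to
#' every node. Unreachable nodes get \code{Inf}. Sources missing from
#' the network are dropped with a warning.
#'
#' @param net igraph with named nodes.
#' @param sources Character vector of source symbols.
#' @return Numeric matrix, one row per retained source, one column per
#'   network node.
#' @export
distance_map <- function(net, sources) {
  g <- as_igraph(net)
  r <- restrict_to_net(g, sources, "source")
  if (!length(r$found)) stopf("no sources present in the network")
  igraph::distances(g, v = r$found, algorithm = "unweighted")
}

# distances between two symbol sets, given an optional precomputed
# distance matrix (rows >= sources, all columns)
set_dist_matrix <- function(g, from, to, cache = NULL) {
  if (!is.null(cache)) return(cache[from, to, drop = FALSE])
  igraph::distances(g, v = from, to = to, algorithm = "unweighted")
}

#' Mean cross-set distance \eqn{\langle d_{AB}\rangle}
#'
#' Mean shortest-path length over all ordered pairs (a in A, b in B);
#' self-pairs contribute 0; unreachable pairs are excluded from both
#' numerator and denominator.
#'
#' @param net igraph.
#' @param a,b Character vectors of node symbols.
#' @return Mean distance in hops (scalar).
#' @export
cross_set_distance <- function(net, a, b) {
  g <- as_igraph(net)
  ra <- restrict_to_net(g, a, "A")$found
  rb <- restrict_to_net(g, b, "B")$found
  if (!length(ra) || !length(rb)) stopf("empty set after network restriction")
  D <- set_dist_matrix(g, ra, rb)
  fin <- is.finite(D)
  if (!any(fin)) stopf("all cross-set pairs are unreachable")
  mean(D[fin])
}

#' Mean within-set distance \eqn{\langle d_{AA}\rangle}
#'
#' Mean shortest-path length over unordered distinct pairs of the set;
#' a singleton set returns 0 by convention; unreachable pairs are
#' excluded.
#'
#' @param net igraph.
#' @param s Character vector of node symbols.
#' @return Mean distance in hops (scalar).
#' @export
within_set_distance <- function(net, s) {
  g <- as_igraph(net)
  rs <- restrict_to_net(g, s, "set")$found
  if (!length(rs)) stopf("empty set after network restriction")
  if (length(rs) == 1L) return(0)
  D <- set_dist_matrix(g, rs, rs)
  ut <- D[upper.tri(D)]
  fin <- is.finite(ut)
  if (!any(fin)) stopf("all within-set pairs are unreachable")
  mean(ut[fin])
}

sep_score_impl <- function(g, a, b, cache = NULL) {
  ra <- restrict_to_net(g, a, "A")
  rb <- restrict_to_net(g, b, "B")
  if (!length(ra$found) || !length(rb$found))
    stopf("target set empty after network restriction (dropped: %s)",
          paste(c(ra$dropped, rb$dropped), collapse = ", "))
  A <- ra$found; B <- rb$found
  DA <- set_dist_matrix(g, A, igraph::V(g)$name, cache)

  Dab <- DA[, B, drop = FALSE]
  fin_ab <- is.finite(Dab)
  if (!any(fin_ab)) stopf("all cross-set pairs are unreachable")
  d_ab <- mean(Dab[fin_ab])

  Daa <- DA[, A, drop = FALSE][upper.tri(matrix(0, length(A), length(A)))]
  d_aa <- if (length(A) == 1L) 0 else {
    fa <- is.finite(Daa)
    if (!any(fa)) stopf("all within-A pairs are unreachable")
    mean(Daa[fa])
  }
  if (length(B) == 1L) {
    d_bb <- 0
    n_inf_bb <- 0L
  } else {
    DB <- set_dist_matrix(g, B, B, if (all(B %in% rownames(cache))) cache)
    ub <- DB[upper.tri(DB)]
    fb <- is.finite(ub)
    if (!any(fb)) stopf("all within-B pairs are unreachable")
    d_bb <- mean(ub[fb])
    n_inf_bb <- sum(!fb)
  }
  s_ab <- d_ab - (d_aa + d_bb) / 2
  structure(list(
    norm_a = length(A), norm_b = length(B),
    d_ab = d_ab, d_aa = d_aa, d_bb = d_bb, s_ab = s_ab,
    classification = if (s_ab < 0) "proximal" else "separated",
    dropped = c(ra$dropped, rb$dropped),
    unreachable_pairs = sum(!fin_ab) +
      (if (length(A) > 1L) sum(!is.finite(Daa)) else 0L) + n_inf_bb
  ), class = "proximity_result")
}

#' Separation score S_AB between two target sets
#'
#' \deqn{S_{AB} = \langle d_{AB}\rangle - \frac{\langle d_{AA}\rangle +
#' \langle d_{BB}\rangle}{2}}
#'
#' where \eqn{\langle d_{AB}\rangle} is the mean shortest-path length
#' over all ordered pairs (a, b) and the within-set terms average over
#' distinct unordered pairs. A strictly negative score means the two
#' sets occupy overlapping network neighbourhoods and A is called
#' \emph{proximal} to B (the molecule's targets are positioned to
#' regulate the disease targets); \eqn{S_{AB} \ge 0} means the sets are
#' topologically \emph{separated}.
#'
#' @param net igraph; the background interactome.
#' @param a Molecule/drug direct-target symbols (set A).
#' @param b Disease treatment-target symbols (set B).
#' @return Object of class \code{proximity_result}: \code{norm_a},
#'   \code{norm_b} (set sizes after network restriction), \code{d_ab},
#'   \code{d_aa}, \code{d_bb}, \code{s_ab}, \code{classification},
#'   \code{dropped} (symbols absent from the network) and
#'   \code{unreachable_pairs}.
#' @examples
#' p5 <- igraph::make_ring(5, circular = FALSE)
#' igraph::V(p5)$name <- as.character(1:5)
#' separation_score(p5, c("1", "2"), c("4", "5"))  # S_AB = 2, separated
#' @export
separation_score <- function(net, a, b) {
  g <- as_igraph(net)
  sep_score_impl(g, a, b)
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "S_AB = %.3f (%s): <d_AB> = %.3f, <d_AA> = %.3f, <d_BB> = %.3f; ||A|| = %d, ||B|| = %d\n",
    x$s_ab, x$classification, x$d_ab, x$d_aa, x$d_bb, x$norm_a, x$norm_b))
  if (length(x$dropped))
    cat("dropped symbols:", paste(x$dropped, collapse = ", "), "\n")
  if (x$unreachable_pairs > 0L)
    cat("unreachable pairs excluded:", x$unreachable_pairs, "\n")
  invisible(x)
}

#' Indirect targets: disease targets not hit directly
#'
#' Set difference clinical \ direct after uppercase normalisation: the
#' disease treatment targets a molecule can only reach through the
#' network rather than by direct binding.
#'
#' @param direct Molecule direct-target symbols.
#' @param clinical Clinically established disease-target symbols.
#' @return Sorted uppercase character vector.
#' @examples
#' fx <- load_fixtures()
#' length(indirect_targets(fx$dioscin4, fx$clinical23))  # 22
#' @export
indirect_targets <- function(direct, clinical) {
  sort(setdiff(norm_symbols(clinical), norm_symbols(direct)))
}

#' Intermediary proteins on the geodesics between two target sets
#'
#' The union, over all pairs (a in A, b in B), of the interior nodes of
#' ALL shortest a-b paths, minus A and B themselves. A node v lies on a
#' shortest a-b path iff d(a, v) + d(v, b) = d(a, b), which is checked
#' against the BFS distance maps rather than by path enumeration.
#'
#' @param net igraph.
#' @param a,b Character vectors of node symbols.
#' @return Sorted character vector of intermediary node symbols.
#' @examples
#' p5 <- igraph::make_ring(5, circular = FALSE)
#' igraph::V(p5)$name <- as.character(1:5)
#' intermediary_nodes(p5, "1", "5")  # "2" "3" "4"
#' @export
intermediary_nodes <- function(net, a, b) {
  g <- as_igraph(net)
  A <- restrict_to_net(g, a, "A")$found
  B <- restrict_to_net(g, b, "B")$found
  if (!length(A) || !length(B)) stopf("empty set after network restriction")
  nodes <- igraph::V(g)$name
  DA <- igraph::distances(g, v = A, algorithm = "unweighted")
  DB <- igraph::distances(g, v = B, algorithm = "unweighted")
  onpath <- rep(FALSE, length(nodes))
  for (i in seq_along(A)) for (j in seq_along(B)) {
    d <- DA[i, B[j]]
    if (!is.finite(d)) next
    onpath <- onpath | (DA[i, ] + DB[j, ] == d)
  }
  sort(setdiff(nodes[onpath], c(A, B)))
}

#' Batch separation scoring of many molecules against one disease set
#'
#' Scores each (A_i, B) pair with [separation_score()], sharing the
#' distance computation across pairs. Per-pair failures are collected
#' (as \code{NULL} results with the error message in the summary), not
#' fatal to the batch.
#'
#' @param net igraph; the background interactome.
#' @param pairs Named list: each element a list with elements \code{a}
#'   and \code{b} (symbol vectors).
#' @return Object of class \code{batch_separation}: \code{results}
#'   (list of \code{proximity_result} or NULL, input order preserved)
#'   and \code{summary} (data.frame id, n_a, n_b, d_ab, d_aa, d_bb,
#'   s_ab, class, dropped, unreachable_pairs, error).
#' @export
batch_separation <- function(net, pairs) {
  g <- as_igraph(net)
  if (!is.list(pairs) || !length(pairs)) stopf("`pairs` must be a non-empty list")
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("pair%03d", seq_along(pairs))
  all_src <- unique(norm_symbols(unlist(lapply(pairs, function(p) c(p$a, p$b)))))
  all_src <- intersect(all_src, igraph::V(g)$name)
  cache <- if (length(all_src))
    igraph::distances(g, v = all_src, algorithm = "unweighted") else NULL
  results <- vector("list", length(pairs))
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    res <- tryCatch(sep_score_impl(g, pairs[[i]]$a, pairs[[i]]$b, cache),
                    error = function(e) e)
    if (inherits(res, "error")) {
      results[i] <- list(NULL)
      rows[[i]] <- data.frame(id = ids[i], n_a = NA, n_b = NA, d_ab = NA,
                              d_aa = NA, d_bb = NA, s_ab = NA,
                              class = NA, dropped = NA,
                              unreachable_pairs = NA,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(id = ids[i], n_a = res$norm_a,
                              n_b = res$norm_b, d_ab = res$d_ab,
                              d_aa = res$d_aa, d_bb = res$d_bb,
                              s_ab = res$s_ab, class = res$classification,
                              dropped = paste(res$dropped, collapse = ","),
                              unreachable_pairs = res$unreachable_pairs,
                              error = "", stringsAsFactors = FALSE)
    }
  }
  structure(list(results = setNames(results, ids),
                 summary = do.call(rbind, rows)),
            class = "batch_separation")
}

#' @export
print.batch_separation <- function(x, ...) {
  cat(sprintf("batch_separation: %d pair(s), %d proximal\n",
              nrow(x$summary),
              sum(x$summary$class == "proximal", na.rm = TRUE)))
  print(x$summary[c("id", "n_a", "n_b", "d_ab", "d_aa", "d_bb",
                    "s_ab", "class")])
  invisible(x)
}
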