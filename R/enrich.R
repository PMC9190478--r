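# Hypergeometric over-representation analysis (ORA) against gene-set
# collections, with BH and Storey q-values, and the hub-by-pathway
# key-target intersection.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member
#'   symbols).
#' @param set_names Optional named character vector of human-readable
#'   set names (defaults to the ids).
#' @param universe Background gene universe; defaults to the union of
#'   all members. Members outside the universe are removed.
#' @return Object of class \code{gene_set_collection} with elements
#'   \code{sets}, \code{set_names}, \code{universe}.
#' @export
gene_set_collection <- function(sets, set_names = NULL, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("`sets` must be a list with unique names")
  sets <- lapply(sets, norm_symbols)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  else universe <- sort(unique(norm_symbols(universe)))
  sets <- lapply(sets, intersect, universe)
  if (is.null(set_names)) set_names <- setNames(names(sets), names(sets))
  structure(list(sets = sets, set_names = set_names, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# Storey q-values with a lambda grid and spline-smoothed pi0;
# returns NULL when the estimate is unusable (caller falls back to BH)
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 4L || length(unique(p)) < 4L) return(NULL)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (!is.finite(pi0) || pi0 <= 0 || pi0 >= 1) return(NULL)
  ord <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[ord] / rank(p, ties.method = "max")[ord]
  q <- pmin(cummin(q), 1)
  q[order(ord)]
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set with at least one query hit, the upper-tail
#' probability P(X >= k) of drawing k or more set members when n query
#' genes are sampled from a universe of N genes containing K set
#' members (equivalently, a one-sided Fisher exact test on the 2x2
#' overlap table). Sets with no overlap are not tested and do not enter
#' the multiple-testing denominator. BH-adjusted p-values and Storey
#' q-values (lambda grid 0.05..0.95, spline-smoothed pi0; BH fallback
#' when the pi0 estimate is unstable or >= 1) are both reported.
#'
#' @param query Character vector of gene symbols; genes outside the
#'   collection universe are dropped with a message.
#' @param coll A [gene_set_collection()].
#' @return data.frame ordered by p with columns \code{set_id},
#'   \code{name}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p},
#'   \code{adj_p}, \code{q} and \code{hits} (comma-separated overlap
#'   symbols).
#' @examples
#' coll <- read_gmt(ra_pathways_gmt())
#' enrich(c("CCL5", "CXCL10", "CXCL6", "JUN", "MMP9"), coll)
#' @export
enrich <- function(query, coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(norm_symbols(query))
  eff <- intersect(query, coll$universe)
  n_dropped <- length(query) - length(eff)
  if (n_dropped > 0L)
    message(sprintf("enrich: %d query gene(s) outside the universe dropped",
                    n_dropped))
  if (!length(eff))
    stopf("no query genes remain within the universe")
  N <- length(coll$universe)
  n <- length(eff)
  rows <- lapply(names(coll$sets), function(id) {
    members <- coll$sets[[id]]
    hits <- intersect(eff, members)
    k <- length(hits)
    if (k == 0L) return(NULL)
    K <- length(members)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, name = unname(coll$set_names[id]),
               k = k, K = K, n = n, N = N, p = p,
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(set_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), adj_p = numeric(0),
                      q = numeric(0), hits = character(0),
                      stringsAsFactors = FALSE))
  }
  rows$adj_p <- p.adjust(rows$p, method = "BH")
  q <- storey_qvalue(rows$p)
  rows$q <- if (is.null(q)) rows$adj_p else q
  rows <- rows[order(rows$p, rows$set_id), ]
  rownames(rows) <- NULL
  rows[c("set_id", "name", "k", "K", "n", "N", "p", "adj_p", "q", "hits")]
}

#' Filter enrichment records at p and q thresholds
#'
#' Strict inequalities on both: kept iff p < p_cut and q < q_cut.
#'
#' @param records data.frame from [enrich()].
#' @param p_cut,q_cut Thresholds (defaults 0.05 and 0.05).
#' @return The filtered data.frame.
#' @export
filter_significant <- function(records, p_cut = 0.05, q_cut = 0.05) {
  stopifnot(is.data.frame(records), all(c("p", "q") %in% names(records)))
  out <- records[records$p < p_cut & records$q < q_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Key targets: intersection of hub proteins and pathway genes
#'
#' Case-insensitive symbol intersection, returned uppercase and sorted.
#' Applied to the bundled fixtures this reproduces the five chemokine
#' key targets of the RA case study.
#'
#' @param hubs,pathway_genes Character vectors of gene symbols.
#' @return Sorted uppercase character vector.
#' @examples
#' fx <- load_fixtures()
#' key_target_intersection(fx$hub27, fx$pathway30)
#' # "CCL5" "CXCL10" "CXCL11" "CXCL6" "CXCL9"
#' @export
key_target_intersection <- function(hubs, pathway_genes) {
  sort(intersect(norm_symbols(hubs), norm_symbols(pathway_genes)))
}
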