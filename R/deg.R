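# Differential-expression screening: moderated t with empirical-Bayes
# variance shrinkage, threshold screening, and the multi-dataset
# consensus rule.

#' Construct an expression dataset
#'
#' Bundles a genes/probes x samples matrix of log2 intensities with
#' per-sample case/control labels and an optional probe-to-symbol
#' annotation.
#'
#' @param matrix Numeric matrix, rows = genes or probes (unique
#'   rownames), columns = samples.
#' @param groups Character vector of per-sample labels, values
#'   \code{"case"} or \code{"control"}, length = \code{ncol(matrix)};
#'   each group needs at least 2 samples.
#' @param annotation Optional probe-to-gene-symbol map: a named
#'   character vector (names = probe IDs) or a two-column data.frame
#'   (probe, symbol).
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(matrix, groups, annotation = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stopf("`matrix` needs unique rownames")
  groups <- tolower(as.character(groups))
  if (length(groups) != ncol(matrix))
    stopf("length(groups) [%d] != ncol(matrix) [%d]",
          length(groups), ncol(matrix))
  if (!all(groups %in% c("case", "control")))
    stopf("group labels must be 'case' or 'control'")
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stopf("each group needs at least 2 samples")
  if (!is.null(annotation)) {
    if (is.data.frame(annotation)) {
      if (ncol(annotation) < 2L)
        stopf("annotation data.frame needs columns probe, symbol")
      annotation <- setNames(as.character(annotation[[2]]),
                             as.character(annotation[[1]]))
    }
    if (is.null(names(annotation)))
      stopf("annotation must be named by probe ID")
  }
  structure(list(matrix = matrix, groups = groups, annotation = annotation),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples (%d case, %d control)%s\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$groups == "case"), sum(x$groups == "control"),
              if (is.null(x$annotation)) "" else ", annotated"))
  invisible(x)
}

#' Collapse probes to gene symbols
#'
#' One row per gene symbol: probes without a mapping are dropped, and
#' among multiple probes mapping to the same symbol the probe with the
#' highest mean expression is kept (the common GEO convention).
#'
#' @param ds An [expression_dataset()] with a non-empty annotation.
#' @return An \code{expression_dataset} keyed by uppercase gene symbol,
#'   with the annotation consumed (set to NULL).
#' @export
collapse_probes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ann <- ds$annotation
  if (is.null(ann) || !length(ann))
    stopf("collapse_probes() requires a probe annotation")
  sym <- toupper(trimws(ann[rownames(ds$matrix)]))
  keep <- !is.na(sym) & nzchar(sym)
  m <- ds$matrix[keep, , drop = FALSE]
  sym <- sym[keep]
  if (!nrow(m)) stopf("no probes could be mapped to symbols")
  means <- rowMeans(m)
  # highest-mean probe wins within each symbol
  ord <- order(sym, -means)
  first <- !duplicated(sym[ord])
  sel <- ord[first]
  m <- m[sel, , drop = FALSE]
  rownames(m) <- unname(sym[sel])
  expression_dataset(m, ds$groups, annotation = NULL)
}

# Newton solve of trigamma(x) = y; used to turn the spread of the log
# sample variances into a prior df estimate.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated t-test for a two-group log2 expression matrix
#'
#' Per gene: log2FC = case mean minus control mean; the pooled residual
#' variance s^2 (df d = n_case + n_control - 2) is shrunk towards a
#' prior variance s0^2 with prior df d0 estimated by moments from the
#' distribution of the log sample variances (matching the mean and
#' spread of log s^2 against those of a scaled log-F, via digamma /
#' trigamma inversion). The moderated statistic is
#' t = log2FC / sqrt(s2_post * (1/n_case + 1/n_control)) with
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d), referred to a t distribution
#' on d0 + d degrees of freedom; p-values are two-sided and adjusted by
#' Benjamini-Hochberg across all genes.
#'
#' Zero-variance genes have their sample variance floored at 1e-8
#' before shrinkage, so a constant gene yields t = 0 rather than a
#' division by zero.
#'
#' @param ds An [expression_dataset()] (two groups, >= 2 samples each).
#' @param method \code{"moderated"} (default) or \code{"welch"} for a
#'   plain Welch two-sample t with Satterthwaite df (no shrinkage).
#' @param prior_df Override for d0: \code{NULL} (estimate, default),
#'   \code{0} (no shrinkage; ordinary pooled t), or a positive number.
#' @param lfc_cut,alpha Thresholds used only to fill the
#'   \code{direction} column (up: log2FC > lfc_cut and adj_p < alpha;
#'   down symmetric; otherwise none).
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{t}, \code{p}, \code{adj_p}, \code{direction}, ordered as the
#'   input rows.
#' @examples
#' sim <- simulate_expression(n_genes = 200, n_case = 5, n_control = 5,
#'                            n_de = 20, lfc = 2, sigma = 0.5, seed = 1)
#' deg <- moderated_t(sim)
#' head(deg[order(deg$p), ])
#' @export
moderated_t <- function(ds, method = c("moderated", "welch"),
                        prior_df = NULL, lfc_cut = 1.0, alpha = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  m <- ds$matrix
  case <- ds$groups == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L) stopf("each group needs >= 2 samples")
  mu1 <- rowMeans(m[, case, drop = FALSE])
  mu2 <- rowMeans(m[, !case, drop = FALSE])
  lfc <- mu1 - mu2
  v1 <- apply(m[, case, drop = FALSE], 1L, var)
  v2 <- apply(m[, !case, drop = FALSE], 1L, var)

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    se2 <- pmax(se2, 1e-8)
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    s2 <- pmax(s2, 1e-8)
    if (is.null(prior_df)) {
      # moments fit of the log sample variances to a scaled log-F
      e <- log(s2) - digamma(d / 2) + log(d / 2)
      evar <- var(e)
      t2 <- evar - trigamma(d / 2)
      if (is.finite(t2) && t2 > 0) {
        d0 <- 2 * trigamma_inverse(t2)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(mean(e))
      }
    } else {
      d0 <- prior_df
      s02 <- if (d0 > 0) exp(mean(log(s2))) else 0
    }
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
               else (d0 * s02 + d * s2) / (d0 + d)
    tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
    df <- min(d0 + d, 1e6)
  }
  p <- 2 * pt(-abs(tstat), df = df)
  p[lfc == 0] <- 1      # identical group means: no evidence by definition
  tstat[lfc == 0] <- 0
  adj <- p.adjust(p, method = "BH")
  direction <- ifelse(lfc > lfc_cut & adj < alpha, "up",
               ifelse(lfc < -lfc_cut & adj < alpha, "down", "none"))
  data.frame(gene = rownames(m), log2fc = lfc, t = tstat, p = p,
             adj_p = adj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a DEG table at fold-change and adjusted-p thresholds
#'
#' Up = log2FC strictly greater than \code{lfc_cut} and adjusted p
#' strictly below \code{alpha}; down is symmetric with
#' log2FC < -lfc_cut. Boundary values (log2FC exactly 1.0) are excluded.
#'
#' @param records DEG data.frame from [moderated_t()].
#' @param lfc_cut Absolute log2 fold-change threshold (default 1.0).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with character vectors \code{up} and \code{down}.
#' @export
screen_degs <- function(records, lfc_cut = 1.0, alpha = 0.05) {
  if (!is.data.frame(records) || !nrow(records))
    stopf("`records` must be a non-empty DEG data.frame")
  stopifnot(all(c("gene", "log2fc", "adj_p") %in% names(records)))
  up <- records$gene[records$log2fc > lfc_cut & records$adj_p < alpha]
  down <- records$gene[records$log2fc < -lfc_cut & records$adj_p < alpha]
  list(up = norm_symbols(up), down = norm_symbols(down))
}

#' Consensus gene set across datasets
#'
#' A gene enters the consensus when it is differentially expressed in at
#' least \code{k} of the input datasets; up and down calls are pooled
#' within a dataset before counting, so a gene counts once per dataset
#' regardless of direction (direction conflicts between datasets are
#' retained, not dropped).
#'
#' @param deg_sets List of character vectors, one per dataset (each the
#'   union of that dataset's up and down genes, or a
#'   \code{list(up=, down=)} pair from [screen_degs()]).
#' @param k Minimum number of datasets a gene must appear in
#'   (default 2). \code{k = 1} gives the union, \code{k = length(deg_sets)}
#'   the intersection.
#' @return Sorted character vector of consensus gene symbols.
#' @export
consensus_degs <- function(deg_sets, k = 2L) {
  if (!is.list(deg_sets) || !length(deg_sets))
    stopf("`deg_sets` must be a non-empty list of gene sets")
  sets <- lapply(deg_sets, function(s) {
    if (is.list(s)) s <- unlist(s, use.names = FALSE)
    unique(norm_symbols(s))
  })
  k <- assert_count(k, "k")
  if (k > length(sets))
    stopf("k = %d exceeds the number of datasets (%d)", k, length(sets))
  counts <- table(unlist(sets, use.names = FALSE))
  sort(names(counts)[counts >= k])
}
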