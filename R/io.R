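# Readers and writers for the plain-text formats the pipeline consumes:
# genes x samples TSV, GEO series-matrix TSV, sample-annotation TSV,
# GMT gene-set collections, docking CSV, DEG/enrichment/proximity TSVs.

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column is the gene/probe identifier, remaining columns are
#' samples of log2 intensities.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene IDs as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stopf("expression TSV needs an ID column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)))
    stopf("duplicate row IDs in %s", path)
  m
}

#' Read the expression block of a GEO series-matrix file
#'
#' Extracts the table delimited by \code{!series_matrix_table_begin} /
#' \code{!series_matrix_table_end} and returns it as a numeric matrix
#' (probes x samples). Metadata lines (starting with \code{!}) are
#' ignored; sample group labels must be supplied separately.
#'
#' @param path Series-matrix TSV file path.
#' @return Numeric matrix with probe IDs as rownames.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stopf("no series_matrix_table block found in %s", path)
  block <- lines[(beg + 1L):(end - 1L)]
  df <- read.delim(text = block, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "\"")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gsub("\"", "", as.character(df[[1]]))
  m
}

#' Read a two-column sample-annotation TSV (sample, group)
#'
#' @param path TSV with header; first column sample IDs, second column
#'   group labels (\code{case}/\code{control}).
#' @return Named character vector of group labels.
#' @export
read_groups_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("groups TSV needs columns sample, group")
  setNames(tolower(trimws(df[[2]])), as.character(df[[1]]))
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: \code{set_id TAB description TAB member TAB ...}.
#' The description column is retained as the set name (which is why the
#' package carries its own reader rather than one that discards it).
#'
#' @param path GMT file path.
#' @param universe Optional explicit background gene universe; defaults
#'   to the union of all set members.
#' @return A \code{gene_set_collection} (see
#'   [gene_set_collection()]).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stopf("GMT line %d has fewer than 3 fields", bad[1])
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stopf("duplicate set ids in %s", path)
  sets <- lapply(parts, function(p) norm_symbols(p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets,
                      set_names = setNames(vapply(parts, `[[`, "", 2L), ids),
                      universe = universe)
}

#' Read a docking-score table (receptor, ligand, affinity) from CSV
#'
#' Expected columns: \code{receptor}, \code{ligand}, \code{formula},
#' \code{pubchem_cid}, \code{affinity_kcal_mol} (extra columns are
#' retained). Affinities are AutoDock-Vina-style binding scores in
#' kcal/mol; more negative means stronger predicted binding.
#'
#' @param path CSV file path.
#' @return data.frame with one row per (receptor, ligand) pair.
#' @export
read_docking_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor", "ligand", "affinity_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("docking table missing column(s): %s", paste(miss, collapse = ", "))
  df$receptor <- norm_symbols(df$receptor)
  if (!all(is.finite(df$affinity_kcal_mol)))
    stopf("non-finite affinity values in docking table")
  if (anyDuplicated(df[c("receptor", "ligand")]))
    stopf("duplicate (receptor, ligand) rows in docking table")
  df
}

#' Write a DEG table as TSV
#'
#' Columns: gene, log2fc, t, p, adj_p, direction. log2FC orientation is
#' case minus control throughout the package.
#'
#' @param deg data.frame from [moderated_t()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_deg_tsv <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
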