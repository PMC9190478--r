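#' Bundled gene lists and docking table from the RA case study
#'
#' Returns the printed target lists of the rheumatoid-arthritis study the
#' pipeline was built around, shipped as plain-text files under
#' \code{inst/extdata}: the 27 hub proteins selected by maximal clique
#' centrality from the 267-gene consensus DEG PPI network (with their
#' reported degrees as metadata), the 30 genes of the RA-related enriched
#' KEGG pathways, the 23 clinically established RA treatment targets
#' (TTD/DrugBank intersection), dioscin's 4 direct targets, and the
#' 20-row molecular-docking affinity table for receptors CCL5 and CXCL10.
#'
#' Cardinalities (27/30/23/4/20) are asserted at load time.
#'
#' @return A list with elements \code{hub27}, \code{pathway30},
#'   \code{clinical23}, \code{dioscin4} (character vectors of uppercase
#'   gene symbols), \code{hub27_degrees} (named integer vector, the
#'   degrees reported alongside the hubs; metadata, version-sensitive),
#'   and \code{docking_table} (data.frame with columns \code{receptor},
#'   \code{ligand}, \code{formula}, \code{pubchem_cid},
#'   \code{affinity_kcal_mol}).
#' @examples
#' fx <- load_fixtures()
#' key_target_intersection(fx$hub27, fx$pathway30)
#' @export
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "netpharm",
                                  mustWork = TRUE)
  hub <- read.delim(path("hub27.tsv"), stringsAsFactors = FALSE)
  fx <- list(
    hub27 = norm_symbols(hub$symbol),
    hub27_degrees = setNames(as.integer(hub$degree),
                             norm_symbols(hub$symbol)),
    pathway30 = read_symbol_list(path("pathway30.txt")),
    clinical23 = read_symbol_list(path("clinical23.txt")),
    dioscin4 = read_symbol_list(path("dioscin4.txt")),
    docking_table = read_docking_table(path("docking_table.csv"))
  )
  stopifnot(
    length(fx$hub27) == 27L, length(fx$pathway30) == 30L,
    length(fx$clinical23) == 23L, length(fx$dioscin4) == 4L,
    nrow(fx$docking_table) == 20L
  )
  fx
}

#' Path to the bundled RA pathway gene sets (GMT)
#'
#' The six RA-associated KEGG pathways reported by the case study
#' (Th17 and Th1/Th2 cell differentiation, rheumatoid arthritis,
#' NF-kappa B, TNF and Toll-like receptor signalling) with their
#' enriched member genes, in GMT format; the union of members is the
#' 30-gene pathway fixture.
#'
#' @return File path to the GMT file.
#' @seealso [read_gmt()]
#' @export
ra_pathways_gmt <- function() {
  system.file("extdata", "ra_pathways.gmt", package = "netpharm",
              mustWork = TRUE)
}
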