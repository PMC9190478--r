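# End-to-end orchestration: a single config drives
# DEG -> consensus -> PPI/hubs -> enrichment -> key targets -> proximity,
# writing every intermediate table and a JSON run report. Docking-score
# tables are ingested (never computed) for ligand ranking.

REPORT_SCHEMA_VERSION <- "1.0"

#' Rank ligands for a receptor by docking affinity
#'
#' Ascending by affinity (kcal/mol; more negative = stronger predicted
#' binding), ties broken by ligand name ascending.
#'
#' @param table Docking data.frame from [read_docking_table()].
#' @param receptor Receptor symbol.
#' @param top_k Number of ligands to return (default all).
#' @return Character vector of ligand names, best first.
#' @examples
#' fx <- load_fixtures()
#' rank_ligands(fx$docking_table, "CCL5", top_k = 3)
#' @export
rank_ligands <- function(table, receptor, top_k = Inf) {
  stopifnot(is.data.frame(table),
            all(c("receptor", "ligand", "affinity_kcal_mol") %in% names(table)))
  receptor <- norm_symbols(receptor)
  rows <- table[table$receptor == receptor, , drop = FALSE]
  if (!nrow(rows))
    stopf("unknown receptor '%s'; available: %s", receptor,
          paste(sort(unique(table$receptor)), collapse = ", "))
  rows <- rows[order(rows$affinity_kcal_mol, rows$ligand), ]
  head(rows$ligand, top_k)
}

default_thresholds <- function() {
  list(lfc_cut = 1.0, alpha = 0.05, string_threshold = 0.7,
       hub_fraction = 0.10, p_cut = 0.05, q_cut = 0.05, consensus_k = 2L)
}

#' Validate and normalise a pipeline configuration
#'
#' A config is a named list (or a YAML file containing one) with
#' elements:
#' \describe{
#'   \item{datasets}{named list; each entry has \code{matrix} (TSV
#'     path), \code{groups} (sample-annotation TSV path) and optional
#'     \code{annotation} (probe-symbol TSV path).}
#'   \item{network}{optional scored edge-list path for the DEG PPI.}
#'   \item{gmt}{optional gene-set collection path.}
#'   \item{background_network}{optional interactome path for the
#'     proximity stage.}
#'   \item{targets_a, targets_b}{optional symbol-list paths (molecule
#'     direct targets, disease targets).}
#'   \item{docking_table}{optional docking CSV path.}
#'   \item{thresholds}{overrides of \code{lfc_cut} 1.0, \code{alpha}
#'     0.05, \code{string_threshold} 0.7, \code{hub_fraction} 0.10,
#'     \code{p_cut} 0.05, \code{q_cut} 0.05, \code{consensus_k} 2.}
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{integer seed recorded in the report.}
#'   \item{fixtures_only}{logical; TRUE skips the expression stages and
#'     runs the fixture lists through hubs/pathways/proximity set
#'     algebra.}
#' }
#'
#' @param cfg Named list or YAML file path.
#' @return Normalised config list.
#' @export
pipeline_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stopf("config must be a list or a YAML file path")
  th <- default_thresholds()
  th[names(cfg$thresholds)] <- cfg$thresholds
  if (th$lfc_cut < 0 || th$alpha <= 0 || th$alpha > 1 ||
      th$string_threshold < 0 || th$string_threshold > 1 ||
      th$hub_fraction <= 0 || th$hub_fraction > 1 ||
      th$p_cut <= 0 || th$p_cut > 1 || th$q_cut <= 0 || th$q_cut > 1 ||
      th$consensus_k < 1)
    stopf("config threshold out of its documented range")
  cfg$thresholds <- th
  if (is.null(cfg$out_dir)) stopf("config needs `out_dir`")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$fixtures_only <- isTRUE(cfg$fixtures_only)
  paths <- c(unlist(lapply(cfg$datasets, function(d)
               c(d$matrix, d$groups, d$annotation))),
             cfg$network, cfg$gmt, cfg$background_network,
             cfg$targets_a, cfg$targets_b, cfg$docking_table)
  paths <- as.character(paths)
  missing <- if (length(paths)) paths[!file.exists(paths)] else character(0)
  if (length(missing))
    stopf("config references missing file(s): %s",
          paste(missing, collapse = ", "))
  cfg
}

read_dataset_cfg <- function(d) {
  m <- if (grepl("series", d$matrix) &&
           any(grepl("^!series_matrix_table_begin",
                     readLines(d$matrix, n = 200L, warn = FALSE))))
    read_series_matrix(d$matrix) else read_expression_tsv(d$matrix)
  grp <- read_groups_tsv(d$groups)
  if (!all(colnames(m) %in% names(grp)))
    stopf("samples in %s missing from group annotation", d$matrix)
  ann <- NULL
  if (!is.null(d$annotation)) {
    adf <- read.delim(d$annotation, stringsAsFactors = FALSE)
    ann <- setNames(as.character(adf[[2]]), as.character(adf[[1]]))
  }
  expression_dataset(m, unname(grp[colnames(m)]), annotation = ann)
}

#' Run the full target-discovery pipeline from a config
#'
#' Stage order: per-dataset DEG screening, consensus, PPI + MCC hubs,
#' enrichment + significance filter, key-target intersection, proximity
#' (separation score, indirect targets, intermediary proteins), docking
#' ingestion. Stages whose inputs are absent from the config are
#' skipped. Every intermediate table is written under \code{out_dir}
#' and a versioned JSON report with the counts at each stage is written
#' to \code{out_dir/report.json}.
#'
#' A stage failure aborts with the stage name; tables already written
#' are preserved.
#'
#' @param cfg Config list or YAML path (see [pipeline_config()]).
#' @return The run report (a list), invisibly readable back from
#'   \code{report.json}.
#' @export
run_pipeline <- function(cfg) {
  cfg <- pipeline_config(cfg)
  th <- cfg$thresholds
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(report_version = REPORT_SCHEMA_VERSION,
                 package_version = as.character(packageVersion("netpharm")),
                 seed = cfg$seed, thresholds = th, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  consensus <- NULL
  if (cfg$fixtures_only) {
    fx <- stage("fixtures", load_fixtures())
    hubs <- fx$hub27
    pathway_genes <- fx$pathway30
    report$stages$fixtures <- list(hub_count = length(hubs),
                                   pathway_gene_count = length(pathway_genes))
  } else {
    hubs <- pathway_genes <- NULL
    if (length(cfg$datasets)) {
      per_ds <- list()
      for (nm in names(cfg$datasets)) {
        ds <- stage(paste0("deg:", nm), {
          d <- read_dataset_cfg(cfg$datasets[[nm]])
          if (!is.null(d$annotation)) d <- collapse_probes(d)
          d
        })
        deg <- stage(paste0("deg:", nm),
                     moderated_t(ds, lfc_cut = th$lfc_cut, alpha = th$alpha))
        write_deg_tsv(deg, file.path(cfg$out_dir, paste0("deg_", nm, ".tsv")))
        scr <- screen_degs(deg, th$lfc_cut, th$alpha)
        per_ds[[nm]] <- scr
        report$stages$deg[[nm]] <- list(n_genes = nrow(deg),
                                        n_up = length(scr$up),
                                        n_down = length(scr$down))
      }
      consensus <- stage("consensus", consensus_degs(per_ds, k = th$consensus_k))
      write_symbol_list(consensus, file.path(cfg$out_dir, "consensus_degs.txt"))
      report$stages$consensus <- list(k = th$consensus_k,
                                      n_genes = length(consensus))
    }
    if (!is.null(cfg$network) && !is.null(consensus)) {
      hub_res <- stage("network_hub", {
        net <- load_scored_edges(cfg$network, th$string_threshold)
        sub <- igraph::induced_subgraph(
          net, intersect(consensus, igraph::V(net)$name))
        select_hubs(mcc_scores(sub), th$hub_fraction, sub)
      })
      hubs <- hub_res$hubs
      write_tsv_plain(hub_res$table, file.path(cfg$out_dir, "hubs.tsv"))
      report$stages$network_hub <- list(
        n_network_nodes = nrow(hub_res$table) / th$hub_fraction,
        n_hubs = length(hubs),
        n_submodules = length(hub_res$submodules))
    }
    if (!is.null(cfg$gmt) && !is.null(consensus)) {
      sig <- stage("enrichment", {
        coll <- read_gmt(cfg$gmt)
        filter_significant(enrich(consensus, coll), th$p_cut, th$q_cut)
      })
      write_tsv_plain(sig, file.path(cfg$out_dir, "enrichment.tsv"))
      pathway_genes <- sort(unique(unlist(strsplit(sig$hits, ","))))
      report$stages$enrichment <- list(n_significant_sets = nrow(sig),
                                       n_pathway_genes = length(pathway_genes))
    }
  }

  if (!is.null(hubs) && !is.null(pathway_genes)) {
    key <- key_target_intersection(hubs, pathway_genes)
    write_symbol_list(key, file.path(cfg$out_dir, "key_targets.txt"))
    report$stages$key_targets <- list(n = length(key), genes = key)
  }

  if (!is.null(cfg$targets_a) && !is.null(cfg$targets_b)) {
    ta <- read_symbol_list(cfg$targets_a)
    tb <- read_symbol_list(cfg$targets_b)
    ind <- indirect_targets(ta, tb)
    write_symbol_list(ind, file.path(cfg$out_dir, "indirect_targets.txt"))
    report$stages$indirect_targets <- list(n = length(ind))
    if (!is.null(cfg$background_network)) {
      prox <- stage("proximity", {
        bg <- load_scored_edges(cfg$background_network, 0)
        list(score = separation_score(bg, ta, tb),
             intermediaries = intermediary_nodes(bg, ta, tb))
      })
      res <- prox$score
      write_tsv_plain(
        data.frame(id = "targets_a_vs_b", n_a = res$norm_a, n_b = res$norm_b,
                   d_ab = res$d_ab, d_aa = res$d_aa, d_bb = res$d_bb,
                   s_ab = res$s_ab, class = res$classification,
                   dropped = paste(res$dropped, collapse = ","),
                   unreachable_pairs = res$unreachable_pairs),
        file.path(cfg$out_dir, "proximity.tsv"))
      write_symbol_list(prox$intermediaries,
                        file.path(cfg$out_dir, "intermediary_nodes.txt"))
      report$stages$proximity <- list(
        s_ab = res$s_ab, d_ab = res$d_ab, d_aa = res$d_aa, d_bb = res$d_bb,
        classification = res$classification,
        n_intermediaries = length(prox$intermediaries))
    }
  }

  if (!is.null(cfg$docking_table)) {
    dt <- stage("docking", read_docking_table(cfg$docking_table))
    ranked <- lapply(setNames(nm = sort(unique(dt$receptor))),
                     function(r) rank_ligands(dt, r))
    report$stages$docking <- list(n_rows = nrow(dt),
                                  best_ligand = lapply(ranked, `[`, 1L))
  }

  validate_report(report)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

validate_report <- function(report) {
  need <- c("report_version", "package_version", "seed", "thresholds", "stages")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stopf("run report missing field(s): %s", paste(miss, collapse = ", "))
  if (!identical(report$report_version, REPORT_SCHEMA_VERSION))
    stopf("unknown report schema version")
  invisible(TRUE)
}
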