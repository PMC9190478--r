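# netpharm

Network-pharmacology target discovery in R: from case/control expression
data to a quantitative answer to the question *"do this molecule's direct
targets sit close enough to the disease's treatment targets, on the human
interactome, to regulate them?"*

The package grew out of a rheumatoid-arthritis (RA) case study in which
dioscin's four direct targets (CCL5, CXCL10, CXCR2, IL2) were shown to be
network-proximal to the 23 clinically established RA treatment targets.
It packages the full computational chain as tested, reusable stages:

1. **Consensus DEG screening** — per-dataset differential expression with
   an empirical-Bayes moderated t-statistic (pooled variance shrunk
   towards a moments-estimated prior), screened at |log2 FC| > 1.0 and
   BH-adjusted p < 0.05, then a two-of-three consensus across datasets.
2. **Hub identification** — a PPI subnetwork is built from a scored
   (STRING-style) edge list at combined score ≥ 0.7, and nodes are
   ranked by maximal clique centrality,
   MCC(v) = Σ<sub>C ∋ v</sub> (|C| − 1)! over maximal cliques C, with
   the top 10 % kept as hubs and decomposed into submodules.
3. **Enrichment** — hypergeometric over-representation analysis against
   GMT gene-set collections, with BH-adjusted p and Storey q-values,
   filtered at p < 0.05 and q < 0.05; key targets are the intersection
   of the hubs with the enriched-pathway genes.
4. **Interactome proximity** — the separation score

   S<sub>AB</sub> = ⟨d<sub>AB</sub>⟩ − (⟨d<sub>AA</sub>⟩ + ⟨d<sub>BB</sub>⟩)/2

   where ⟨d<sub>AB</sub>⟩ is the mean shortest-path length over all
   ordered pairs (a ∈ A, b ∈ B) on the background interactome and the
   within-set terms average distinct pairs. S<sub>AB</sub> < 0 calls the
   molecule's target set *proximal* to the disease set (positioned to
   regulate it); S<sub>AB</sub> ≥ 0 calls it *separated*. Indirect
   targets, intermediary proteins on the connecting geodesics, and batch
   scoring of many molecules are included.

A synthetic-data module generates expression matrices with planted
log2 fold-changes and scale-free interactomes with planted
proximal/separated target-set pairs, and the RA study's printed gene
lists (27 hubs, 30 pathway genes, 23 clinical targets, 4 direct targets)
and 20-row docking table ship as plain-text fixtures — so everything
runs and is testable without a download.

## Worked example

```r
library(netpharm)

# key targets: hubs ∩ enriched-pathway genes, on the bundled study lists
fx  <- load_fixtures()
key <- key_target_intersection(fx$hub27, fx$pathway30)
key
#> [1] "CCL5"   "CXCL10" "CXCL11" "CXCL6"  "CXCL9"
```

The five chemokines are the genes that are simultaneously topologically
central in the disease PPI network and members of RA-associated
pathways — the study's candidate receptors for docking.

```r
# proximity of a planted-proximal target pair on a synthetic interactome
g <- simulate_interactome(1000, 2, seed = 42)
p <- plant_target_sets(g, 4, 8, "proximal", seed = 1)
separation_score(g, p$a, p$b)
#> S_AB = -0.551 (proximal): <d_AB> = 3.188, <d_AA> = 3.833, <d_BB> = 3.643; ||A|| = 4, ||B|| = 8
```

The cross-set distances (3.19 hops on average) are shorter than the
within-set averages, so S<sub>AB</sub> < 0: the two sets overlap in
network space and the planted "proximal" label is recovered.

```r
# docking-table ingestion: best CCL5 binders, most negative affinity first
rank_ligands(fx$docking_table, "CCL5", top_k = 3)
#> [1] "Ginsenoside Re" "Asiaticoside"   "Ergotamine"

# indirect targets: clinical set minus direct targets (IL2 is in both)
length(indirect_targets(fx$dioscin4, fx$clinical23))
#> [1] 22
```

`run_pipeline()` chains every stage from a single YAML/list config and
writes per-stage TSVs plus a versioned JSON run report; a thin CLI over
the same functions is at `inst/cli/netpharm.R`.

## Scope

ADMET prediction, the docking computation itself (PDB/PDBQT handling),
and web target-prediction services are out of scope: docking scores and
predicted target lists enter as files. See `vignettes/methods.Rmd` for
the model details, conventions (self-pairs in ⟨d_AB⟩, tie-breaking,
unreachable-pair handling) and limitations.
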