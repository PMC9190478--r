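---
title: "Methods: consensus DEGs, MCC hubs, enrichment and interactome proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus DEGs, MCC hubs, enrichment and interactome proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

netpharm implements a network-pharmacology target-discovery chain for a
disease (the bundled case study is rheumatoid arthritis, RA): screen
differentially expressed genes (DEGs) from several case/control
expression sets, find hub proteins in the DEG interaction network,
intersect them with enriched-pathway genes to nominate key targets, and
quantify whether a candidate molecule's direct targets are positioned on
the human interactome to regulate the disease's established treatment
targets. This vignette documents the statistical models, the
conventions that change the numbers, and what the bundled synthetic
data can and cannot show.

## Differential expression

Each dataset is a genes-by-samples matrix of log2 intensities with
case/control labels (series-matrix or plain TSV input; probe-level data
are collapsed to one row per symbol, keeping the probe with the highest
mean expression, the common convention for array re-analysis). For gene
$g$ with group sizes $n_1, n_2$:

$$\mathrm{log_2FC}_g = \bar y_{g,\mathrm{case}} - \bar y_{g,\mathrm{control}}, \qquad
s_g^2 = \frac{(n_1-1)v_{g1} + (n_2-1)v_{g2}}{d}, \quad d = n_1+n_2-2.$$

The per-gene variances are unstable at microarray sample sizes, so they
are shrunk towards a common prior: assuming $s_g^2 \mid \sigma_g^2 \sim
\sigma_g^2 \chi^2_d / d$ and $1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0
s_0^2)$, the posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and $t_g = \mathrm{log_2FC}_g \big/ \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$
is referred to $t_{d_0+d}$. The hyperparameters $(d_0, s_0^2)$ are
estimated by moments on the log sample variances: under the model,
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ has variance $\psi'(d_0/2) +
\psi'(d/2)$, so $d_0$ is obtained by inverting the trigamma function on
$\mathrm{var}(e) - \psi'(d/2)$ (Newton iteration) and $s_0^2$ from the
mean of $e$. When the observed spread is no larger than the sampling
spread the prior df is infinite and all genes share one variance. The
test suite verifies this implementation against the installed `limma`
to 1e-10 and, with shrinkage disabled (`prior_df = 0`), against the
ordinary pooled two-sample t.

Numerical choices: sample variances are floored at $10^{-8}$ before
shrinkage so constant genes give $t = 0, p = 1$ rather than a division
by zero; p-values are two-sided; adjustment is Benjamini–Hochberg over
all genes in the dataset. A `method = "welch"` switch provides a plain
Welch t (Satterthwaite df) for users who prefer no pooling and no
shrinkage.

**Screening and consensus.** A gene is called up when
$\mathrm{log_2FC} > 1.0$ *and* adjusted $p < 0.05$ (down symmetric);
both inequalities are strict, so a fold change of exactly 1.0 is
excluded. The disease gene set is the *consensus*: genes differentially
expressed in at least $k = 2$ of the input datasets, counting a gene
once per dataset regardless of direction (a gene up in one set and down
in another stays in, flagged by its per-dataset records — dropping such
conflicts would silently discard reproducible signal of uncertain
sign). $k=1$ gives the union and $k=$ number of datasets the
intersection, which the tests assert.

## Hub identification

The consensus genes are taken into a PPI subnetwork from a scored edge
list. STRING files store combined confidence as integers 0–1000, so
scores above 1 are divided by 1000; the threshold comparison is
inclusive ($\ge 0.7$ keeps a combined score of exactly 700, matching
STRING's own convention for "0.7"). Self-loops and duplicate edges are
removed; direction is ignored.

Maximal clique centrality scores each node by
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over the *maximal* cliques
$C$ of the graph, enumerated exactly with the pivoted Bron–Kerbosch
algorithm. On triangle-free graphs each edge is a maximal clique and
MCC reduces to degree; on $K_n$ every node scores $(n-1)!$; an isolated
node is its own maximal clique and scores $0! = 1$ (the convention for
edgeless nodes is not observable in the reference tool, so it is simply
documented here). Enumeration is worst-case exponential, so it runs
under configurable node- and clique-count budgets and aborts with a
clear error instead of hanging.

Hubs are the top $\lceil 0.10 \cdot n \rceil$ nodes — ceiling, so a
267-node network yields 27 hubs. Ties are broken by degree (descending)
then symbol (ascending); the reference tool's internal tie order is
undocumented, so this rule is our own and is stated in the output.
Submodules are the connected components (size ≥ 2) of the hub-induced
subgraph — the minimal reading of "divided into submodules with high
internal connections".

## Enrichment and key targets

Over-representation of a query set in gene set $S$ is the
hypergeometric upper tail $P(X \ge k)$ with universe size $N$, set size
$K$, query size $n$ and overlap $k$ — identical to the one-sided Fisher
exact test, which the suite checks to 1e-12 on random tables. The
universe defaults to the union of all collection members because an
organism-wide annotation background is a moving target offline; an
explicit background file can be supplied. Sets with zero overlap are
not tested and do not enter the BH denominator (standard ORA practice;
this makes adjusted p-values slightly smaller than testing everything).
Both BH-adjusted p and Storey q-values are reported; the q-value uses
the $\lambda$ grid 0.05–0.95 with a df-3 spline for $\pi_0$ and falls
back to BH when the estimate is unstable or $\ge 1$ (small collections
almost always take the fallback). Significance is $p < 0.05$ *and*
$q < 0.05$, strict.

Key targets are the case-insensitive intersection of the hub symbols
with the enriched-pathway genes; on the bundled study lists this yields
the five chemokines CCL5, CXCL10, CXCL11, CXCL6, CXCL9.

## Interactome proximity

For a molecule target set $A$ and disease target set $B$ on a
background interactome:

$$\langle d_{AB}\rangle = \frac{1}{\|A\|\,\|B\|}\sum_{a\in A,\,b\in B} d(a,b),
\qquad S_{AB} = \langle d_{AB}\rangle - \frac{\langle d_{AA}\rangle + \langle d_{BB}\rangle}{2},$$

with $d(\cdot,\cdot)$ the unweighted shortest-path hop count (edge
confidence is deliberately ignored in distances). $S_{AB} < 0$
(strict) classifies $A$ as *proximal* to $B$ — its targets sit inside
$B$'s network neighbourhood and can plausibly regulate it; $S_{AB} \ge
0$ classifies them *separated*.

Conventions that materially change the value:

* $\langle d_{AB}\rangle$ runs over **all ordered pairs including
  self-pairs** $d(a,a)=0$ when $A \cap B \neq \emptyset$. The sum in
  the definition is over all $a, b$, and overlapping sets genuinely
  occur — in the case study IL2 is both a direct target and a clinical
  target — so the zeros are part of the statistic, and they lower
  $\langle d_{AB}\rangle$.
* $\langle d_{AA}\rangle, \langle d_{BB}\rangle$ average **distinct
  unordered pairs**; a singleton set contributes 0. A consequence worth
  knowing: for singletons $A=\{a\}, B=\{b\}$, $S_{AB} = d(a,b) \ge 0$,
  so singleton pairs can never be called proximal.
* Pairs in different components are excluded from numerator and
  denominator (count reported) rather than set to $\infty$ or handled
  by restricting to the largest component; symbols absent from the
  network are dropped and listed.
* An $S_{AB} = 0$ tie is classified separated (the call is strict).

$S_{AB}$ is exactly symmetric in $A$ and $B$, which the suite asserts
on 100 random instances alongside a Floyd–Warshall distance oracle.

*Indirect targets* are $B \setminus A$ (the clinical targets reachable
only through the network; 22 of the 23 RA targets, since IL2 is shared).
*Intermediary proteins* are the union over pairs $(a, b)$ of interior
nodes of **all** shortest $a\!-\!b$ paths, minus $A \cup B$, computed
by the geodesic criterion $d(a,v) + d(v,b) = d(a,b)$ on BFS distance
maps; counting only one geodesic per pair, or first neighbours, are
alternative readings that give different counts, which is why the
reference count of 54 intermediaries for the dioscin case is treated as
descriptive, not as a check. `batch_separation()` scores many molecules
against one disease set with the BFS maps shared across pairs; per-pair
failures are collected into the summary rather than aborting the batch.

The case study's own headline numbers — $S_{AB} = -1.16$ with
$\langle d_{AB}\rangle = 2.85$, $\langle d_{AA}\rangle = 4.62$,
$\langle d_{BB}\rangle = 3.40$ for dioscin's four targets against the
23 clinical RA targets — were computed on a specific published human
interactome that is not redistributable here and whose exact
version/edge set the score is sensitive to. They are reproducible with
this package by loading that network with `load_scored_edges()` and
calling `separation_score()`; offline, the sign logic and distance
machinery are validated on toy graphs with hand-computed answers and on
planted synthetic pairs instead.

An optional degree-preserving permutation null (z-score of $S_{AB}$
over shuffled target sets) was considered and left out: the decision
rule of record is the raw sign, and a null model would change the
question being asked.

## Synthetic data: what it emulates and what it does not

`simulate_expression()` draws per-gene baselines uniform on log2
intensities 4–12 with i.i.d. Gaussian noise on the log2 scale
(matching the normality-after-preprocessing assumption the moderated t
itself makes), and shifts the case mean of the first `n_de` genes by
$\pm$`lfc` with deterministically alternating signs so up/down counts
are exactly predictable. Defaults (`lfc = 2`, `sigma = 0.5`,
10 vs 10 samples) represent a strong, clean microarray effect: at these
settings the two-sample t has essentially full power, so the pipeline's
recovery targets (sensitivity ≥ 0.95, false-discovery proportion
≤ 0.10, null raw-p rate 0.05 ± 0.02) test the plumbing and calibration,
not the statistical frontier. The generator does not emulate probe
artefacts, batch effects, correlated genes or RNA-seq counts — passing
on it shows the chain is correct, not that it is robust to real-world
confounding.

`simulate_interactome()` is Barabási–Albert preferential attachment
(default attachment 2): connected, simple, heavy-tailed like the human
interactome, and hub-dominated, which stresses the shortest-path code.
The real background network's size and degree sequence are not
characterised in the source material, so these defaults are stated
assumptions, not a calibration.

`plant_target_sets()` constructs pairs of known class. *Proximal*: $A$
is a uniform node sample and $B$ is drawn from the closed 2-hop
neighbourhood of $A$ with about half of $B$ taken from $A$ itself —
mirroring the overlapping-target situation the score was designed for;
the shared members and short cross distances force
$\langle d_{AB}\rangle$ below the within-set averages. *Separated*: $A$
is a compact cluster around a low-degree centre (keeping hubs out of
$A$, since a hub in $A$ puts everything within ~3 hops) and $B$ is
sampled from nodes ≥ 4 hops from every member of $A$ — the margin
"≥ 4" sits safely above typical within-set distances (≈ 3.4 on the
real network) — falling back with a warning to maximal-distance nodes
on graphs too small to satisfy it. Default sizes 4 and 8 are the
smallest that keep the class signal comfortably away from the
singleton degeneracy noted above. Over 100 seeds at defaults on a
1000-node interactome, the sign of $S_{AB}$ recovers the intended
class in ≥ 95 % of draws (in practice 100 %), which is what the
acceptance script re-measures.

## Pipeline

`run_pipeline()` executes DEG → consensus → hubs → enrichment → key
targets → proximity from one config (YAML or list), writes each
intermediate table in the format its consuming module reads back
(round-tripping is tested), and emits a versioned JSON report with the
counts at every stage, the thresholds and the seed. All threshold
defaults equal the case study's printed choices (|log2 FC| > 1.0,
adj. p < 0.05, combined score 0.7, top 10 %, p and q < 0.05, k = 2).
Docking scores and predicted target lists are ingested as files, never
computed: keeping the external tools out keeps every result
reproducible from text inputs. A `fixtures_only` mode runs the bundled
study lists through the set-algebra stages, which is also how the
package's worked examples reproduce the 5 key targets and 22 indirect
targets. Test-suite and acceptance problem sizes (≤ 2000 genes,
1000-node interactomes, 100-seed Monte-Carlos) were chosen to keep a
full run in the low minutes on one CPU while leaving the Monte-Carlo
margins far from their thresholds.

## Known limitations

* The per-dataset DEG counts of the original study depend on an
  unspecified preprocessing step, and its enriched-term counts on
  annotation-database versions; neither is a package-level check.
* MCC enumeration is exponential in the worst case; the budgets make
  this an explicit error, not a silent hang.
* The Storey q-value needs a reasonably large collection; small GMT
  files will silently use the BH fallback (both columns are always
  reported).
* Distances ignore edge weights by design; a confidence-weighted
  variant would change both the distances and the decision boundary.
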