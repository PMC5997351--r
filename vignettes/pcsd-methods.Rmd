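---
title: "Scoring protein essentiality from complex participation and subgraph density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein essentiality from complex participation and subgraph density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsd)
```

## The problem

Essential proteins are those a cell cannot grow or reproduce without.
Knockout screens identify them directly but are slow and expensive, so a
long line of methods instead ranks the proteins of a protein–protein
interaction (PPI) network by a computed centrality and treats the top of
the ranking as candidate essentials.  Purely topological centralities
ignore two well-established biological signals: essential proteins
cluster in protein complexes (and multi-complex proteins are more often
essential), and high-throughput PPI data contain many false positive
interactions that never co-occur in time.  The score implemented here
combines both signals.

## The model

### Refinement: deleting never-co-expressed interactions

Each gene's expression time course (36 points spanning three metabolic
cycles in the yeast compendium this emulates) defines a per-gene
activity threshold by a damped three-sigma rule:

$$thr(g) = \mu_g + k\,\sigma_g\left(1 - \frac{1}{1+\sigma_g^2}\right),
\qquad k = 3,$$

where $\mu_g$ and $\sigma_g$ are the mean and standard deviation of the
gene's curve.  A gene is *active* at a time point when its expression is
greater than or equal to its threshold; the damping factor
$1-1/(1+\sigma^2)$ pulls the threshold toward the mean for flat
low-variance curves, so housekeeping-like genes are not declared
permanently inactive.  An interaction is kept only if its two endpoint
genes are active at at least one common time point; the result is the
refined network (RPIN).  The node set is preserved, so proteins isolated
by refinement still appear in the ranking.

Two conventions here are genuinely open and are exposed as arguments:

* $\sigma$ is the *sample* standard deviation (`stats::sd`); with 36
  points the difference from the population form is below 1.5% of
  $\sigma$ and does not change which comparisons the package makes.
  The multiplier $k$ defaults to 3 (`sigma_multiplier`).
* Interactions with an endpoint missing from the expression matrix are
  deleted — such a pair can never be observed co-expressed.  In the
  yeast benchmarks expression covers 97–99% of proteins, so the choice
  affects few edges; `keep_missing_expression = TRUE` inverts it for
  sensitivity analysis (kept edges then get the neutral co-expression
  similarity 0.5 during weighting).

### Weighting: edge clustering × co-expression

Every surviving interaction $(i,j)$ is weighted

$$W_{ij} = ECC_{ij} \times \frac{PCC_{ij}+1}{2}, \qquad
ECC_{ij} = \frac{Z_{ij}+1}{\min(d_i, d_j)},$$

where $Z_{ij}$ is the number of triangles through the edge, $d_i$ the
endpoint degrees **in the refined network** (the pipeline operates on
the RPIN throughout), and $PCC$ the Pearson correlation of the two
expression curves over all time points (no masking to active points —
the correlation is defined over the full series).  $ECC \in (0,1]$ on a
simple graph and the rescaled correlation lies in $[0,1]$, so
$W \in [0,1]$.  A zero-variance curve has an undefined correlation; the
raw value is taken as 0 (rescaled 0.5), recording the absence of
evidence rather than propagating `NaN`.

### Participation degree in complexes (PC)

With a catalogue of known complexes, a protein contained in complexes
scores, for each complex it belongs to, its weighted degree restricted
to co-members of that complex, summed over its complexes:

$$PC(v) = \sum_{C \ni v} \; \sum_{u \in N(v) \cap C} W_{vu}.$$

An interaction shared with a partner that co-occurs in $k$ common
complexes is counted $k$ times — this is the literal reading of the
definition and realizes the observation that multi-complex proteins are
more often essential.  A protein outside every complex participates
indirectly: it scores the summed weights of its interactions with
complexed neighbors.  Complexes never create interactions; only edges of
the weighted network contribute.

### Subgraph density (SD)

For each protein a subgraph is induced on the protein plus its direct
(level-1) and indirect (level-2) neighbors.  Each interaction inside the
subgraph is weighted by two flat set similarities,

$$SG_{ij} = \frac{|G_i \cap G_j|^2}{|G_i||G_j|}, \qquad
SC_{ij} = \frac{|C_i \cap C_j|^2}{|C_i||C_j|},$$

over GO annotation sets $G$ and complex membership sets $C$ (zero when
either set is empty; no ontology propagation or semantic similarity —
annotation sets are used as given).  The density is

$$SD(v) = \frac{2\sum_{(i,j)\in E_s}(SG_{ij}+SC_{ij})}{N_s(N_s-1)},$$

with $E_s$ the subgraph's edges and $N_s$ its vertex count including the
center.  The sum ranges over *interacting* pairs only — the score
weights the interactions of the subgraph, not all member pairs.  By
Cauchy–Schwarz $SG, SC \le 1$, hence $0 \le SD \le 2$ with the maximum
attained on a clique of identically-annotated co-complexed proteins.
Degenerate subgraphs ($N_s \le 1$) score 0 by convention.  SD is
computed on the refined topology by default, consistently with the rest
of the pipeline; `sd_on = "original"` provides the ablation.

### Combination and ranking

$$score(v) = \alpha\,PC(v) + (1-\alpha)\,SD(v), \qquad \alpha = 0.8.$$

The two components are combined raw, without normalization, exactly as
defined; PC and SD live on different scales, which is part of why the
published operating point weights PC heavily, and `alpha_sweep()` makes
the trade-off inspectable.  Ranking is descending by score with ties
broken by ascending protein identifier in byte order, so the entire
pipeline is deterministic and two runs on the same inputs produce
byte-identical score tables.

## Evaluation protocol

`evaluate_essentials()` reproduces the standard protocol against a
gold-standard essential list: counts of true essentials among the top 1,
5, 10, 15, 20 and 25 percent of ranked proteins (cutoff
`round(N * p / 100)`; the rounding convention is unstated in the
literature this follows, so `floor`/`ceil` are available), the jackknife
curve (cumulative true essentials by rank), the precision–recall curve
(precision $TP/k$, recall $TP/(TP+FN)$), and the ROC with trapezoidal
AUC.  The ROC uses the conventional orientation (false positive rate
horizontal); tied scores collapse into single thresholds so the AUC
equals the Mann–Whitney probability that a random essential protein
outscores a random non-essential one, ties counting one half — the test
suite checks this equivalence against an independent pairwise
enumeration to $10^{-9}$.  The evaluation universe is the proteins of
the fitted network; gold-standard identifiers absent from it are
excluded from the positive class.

## The synthetic study generator

`simulate_ppi_data()` produces all five inputs with known ground truth:
an Erdős–Rényi background with planted cliques, expression as a
three-cycle sinusoid (36 points) with clique members sharing a phase
plus i.i.d. Gaussian noise (sd 0.25 by default), complexes optionally
aligned with the planted cliques, GO terms drawn from a small vocabulary
with clique-biased sampling, and essential labels covering the clique
members plus a random fill to 20% of proteins — roughly the essential
fraction of the yeast interactome benchmarks.  Default sizes (50
proteins, mean degree ≈ 3) keep every stage checkable against
brute-force oracles.

What the generator emulates: sparse topology with locally dense planted
modules, periodic co-expression blocks, complex/annotation structure
correlated with those modules.  What it does not emulate: the heavy-tail
degree distribution of real interactomes, correlated false-negative
edges, GO term frequency bias, or biologically structured noise.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted structure, not predictive performance on real
interactomes.

## Numerical and design choices

* Identifiers are opaque exact-match strings; no case folding or
  synonym mapping.
* Degenerate inputs: empty edge lists warn and return an empty network;
  empty complexes are rejected; unannotated proteins have empty GO sets;
  an evaluation with no gold-standard positive in the universe is an
  error rather than a silent zero.
* `round()` (R's round-half-to-even) sizes the top-$p\%$ cutoff; at the
  benchmark network sizes the convention only matters when
  $N p/100$ lands exactly on .5.
* All randomness lives in the generator and is seed-controlled;
  identical seeds give byte-identical fixture files.
* Problem sizes in the shipped tests (fixtures of 12–50 proteins for
  oracle comparisons, one 1000-protein end-to-end run, a 500-protein
  run in the reproduction script) were chosen to keep brute-force
  oracles exact and runs quick while exercising every code path.

## Known limitations

* The two score components are not rescaled before mixing, so the
  effective meaning of $\alpha$ depends on the network's weight scale;
  compare settings with `alpha_sweep()` rather than transferring an
  $\alpha$ between data sets.
* Flat annotation overlap treats all GO terms as equally informative;
  shallow, frequent terms inflate $SG$.
* Refinement assumes the expression compendium's conditions are
  representative; interactions specific to unsampled conditions are
  deleted.

## A worked example

```{r example}
fx <- simulate_ppi_data(n_proteins = 50, n_cliques = 2, n_complexes = 6,
                        seed = 101)
fit <- pcsd(fx$network, fx$expression, fx$complexes, fx$annotations,
            alpha = 0.8)
fit
evaluate_essentials(fit, fx$essentials)
alpha_sweep(fit, fx$essentials, alphas = c(0, 0.5, 0.8, 1))
```
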