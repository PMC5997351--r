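# pcsd

Essential proteins are those an organism cannot survive or reproduce
without; finding them matters for understanding minimal cell biology and
for prioritizing drug targets.  `pcsd` ranks the proteins of a
protein–protein interaction (PPI) network by a combined essentiality
score that joins network topology with three layers of biological
evidence: gene-expression dynamics, protein-complex membership, and GO
annotation.

The score has two components, computed on a *refined* network from
which interactions whose endpoint genes are never simultaneously active
(per-gene three-sigma activity thresholds over an expression time
course) have been deleted:

- **PC — participation degree in complexes.**  Interactions are weighted
  by `W_ij = ECC_ij × (PCC_ij + 1)/2`, the edge clustering coefficient
  `ECC_ij = (Z_ij + 1)/min(d_i, d_j)` (triangles through the edge over
  the smaller endpoint degree) times rescaled Pearson co-expression.
  `PC(v)` sums, over every complex containing `v`, the weights of `v`'s
  interactions with co-members of that complex; proteins outside all
  complexes score the weights of their edges to complexed neighbors.
- **SD — subgraph density.**  On the subgraph induced by `v` and its
  first- and second-order neighbors, each interaction `(i,j)` is
  weighted by shared GO annotations `SG_ij = |G_i ∩ G_j|² / (|G_i||G_j|)`
  plus shared complexes `SC_ij = |C_i ∩ C_j|² / (|C_i||C_j|)`, and
  `SD(v) = 2 Σ (SG + SC) / (Ns (Ns − 1))`.

The final score is `α·PC + (1−α)·SD` with `α = 0.8` by default, ranked
descending with a deterministic tie-break.  The package also ships the
standard evaluation protocol (top-p% true-essential counts, jackknife
curves, precision–recall, ROC/AUC), readers for the usual plain-text
input formats, a synthetic-study generator with planted ground truth,
and a small command line wrapper (`inst/cli/pcsd.R`).

## Worked example

```r
library(pcsd)

fx  <- simulate_ppi_data(n_proteins = 50, n_cliques = 2, n_complexes = 6,
                         seed = 101)
fit <- pcsd(fx$network, fx$expression, fx$complexes, fx$annotations,
            alpha = 0.8)
fit
#> refine_network: deleted 40 of 81 interaction(s)
#> Essentiality scores (complex participation + subgraph density)
#>   proteins: 50   interactions: 81 (refined: 41, 40 deleted)
#>   alpha = 0.8
#> Top proteins:
#>     id       pc        sd     pcsd rank
#>  P0003 2.861241 0.5174603 2.392485    1
#>  P0001 2.860600 0.5174603 2.391972    2
#>  P0007 2.818921 0.5588889 2.366915    3
#>  P0005 2.815853 0.5588889 2.364460    4
#>  P0002 2.643054 0.5174603 2.217935    5

evaluate_essentials(fit, fx$essentials)
#> Essentiality evaluation over 50 proteins ( 10 gold-standard essentials )
#> True essentials in top ranked proteins:
#>  top1%  top5% top10% top15% top20% top25%
#>      0      2      5      8      8      8
#> ROC AUC: 0.96000
```

The fixture plants two co-expressed 4-cliques aligned with complexes
(`P0001`–`P0008`); they occupy the top ranks because their interactions
survive refinement with high weights and their complex participation is
maximal.  Of the 50 proteins, refinement deletes the 40 interactions
whose endpoints never peak together.  The top-1% count is 0 because
`round(50 · 1/100) = 0` proteins are selected at that cutoff; from the
top 10% on, the planted essentials dominate, and the AUC of 0.96 says a
random essential protein outranks a random non-essential one 96% of the
time.

Other entry points: `predict(fit, top = 5)` (candidate ids),
`coef(fit)` (named score vector), `plot(fit)` (PC vs SD),
`alpha_sweep(fit, essentials)` (sensitivity to the mixing parameter),
`refine_network()`, `weight_network()`, `complex_participation()`,
`subgraph_density()` for the individual stages, and
`write_fixture()` / `read_edge_list()` & co. for file I/O.

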