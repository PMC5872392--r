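# henetrw

Computational target identification for medicinal herbs. Experimentally
mapping the protein targets of an herb is slow and expensive; `henetrw`
predicts candidate targets by propagating information through a two-layer
heterogeneous network that fuses three kinds of evidence:

- an **herb layer**: herbs connected by the cosine similarity of their
  curated efficacy annotations,
- a **protein layer**: proteins connected by the cosine similarity of their
  pathway annotations,
- **herb–target links** bridging the layers (known associations).

The package is aimed at network-pharmacology researchers who have
entity–attribute association tables (herb–efficacy, protein–pathway,
herb–target, each as two-column delimited text) and want ranked candidate
targets plus the evaluation and sanity-check machinery around them.

## The model

Similarity between two entities with binary annotation sets `A_x`, `A_y` is
the cosine of their indicator vectors,

    S(x, y) = |A_x ∩ A_y| / (√|A_x| · √|A_y|).

The heterogeneous network is `I = (H, G, R)`: herb-layer weights `H` (m×m),
protein-layer weights `G` (n×n), binary herb–target adjacency `R` (m×n).
Before the walk, each layer is sparsified to the `α` (herbs) or `β`
(proteins) strongest neighbors per node, keeping an edge when either
endpoint selects it.

A random walk with restart starts from the query herb (and, when some
targets are known, from those seed targets, which receive a share `η` of the
initial mass). At each step the walker restarts at the initial distribution
`p(0)` with probability `θ`, otherwise it moves: a node with both
intra-layer neighbors and cross-layer links sends fraction `φ` of its
outgoing mass across layers (proportionally to `R`) and `1 − φ` within its
layer (proportionally to `H` or `G`); a node with only one kind of link
gives it everything. With `M` the resulting column-stochastic operator,

    p(t) = (1 − θ) · M · p(t−1) + θ · p(0)

is iterated until the L1 change drops below `ε`. The stationary
protein-layer scores, sorted descending, rank the candidate targets.

Also included:

- **PRINCE baseline** — label propagation on a PPI network from a prior
  built over the known targets of herbs efficacy-similar to the query.
- **LOOCV evaluation** — `NoTarget` (all of the query's targets held out)
  and `HalfTarget` (a random half held out, the rest used as seeds), scored
  by precision/recall/F1 at `k = |test|` and Hit@1.
- **Overlap analysis** — do herbs with similar efficacies have similar
  targets? Pair similarities binned into ten equal-width bins and compared
  with a Fisher–Yates shuffle null.
- **Shortest-path validation** — average shortest path length (ASPL) from a
  novel candidate to the query's known targets in a PPI network, against a
  10,000-replicate random-candidate null.
- **Synthetic generator** — reproducible association tables with planted
  herb/protein modules, so the whole pipeline is testable end to end.

## Worked example

```r
library(henetrw)

tabs <- generate_tables(synth_config(rng_seed = 1))
tabs$herb_target
#> <assoc_table> 40 entities x 100 attributes, 857 pairs

cfg <- walk_config(alpha = 5, beta = 10)   # kNN sizes scaled to 40 herbs / 100 proteins
res <- predict_targets(tabs$herb_efficacy, tabs$protein_pathway,
                       tabs$herb_target, "herb001", cfg = cfg)
head(res$ranking, 5)
#>   rank protein  score
#> 1    1 prot009 0.0141
#> 2    2 prot008 0.0140
#> 3    3 prot017 0.0137
#> 4    4 prot025 0.0137
#> 5    5 prot023 0.0136

cv <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
            mode = "NoTarget", cfg = cfg)
cv$aggregate
#> $n_herbs      40
#> $mean_f1      0.789
#> $sd_f1        0.0785
#> $hit_at_1_pct 85
```

`herb001` belongs to planted module 1, which is coupled to protein module 1
(`prot001`–`prot025`): the top-ranked candidates are exactly that module's
proteins, and leave-one-out NoTarget evaluation recovers held-out targets
with mean F1 0.79 and Hit@1 85% — far above the ≈0.19 F1 of a
degree-preserving link-shuffled control (see the acceptance script).

A thin command-line front end at `inst/cli/henetrw` wraps the same
functions (`synth`, `predict`, `prince` subcommands); output is a
rank/protein/score TSV.

## Real data

The three association tables this method was designed for are distributed
as spreadsheets alongside the original study (herb–target from HIT,
herb–efficacy from the Chinese pharmacopoeia, protein–pathway from KEGG).
Convert each to two-column TSV (entity TAB attribute; any spreadsheet tool
or `python -c "import pandas; ..."` one-liner works) and place them as

    data-raw/HIT_herb_target.tsv
    data-raw/CHPA_herb_efficacy.tsv
    data-raw/KEGG_protein_pathway.tsv

(or point `options(henetrw.data_dir = ...)` elsewhere). The four
reference-statistics tests in `test-acceptance.R` then run against them:
table sizes and mean degrees, layer/heterogeneous network edge counts,
overlap-analysis bin means, and the NoTarget/HalfTarget LOOCV aggregates.

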