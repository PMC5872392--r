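---
title: "Heterogeneous network propagation for herb target prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous network propagation for herb target prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(henetrw)
```

## The problem and the model

Herbal drugs act through many protein targets at once, and the curated
herb–target record is sparse. The method implemented here exploits a
guilt-by-association assumption with two halves: herbs that share curated
efficacy labels tend to share targets, and proteins that share pathway
membership tend to be targeted by the same herbs. Both halves are
empirically checkable with the package's overlap analysis (below), and both
are wired into one propagation scheme.

All similarities are cosines of binary annotation vectors. For entities
$x, y$ with annotation sets $A_x, A_y$,
$$S(x,y) = \frac{|A_x \cap A_y|}{\sqrt{|A_x|}\sqrt{|A_y|}} \in [0,1].$$
The heterogeneous network $I=(H,G,R)$ stacks an herb layer $H$
(efficacy-based similarities), a protein layer $G$ (pathway-based
similarities) and the bipartite herb–target adjacency $R$. Node sets are
unions: a herb with targets but no efficacy record still enters, reachable
only through $R$.

A random walk with restart is run from the query herb. Writing
$p^{(t)} = (u^{(t)}, v^{(t)})$ for the herb/protein probability vectors,
$$p^{(t)} = (1-\theta)\,M\,p^{(t-1)} + \theta\,p^{(0)},$$
iterated until $\lVert p^{(t)}-p^{(t-1)}\rVert_1 < \varepsilon$. Because the
map is a contraction with factor $1-\theta$, convergence is geometric and
the iteration count is bounded by roughly
$\log\varepsilon / \log(1-\theta)$; the test suite asserts this bound and
checks the iterate against the closed form
$p^\ast = \theta\,(I-(1-\theta)M)^{-1}p^{(0)}$ on small networks. Stationary
protein scores $v^{(t)}$, sorted descending with lexicographic tie-break,
rank the candidate targets.

## The transition operator

The construction of $M$ is the one place where the surrounding description
admits a single coherent reading but no displayed formula, so the package
fixes it explicitly (the standard two-layer random-walk-with-restart
construction):

- Columns of $M$ are normalized — the walker leaves each node with total
  probability one — and the update is $M p$. Row-normalized variants differ
  only by transposition conventions.
- A herb with both herb neighbors and known targets sends mass $\varphi$
  across the layer, distributed proportionally to its $R$ row, and
  $1-\varphi$ within the layer, proportionally to its $H$ column. Proteins
  behave symmetrically via $R$ columns and $G$.
- A node with only one kind of link gives that kind all its mass
  (single-kind fallback), so $\varphi$ never strands probability on nodes
  lacking cross-layer links.
- A dangling node (no links at all) redirects its mass to the restart
  vector. This keeps the effective operator stochastic and total mass at
  exactly one — an invariant asserted at every iteration in the tests.

Before $M$ is built, each layer is kNN-pruned: edge $(i,j)$ survives when
$j$ is among $i$'s top-$\alpha$ (herbs) or top-$\beta$ (proteins) neighbors
by weight *or* vice versa. The union rule keeps the layer symmetric, and
ties at the $k$-th weight are all retained, which makes pruning
deterministic and idempotent. Network summary statistics are computed on
the *unpruned* positive-similarity networks; pruning is a walk-time
confidence filter, not part of the network definition (the reported edge
counts of the reference networks are only consistent with the unpruned
reading).

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `theta` | 0.4 | restart probability; reported as the best-performing value in the reference tuning, and insensitive in the NoTarget setting |
| `phi` | 0.9 | cross-layer jump probability; larger values reported better, so the default sits at the top of the tuned grid |
| `alpha` | 20 | herb-layer kNN size; "small alpha" reported better |
| `beta` | 100 | protein-layer kNN size; "large beta" reported better |
| `epsilon` | 1e-9 | L1 convergence tolerance; not stated by the source, chosen far below any score gap that could affect a ranking |
| `eta` | 0.5 | share of initial mass on seed targets when some targets are known; the source's initial vector spans both layers without naming the split, so mass is divided evenly between the query herb and the seed set |
| `max_iter` | 10000 | safety cap; with the defaults convergence takes ~40 iterations |
| `exclude_train` | TRUE | drop retained training targets from the candidate ranking under HalfTarget; whether the reference results do this is unstated, so it is a switch rather than a constant |

For the synthetic study conditions (40 herbs, 100 proteins) the examples and
acceptance script use `alpha = 5, beta = 10` — the same "small herb-kNN,
larger protein-kNN" shape scaled to the smaller layers.

## Evaluation protocol

Leave-one-out cross-validation removes targets of one query herb at a time,
leaving all other herbs' links intact (the tests assert this isolation).
Two settings:

- **NoTarget**: every known target of the query is held out; the walk seeds
  only the query herb. The roster is restricted to herbs with at least one
  herb-layer neighbor *and* at least one known target — otherwise the
  restart vector has nothing to spread.
- **HalfTarget**: $\lfloor k/2 \rfloor$ of the $k$ known targets are held
  out (odd $k$ is not covered by the reference's even examples; the floor
  makes the train side larger); the rest seed the protein layer. Requires
  $k \ge 2$. One RNG stream per run draws all splits; a `repeats` argument
  averages aggregates over several split seeds.

With $k=|{\rm test}|$ predictions, TP the number of held-out targets in the
top-$k$, precision $={\rm TP}/k$, recall $={\rm TP}/|{\rm test}|$ and F1
their harmonic mean coincide — an algebraic identity the tests assert on
every record. F1 is defined as 0 when TP $=0$ (the $0/0$ case); this
convention matters because a large fraction of per-herb F1 scores is zero
for propagation methods on sparse networks. Hit@1 is the percentage of
query herbs whose top-ranked candidate is a held-out target.

## PRINCE baseline

The comparison method propagates a prior over a protein–protein interaction
network: $F^{(t)} = \lambda W' F^{(t-1)} + (1-\lambda) Y$ with $W'$ the
degree-symmetric normalization $D^{-1/2} W D^{-1/2}$ and mixing weight
$\lambda \in (0,1)$ (default 0.5; the value used by the reference
comparison is unstated). The prior of a protein is the *maximum* similarity
$S(q,h)$ over herbs $h \ne q$ that are known to target it, normalized to
sum one — best single piece of evidence rather than accumulated evidence,
following the cited formulation of the baseline. PRINCE is verified by
closed-form oracle equivalence and limiting cases only: its PPI input is an
external resource, so no numeric reproduction of the published baseline
rows is attempted.

## Overlap analysis

All unordered entity pairs are placed into ten equal-*width* bins
$[0,0.1),\dots,[0.9,1.0]$ by one similarity (e.g. efficacy-based), and the
mean of the other similarity (e.g. target-based) is reported per bin.
"Equal size" is read as equal width — the reference figure labels its bins
by intervals — and the last bin is right-closed. Zero-similarity pairs fall
in the first bin by default; because the reference herb analysis reports
bins starting at 0.1, a `min_sim` filter is available to drop them. The
null keeps the binning similarity fixed and redraws each entity's second
annotation set uniformly (Fisher–Yates) at its original size from the full
attribute universe, 100 replicates by default; bin membership never changes
across replicates, so observed and null bins are exactly comparable.

## Shortest-path validation

A novel candidate $t$ is compared against a herb's known target set $S$ in
a PPI network by
$${\rm ASPL}(t,S) = \frac{1}{|S|}\sum_{s\in S} {\rm SPL}(t,s),$$
with unweighted breadth-first path lengths. Known targets absent from the
PPI are dropped with a warning; pairs in different components are excluded
from the mean and counted rather than poisoning it with infinities. The
null draws a uniformly random PPI node per replicate (10,000 by default)
and pools the SPL distribution.

## The synthetic generator

`generate_tables()` plants the structure the method assumes: herb modules
sharing an efficacy repertoire, protein modules sharing pathways, and
herb–target links concentrated between coupled modules. Defaults — 4 herb
modules × 10 herbs with 5 efficacies each, 4 protein modules × 25 proteins
with 5 pathways each, within-module link probability 0.8 over a 0.02
background, identity coupling, and at least one link guaranteed per entity
— give each herb ≈20 targets, the order of magnitude of a well-annotated
real herb, while keeping a full LOOCV run under a minute. These sizes are
the package's study conditions throughout the tests and the acceptance
script.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real curated tables, herbs annotated in only one table
(every synthetic herb has both efficacies and targets), polysemous efficacy
vocabularies, and any correlation structure beyond block modules. Passing
tests on synthetic data therefore demonstrate that the machinery recovers
planted signal and beats a degree-preserving link-shuffled control — not
that real-data performance figures are reproduced. The real-data checks
live in `test-acceptance.R` and activate when the converted supplementary
tables are supplied (see the README).

## Numerical choices and degenerate inputs

- Sparse incidence products (`Matrix`) compute all similarities; co-member
  counts are integers, so the diagonal is pinned to exactly 1 for annotated
  entities.
- Ranking ties break lexicographically by protein id — deterministic across
  platforms.
- An unannotated entity gets a zero similarity row (flagged, not fatal); a
  query herb with no links at all triggers a warning and returns the
  restart vector itself.
- A ranking shorter than $k$ (possible when training targets are excluded
  from a small candidate set) is padded with misses and flagged.
- A zero PRINCE prior (no efficacy-similar herbs) returns an empty, flagged
  ranking and scores 0 — the robustness gap between the baseline and the
  heterogeneous walk that motivates the latter.

## Known limitations

- Single-herb queries only; formula-level (multi-herb) prediction is out of
  scope.
- Similarities are unweighted set cosines; graded annotations and semantic
  similarity of labels are not modeled.
- The exact $\varphi$, $\alpha$, $\beta$ behind the published performance
  tables are not printed in the source; the defaults follow its qualitative
  tuning guidance, and the real-data evaluation tests carry tolerances wide
  enough to absorb that uncertainty.
- The heterogeneous node total reported by the source (6716) differs by one
  from the reconstructable union of the four id sets; node totals are
  treated as approximate and edge totals as exact.
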