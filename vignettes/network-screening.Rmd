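---
title: "Screening a protein-interaction network for latent disease genes"
author: "NetScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a protein-interaction network for latent disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetScreen)
```

# The problem

Many diseases have a short list of *validated* genes — genes with curated
evidence of involvement — and a much longer list of genes that contribute but
have not yet been observed to. Because interacting proteins tend to share
function, the network neighbourhood of the validated genes is a natural place
to look for the missing ones. NetScreen implements a guilt-by-association
screen over a weighted protein-protein interaction (PPI) network: a random
walk with restart ranks every gene by network proximity to the validated
set, and three successive filters remove genes whose high rank is explained
by topology, weak interaction evidence, or functional dissimilarity.

The design follows the protocol used for disease-gene discovery on
STRING-style networks: gene identifiers are opaque strings (Ensembl peptide
IDs in real data), edges carry integer confidence scores from 1 to 999, and
a score of 900 or more marks the highest-confidence tier.

# The model

## Random walk with restart

Given the column-stochastic transition operator $A$ of the network, with
entry $A_{ij} = Q(i,j) / \sum_k Q(k,j)$ (a walker at $j$ follows each edge in
proportion to its confidence $Q$), and a seed distribution $P_0$ that puts
$1/k$ on each of the $k$ validated genes, the walk iterates

$$P_{t+1} = (1 - r)\,A P_t + r P_0$$

until $\lVert P_{t+1} - P_t \rVert_{L1} < 10^{-6}$. The restart probability
$r = 0.8$ keeps most mass near the seeds, so the converged vector is a local
proximity score. Because $A$ is column-stochastic and the update is a convex
combination, every iterate is itself a probability vector; the tests verify
mass conservation at $10^{-9}$ and agreement with the closed form
$P = r\,(I - (1-r)A)^{-1} P_0$ at $10^{-8}$.

One representational point deserves a note. A "column-wise normalised
adjacency matrix" applied as a transpose is, on weighted graphs, not
mass-conserving; NetScreen uses the standard conservative convention — the
operator applied to $P_t$ is itself column-stochastic — which coincides with
the transpose form on unweighted graphs and is the only reading under which
probabilities remain probabilities.

Isolated nodes (possible after confidence filtering) receive a
self-transition column of 1, so the operator stays stochastic; they can only
carry mass if seeded. Nodes are kept in lexicographic (C-locale byte) order
throughout, so every vector, matrix and exported file is reproducible across
runs and platforms.

Genes whose converged probability is strictly greater than $10^{-5}$ and
which are not seeds themselves become the *raw candidates*.

## Stage 1: permutation Z-score

A gene can rank high simply because of where it sits in the network (a hub,
or a neighbour of hubs). To control for this, the walk is repeated for
`nPermutations` (default 1000) random seed sets of the same size $k$, drawn
uniformly without replacement from all network nodes, and each candidate $g$
is standardised:

$$Z(g) = \frac{P(g) - PM(g)}{PSTD(g)}$$

where $PM$ and $PSTD$ are the mean and standard deviation of $g$'s
probabilities across the random sets. Candidates with $Z > 1.96$ survive
(strict inequality).

**Null statistics and self-exclusion.** When the random sets are drawn from
all nodes, a candidate lands in its own null seed set in roughly $k/n$ of the
draws, and in those draws it holds the restart mass $r/k$ — orders of
magnitude above any diffusion value. Averaging over *all* draws therefore
inflates $PSTD$ to the point where no candidate, however strongly connected
to the seeds, can reach $Z = 1.96$; published per-gene Z-scores in this
protocol (2–5 at probabilities near $10^{-4}$ on a $\sim$19,000-node
network) are only arithmetically reachable if the candidate's own seeded
draws do not enter its null. NetScreen therefore computes each candidate's
$PM$ and $PSTD$ over the draws *not* containing it (`selfExclude = TRUE`,
the default; the literal all-draws convention remains available as a
switch). With 1000 draws and $k/n \ll 1$ this discards a few draws per gene.

$PSTD$ uses the population (denominator $n$) convention by default,
switchable to $n-1$; at 1000 permutations the difference is negligible. A
degenerate $PSTD = 0$ yields $Z = \pm\infty$ by the sign of the numerator
(0 when the numerator is also 0) and is logged.

**Calibration.** `calibrateNull()` measures how often null-on-null Z-scores
exceed 1.96: a bank of random-seed walks defines the per-gene null, further
independent random-seed walks play the role of observations. Under the fully
exchangeable convention (all draws, all genes pooled) the exceedance rate
sits near the seed-inclusion probability $k/n$; this is the figure the
acceptance battery checks against the interval $[0.010, 0.045]$. Under the
operational convention (self-excluded nulls, non-seed genes only) the rate
is somewhat higher than the nominal 0.025 because diffusion scores are
right-skewed — the 1.96 cutoff should be read as a screening heuristic, not
a calibrated 2.5% test. Both conventions are exposed so users can measure
either on their own network.

## Stage 2: maximum association score

$$\mathrm{MAS}(g) = \max\{\,Q(g, g') : g' \text{ validated}\,\}$$

the candidate's strongest direct interaction with any validated gene, with 0
when it has none. The default cutoff 900 is *inclusive*: 900 is the lower
bound of STRING's highest-confidence tier.

## Stage 3: maximum function score

For every gene $g$ still in play (and every validated gene), the
neighbourhood $\{g\} \cup \{\text{direct interactors of } g\}$ is tested for
over-representation of each functional term in the corpus with a one-sided
hypergeometric tail, and the values $-\log_{10} p$ are collected into the
enrichment vector $V(g)$. Functional similarity between genes is the cosine

$$\Lambda(g, g') = \frac{V(g) \cdot V(g')}{\lVert V(g)\rVert\,\lVert V(g')\rVert}
\in [0, 1],$$

defined as 0 when either norm vanishes, and

$$\mathrm{MFS}(g) = \max\{\,\Lambda(g, g') : g' \text{ validated}\,\}.$$

The MFS cutoff is disease-specific (published screens used 0.9 and 0.96);
the package default is 0.9, inclusive. Tail probabilities are computed in
log space via `phyper(log.p = TRUE)` and capped at $-\log_{10} p = 300$ so
extreme enrichments cannot overflow; the test suite checks the kernel
against exact rational enumeration for every parameter combination with a
universe of at most 12 genes.

## Final characterisation

Surviving "putative" genes are tested for over-represented terms with the
classic per-term hypergeometric test at raw $p < 0.001$ (strict), grouped by
namespace (BP/CC/MF). No graph decorrelation is applied and gene-to-term
ancestry is not propagated: the corpus is taken as given, so p-values match
the "classic" algorithm of GO tools rather than decorrelating variants, and
term counts from annotation-aware tools will differ. No multiple-testing
correction is applied, matching the protocol's fixed raw-p cutoff. A
reporting cutoff of 1 is treated as "return every term". The
putative-versus-validated confidence matrix (the data behind the usual
heat-map figure) is exported as TSV; rendering is out of scope.

# Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.8 | teleport probability; high values keep mass near seeds |
| `tol` | 1e-6 | L1 convergence tolerance of the walk |
| `candidateCutoff` | 1e-5 | raw-candidate probability cutoff (strict) |
| `nPermutations` | 1000 | random seed sets for the Z-score |
| `zCutoff` | 1.96 | permutation filter (strict) |
| `masCutoff` | 900 | association filter (inclusive), in [1, 999] |
| `mfsCutoff` | 0.9 | function filter (inclusive), in [0, 1] |
| `goPCutoff` | 0.001 | over-representation reporting threshold (strict) |
| `universe` | all nodes | hypergeometric background, configurable |
| `seed` | — | single integer driving all permutation draws |

Permutation draw $i$ uses an RNG stream derived deterministically from the
single base seed and $i$, so individual draws are reproducible in isolation
and the whole pipeline is byte-deterministic: running `screenGenes()` twice
with the same seed produces identical TSV exports.

# The synthetic benchmark

Real inputs (a STRING links file, a curated disease-gene list, a GO/KEGG
corpus) are large, versioned and licensed, so the package ships a generator
that emulates their statistical structure instead:

* **background topology** — preferential attachment (`attachment = 2`,
  mean degree near 4), giving the heavy right tail of PPI degree
  distributions; on 500 background genes the maximum degree exceeds five
  times the median, which the tests assert;
* **planted disease module** — `moduleSize = 20` extra genes wired as a
  near-clique (pair probability 0.9) with confidences in 900–999, each
  anchored to one random background gene at background confidence
  (150–700); the graph is bridged into one component if needed;
* **seed/latent split** — `ceiling(seedFraction × moduleSize)` module genes
  (default half) become the validated seeds handed to the pipeline; the
  rest are the latent targets the screen should recover;
* **annotation corpus** — `nTerms = 60` terms cycling BP/CC/MF; a fraction
  `termModuleBias = 0.8` of them are module-centric (sizes 0.5–1.4 times
  the module, ~70% of members from the module, hence always
  module-majority), the rest sample 10–40 genes uniformly.

These defaults are the study conditions for the recovery benchmark: with
`syntheticSpec()` defaults (520 nodes, 10 seeds, 10 latent targets) the
acceptance battery requires the median recovery of latent targets among the
final putative genes, over 20 generator seeds at the full published
thresholds, to be at least 70%.

What the generator does **not** emulate: STRING's score calibration and
sub-score channels, the GO DAG (terms are flat sets, no ancestry), annotation
bias toward well-studied genes, and the sheer scale (19,247 proteins) of the
real network. Passing the recovery test therefore shows the cascade is
internally coherent and able to separate a genuinely wired-in module from a
scale-free background — not that any particular real-data gene list will be
recovered, which depends on database versions and annotation depth.

# Numerical and design choices

* **Node order** is lexicographic (byte order), fixed at construction; ties
  in candidate ranking are broken lexicographically after probability.
* **Duplicate edges** collapse to the maximum confidence, with the conflict
  reported; self-loops are dropped with a warning.
* **Edge filtering** (`minConfidence`) happens before the node universe is
  formed, so fully filtered nodes vanish rather than linger as isolates.
* **Strict vs inclusive cutoffs**: strictly greater for probabilities and
  Z (the published wording is "higher than" / "greater than"), inclusive
  for MAS and MFS (described as the values at which genes are selected).
* **Degenerate cases**: empty candidate sets, an unreachable Z cutoff, or an
  empty putative set propagate cleanly (empty tables, a 0-row confidence
  matrix) rather than erroring; the walk failing to converge within
  `maxIter` is an error that reports the last L1 change.
* **Problem sizes in the shipped tests** were chosen to exercise every code
  path at desk scale: 200 random graphs of up to 50 nodes for the
  linear-solve oracle, a 300-node network with 3000 walks for calibration,
  a frozen 60-node fixture with pinned stage counts for bit-stability, and
  20 runs of the 520-node benchmark for recovery.

# Limitations

* Identifier namespaces are taken as-is; mapping between Ensembl
  peptide/gene/symbol spaces is out of scope.
* The permutation null samples seed sets uniformly from all network nodes;
  if disease genes are systematically high-degree, a degree-matched null
  would be stricter. The published protocol does not specify the sampling
  frame; uniform-over-nodes is the implemented and documented choice.
* Enrichment vectors use all corpus terms with equal weight; highly
  overlapping terms are not decorrelated, which inflates cosine
  similarities between genes annotated to the same term family. The MFS
  cutoffs published for this protocol already reflect that behaviour.
* With very small seed sets ($k \le 2$) the restart mass $r/k$ dominates
  the walk and the permutation null becomes coarse; the screen is intended
  for seed lists of tens of genes.
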