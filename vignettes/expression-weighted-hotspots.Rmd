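---
title: "Expression-weighted signalling hotspots and TF compatibility: methods"
author: "SignalingHotspots authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted signalling hotspots and TF compatibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SignalingHotspots)
```

This vignette documents the model behind the package, the parameters
that matter, the numerical choices we made where the design was
genuinely open, and what the synthetic benchmark does and does not
show about real data.

## The problem

A cell's microenvironment — for a tissue stem cell, its niche —
influences cell state through many simultaneous cues. Rather than
modelling each cue explicitly, we treat the niche as a mean field that
induces *sustained* activation or inhibition of signalling pathways,
and ask two questions:

1. Which signalling intermediates carry the most sustained signal
   traffic, given the wiring of the signed interactome and the
   expression state of the cell? These are the **hotspots**.
2. Is a hotspot's predicted effect on the transcription factors that
   actually change between two conditions consistent with the observed
   directions of change? This is the **compatibility score**, read as
   the probability that the node drives the observed TF response.

Signalling is post-translational, so expression of a kinase does not by
itself prove activity. The two-stage design addresses this: stage one
finds where signal *can* flow in quantity; stage two checks whether
that flow, with its activation/inhibition signs, *explains* the TF
signature.

## The random-walk model

For one sample with expression vector $E$, the chain over the $n$
network nodes has transition probabilities

$$p_{ij} = \frac{w_{ij}}{\sum_{k \in N(i)} w_{ik}},
  \qquad w_{ij} = E_i \, E_j ,$$

for out-neighbours $j$ of $i$. Three properties motivate the product
weight (`weight = "product"`, the default):

* flux through an unexpressed node vanishes in both directions;
* after row normalisation the source term $E_i$ cancels, so $p_{ij}$ is
  node $j$'s share of the expressed out-neighbourhood — a local,
  interpretable routing rule;
* $P$ is invariant under global rescaling of $E$, so TPM, normalised
  counts, or any other non-negative scale give identical results (this
  is tested to $10^{-12}$).

`"target"` ($w_{ij} = E_j$) and `"min"` ($w_{ij} = \min(E_i, E_j)$) are
available for sensitivity analysis; all three coincide in their zeros
and are monotone in target expression.

### Dangling and zero-weight rows

Terminal TFs have no out-edges, and under single-cell dropout a node's
entire out-neighbourhood can be unexpressed. Such zero-weight rows are
replaced by the uniform row $1/n$ — the standard dangling-node
treatment in PageRank-type chains. We initially evaluated the obvious
alternative, a self-loop, and rejected it on measurement: a self-loop
makes the row an absorbing state of the damped chain, and every
absorbing state receives stationary probability at least $\beta/n
\cdot \beta^{-1} = 1/n$ from teleportation alone, regardless of
expression. Under a realistic dropout rate (0.3), nodes with small
out-degree then absorb in most cells and the intermediate ranking
measures "which nodes absorb", not "where signal flows": in our
planted-cascade benchmark the known driver fell from rank 1 (clean
bulk data) to ranks 8–39 of 42. With uniform redistribution there are
no absorbing states and the driver is recovered at rank 1–2 under the
same noise.

### Damping and uniqueness

The damped chain $P' = (1-\beta)P + (\beta/n)J$ with $\beta = 0.01$ is
ergodic on any topology, so $\pi$ exists and is unique even on
reducible or periodic graphs. $\beta$ trades off uniqueness and bias:
large $\beta$ drowns structure in the uniform component; $10^{-2}$ is
the conventional order for chains of $10^2$–$10^4$ nodes and leaves
the intermediate ranking unchanged over a decade in either direction
in our benchmark.

### Solvers

* `power` — iterate $x \leftarrow xP'$ from the uniform vector until
  the L1 change falls below `tol` ($10^{-10}$ by default; the
  convergence factor is at most $1-\beta$). Iterations and the final
  fixed-point residual are stored in the result.
* `linear` — solve $\pi P' = \pi$, $\sum_i \pi_i = 1$ directly. Exact
  to floating point, and the default in the pipeline configuration: at
  the network sizes this tool targets (hundreds of nodes) a dense
  solve per sample is faster than iterating to tight tolerance across
  hundreds of cells.
* `montecarlo` — visit frequencies of one simulated walk
  (compiled; default $10^6$ steps after a 1000-step burn-in), seeded
  explicitly and reproducible. Useful as an independent cross-check;
  agreement with `linear` is ~$10^{-3}$ L1 at $10^6$ steps.

The three agree within the tolerances asserted in the test suite
(power vs linear $10^{-8}$ L1; Monte Carlo 0.02 L1).

### Per-condition aggregation and hotspot selection

Each sample (or cell) yields its own $\pi$; the condition-level
distribution is the element-wise mean (default; median available),
renormalised, with the per-node standard deviation retained for the
heterogeneity report. Aggregating $\pi$ rather than expression keeps
per-cell structure visible to the single-cell report while the
condition call stays stable.

Hotspots are **intermediate-layer** nodes at or above the
`percentile`-th percentile (default 90) of the intermediate $\pi$
values; ties at the threshold are all included, and ordering is
deterministic (decreasing $\pi$, then node id). Receptors and TFs are
excluded from candidacy — receptors are the model's inputs and TFs its
outputs — but both are ranked within their own layers in the output,
because the receptor-layer ranking is exactly where candidate niche
factors (ligand–receptor axes) are read off.

## Compatibility scoring

For a node $v$ and signature TF $t$ with direction $d \in \{+1,-1\}$:

1. enumerate all minimum-hop directed paths $v \to t$ (truncated at
   `maxPaths = 10000` with a warning; counts can explode on dense
   graphs);
2. each path's sign is the product of its edge signs;
3. each path's contribution is
   $\Omega = \mathrm{raw} / \sum \mathrm{raw}$ with raw weight the
   geometric mean of $\pi$ over the path's interior nodes (direct
   edges have raw weight 1);
4. the score is $\sum_{\text{sign}=d} \Omega$.

The geometric mean (variant `"geometric"`) was chosen over the product
because among equal-length shortest paths it does not re-penalise
length, and over the arithmetic mean because a single unexpressed
interior node should suppress a path's contribution; `"product"` and
`"arithmetic"` are exposed for sensitivity analysis. Because $\Omega$
normalises within the pair, the up- and down-scores of any reachable
pair sum to one exactly, and flipping the signature (as done
automatically for condition B) mirrors every fully-reachable node's
mean score about $\tfrac12$.

Per-node scores average **unweighted** over the signature TFs the node
can reach. Unreachable TFs are excluded rather than scored zero: no
route is absence of evidence, whereas a zero is positive evidence of
contradiction, and conflating them would bias sparsely connected nodes
toward "inactive". Nodes reaching no signature TF report `NA`. The
activity call uses threshold 0.5 (above: active; below: inactive;
exactly 0.5: indeterminate), matching the interpretation of scores
near 0.3 as inactive and near 0.7 as active in applications of this
model family.

Signature TFs absent from the interactome are scored through
interactome TFs that regulate them via **exactly one** signed edge of
the gene-regulatory layer; the regulatory edge's sign multiplies the
path sign, and when several regulators exist the pooled path set keeps
only those through the nearest regulator(s). Longer regulatory chains
compound indirection and are out of scope.

When two conditions are compared, each condition's own $\pi$ weights
its $\Omega$ values: the contribution of a route should reflect the
expression state it is scored in.

## The synthetic benchmark

`generateScenario()` builds a layered signed network (receptors →
intermediate layers → TFs, edges between consecutive layers, 70%
activating) and plants two cascades:

* a **driver** cascade, all-activating, ending in a node wired `+` to
  two up-regulated signature TFs;
* a **decoy** cascade of identical expression whose terminal edges are
  inhibitory — sign-incompatible with the signature by construction.

Both cascade terminals additionally receive activating edges from
several upstream intermediates, making them convergence hubs like the
signalling integrators they emulate; this is what licenses the planted
truth "the driver *is* the dominant mediator" on every generated
topology rather than only when background in-degrees happen to
cooperate. Two further signature TFs live outside the interactome and
are reachable only through one signed regulatory edge (one activated
by an interactome TF, one repressed), so the regulatory-layer path is
exercised by every run.

Expression: cascade genes at `foldChange` (default 10) times the
`baseline` mean (default 5, a typical normalised count for an
expressed gene) in condition A, baseline in condition B. Bulk values
are log-normal around the mean with coefficient of variation
`noiseCv`; single-cell values are Poisson counts around a log-normally
perturbed mean, thinned by Bernoulli dropout (`dropout`, default 0.3).
Everything is reproducible from one seed (Mersenne–Twister, recorded
in the run manifest).

Default problem sizes — 60 nodes, 4 layers, 100 cells, dropout 0.3,
CV 0.2, fold-change 10 — describe a small but structured instance:
large enough for background topology to compete with the planted
signal, small enough that the recovery study (100 seeded replicates,
as run by `scripts/acceptance.R` and the test suite) completes in
minutes on one CPU.

**What passing does and does not show.** Recovery of the planted truth
demonstrates that the two-stage logic — traffic first, sign
consistency second — identifies a sustained, sign-consistent cascade
under realistic single-cell noise, and that expression alone cannot
(driver and decoy are indistinguishable by $\pi$). It does not
demonstrate performance on real interactomes, whose degree
distributions are heavy-tailed, whose sign annotations are incomplete
and sometimes wrong (contradictory database entries are resolved
conservatively toward inhibition, with a warning), or whose expression
data contain batch and cell-type structure that no log-normal/Poisson
model emulates. The benchmark is a correctness and sensitivity
instrument, not a biological validation.

## Degenerate inputs and edge behaviour

* All-zero expression for a sample is an error (`no expressed nodes`).
* Genes are matched to nodes case-insensitively; unmatched nodes get
  expression 0 (and become avoided by the walk), with a logged count.
* Duplicate expression rows are summed; missing values become 0 with a
  warning; negative values are a hard error.
* A TF catalogue entry with no incoming edge cannot sit in the TF
  layer and is kept in its inferred layer with a warning.
* A node–TF pair whose $\Omega$ weights are all zero (possible only
  with an undamped, externally supplied $\pi$) falls back to uniform
  contributions with a warning.
* An empty hotspot set is a warning, not an error; reports are emitted
  empty.

## Known limitations

* Minimum-hop paths only: longer-than-shortest routes carry no weight,
  so feedback and bypass circuitry is invisible to the compatibility
  stage (it does shape $\pi$).
* The TF signature is binary; magnitudes of differential expression
  are deliberately ignored.
* One regulatory hop at most for out-of-interactome TFs.
* The mean-field premise — sustained, time-invariant pathway
  activation — is the modelling assumption that makes a stationary
  distribution meaningful; transient or oscillatory signalling is out
  of scope.
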