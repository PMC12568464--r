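---
title: "Degree-based topological indices and edge-entropy of fractal molecular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and edge-entropy of fractal molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoEntropy)
```

## The model

A molecular graph is the hydrogen-suppressed heavy-atom skeleton of a
molecule: vertices are atoms, edges are bonds, and all chemical labels are
discarded.  Every index this package computes is *edge-additive in the
endpoint degrees*: for an edge $e = pq$ with endpoint degrees $d_p$, $d_q$,
define the product and sum weights

$$w^*(e) = d_p d_q, \qquad w^+(e) = d_p + d_q,$$

and a per-edge contribution $j_e$ depending only on these.  The ten
supported contributions are the classical QSPR descriptors: first and
second Zagreb ($w^+$, $w^*$), general Randić ($(w^*)^\alpha$) and Randić
($\alpha = -1/2$), hyper-Zagreb ($(w^+)^2$), sum-connectivity
($(w^+)^{-1/2}$) and general sum-connectivity ($(w^+)^\alpha$),
geometric–arithmetic ($2\sqrt{w^*}/w^+$), atom–bond connectivity
($\sqrt{(w^+ - 2)/w^*}$), and harmonic ($2/w^+$).  The index value is
$D = \sum_e j_e$.

Because contributions depend only on degrees, the whole computation factors
through the **degree-pair edge partition** (joint degree matrix): the count
of edges per unordered degree pair $(d_{lo}, d_{hi})$.  `EdgePartition` is
therefore the central class; `indexFromGraph()` and `indexFromPartition()`
are two routes to the same number, and the test suite checks their
agreement on randomly realized graphs.

## The entropy measure

Treating each edge as one outcome with probability $j_e / D$, the Shannon
entropy of the contribution distribution is

$$\mathrm{ENT}_D = \log D - \frac{1}{D} \sum_{e} j_e \log j_e,$$

an algebraic identity with $-\sum p \log p$ that the suite verifies to
$10^{-12}$.  Consequences used as tests: the value lies in
$[0, \log |E|]$, attains the maximum exactly on edge-regular graphs
(cycles, complete graphs), and is invariant under scaling all
contributions by a positive constant — so the harmonic and
$\chi_{\alpha=-1}$ entropies coincide exactly, as do the hyper-Zagreb and
$\chi_{\alpha=2}$ entropies.

Two conventions matter and are fixed package-wide:

* **Natural logarithm.**  The published reference tables never state a
  base; base $e$ is forced numerically (e.g. the Sierpinski hyper-Zagreb
  entropy at stage 1, with $D = 6366$, reproduces the printed 5.2198 only
  in nats).  `shannonEntropy()` accepts other bases; the index-weighted
  entropy does not.
* **Positive contributions.**  $0 \log 0 = 0$ is honoured in
  `shannonEntropy()`, but a non-positive contribution (the ABC index on a
  $(1,1)$ edge) is a hard error in the index-weighted entropy: the
  normalisation by $D$ is then ill-posed.  Index *sums* still accept the
  zero ABC contribution.

## The fractal families

Two families are built in as symbolic partition models in the growth stage
$n$:

* **Kekulene series `KE`** — the cycloarene of twelve fused benzene rings
  (C48H24 at stage 1) grown fractally: $(2,2) \mapsto 75n^2 - 207n + 138$,
  $(2,3) \mapsto \tfrac{9}{2} 8^n$, $(3,3) \mapsto \tfrac{3}{2} 12^n$.
  The exponential reading of the latter two classes is the unique one that
  matches both the explicit C48 skeleton at $n = 1$ (36 and 18 edges) and
  the published entropy values at $n \ge 2$; a polynomial reading fails by
  more than one nat already at $n = 2$.
* **Terpyridine Sierpinski series `SE`** — supramolecular Sierpinski
  triangles of terpyridine–metal motifs, defined by five quadratic classes
  including metal centres of degree 6 and peripheral degree-1 atoms (class
  $(1,3)$); the partition model is taken as the family definition, and no
  geometric reconstruction of the stage-$n$ molecule is attempted.

`closedFormIndex()` stores the published closed-form index polynomials with
exact rational/radical coefficients.  For the kekulene family all ten are
internally consistent with the partition model.  For the Sierpinski family
the first and second Zagreb and hyper-Zagreb polynomials match the
partition sums as exact integer identities; six further forms are
typographically unrecoverable from the source and are re-derived exactly
from the class polynomials (their provenance is recorded as `"rederived"`);
and the printed harmonic closed form is an erratum — it evaluates to 151.1
at $n = 1$ where its own partition sums to 82.6 — so `verifyClosedForms()`
flags it rather than uses it.  Partition sums are authoritative everywhere.
The Sierpinski consistency report also records the exact coefficients of
the hyper-Zagreb entropy numerator $\sum_e j_e \log j_e$ (a quadratic in
$n$ with $n^2$ coefficient $\approx 10648.40$), since the published decimal
expansion of that intermediate (10645.4) was rounded too early to
reproduce the final table; the exact pipeline does reproduce it.

### Reproducing the published tables

`referenceEntropyTable()` emits the two published ten-column tables for
$n = 1..10$.  The parametric columns use different exponents per table,
both supported explicitly: the kekulene table's general-Randić and
general-sum-connectivity columns duplicate the $\alpha = -1/2$ columns,
while the Sierpinski table's use $\alpha = +1/2$ and $\alpha = -1$
respectively.  Elsewhere $\alpha$ has **no default**: callers must supply
it.

Reproduction is asserted at an absolute tolerance of ±0.002 nats, which
absorbs the reference values' own 4-decimal rounding (typical agreement is
within $10^{-4}$).  Four isolated Sierpinski cells (second-Zagreb at
$n = 3$, general-Randić at $n = 6$, geometric–arithmetic and atom–bond
connectivity at $n = 7$) disagree by 0.004–0.018 while every neighbouring
cell agrees to $10^{-4}$; these are evidently printing errors in the
reference and the corresponding assertions are expected to fail — the
package reports its exactly-computed values rather than matching them.

## Graph fixtures and the synthetic generator

`buildKekulene()` constructs the one graph-level ground truth: the C48
skeleton as an outer 30-cycle, inner 18-cycle and 12 alternating spokes,
giving 12 fused hexagons, degree sequence $2^{24} 3^{24}$, and edge
partition $\{(2,2){:}6, (2,3){:}36, (3,3){:}18\}$ — equal to the family
model at $n = 1$.  All ten entropies computed on this graph by edge
enumeration match the partition route and the published stage-1 row.

`realizePartition()` turns any feasible partition into a concrete simple
graph: the forced number of vertices per degree class is created
(`partitionRealizability()` checks the stub-divisibility condition and
reports the forced counts), stubs are paired class by class from a seeded
shuffle, and self-loops or parallel edges are repaired by double-edge swaps
*within the same degree-pair class*, which preserves the partition exactly.
Swaps are bounded (default $10^5$, split over up to 50 reshuffle restarts —
a stuck configuration, such as a single-edge class paired into a loop, is
resampled rather than declared fatal); genuine failures, like
$\{(2,2){:}2\}$ which passes divisibility but admits no simple graph, error
out loudly.  Realization targets only the partition: no planarity, ring
sizes or chemical plausibility, because no computed quantity depends on
them.  Identical seeds give identical graphs, and the global RNG stream is
left untouched.

`randomPartition()` generates the random inputs for the property suite by
sampling a bounded-degree random simple graph and extracting its partition.
This guarantees every emitted partition is realizable (a witness exists by
construction), which the stub-divisibility condition alone cannot: that
condition is necessary, not sufficient.  The generator emulates small
heavy-atom skeletons (degrees ≤ 4–5, tens of edges); it does not emulate
chemically realistic ring statistics or degree correlations, so passing
property tests demonstrate the algebraic identities and the realization
machinery, not chemical coverage.

## Numerical choices

* Contributions and entropies are computed in double precision; the
  reference tables are printed to 4 decimals, so display rounds to 4 d.p.
  (round-half-to-even) while JSON output keeps full precision.
* Family counts are stored as doubles and the growth stage is capped at
  $n = 33$ in the API (30 in the CLI): $8^n$ and $12^n = 3^n 4^n$ are
  exactly representable in binary64 up to there (the odd factor $3^n$
  stays below $2^{53}$), so no arbitrary-precision integers are needed.
* Entropy values are clamped to $[0, \log|E|]$ to absorb last-bit
  round-off at the boundary attained by regular graphs.
* Closed-form cross-checks flag relative differences above $10^{-6}$;
  property tests use $10^{-12}$ for exact algebraic identities and
  $10^{-9}$ for route-equivalence on random graphs.
* Property-suite problem sizes — graphs of 4–14 vertices, 100 partitions
  for the entropy identities, 200 for realization round-trips — keep each
  case small enough to check by enumeration while covering all degree-pair
  classes up to degree 5.

## Limitations

* Only degree-based, edge-additive indices: no distance-based (Wiener) or
  spectral descriptors, and no vertex-partition entropies.
* Graphs are strictly simple and undirected; multigraphs are rejected, not
  coerced.  Bond orders and hydrogens are discarded on MOL/SDF ingestion.
* The Sierpinski family exists in this package only through its partition
  model; stage-$n$ molecular geometry is out of scope.
* QSPR regression against physicochemical properties is not included; the
  entropies are descriptors, not property predictions.
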