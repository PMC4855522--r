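---
title: "Methods: the WMEM model, solver and cohort pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WMEM model, solver and cohort pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmemcover)
```

## The model

A weighted mutually exclusive maximum set cover (WMEM) instance is a ground
set $X$ of $n$ elements, a family $\mathcal{F}$ of $m$ subsets of $X$, and a
weight function $w:\mathcal{F}\to(-\infty,\infty)$. A feasible solution is
a pairwise-disjoint subfamily $\mathcal{F}'$; the objective is
lexicographic: first maximize the number of covered elements
$|\cup\mathcal{F}'|$, then minimize $\sum_{S\in\mathcal{F}'} w(S)$. In the
biological application the elements are tumors whose gene-signature
expression marks a perturbed common signal, the subsets are candidate
genes' altered-tumor sets, and the weights are hypergeometric tail
probabilities, so the optimum is a mutually exclusive gene module that
explains as many perturbed tumors as possible with maximally informative
genes. The model itself allows weights of any sign; because coverage is
strictly prior to weight, a disjoint non-empty set is always worth taking
regardless of its weight.

The assumptions that make this biologically meaningful: genes in a signature
are co-regulated by one signal; SGAs perturbing that signal occur (almost)
mutually exclusively across tumors; and a perturbed signal shows up as a
strong, coherent expression change of the signature.

## Solver control flow

The solver operates on the intersection graph (one node per subset, edges
between overlapping subsets). The published description gives the branching
rules and complexity proofs but not executable pseudocode, so the control
flow here is reconstructed from the proofs, with every free choice fixed
deterministically:

* **Global order.** The family is sorted by set id (C-locale radix order)
  during normalization; every "choose any node" step picks the smallest id.
  Weight sums are always accumulated over sorted set ids so that genuine
  floating-point ties reproduce exactly, and exact ties between solutions
  are broken by the lexicographically smallest sorted id tuple.
* **Reduction.** Isolated nodes are included immediately. Connected
  components are solved independently and concatenated (their element sets
  are disjoint, so per-component optima compose, and per-component
  tie-breaks yield the globally smallest tuple).
* **Degree ≤ 2 components** are simple paths or rings. A path branches on
  its middle node — for an even path the lower-indexed of the two middle
  nodes, indexing from the endpoint with the smaller id; a ring branches on
  its smallest-id node, reducing to paths. Recursion bottoms out at empty
  and singleton paths. The leaf count of this recursion is reported as
  `cover2_internal_leaves` and satisfies $T(m) \le (m-3)^2 + (m-1)^2 <
  2m^2$ per component.
* **Degree exactly 3** branches on the node returned by
  `find_branch_node_deg3()`: walk from the smallest-id minimum-degree node
  along degree-≤ 2 nodes (the only free successor choice, at the start, is
  resolved by smallest id) to the first degree-3 node. Branching there lets
  the walked path fall off as an isolated polynomial component in the
  exclude branch, which is what pushes the recurrence down to $1.325^m$.
  In a 3-regular graph the smallest-id node is branched first; afterwards
  low-degree nodes always exist.
* **Degree ≥ 4** branches on the smallest-id maximum-degree node
  (include: remove its closed neighborhood; exclude: remove the node),
  giving $T(m)\le T(m-5)+T(m-1)$, whose root is below 1.325.
* After every reduction the solver re-normalizes and re-decomposes; there is
  no incremental graph maintenance. Pairwise intersections never change
  when other sets are removed, so the boolean intersection matrix is
  computed once per top-level call and subfamilies reuse submatrices — the
  simplicity of full re-decomposition costs only matrix slicing.
* No memoization: subinstances essentially never repeat, and the functional
  recursion keeps memory proportional to depth.

**Instrumentation.** `branch_leaves` counts terminals of the
include/exclude recursion — subinstances resolved without branching (empty,
all-isolated, or a degree-≤ 2 component handed to the polynomial routine).
Component splits contribute additively, mirroring how the published
recurrences treat polynomial subcases as terminal; the proofs do not state
how splits interact with the recurrences, so additive counting is this
package's convention (it can only undercount relative to a multiplicative
reading, and the $1.325^m$ bound is checked against it empirically, not
assumed). `branch_nodes`, `max_depth` and `cover2_internal_leaves`
complete the picture.

A brute-force oracle (`brute_force_solve()`, $2^m$ enumeration with an
identical ordering contract) backs the correctness tests; it refuses
$m > 20$ by default.

## Cohort preprocessing

All thresholds live in `default_config()` and are exposed; defaults are the
standard values with their exact boundary semantics:

| parameter | default | boundary | meaning |
|---|---|---|---|
| `z_threshold` | 1.64 | inclusive (≥ / ≤ −) | one-sided p ≈ 0.05 for CNV-expression concordance |
| `min_event_tumors` | 5 | `≤ 5` removed | rare-gene filter (a kept gene has ≥ 6 events) |
| `eps` | 1 | — | fold-change pseudocount |
| `up_fold` | 3 | inclusive | significant per-gene up/down regulation |
| `near_fold` | 2 | strict | "within twofold" normal-like bound |
| `sp_frac` | 0.75 | strict > | fraction of signature genes regulated for `S_p` |
| `sn_frac` | 0.5 | inclusive ≥ | fraction near-normal for `S_n` |
| `subgroup_frac` | 0.1 | strict < | small up/down sub-group tolerance |
| `min_sp` | 30 | strict > | minimum `S_p` size for acceptance |
| `max_signature_genes` | 49 | `≥ 50` dropped | signature size cap at load |
| `top_k`, `max_weight` | 200, 0.2 | ≤ 200, strict < | candidate selection |

Decisions taken where the published description leaves room:

* **"Middle value" of normal expression** is read as the median (mean is an
  option). Fold changes are computed on a linear scale with pseudocount 1
  in numerator and denominator; log2 input is un-logged first. The scale is
  not stated in the source material; linear with a pseudocount is the
  conservative reading that keeps zero-expression genes finite.
* **Hypergeometric weight** is the upper-tail probability
  $P(X \ge k_g)$ with $N = |S_p|+|S_n|$, $K = |S_p|$, $n_g$ altered tumors
  among the partitioned ones, $k_g$ of them in $S_p$. The distribution is
  named but the statistic is not; the upper tail matches "enriched in
  $S_p$" and the smaller-is-better weight convention. The same tail
  function scores whole modules (`module_enrichment_pvalue()`), pooled at
  tumor level — a tumor counts once no matter how many module genes hit it,
  consistent with the mutual-exclusivity framing. Underflowing p-values are
  clamped to the smallest positive double so $-\log_2 p$ stays finite.
* **Tumors in neither subset** are excluded from weighting: the weight
  measures information about the partitioned tumors only.
* **GISTIC ±1 events are ignored entirely** (only ±2 counts as a CNV
  event), and ±1 tumors are also excluded from the z-score background,
  which uses GISTIC-0 tumors only. Genes with fewer than two background
  tumors or zero background spread have the CNV channel skipped with a
  warning; the mutation channel is unaffected.
* **The up/down sub-group rule** is self-contradictory as printed in the
  source description. Implemented reading: if the smaller directional
  sub-group of `S_p` holds less than 10 % of the larger's tumors, its
  tumors are dropped and the signature continues; otherwise the signature
  is rejected as bidirectionally perturbed.
* **Configuration files are JSON**, not YAML: the deployment environment
  provides `jsonlite` but no YAML parser, and the config contract
  (round-trip identity, unknown-key rejection, domain checks) is
  format-independent.

## The synthetic cohort: what it emulates, and what it does not

`synthetic_cohort()` states a world with the structural assumptions the
method relies on, not TCGA's marginal distributions:

* A fixed fraction of tumors (default 0.5) is signal-perturbed; each
  perturbed tumor receives **exactly one** planted driver SGA — mutual
  exclusivity holds by construction. Drivers are assigned round-robin over
  shuffled perturbed tumors, so event counts per driver are balanced and
  comfortably clear the ≥ 6-event filter at the default sizes (200 tumors,
  4 drivers).
* Driver events are mutations or GISTIC ±2 calls with equal probability;
  CNV events shift the gene's expression to exactly ±3 background standard
  deviations, so the inclusive 1.64 z-threshold is cleared deterministically
  even in the noiseless setting.
* Signature genes sit exactly at the normal level in unperturbed tumors and
  exactly at `fold_effect` (default 3) in perturbed tumors, *as the
  pipeline measures fold change* — i.e. at
  `fold_effect * (reference + eps) - eps` — so the inclusive 3-fold rule
  fires exactly when `noise_sd = 0`.
* Driver and background genes carry log-normal biological spread
  (`bio_sd = 0.25` on log expression, a typical within-cohort dispersion);
  without it the noiseless world would have zero background standard
  deviation and no defined z-scores. Signature genes are deliberately flat
  so that label recovery is exact in the noiseless world.
* Passenger mutations hit background genes at `passenger_rate = 0.05` per
  gene per tumor (roughly TCGA-like prevalence for recurrently altered
  passengers at cohort scale; at 200 tumors this leaves a healthy set of
  decoy genes above the 6-event filter). Passengers are mutations only —
  passenger CNVs would add nothing the weighting does not already see.
* Measurement noise `noise_sd` multiplies all expression entries
  log-normally at the end.

A green end-to-end test therefore establishes that the pipeline's rules
compose correctly on data satisfying the model's assumptions exactly. It
does **not** establish robustness to mis-specified signatures, partially
penetrant drivers, overlapping pathways, subclonal events, or realistic
mutation spectra — none of which the generator attempts.

`planted_instance()` plays the same role for the solver alone: planted
disjoint sets tile the universe with near-zero weights (uniform on
[0, 0.01]) while decoys of the same size carry weights in [0.5, 1]; any
equal-coverage alternative must include a decoy and loses on weight, so
recovery is guaranteed by construction and the test checks the solver, not
the generator.

## Numerical and degenerate-input choices

* Weight comparisons are exact (`==` on doubles): both sides of any
  comparison are sums of the same weights in the same sorted-id order, so
  mathematically equal values are bitwise equal.
* Empty instances solve to the empty solution with `branch_leaves = 1`.
  Empty sets are removed at normalization: they cannot change coverage, and
  a negative-weight empty set would make the objective unbounded in
  pathological inputs; the cohort pipeline cannot produce them anyway.
* Element ids and set ids are opaque strings; all ordering uses C-locale
  radix sort, so results are locale-independent.
* The universe may strictly contain the union of the family (uncovered
  elements are representable and survive file round-trips via a
  `#universe:` header), though the cohort construction happens to cover
  `S_p` only when the candidates do.

## Known limitations

* No overlap tolerance: strict mutual exclusivity only. The relaxed
  "small overlap" variant is out of scope.
* Degree-≤ 2 components use the quadratic midpoint recursion, not the
  linear dynamic program that exists for paths.
* The solver is exact and exponential in `m`; it is intended for the
  post-filtering regime (`m` up to a few hundred candidates, intersection
  graphs that decompose). The brute-force oracle is for testing only.
* `fold_changes()` requires at least one normal sample; cohorts without
  normals cannot be partitioned.
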