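---
title: "Individual-length bi-random walks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-length bi-random walks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrw)
```

## The model

Drug repositioning is cast as link prediction on a heterogeneous network
with two node kinds.  The data are a binary drug-by-feature matrix
(chemical fingerprints), a binary disease-by-feature matrix (symptom
profiles), and a binary drug-by-disease association matrix $W$.  The
method's premise is guilt-by-association: similar drugs tend to treat
similar diseases, so score mass placed on known associations and diffused
through the two intra-kind similarity networks should accumulate on
plausible unknown pairs.

Two modelling ideas distinguish this pipeline from a plain random walk
with restart:

1. **Walks are run separately per subnetwork** ("bi-random walk"): one
   walk diffuses each drug's association profile through the *disease*
   similarity network, the other diffuses each disease's profile through
   the *drug* similarity network, and the two score matrices are averaged
   once at the end.  This respects the structural difference between the
   two similarity networks instead of flattening them into one global
   graph.
2. **Every node gets its own iteration budget.**  The influence of a
   drug–disease pair is measured by a Jaccard index adapted to bipartite
   graphs (a drug's neighbor set is compared with the disease's two-hop
   set, so both are sets of diseases), and a node's walk length is its
   total influence: $L_r(i) = \sum_j JI(i,j)$, $L_d(j) = \sum_i JI(i,j)$.
   A row (column) of the walk is frozen once the iteration index exceeds
   $\lfloor L \rfloor$.  High-influence hubs therefore propagate longer
   than peripheral nodes.

The walk recursion, with $\tilde S = D^{-1/2} S D^{-1/2}$ the symmetric
Laplacian normalization and $F^0 = W$:

$$F_r^t(i,\cdot) = \alpha\, F_r^{t-1}(i,\cdot)\,\tilde S_d +
  (1-\alpha)\, W(i,\cdot), \qquad t \le \lfloor L_r(i)\rfloor,$$

and $F_r^t = F_r^{t-1}$ otherwise; mirrored on the disease side; finally
$F = (F_r + F_d)/2$.  Because $\|\tilde S\|_2 \le 1$ and $W$ is 0/1, every
iterate stays in $[0, 1]$ up to rounding; the test suite asserts
$\max F \le 1 + 10^{-9}$ on all fixtures.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.1 | walk weight; `1 - alpha` = restart mass returned to `W` each step.  0.1 keeps scores anchored to known biology and makes the walk a contraction. |
| `logistic_d` | `log(999)` | logistic offset; anchors `S2(0) = 0.001`, i.e. a raw similarity of zero survives at one part in a thousand. |
| `x_star` | calibrated | informativeness threshold in (0,1]; the logistic midpoint.  `NULL` triggers the shuffle calibration below. |
| `shuffles` | 20 | permutations for the calibration baseline.  One shuffle is noise-prone; 20 stabilizes the per-subrange baseline at negligible cost. |
| `clusterone_penalty` | 2 | per-node cohesiveness penalty; discourages sprawling clusters on the sharing graph. |
| `clusterone_min_size` | 2 | smallest retained cluster. |
| `clusterone_overlap` | 0.8 | merge threshold on the match score `|A∩B|²/(|A||B|)`. |
| `gip_gamma_tilde` | 1 | GIP bandwidth numerator (dimensionless; the bandwidth itself is normalized by the mean squared profile norm). |
| `mode`, `fixed_L_r`, `fixed_L_d` | individual | `fixed` replaces the per-node budgets with one global length per side — the ablation harness. |
| `seed` | 1 | master seed; stage seeds are derived by fixed offsets so toggling one stage does not perturb another's randomness. |

## Numerical and design choices

**The logistic as printed is decreasing.**  The adjustment formula
$S^2 = 1/(1 + e^{cS^1 + d})$ with $c, d > 0$ decreases in $S^1$, which
contradicts its stated purpose (shrink uninformative similarities, enlarge
informative ones).  We use the effective steepness $c_\mathrm{eff} =
-d/x^\ast$: the map is then strictly increasing, fixes $S^2(0) =
1/(1+e^d) = 0.001$ at the default $d$, and puts the midpoint
$S^2(x^\ast) = 0.5$ exactly at the informativeness threshold.

**Threshold calibration.**  Off-diagonal raw similarities are binned into
ten subranges $(0, 0.1], \ldots, (0.9, 1]$.  The statistic per subrange is
the mean number of shared association counterparts per pair (for drug
pairs: diseases treated by both).  Its null baseline is obtained by
permuting the pooled similarity values among the pairs — which preserves
both the similarity distribution and the sharing structure while breaking
their relation — averaged over `shuffles` permutations.  A subrange whose
observed sharing falls below its baseline carries no association signal;
$x^\ast$ is the upper bound of the highest such subrange, i.e. the
boundary below which similarities are shrunk.  We deliberately do *not*
use the mean *similarity* of shared pairs as the statistic: both the
observed and the shuffled version of that quantity are confined to the
same 0.1-wide interval, so their comparison is decided by third-decimal
noise and carries no power (we verified this numerically; thresholds
returned under that statistic are essentially random).  The permutation is
applied to the pooled off-diagonal values rather than per subrange, which
keeps the baseline well-defined for sparsely populated bins.

**Clustering.**  The cluster stage needs overlapping, cohesiveness-scored
clusters on a weighted graph.  We implement a greedy grower: seed at the
unclaimed node of largest weighted degree, repeatedly apply the single
node addition or removal that most increases
$f(C) = W_{in}/(W_{in} + W_{bound} + p\,|C|)$, merge cluster pairs whose
overlap score exceeds the threshold, discard clusters below the minimum
size.  All tie-breaks are by node order, so clustering is deterministic.
A pair contained in several clusters is boosted by the *largest*
cohesiveness among them — a deterministic, order-independent resolution of
the overlap ambiguity.

**GIP bandwidth.**  The bandwidth numerator $\tilde\gamma$ is exposed as a
parameter with default 1 (for both node kinds), the convention of the GIP
kernel literature.  An alternative reading — setting $\tilde\gamma$ to the
average number of associations per node — would couple the bandwidth to
network density twice (the denominator already normalizes by the mean
squared profile norm); we did not adopt it.

**Diagonal convention.**  Every similarity stage forces the diagonal to 1
before Laplacian normalization, so isolated-but-self-similar nodes remain
well-defined and the normalized matrix keeps spectral radius $\le 1$.

**Zero-degree rows.**  Laplacian normalization maps zero-degree
rows/columns to zero; an isolated node propagates nothing, and with a
floored budget below 1 its scores remain exactly its `W` row — consistent
with the walk-freezing semantics.

**Iteration count.**  The walk runs to the largest floored budget with
per-row (per-column) freezing; there is no convergence tolerance, because
the stopping rule *is* the method's contribution.  Non-integer budgets are
floored as specified, so $L < 1$ means no propagation at all.

**Per-step averaging is not done.**  Some bi-random-walk variants average
$F_r$ and $F_d$ after every iteration; here the two recursions are
independent and integrated once at the end, as the update equations are
written.

**Walk budgets and CV masking.**  Budgets depend only on the association
matrix, so during cross-validation they are recomputed from each fold's
masked training matrix, never from test pairs — as are the calibration
threshold, the clusters and the GIP kernel.  Binarized metrics
(precision/recall/F1) use the observed score cut-point that maximizes
micro-F1, reported with the threshold; micro-F1 is the positive-class F1
(forced by the contract's worked example), macro-F1 the unweighted mean of
the two per-class F1 scores.

## What the synthetic generator does and does not emulate

`synth_generate()` plants `n_blocks` co-modules: drugs and diseases are
assigned to blocks round-robin; each block owns a binary feature template
(bit density 0.3) from which individual profiles deviate by independent
flips (`feature_flip_prob = 0.05`); associations are Bernoulli with
probability 0.3 inside a block and 0.01 across; 20% of the positives are
moved to a separate held-out truth matrix.  Defaults (60 drugs, 50
diseases, 5 blocks) are a desk-scale analogue of the curated datasets the
method was originally evaluated on (hundreds of drugs/diseases, a few
thousand associations, 881 fingerprint bits, 322 symptoms); the 100/80
feature counts and the 0.3 template density were fixed once as realistic
for binary profile data and are not tuned.

What a green test on this generator establishes: the pipeline recovers
planted block structure from features plus masked associations, individual
budgets beat the no-walk control, and all stage contracts hold.  What it
does **not** establish: performance on real pharmacological data.  Real
fingerprints have heavy-tailed bit marginals and correlated substructure
bits; real associations are not conditionally independent given a block
partition; and MeSH-style disease vocabularies induce hierarchical, not
blocky, similarity.  None of that is modelled.

A consequence worth stating explicitly: *within* a block, held-out
positives are exchangeable with unknown pairs (associations are i.i.d.
Bernoulli given block membership, and holdout/CV masks are uniform), so
the Bayes-optimal ranking is block membership with ties.  Under the
default generator and the all-unknown-negatives CV protocol, that oracle's
mean AUROC over seeds 1–10 is about 0.85.  The pipeline reaches about
0.81 (and is within 0.01 of the oracle on a pure holdout split), so the
recovery bound of 0.9 asserted in the acceptance suite is not attainable
in this stated world and is left failing rather than weakened; the
companion assertions (no-walk control at exactly 0.5, individual budgets
strictly better than the control) hold for every seed.

## Degenerate inputs and edge cases

- All-zero feature rows get cosine similarity 0 against everything (no
  division error); the stage diagonal is still forced to 1.
- An all-zero association matrix is an error for the GIP kernel
  ("GIP undefined") and triggers the 0.1 calibration fallback with a
  warning elsewhere.
- Empty Jaccard sets use the 0/0 := 0 convention, so isolated nodes get
  budget 0 and keep their `W` scores.
- Ties in ranked predictions break lexicographically by (drug id,
  disease id); tied scores in AUROC get half credit via average ranks.
- Duplicate association pairs collapse to one with a warning; unknown
  identifiers are hard errors naming the offending pair.

## Known limitations

- Dense matrices throughout: fine for the hundreds-of-nodes scale the
  method targets, quadratic memory beyond that.
- The greedy cohesiveness grower is a faithful, deterministic stand-in for
  the cited overlapping-clustering tool, not a re-implementation of its
  exact search schedule.
- Feature matrices enter only through cosine similarity; no alternative
  chemical similarity metrics are provided.
- The evaluation module scores pair-wise masking only (no cold-start
  whole-drug masking).
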