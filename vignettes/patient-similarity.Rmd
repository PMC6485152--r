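---
title: "Measuring patient similarity with taxonomic concept-set distances"
author: "taxsetdist authors"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxsetdist)
```

## The problem

Clinical concepts such as diagnoses are coded in hierarchical taxonomies
(ICD-10, ATC, ICD-9-CM-3). The hierarchy carries semantic information: two
codes under the same subcategory describe closer conditions than codes from
different chapters. A patient record is a *set* of such codes, so comparing
patients means comparing sets of taxonomy nodes — and a subpopulation can be
summarised by a *prototype*, a ranked list of its most central diagnosis
codes. This package implements the full stack: information content of a
node, pairwise code distance, set-to-set distance (including minimum
weighted bipartite matching), prototype construction, and a
nearest-prototype classifier for a binary hospital length-of-stay (HLOS)
outcome, together with a synthetic cohort generator so the whole pipeline is
testable without access to protected clinical data.

Throughout the package all measures are *distances*: 0 means maximal
resemblance. The literature often calls the same formulas "similarities";
we keep one orientation to avoid sign errors in ranking code.

## Information content

Two definitions over a rooted, level-labelled taxonomy (levels count from 1
at the root):

* **path** (`ic(t, a, method = "path")`): the number of levels on the
  node-to-root path, inclusive. The virtual root has IC 1, a chapter node
  IC 2, and a full five-level expansion code (e.g. `I00.x01`) IC 5. Cheap,
  and effective when all codes live in a narrow subdomain.
* **ontology** (`"ontology"`):
  $-\log\big(\frac{|leaves(a)|/|subsumers(a)| + 1}{|leaves(r)| + 1}\big)$,
  0 at the root and strictly increasing along any root-to-leaf chain. It
  discriminates better across a broad concept background because it sees
  how bushy each subtree is, at the price of counting leaves below every
  node (both IC vectors are precomputed when the taxonomy is built, which
  makes the cost irrelevant in practice).

The log base is not fixed by the definition; we use the natural log. The
base cancels in the ratio-form code distance and only rescales the
exponent-form one, and the test suite confirms base-invariance of the ratio
form numerically.

## Code-level distances

With $c$ the least common ancestor of $a$ and $b$, and $IC$ either method:

| method | formula | notes |
|---|---|---|
| `binary` | $[a \ne b]$ | exact, case-sensitive string match |
| `wu` | $1 - \frac{2\,IC(c)}{IC(a)+IC(b)}$ | information-theoretic ratio |
| `li` | $1 - e^{-\alpha(IC(a)+IC(b)-2IC(c))}\tanh(\beta\, IC(c))$ | $\alpha = 0.2$, $\beta = 0.6$ |
| `simplified` | $\frac{IC(l)-IC(c)}{IC(l)}$ | $IC(l)$ = max IC over nodes |

Numerical conventions worth spelling out:

* **Sign of the `li` exponent.** Some printed statements of this formula
  carry a positive exponent on the separation term, which grows without
  bound and inverts the intended ranking. We implement the decaying form
  $e^{-\alpha\Delta}$, $\Delta = IC(a)+IC(b)-2IC(c) \ge 0$, which keeps the
  value in $[0,1]$ and decreasing in separation, consistent with the
  original parameterised formulation this distance derives from.
* **`li` is not zero at identity**: $d(a,a) = 1 - \tanh(\beta\, IC(a))$,
  about 0.005 for a level-5 node. This is a property of the formula, not a
  bug; it never changes ascending ranks among candidates at equal depth,
  but callers comparing across methods should know. At the root the value
  depends on the IC method (path IC gives the root IC 1, ontology IC
  gives 0).
* **`simplified` and $IC(l)$.** "The deepest level" has one IC under path
  IC (the level count $L$) but many under ontology IC; we define $IC(l)$
  as the maximum IC over all nodes, which reduces to $L$ under path IC and
  is well defined for both. A single-node taxonomy has no positive maximum
  under ontology IC and is rejected.
* **`wu` at the root pair** is 0/0 under ontology IC; identity takes
  precedence and the distance is 0. Code *sets* should not contain the
  virtual root in the first place.

`concept_distance_matrix()` computes the full grid between two code vectors
in one vectorised pass (pairwise LCAs are found level-by-level on an
ancestor matrix). Every set-level and prototype computation goes through
such a matrix over the distinct codes involved, computed once — this is the
memoization that makes sweeps over hundreds of patients cheap.

## Set-level distances

Eight measures in `set_distance()`. Dice, Jaccard, cosine and overlap work
on exact-match counts only. The other four aggregate code distances:
closest-pair (each code contributes its nearest counterpart), the
non-shared average, the all-pairs average, and **minimum weighted bipartite
matching**: the Hungarian algorithm selects $\min(|A|,|B|)$ edges, one per
code, minimising the summed distance.

Three conventions we had to fix ourselves:

* **Bipartite normalisation.** The raw matching total grows with set size,
  so we divide by the number of matched edges, keeping the result in
  $[0,1]$ and comparable across sizes — the same scale as the other
  measures. Surplus codes of the larger set are deliberately ignored:
  keeping only the best matches and discarding redundant codes is exactly
  what makes this measure robust for unbalanced sets.
* **Empty sets are an error**, not a default distance; silent defaults
  would silently corrupt parameter sweeps.
* **Duplicates are collapsed** before any set computation (patient records
  hold distinct diagnoses).

The Hungarian solver is written in the package (shortest augmenting path
with potentials, rectangular matrices handled natively without padding).
Its contract — the minimum over all injective assignments — is tested
against brute-force enumeration on shapes up to 6×6; any equally optimal
matching may be returned, only the total is contractual.

Useful order relations, all tested on random sets: closest-pair never
exceeds the all-pairs mean, and for equal-size sets the normalised matching
never exceeds the all-pairs mean (an average over permutations equals the
all-pairs mean, and the best matching is below that average).

## Prototypes and the HLOS classifier

Patients are stratified by age (18–50 vs 51+) crossed with short
(HLOS ≤ 18 days) vs long (19–50 days) stays; `hlos_strata()` holds the
bands. For each stratum, every distinct code is scored by the sum of its
code distances to **every diagnosis occurrence** in the stratum
(`prototype_score()`), and the prototype is the ascending ranking of those
sums: the smallest summed distance is the most central, most prototypical
code. Two interpretive choices, both exposed as arguments:

* **Ascending rank.** The score formula sums what are distances here, so
  "core" codes — the mutually closest ones — are those with the *smallest*
  sums.
* **Multiset, not set.** Scoring against occurrences lets common diagnoses
  dominate centrality, which is what a frequency-scaled prototype should
  do; `distinct = TRUE` switches to the set reading.

Self-occurrences contribute the identity distance (0 under `wu`); ties are
broken lexicographically by code so prototypes are deterministic and
independent of patient order.

`protoclass()` packages the four prototypes with an ⟨IC, CS, SS⟩
configuration into a fitted classifier; `predict()` compares a patient's
code set against the top-$k$ codes of the short and long prototype of the
patient's age band and returns the nearer label. The positive class is
fixed to *short*. Exact ties go to *short* with a warning — ties are
measure-zero for real-valued distances but must be reproducible, and the
bias direction is documented rather than hidden. Precision, recall and the
F-score (harmonic mean) come from `evaluate_hlos()`; if the classifier
never predicts the positive class, precision is reported as 0.
`hlos_sweep()` grids triples × prototype sizes, fitting one prototype set
per (IC, CS) pair and reusing it across SS methods. The ten benchmark
triples are in `triple_preset()`.

`mds_embed()` delegates classical (Torgerson) multidimensional scaling to
`stats::cmdscale` — double-centred squared distances, leading eigenvectors
scaled by root eigenvalues — which is deterministic up to sign and
rotation, so tests compare embedded *distances*, never raw coordinates.

## The synthetic cohort generator

`gen_taxonomy()` builds complete trees with readable path-string codes.
`gen_cohort()` emulates a department-scale cohort: four strata with the
default counts 283/257/82/83 (young-short, old-short, young-long,
old-long; 705 patients), ages and stays uniform within the stratum bands,
and each patient drawing a truncated-Poisson (mean 4, minimum 1) number of
distinct codes — a `core_fraction` share (default 0.7) from the stratum's
own core pool and the rest from a shared background pool. The default
pools deal whole level-2 branches of the taxonomy to the four cores and
pour the remaining branches into the background; the benchmark taxonomy
used in the tests has 5 levels, branching 6/4/4/3 (415 nodes, 288
leaves) — a deliberate echo of a five-level ICD-10 slice of a few hundred
active codes. `split_cohort()` does a seeded, stratum-stratified 70/30
split. All randomness is local to each call's seed; global RNG state is
saved and restored.

Two pool configurations reproduce the two qualitative phenomena the
package's acceptance tests demonstrate, and they are intentionally
*different* constructions because the phenomena have different mechanisms:

* **Disjoint cores, shared background** (the default): prototypes are pure
  core at small $k$ and grow into the common background at large $k$. All
  four CS-based set measures then dilute *together*, which is why their
  distance-vs-$k$ curves are strongly positively correlated
  (`ss_correlation()`).
* **Leaky cores** (core codes also present in the shared background, as in
  the test helpers' dilution pools): the *wrong* stratum's prototype
  eventually acquires exact matches for a typical 4-code patient, so the
  bipartite classifier — which only looks at the four matched edges —
  loses its discrimination beyond a crossover prototype size, while the
  averaging measures, which aggregate over all pairs, degrade far less.
  This is the unbalanced-set dilution effect: matching excels while
  prototypes are small and distinctive, averages are the stable choice for
  large prototype sizes.

What the generator does **not** emulate: real diagnosis frequency
distributions (heavy-tailed, correlated comorbidities), within-patient code
correlation beyond the core/background split, any relationship between age
and code content, or coding noise. Passing tests therefore show the
algorithms behave as specified under controlled overlap structure — not
that any particular F-score is attainable on real hospital data.

## Problem sizes and budgets

The test suite runs the full ten-triple sweep on five seeded 705-patient
cohorts (about 210 held-out patients per seed) at prototype size 20, the
dilution sweep at sizes 5–100, 1000-instance ordering checks and a
120-instance brute-force Hungarian comparison; everything completes in well
under a minute on one core because all set distances are served from one
precomputed code-distance matrix per (IC, CS) pair.

## Limitations

* Trees only: DAG-shaped ontologies (multiple parents) are out of scope;
  every formula here assumes a unique ancestor chain.
* The binary HLOS label (≤ 18 vs ≥ 19 days) is taken as given; no survival
  modelling.
* $\alpha, \beta$ of the `li` distance are adopted from the original
  benchmark calibration, not re-tuned.
* The ICD-10 derivation synthesises chapter/category/subcategory layers
  from code prefixes; coding systems with block layers (e.g. A00–A09
  groupings) should be loaded from an explicit edge list instead.
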