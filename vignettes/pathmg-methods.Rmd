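---
title: "Mining commonly and differentially mutated sub-pathways with pathMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining commonly and differentially mutated sub-pathways with pathMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathMG)
```

## The problem

Somatic mutation frequencies of individual genes are low in most cancers, so
gene-level marker panels transfer poorly between cohorts. Mutations do,
however, concentrate in pathways: many different genes of the same pathway
can be hit in different patients. `pathMG` works at the level of *connected
sub-pathways* — connected subgraphs of a pathway's gene--gene interaction
graph — and asks two questions of a binary gene × sample mutation matrix:

1. which sub-pathways are mutated in a large fraction of a cohort
   ("common sub-pathways", candidate diagnostic panels), and
2. which sub-pathways are mutated much more often in one cancer subtype
   than in another ("subtype-specific sub-pathways").

A pathway or gene set counts as *mutated in a sample* iff at least one of
its member genes carries a somatic variant in that sample; its *coverage*
is the fraction of samples so mutated.

## Significantly mutated pathways

Before sub-pathway extraction, pathways are screened for excess mutation
burden. For pathway $i$, let $M_i$ be its observed mutated-sample count in
a cohort of $N$ samples. The null model preserves each sample's mutated
gene count: in one random experiment, every sample redraws exactly its
observed number of mutated genes, uniformly without replacement, from a
background gene universe (a RefSeq-style gene list, or the union of the
pathway collection). With $R_i$ the mutated-sample count of pathway $i$ in
one such experiment, repeated $n$ times (default 1{,}000),

$$ p_i = \frac{1}{n}\sum_{r=1}^{n} H_r, \qquad
   H_r = \mathbf{1}\{R_i > M_i\}, $$

and the $p_i$ are BH-adjusted; pathways with $q < 0.05$ are retained. Every
pathway is evaluated against the *same* $n$ simulated cohorts, and runs are
bit-reproducible given a seed.

Two deliberate details:

* **Strict exceedance.** Ties ($R_i = M_i$) do not count, exactly as the
  estimator is defined, which means $p = 0$ is attainable. An add-one
  estimator $(\sum H_r + 1)/(n + 1)$ is available behind
  `pathMGParams(addOne = TRUE)` for users who prefer a never-zero estimate;
  it is off by default to keep the estimator in its plain form.
* **Background folding.** Genes mutated in the profile but missing from the
  supplied background are added to the universe with a warning; otherwise a
  sample's count could exceed the drawable pool.

## Greedy extraction of common sub-pathways

Within each significant pathway, each connected component of its
interaction graph is processed independently:

1. **Seed** at the component gene with the highest cohort mutation
   frequency $f$.
2. For the current seeds' unvisited direct neighbours, compute each
   candidate's marginal coverage gain $P_f$ (new samples covered divided by
   $N$) and add candidates in descending $P_f$ order.
3. A candidate whose *realized* gain at insertion time is positive joins
   the sub-pathway (set $GI$) and becomes a new seed. A candidate with zero
   realized gain (set $GN$) is kept only if at least one of its own
   unvisited neighbours, tried in descending gain order, has positive gain;
   those neighbours become new seeds. Otherwise the $GN$ gene is removed
   and never revisited.
4. Repeat until no seed has an unvisited neighbour; emit the sub-pathway
   iff its coverage is at least the threshold (default 90%) and it has at
   least `minGenes` genes (default 5).

Design choices where the procedure description leaves room:

* **Ranking vs realization.** $P_f$ is computed once per frontier pass
  (against the sub-pathway state at the start of the pass) and used only
  for ordering; the gain that decides $GI$ vs $GN$ membership is
  re-evaluated at insertion time. This reconciles "add in descending
  $P_f$ order" with the fact that earlier insertions change later gains.
* **Tie-breaking** (seed frequency ties, gain ties) is lexicographic on the
  gene symbol, so results are identical across platforms.
* **Each gene is visited at most once per component**; a rejected $GN$ gene
  is final. This guarantees termination. Zero-gain genes merely *examined*
  during a $GN$ rescue scan stay unvisited and may be reconsidered from a
  later frontier.
* **One sub-pathway per component**, grown from the single maximum-$f$
  seed; multi-start extraction is out of scope.
* Genes present in the pathway but absent from the mutation profile have
  $f = 0$; they can still be retained as $GN$ bridges, which is exactly the
  role interaction hubs with few mutations play.

The emission gate uses `coverage >= threshold`; only results at exact
threshold equality are affected by reading "higher than" inclusively, and
the invariant "no emitted sub-pathway is below threshold" is tested.

## Subtype-specific sub-pathways

For two subtypes $A$ and $B$, pathways are first screened with a two-sided
Fisher exact test on the 2×2 table of pathway-mutated status vs subtype,
BH-adjusted to $q < 0.05$. Within each retained pathway's components,
per-gene subtype frequencies $f_a$, $f_b$ and their difference
$v = f_a - f_b$ split the genes into $G_a$ ($v > 0$) and $G_b$ ($v < 0$);
genes with $v = 0$ serve neither direction. Growth mirrors the common mode
with three changes:

* the objective is the coverage difference, so a candidate's gain $P_v$ is
  the change in $\mathrm{cov}_A - \mathrm{cov}_B$ and may be negative;
* the frontier is restricted to the direction's gene set;
* **at most one** retained gene in the whole sub-pathway may fail to
  increase the difference (budget configurable via `nonGainBudget`),
  whereas common mode allows any number of independently justified bridge
  genes. The budget is global per sub-pathway, the literal reading of the
  procedure; when it is spent, further non-gain candidates are rejected
  without a rescue scan so that connectivity is never broken.

A sub-pathway is emitted iff its direction-oriented difference is at least
`diffThreshold` (default 0.25) *and* a two-sided Fisher exact test on its
own 2×2 table gives $p < 0.05$ (raw, not FDR-adjusted — the screen already
controls the pathway-level FDR). Both Fisher tests are two-sided:
directionality is enforced by the difference threshold, so a one-sided
test would double-count the direction constraint. Direction $B$ is computed
by swapping subtype roles; reported `coverageA`/`coverageB`/`diff` stay in
the original orientation, so B-specific results carry negative `diff`.

## Enrichment reporting

Emitted gene sets are tested against cancer-gene and drug-target lists with
an upper-tail hypergeometric test over a background universe, by default
the union of genes in the loaded pathway collection (lists are intersected
with the universe first, mirroring how target lists are restricted to
pathway-annotated genes). Raw p-values are reported without multiplicity
correction, as is conventional for these descriptive enrichment flags.

## The synthetic-data generator

Real cohorts and curated pathway databases are large, versioned and
licence-encumbered; the package therefore ships a generator that emulates
the *statistical* structure the algorithms care about:

* per-sample mutated-gene counts from a negative binomial (default mean 20,
  size 2 — overdispersed, giving the heavy hypermutator tail seen in real
  cohorts such as right-sided colorectal tumours), genes drawn uniformly
  from a background universe (default 1{,}000 genes);
* random pathways (default ten of 15 genes) wired as Erdős–Rényi graphs at
  a configurable edge density, so component decomposition, isolated genes
  and fragmented pathways all occur naturally;
* `plantCommonSignal()` rewrites a connected gene set's rows so that
  exactly $\lceil cN \rceil$ samples carry a planted mutation, assigned
  round-robin over the planted genes — every planted gene then has positive
  marginal gain, exercising the $GI$ path; an optional redundant gene is
  mutated only in already-covered samples to exercise the $GN$ rescue;
* `plantSubtypeSignal()` sets planted coverages `base + max(d, 0)` and
  `base + max(-d, 0)` (base 0.3), realizing a target difference `d` to
  within one sample of the smaller subtype.

What the generator does *not* emulate: mutational signatures, gene-length
effects (longer genes accumulate more variants; a length-aware null is an
explicit non-goal), copy-number events, and correlated co-mutation
structure beyond the planted sets. Passing the recovery benchmarks
therefore demonstrates correctness of the search and its gates under the
stated statistical conditions, not performance on any particular tumour
cohort.

## Numerical choices and problem sizes

* Coverage bookkeeping is incremental (per-gene hit lists against a covered
  mask) but every emitted result's statistic is recomputed from scratch
  from the final gene set, and the test suite asserts the two agree.
* Permutation replication uses one seeded stream, samples drawn in fixed
  sample order within each replicate, replicates sequential.
* The checks shipped with the package run at desk scale, chosen to keep the
  whole suite in a few minutes while leaving the statistics sharp: null
  calibration on 200 pathways × 100 samples × 500 replicates (binomial
  band $0.05 \pm 3\sqrt{0.05 \cdot 0.95 / 200}$); planted recovery over
  100 replicates of 200-sample cohorts with 6-gene planted sets
  ($c = 0.95$, $d = 0.40$); exhaustive connected-subgraph comparison on
  components of at most 12 genes.
* Degenerate inputs: empty gene sets score zero coverage with a warning;
  components whose genes carry no mutations grow a one-gene sub-pathway
  that fails the coverage gate; a subtype component with no
  direction-specific genes yields nothing.

## Limitations

* The greedy search carries no optimality guarantee; maximum-coverage
  connected-subgraph search is NP-hard and exhaustive search is used only
  as a test oracle on small components.
* Exactly two subtypes are supported.
* The permutation null ignores gene length and expression; pathways rich in
  long genes will look more significant than a length-aware null would
  report.
* Survival association of sub-pathways is out of scope.
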