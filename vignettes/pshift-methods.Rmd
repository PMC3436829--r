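---
title: "Scoring mutation functional impact from pathway context"
author: "pshift maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mutation functional impact from pathway context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshift)
```

## The problem

Tumor exomes carry a mix of driver and passenger mutations, and frequency-based
methods struggle with genes mutated in only a handful of samples.  `pshift`
asks a different question of each mutated gene and each sample: *does the
activity the gene shows to its downstream pathway targets match the activity
its upstream regulators demand?*  A gene whose targets look switched off while
its regulators call for activity behaves like a loss-of-function (LOF) event;
the mirror image suggests gain-of-function (GOF).  Because the evidence is the
surrounding pathway rather than the lesion itself, the score is available even
for single-sample events and non-recurrent genes, and it is complementary to
sequence-conservation methods.

## Model

### Ternary pathway variables

Every pathway entity (protein, complex, family, abstract process) is a ternary
random variable with states *inactive*, *baseline*, *active* — activity
relative to an implicit normal tissue.  Proteins get a three-tier chain,
genome → expression → activity, so copy number informs expression and
expression informs activity; complexes, families and processes are single
activity variables.

Dependencies are encoded as factors on a bipartite factor graph.  Each
variable with parents gets one conditional table: the child's expected state
is the sign of the sum of parent votes (activating parents vote their state,
inhibiting parents the negated state; a gene's own genome tier votes into its
expression tier, its expression into its activity).  The expected state
receives probability $1-2\varepsilon$ and each other state $\varepsilon$
(default $\varepsilon = 0.2$).  Complexes combine their components with a
minimum rule before smoothing (a complex is no more active than its least
active component); families use a maximum rule.  These tables are this
package's own fully-specified parameterization of the usual
activation/inhibition semantics; nothing downstream depends on their fine
structure beyond sign correctness and smoothness.

### Evidence

Expression and copy number matrices are first mapped to *rank-ratios*: all
values of a data type are ranked jointly across genes and samples and rank
$r$ becomes $(r-1)/(NG-1) \in [0,1]$, with average ranks for ties.  This
makes data types comparable and removes marginal scale entirely.  A
rank-ratio $v$ becomes soft evidence through two cut-points (default $1/3$
and $2/3$): the matching state gets likelihood $1-2\varepsilon$, the others
$\varepsilon$.  Missing values contribute no observation factor at all —
absent evidence, not imputed evidence.

### Inference

Marginals are computed by sum-product belief propagation with a synchronous
schedule and running-average damping ($\lambda = 0.5$), to a message
tolerance of $10^{-9}$ or at most $10\,000$ iterations; non-convergence is
flagged, never fatal.  On trees this is exact (the test suite holds it to
$10^{-7}$ against exhaustive $3^n$ enumeration); on graphs with feedback it
is the usual loopy approximation, accurate to $\sim 10^{-3}$ on
single-cycle fixtures but visibly biased (few percent) on tight two-node
feedback loops with strong coupling — a known limitation inherited from
loopy BP itself.  The C++ core solves all evidence columns (samples,
permutation replicates) of one graph structure in a single batched call.

### The inferred pathway level and the shift score

A variable's *inferred pathway level* (IPL) is the signed log posterior odds
of its modal state against the mean alternative:
$$\mathrm{IPL} = \pm \log \frac{2\,P_m}{1 - P_m},$$
positive when *active* is modal, negated when *inactive* is modal, zero when
*baseline* is modal or the mode is tied.  Measuring against the *mean* of
the two alternative states (the factor 2) rather than their sum keeps the
sign aligned with the modal state for any ternary posterior: the modal
probability always exceeds $1/3$, so the score crosses zero exactly at
indifference.  The naive odds $P_m/(1-P_m)$ fail this whenever
$P_m < 1/2$ — routine under $\varepsilon$-smoothed tables — and would
invert the direction of diffuse calls.  The constant $\log 2$ offset
cancels in the Z-normalization below, so downstream statistics are
unaffected by the choice.

For a focus gene $f$ with regulator set $R$ and target set $T$, two
restricted graphs are built per sample: the **regulators run** connects $f$
to $R$ only, with evidence on the regulators *and on $f$'s own
expression/copy number* (cis data is regulatory information); the
**targets run** connects $f$ to $T$ only, with evidence on targets only and
never on $f$.  Each run's IPL is prior-subtracted — the same graph with all
observation factors removed is solved once and its IPL subtracted — and the
raw shift is
$$\mathrm{PS}(f) = \mathrm{IPL}_T(f) - \mathrm{IPL}_R(f).$$
Negative shifts point to LOF, positive to GOF.  Mirroring all evidence
(active ↔ inactive) negates the score exactly; the suite asserts this to
$10^{-9}$.  Note the two runs weight evidence differently by construction
(upstream data passes through each regulator's own cis chain; downstream
data sits directly in the target's conditional), so identical evidence
upstream and downstream gives a score near, but not exactly, zero.

### Neighborhood selection

The local context is every entity with a directed path to (regulators) or
from (targets) the focus containing at most $k$ *intervening proteins* —
complexes, families and processes are free hops, and component/member edges
are traversable in both directions so complexes can sit downstream of their
components.  Entities reachable in both directions (feedback circuitry) are
excluded from both sets.  The default $k = 1$; larger radii change little
while growing the graphs.  Neighbors whose rank-ratio expression has
standard deviation below 0.10 across samples carry no usable signal and are
dropped; complexes and families fall only when every in-neighborhood
constituent fell, entities without expression rows are retained (the filter
targets uninformative data, not missing data), and the focus is never
dropped.

An optional supervised variant runs stratified five-fold cross-validation:
per fold, neighbors with a training two-sample $|t| \ge 1$ of expression
against mutation status are retained and the shift is scored on the held-out
fifth.  Upstream regulators of a true LOF gene are genuinely
mutation-independent, so folds may legitimately empty the regulator set —
this is reported, not hidden.

### Z-normalization, calls and cohort statistics

A gene's neighborhood can lean positive or negative for purely structural
reasons, so raw shifts are standardized against a *shuffled-data
background*: 100 background shifts are computed by reassigning every
evidence-bearing neighborhood slot (including the focus slot of the
regulators run) the whole data tuple — expression and copy-number rows
together — of a uniformly drawn random gene, evaluated at a uniformly drawn
sample column.  Observed shifts are Z-scored by the background mean and SD;
$\sigma = 0$ is flagged, not silently zeroed.  Per-sample calls at a fixed
false-positive rate $\alpha$ (default 0.10) use empirical quantiles of the
background Z-scores, one- or two-sided.

Cohort significance per gene is the *mutant separation* statistic: the
pooled-variance two-sample Student $t$ comparing Z-shifts of mutated versus
non-mutated samples (negative = LOF direction).  Its null distribution
comes from *random neighborhoods*: each of `n_null` replicates (default
1000) assigns random genes' data tuples to the neighborhood slots, re-scores
every sample and records the m-sep; the permutation p-value is
$(1 + \#\{|t_{\mathrm{null}}| \ge |t_{\mathrm{obs}}|\})/(1 + n_{\mathrm{null}})$
(two-sided by default, one-sided available).  One computational note: the
per-gene Z step applies a single affine map to all samples of a replicate
and the $t$ statistic is invariant under affine maps, so null m-seps are
computed on the raw scale — identical numbers, a third less work.  Gene
tables are ordered into waterfall form by m-sep (or mean mutant shift);
genes with fewer than three mutants are flagged low-power.

## The synthetic cohort generator

Real cohorts come with dated snapshots and a hand-curated pathway; every
statistical property of this package is instead validated on synthetic
cohorts with known truth.  The generator plants, per focus gene, a star
motif (defaults: 2 regulators, 2 targets — the smallest motif that still
exercises multi-parent vote factors; chain, DAG and loopy variants exist)
plus unconnected decoy genes that populate the shuffle universe.  Hidden
ternary activities are drawn uniformly at regulators and propagated with a
small flip probability (default 0.05); the focus gene's *transmitted*
activity is forced inactive (LOF) or active (GOF) in mutant samples,
subject to a penetrance parameter (default 1; lower values emulate
heterozygous events), while its own cis expression still follows its
regulator-driven state — a mutation changes function, not transcript
abundance.  Expression is emitted as $N(\text{state} \times
\text{effect\_size},\ \text{noise\_sd})$ (defaults 2 and 1, i.e. a two-SD
separation); copy number the same with the effect halved.  Mutant samples
are drawn uniformly without replacement (default 20 of 100 samples).

What the generator does *not* emulate: realistic marginal distributions,
tumor subtype structure, correlated noise between genes, errors in the
pathway itself, or mutations that alter expression of the focus gene.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions, not performance on any
real cohort.

## Validation summary

The suite checks, among others: belief propagation against exhaustive
enumeration (200 random trees to $10^{-7}$, 8-variable loops to $10^{-3}$);
strict signs and exact mirror antisymmetry of the archetype fixtures;
false-positive calibration on an effect-free cohort of 200 neutral genes ×
200 samples with 100 background permutations and 200 null replicates
(empirical FPR within [0.07, 0.13] at $\alpha = 0.10$, permutation p-values
uniform by KS); and recovery of planted two-SD LOF/GOF drivers (20 mutants
of 100 samples) in at least 90% of 20 seeds.  These problem sizes are the
package's chosen validation operating point; `scripts/acceptance.R`
recomputes a scaled summary of the same quantities from scratch.

## Numerical choices and edge cases

* Cut-point ties: a rank-ratio exactly at a cut-point is classed into the
  middle band (`<` lower, `>` upper, strictly).
* IPL modal ties (within $10^{-12}$) give 0, so fully uninformative graphs
  score exactly zero.
* Factor tables must be non-negative with no all-zero table; evidence
  potentials are strictly positive by construction ($\varepsilon > 0$), so
  BP never divides by zero (a guarded direct-product fallback covers
  user-supplied hard evidence).
* Permutation p-values use the add-one convention and can never be 0.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-gene seeds from the config
  seed, and equal configs give byte-identical outputs.
* Empty regulator or target sets make the shift undefined for that gene
  (`NA` with a warning at the engine level, skip with a message in the
  pipeline) — never silently zero.

## Known limitations

* Loopy BP bias on tight feedback (two-node loops with strong coupling) can
  reach a few percent in the marginals; neighborhoods dominated by such
  motifs should be interpreted with care.
* The conditional tables and the evidence emission are a declared
  stand-in parameterization; absolute score magnitudes are not comparable
  across parameterizations (the Z-normalization exists precisely to absorb
  this).
* Genes absent from the pathway, or with empty up/downstream sets after
  filtering, cannot be scored at all.
* The score's *direction* can disagree with biological expectation for
  genes with complex regulatory logic; the cohort statistics report
  direction separately rather than folding it into significance.
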