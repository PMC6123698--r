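---
title: "Models, algorithms and design choices in caridiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, algorithms and design choices in caridiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

caridiv chains five analysis stages — source-tree curation, MRP supertree
construction, 'equal' time scaling, stochastic character mapping, and
birth–death rate-shift inference — into one pipeline, and ships seeded
generators that produce every input the pipeline consumes. This vignette is
the package's account of the science in each stage: the models and their
assumptions, the parameters that matter, the numerical choices, and what
the synthetic data do and do not establish about behaviour on real data.

## Curation

Source trees are treated as rooted cladograms; branch lengths, where
present, are ignored from this point on because matrix representation with
parsimony uses topology only.

Three rules operationalise data-set independence and name standardisation:

* **Synonyms** are replaced from a user-supplied table (the package does
  not query any nomenclature database; the table is the interface).
* **Higher-taxon leaves** are replaced by a polytomy of those of their
  members that occur in the other source trees. Substituting only observed
  members avoids inflating the taxon sample with species no other source
  can place. A higher taxon with no observed member is dropped with a
  warning. When substitution creates duplicate leaves, the copies collapse
  to a single leaf attached at their most recent common ancestor. This
  placement is deliberately conservative: it retains exactly the groupings
  every copy agreed on and asserts nothing the copies disagreed about.
* **Independence weights**: studies whose matrices are identical (same
  taxa, same declared character sets — recorded as a metadata fingerprint,
  since the artifact does not ingest the original alignments) share a total
  weight of 1; a study whose matrix is a strict subset of another's is
  removed as the less inclusive analysis.

The overlap check (each source must share at least two taxa with some
other source, and the sharing graph must be connected) is report-only: a
disconnected corpus cannot yield a single supertree, but a singleton
component merely warns because downstream stages may still be useful on
the largest component.

## MRP supertree construction

Each internal node of each source tree, except the root, becomes one binary
character: taxa subtended 1, other taxa present in that source 0, all other
taxa `?`. Root characters are omitted — against the all-zero hypothetical
outgroup they assign 1 to every in-source taxon and are
parsimony-uninformative. Character weights equal their source's
independence weight, so duplicating a source while halving its weight
leaves every tree's score unchanged (a tested invariant).

Scoring uses the Hartigan generalisation of the Fitch pass so that
polytomies (which higher-taxon substitution creates routinely) are scored
correctly: a node receives the intersection of its children's state sets
when non-empty, otherwise the majority states, adding one change per child
set that misses the majority. The search runs random taxon-addition starts
followed by NNI and then SPR hill climbing until no improving move remains;
equally best trees are pooled across replicates and deduplicated by a
canonical sorted-newick hash. The rearrangement engine is phangorn's
(weighted Sankoff scoring, identical on two states to the Hartigan/Fitch
count); the package's own scorer decides pooling, and a brute-force
enumeration over all internal labelings is the test oracle.

The maximum agreement subtree of two rooted trees is computed exactly by
dynamic programming over node pairs, with a small exact bitmask matching at
polytomies (polytomy degree is capped at 20 children, far above anything
the pipeline produces). For more than two trees the MAST is folded
sequentially in input order; the multi-tree problem is NP-hard and only the
pairwise step is guaranteed optimal, so the input order is part of the
recorded configuration. Novel-clade flagging (supertree clades that match
no source clade wherever they are testable) is advisory; actual removal
requires a user-supplied rogue list, because automatic removal tends to
create new rogues.

## Time scaling by the 'equal' method

Node calibrations are given as taxon pairs plus ages, assigned to the pair's
MRCA. Duplicate calibrations of one node resolve to the maximum age;
a calibrated node older than a calibrated ancestor is an error. The 'equal'
method then spaces every undated node evenly: along each path between
consecutive age-fixed nodes, the k undated nodes split the interval into
k + 1 equal durations. Where an undated node stands above several dated
descendants the paths conflict; the implementation takes the oldest
spacing candidate, which keeps every downstream interval feasible and
reduces to the textbook behaviour on chains. A second pass enforces a
minimum branch duration (default 0.1 Myr) by pushing parents rootward,
never moving a calibrated node — if the floor cannot be met between two
fixed ages, the function errors naming the node rather than silently
adjusting a calibration. The procedure is deterministic, hence idempotent.

Two practical helpers serve pipeline use: calibrations assembled against
one topology can contradict an inferred supertree, so
`filter_compatible_calibrations()` admits rows greedily and drops those
that would violate nesting or leave no room for minimum branches; and when
no surviving calibration maps onto the root, the root age falls back to
1.05× the oldest calibration (the 'equal' method needs a root constraint;
the 5% headroom is arbitrary but recorded in the run manifest via the
configuration).

**Known limitation.** Equal spacing is a smoothing device, not a clock: a
genuinely young, fast-diversifying clade with no internal calibration is
stretched toward the middle of its enclosing interval, deflating its
apparent rates (and conversely). This is visible in the synthetic studies
as run-to-run variability of the speciation-rate ratio on the pipeline's
tree relative to the same inference on the generator's own tree, and it is
why fossil-style calibrations in the generator sit on the largest clades —
mirroring how fossils are assigned to well-characterised families in
practice.

## Ancestral states and stochastic mapping

Both traits are binary and analysed independently under the equal-rates Mk
model, whose transition probability has the closed form
P(stay) = (1 + e^{−2qt})/2. The likelihood is Felsenstein pruning with a
root prior of (1/2, 1/2) — the stationary distribution of the symmetric
chain; the data cannot identify a root bias under this model, so the
uninformative stationary prior is the neutral choice. The rate q is fitted
by scalar optimisation of log q on [1e−8, 1e3] per Myr; partial likelihoods
are rescaled per node so 500-tip trees at small rates do not underflow.
Monomorphic data pin q to the lower search bound with a warning rather than
erroring, so pipelines over many traits keep running.

Stochastic maps are drawn in the standard two-step way: joint node states
from the conditional distribution given tip data (root from its posterior,
children given parents via the transition matrix times subtree partials),
then each branch path conditional on its endpoints. Paths use
uniformization with auxiliary rate q: for the two-state symmetric chain the
auxiliary transition kernel has zero self-loops, so every auxiliary event
is a real flip and the flip count is simply Poisson(qt) conditioned on
endpoint parity — sampled by inverse CDF, with flip times uniform order
statistics. This is bounded-time regardless of how small q is, unlike
rejection sampling, which survives in the test suite as the independent
oracle (a truncated-series expectation of the conditioned flip count).

Independent origins of the derived state are summarised as the modal
per-map count of 0→1 transitions (a rounded-mean alternative is a function
argument). The modal count is reported because per-map counts form a
distribution over integers and single-integer summaries of such
distributions are conventionally the mode; the origin clades are the
subtrees whose stem branch shows a net 0→1 change, summarised by their
frequency across maps.

## Diversification with rate shifts

The model is a birth–death process with piecewise-constant rates: a root
regime plus shifts attached to nodes, each shift governing its subtree
including the stem branch. Incomplete sampling enters per tip as the ρ of
the smallest enclosing clade listed in a sampling table. The likelihood is
assembled branchwise from the standard E/D propagation (E, the probability
a lineage leaves no sampled descendant, has a closed form per constant-rate
branch; D accumulates the density of the observed subtree), with a
speciation factor at every internal node except the root split, and
conditioning on survival of both crown lineages. Where the two children of
a node propagate different E values — possible when regimes or sampling
fractions differ between the sides — their mean is carried rootward; the
choice is symmetric under child reordering. The critical case λ = μ and
the overflow region of large λt use dedicated branches of the closed form.
The implementation is validated against the exact pure-birth likelihood,
against numerical ODE integration of the same propagation equations, and
its single-regime ML fit coincides with `ape::birthdeath` to four decimals
on random trees.

The reversible-jump sampler moves among shift configurations with five
moves: log-scale perturbation of a regime's λ or μ, shift birth with rates
drawn from their priors, shift death, and relocation to a neighbouring
eligible node. Priors: Poisson (mean 1) on the number of shifts, a uniform
distribution over subsets of eligible nodes for the locations, and
exponentials on every λ and μ with means set to the single-regime ML
estimates (the μ mean is floored at λ̂/10 because μ̂ is frequently zero on
real-looking trees and an exponential with mean zero is degenerate). With
the uniform-subset location prior, the birth/death proposal combinatorics
cancel exactly, and running the sampler with the likelihood switched off
reproduces the Poisson prior on counts and the exponential priors on rates
— a property test, and the check that caught a missing location prior
during development. Eligible shift nodes subtend at least `min_clade_size`
tips (default 5), which both matches how such analyses are configured and
keeps the jump proposals on clades with enough data to matter.

Extinction rates are weakly identified from extant-only trees; tests and
reported summaries therefore lean on λ and net diversification r = λ − μ.
On single-regime data the posterior shift count stays near its prior mean
(the marginal Bayes factor of a neutral shift, averaged over eligible
locations, is close to 1), so "no shift detected" should be read from the
marginal shift probabilities, not from the posterior mean count alone; a
marginal node probability of 0.5 is the default reporting threshold for a
"significant" shift.

Clade rates are extracted per retained sample as branch-duration-weighted
mean λ and μ over the branches below the clade's MRCA (the stem is
excluded: the clade is defined by its crown), clades averaged unweighted
within a category, and r computed per sample so r = λ − μ holds exactly in
every emitted row. Categories are compared with the paired Wilcoxon
signed-rank test on per-sample differences and the two-sample
Kolmogorov–Smirnov test on the marginals; identical series return Wilcoxon
p = 1 and D = 0 by convention since there are no nonzero differences to
rank. Four independent chains can be run and compared by their
log-posterior traces; a Geweke z-test on the log-posterior is the built-in
convergence indicator.

## The synthetic-data generators

`sim_study()` emulates the structure of the real analysis inputs:

* a "true" tree from a forward-time state-dependent birth–death simulation
  (two crown lineages; tip-count stops occur at a uniform time inside the
  event-free interval after the n-th birth, avoiding a zero-length cherry
  at the present) with background speciation 0.06/Myr, extinction
  0.015/Myr, derived-state speciation elevated 2.5-fold, and habitat
  transition rates q01 = 0.0025, q10 = 0.001 per Myr — a handful of
  origins per tree, a couple of them speciose, matching the trait's
  structure in the real system where the speciose freshwater clades hold
  13–20% of species; the generator therefore requires a derived clade of
  at least 20–30 tips and 200-tip trees by default;
* an independent low-rate lifestyle trait (q = 0.004/Myr);
* 35 source trees (0.175 per taxon, the density of the real corpus of 126
  sources for 756 taxa) as random restrictions of the true tree, each
  perturbed by one random rooted NNI move — the smallest controlled unit
  of topological conflict — and resampled until the overlap check passes;
* calibration tables emitted from true node ages: the root and the largest
  clades as fossil-style points (fossils are assigned to speciose,
  recognisable families), plus nine random molecular-style points,
  echoing the real calibration mix of six fossil plus molecular anchors;
* clade-dependent incomplete sampling: derived clades keep tips with
  probability 0.7, the background 0.85, and the realized per-clade
  fractions are reported for use as the sampling-bias table.

Everything is a pure function of its seed; written studies carry the
configuration in `study_config.json` and a provenance header.

**What the synthetic tests do and do not show.** Source-tree conflict here
is NNI-local and unbiased; real conflict is structured (long-branch
effects, correlated sampling across studies), so supertree accuracy on
synthetic corpora is optimistic. Calibration ages are exact true ages;
real fossil calibrations are minima with error. Traits evolve under
exactly the Mk model that is fitted, so origin-count recovery measures the
mapping machinery, not model misspecification. And the state-dependent
generator produces genuinely trait-linked rates, while the inference model
is trait-agnostic (shift locations are free), so agreement between the
trait categories and detected shifts is an empirical outcome, not a
tautology.

## Problem sizes and numerical conventions

The test suite runs property checks at deliberately modest sizes: brute
force parsimony on ≤ 7 leaves (the enumeration oracle is exponential), MAST
oracles on 8-leaf pairs, 50 twelve-taxon recovery corpora, rate recovery on
100–500-tip trees, and rjMCMC runs of 2×10^5 generations on ~100–150-tip
trees; the acceptance script uses a 200-tip study and 5×10^5 generations.
These sizes were chosen so each check has the statistical power it claims
while the whole suite stays desk-scale. Tolerances follow the quantity:
exact identities (r = λ − μ, weight invariance) at 1e−9 to 1e−12, closed
forms against numerical oracles at 1e−6 to 1e−10, and simulation
recoveries at the binomial error of their replicate counts. Ties in the
equal-spacing method, duplicate calibrations, and monomorphic traits all
have the documented deterministic behaviours described above rather than
being errors.
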