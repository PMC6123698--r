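# caridiv

Macroevolutionary analysis of how ecological traits shape diversification,
built around the workflow used for caridean shrimps: a species-level
supertree is assembled from published source trees, scaled to geological
time with fossil and molecular calibrations, binary ecological traits
(habitat: marine vs freshwater/anchialine; lifestyle: free-living vs
symbiotic) are mapped onto it by stochastic character mapping, and
clade-specific speciation/extinction rates are inferred with a
reversible-jump MCMC over birth–death rate-shift configurations. The
package is aimed at systematists who have a corpus of digitised source
trees and trait tables and want the full tree-to-rates pipeline, and at
methodologists who want each stage testable in isolation on synthetic data.

## The stages and their models

1. **Curation** — operational taxonomic units are standardised against a
   synonym table; a leaf naming a higher taxon is replaced by a polytomy of
   its members observed in other sources; studies based on identical
   character matrices are weighted 1/k; matrices that are strict subsets of
   another are removed; taxonomic overlap (≥ 2 shared taxa per source) is
   checked as a graph connectivity problem.
2. **MRP supertree** — Baum–Ragan coding (members of a clade scored 1,
   other taxa in that source 0, absent taxa `?`; rooted by an all-zero
   outgroup), weighted Fitch/Hartigan parsimony, heuristic search by random
   taxon addition plus NNI and SPR hill climbing, strict consensus and an
   exact pairwise maximum agreement subtree (MAST) to strip conflicting
   leaves, plus an advisory detector for novel (unsupported) clades.
3. **Time scaling** — the 'equal' method: calibrated nodes are fixed,
   undated nodes divide each path between dated nodes into equal durations,
   and a second pass enforces a minimum branch duration (default 0.1 Myr).
4. **Ancestral states** — a two-state equal-rates Markov (Mk) model with
   transition probability `P(stay) = (1 + e^{-2qt})/2`; the rate `q` is
   fitted by maximum likelihood via Felsenstein pruning; full character
   histories are drawn by stochastic mapping (joint node states, then
   endpoint-conditioned paths by uniformization), and independent trait
   origins are counted as the modal per-map transition count.
5. **Diversification** — a birth–death model with constant rates per
   regime; shifts attach to nodes (stem branch included) and tips carry
   clade-wise sampling fractions ρ. A reversible-jump MCMC (Poisson prior
   on the shift count, exponential priors on rates) samples shift
   configurations; per-clade mean rates are extracted per posterior sample
   and compared between trait categories with paired Wilcoxon signed-rank
   and two-sample Kolmogorov–Smirnov tests.

A seeded synthetic-data module (`sim_study()` and the generators beneath
it) produces every input the pipeline consumes — including a "true" tree
with elevated speciation in derived-habitat clades — so all stages run and
are tested without any downloads.

## A worked example

```r
library(caridiv)

study <- sim_study(seed = 42, n_tips = 120, m_sources = 20,
                   min_derived_clade = 15)
sources <- assign_independence_weights(study$sources)
mat <- encode_baum_ragan(sources)
ts  <- heuristic_search(mat, replicates = 3, seed = 42)
ts
#> tree_set: 1 equally parsimonious trees, score 536
tree <- if (length(ts$trees) > 1) mast(ts) else ts$trees[[1]]

cal <- filter_compatible_calibrations(tree, study$calibrations)
#> 4 calibration(s) incompatible with the topology dropped
tree <- timescale_equal(tree, cal, min_branch = 0.1,
                        root_age = 1.05 * max(cal$age_ma))

habitat <- setNames(study$traits$habitat, study$traits$species)
fit <- fit_q(tree, habitat[tree$tip.label])
signif(fit$q, 3)
#> [1] 0.0012
maps <- sample_histories(tree, habitat[tree$tip.label], fit,
                         n_maps = 200, seed = 1)
count_origins(maps, "01")$count
#> [1] 1
study$true_transitions["n01"]
#> n01
#>   1
```

The fitted `q` is the Mk transition rate per Myr; `count_origins()` reports
the modal number of marine-to-freshwater origins across the 200 sampled
histories, which here matches the number of transitions the generator
actually simulated. Continuing into the diversification stage:

```r
chain <- run_rjmcmc(tree, config = list(generations = 2e5, store = 5000,
                                        sampling = study$sampling,
                                        default_rho = study$default_rho),
                    seed = 1)
fresh  <- trait_clades(tree, habitat[tree$tip.label], 1, min_tips = 10)
marine <- trait_clades(tree, habitat[tree$tip.label], 0, min_tips = 10)
rates <- clade_rates(chain, rbind(cbind(fresh,  category = "freshwater"),
                                  cbind(marine, category = "marine")))
compare_categories(rates$freshwater, rates$marine)
#> lambda mean ratio 1.157 | Wilcoxon p 7.87e-232 | KS D 0.453 p 0
#> mu     mean ratio 0.2745 | Wilcoxon p 0 | KS D 0.563 p 0
#> r      mean ratio 2.411 | Wilcoxon p 0 | KS D 0.920 p 0
```

The ratios compare posterior mean clade rates between habitat categories
(the generator elevated derived-clade speciation 2.5-fold): here net
diversification in the freshwater clade is 2.4× the marine clades', and the
paired tests separate the two distributions of 4500 retained rate samples
decisively. Speciation-rate ratios fluctuate more between runs because the
'equal' time scaling stretches or compresses uncalibrated clades (see the
methods vignette).

`run_pipeline()` chains all stages from a single YAML config and writes a
manifest of configs, seeds and output hashes; `inst/exec/caridiv` is a thin
shell entry point over it.

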