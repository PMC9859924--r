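---
title: "Models and methods behind beansim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beansim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`beansim` simulates closed recurrent breeding programs for dry bean, a
strictly self-pollinated annual. This vignette is the package's account of
its models: what is simulated, which parameters matter, which choices were
genuinely open and how we resolved them, and what the simulator can and
cannot say about real programs.

## Genome and meiosis

The genome is a genetic (not physical) map: ordered loci with centimorgan
positions on 11 linkage groups. `consensus_map()` emulates the published
Mesoamerican consensus map at the level of its summary statistics — 1010
markers, 2041 cM, 11 groups — because the per-group marker lists of the real
map are not reproduced here. Group lengths are equal and markers evenly
spaced by default (deterministic, hence testable); per-group marker counts
are allocated as evenly as possible (91–92 each), matching the reported
average of ~91 markers per group. Random placement is available under a
seed. QTLs are inserted at their published (group, cM) coordinates; a QTL
beyond its group's nominal end extends the group with a warning.

Meiosis uses the **Haldane mapping function**, r = (1 − e^(−2d/100))/2, with
no crossover interference: along a group the transmitted haplotype is a
Markov walk switching between the parent's two haplotypes with probability
r(Δd) per interval, and groups assort independently. The map's role in the
engine is exactly to supply these recombination fractions; Haldane is the
simplest model consistent with that and is asserted against Monte-Carlo
recombinant counts in the tests. All loci are biallelic 0/1 with phase
tracked explicitly (two haplotypes per plant), which is what makes gametic
LD computable without inference.

## Trait model

All 38 QTLs are purely additive: with `s` the published effect of the
reference allele, genotypes AA/Aa/aa contribute +2s / 0 / −2s, summed over
QTLs. There is no dominance or epistasis, so narrow- and broad-sense
heritability coincide. By package convention allele 1 at a QTL is the allele
whose homozygote contributes +2s.

Three open points and how we fixed them:

* **Optimization direction.** The sources never state which allele is
  "favorable" per trait. Defaults: seed yield maximized; days to flowering
  and white mold severity (1–9 score) minimized. This is configurable
  (`trait_architecture(direction=)`); selection and adjusted fitness operate
  on the *oriented* scale (value × −1 for minimized traits), so the ideotype
  always sits at the upper target bound TG_h = Σ2|s|.
* **Heritability.** Published per-plot narrow-sense h² values per
  environment (nursery, winter nursery, field) are converted to per-plant
  values by fixing V_g = 1, V_p,plot = 1/h², V_e = V_p − V_g and
  H²_plant = 1/(1 + (V_e/y)·n) for plot size n and years y. The printed
  conversion formula is ambiguous about whether V_e is per plant or per
  plot; we read it literally (plot error inflates per-plant error n-fold,
  divided by years), which reduces to the identity at n = y = 1 and gives
  the expected limits. A separate set of round-number heritabilities
  (0.9/0.6/0.3) circulates for the same traits; we implement the
  per-environment table and note the discrepancy.
* **Error variance anchoring.** V_e is scaled against the realized additive
  variance of the cycle-0 parents so that V_g/(V_g+V_e) equals the requested
  per-plant H², then held fixed for the run. Phenotype = genotypic value +
  N(0, V_e/replications).

## Founder synthesis (the synthetic-data stage)

Breeding from a panmictic Hardy–Weinberg population would leave genomic
selection nothing to work with, so founders are produced by a
finite-population **drift burn-in**: linkage-equilibrium start with per-locus
allele frequencies uniform on [0.1, 0.9], then G generations of random
mating at census N. Drift at small N generates LD between linked loci while
leaving allele-frequency expectations untouched. Defaults N = 100, G = 50
are calibration choices of this package (the upstream burn-in procedure's
parameters are not published); an optional viability-selection hook exists
but neutrality is the default because it is parameter-light and suffices for
"substantial LD". `ld_stats()` reports D, D′ and r² on gametic frequencies,
flagging monomorphic pairs as undefined rather than zero, and the tests
assert the canonical r²-decay-with-distance and heterozygosity-decay laws.

What the generator does *not* emulate: real allele-frequency spectra,
population structure or admixture, selection footprints around the actual
QTLs, and the real map's heterogeneous marker density. Passing tests
therefore demonstrate internal consistency of the machinery under a neutral
drift model, not transferability of any particular number to a germplasm
panel.

## Selection strategies

One cycle = full diallel crossing block → F1 … F8 → selection of exactly
`n_parents` finished lines that clone-migrate into the next crossing block
(closed system; nothing enters from outside). Strategies are declarative
step tables (generation, environment, harvest mode, selection rule), so the
presets are inspectable and editable:

* **mass** — visual single-plant culling each generation F2–F5 (retaining
  `mass_prop` = 50% per round), superbulk harvest (one pooled population);
* **bulk** — no artificial selection F2–F4 (bulked families; "natural
  selection" is modelled as neutral random survival, since no competition
  model is published), 10% single-plant truncation at F5;
* **ssd** — one selfed seed per plant F2–F5, selection at F5;
* **pedigree** — among- plus within-family truncation every generation from
  F2 (each at √0.1 so the joint proportion is ~10%), each selected plant
  founding a family;
* **modified pedigree** — plant/row selection at F2 and F4, winter-nursery
  bulk harvests at F3 and F5.

All line-forming strategies then pass staged yield trials — preliminary (F6)
and advanced (F7) among-line selection on replicated family means, keeping
`trial_prop` = 50% per stage — and the cycle ends at F8 with the best plant
of each of the top `n_parents` families recycled. Mass selection reaches F8
as one unstructured bulk: there are no lines whose seed could be replicated,
so its final pick is single-plant and unreplicated.

The per-generation family sizes, proportions and plot designs of the
original programs are not published, so every preset parameter lives in a
`sim_profile()` with documented defaults. Two defaults do the heavy lifting
and deserve emphasis:

* **Plot size 20.** Published h² values are per-plot; in 20-plant short-row
  plots the per-plant heritability implied by the conversion above is small
  (e.g. white mold nursery h² = 0.33 → H²_plant ≈ 0.024). This is what makes
  single-plant (mass) selection weak while replicated family means remain
  informative — the standard quantitative-genetic explanation for the poor
  reputation of mass selection in low-heritability traits.
* **Census capping.** Segregating generations are held near a target census
  (default 2000; 600 in `reduced_profile()`) rather than letting family
  sizes multiply: with 100 parents a full diallel has 4950 crosses, and
  uncapped F2 families would be ~10⁶ plants. Harvest-mode sizes (per plant,
  per family, total) are derived from the census.

Under these defaults the simulator reproduces the qualitative strategy
contrasts documented for real and simulated bean programs — the pedigree
method fixes favorable alleles fastest (it concentrates accurate
family-level selection in every segregating generation) and mass selection
accumulates the largest Hamming distance to the ideotype — and those
contrasts, not any headline percentage, are what the acceptance suite
checks, at 20 runs × 5 cycles on the white mold architecture.

## Breeding frameworks

* **Conventional**: one generation per year, crossing excluded (done over
  winter), so crossing→F8 = 8 years.
* **Speed breeding**: crossing→F4 in one year by rapid single-plant advance;
  we implement the compressed phase as single-seed descent with no selection,
  leaving F5+ untouched; cycle length 5 years. Per-cycle genetics are thus
  identical to conventional in expectation — the frameworks differ only
  per year (ratio 8/5 = 1.6) — which the tests assert. Reports elsewhere of
  speed breeding *retaining less* variance imply the original implementation
  differed genetically in some unstated way; we flag this divergence rather
  than guess a mechanism.
* **Genomic selection**: marker effects from the ridge-regression mixed
  model y = 1μ + Mu + ε, u ~ N(0, Iσ²_u), markers coded −1/0/+1 and centered.
  The variance ratio λ = σ²_e/σ²_u is found by restricted-likelihood
  maximization over log λ using the spectral decomposition of MM′ (the
  training sets are small — the parents — so the n×n form is the cheap one);
  effect estimates are M′(MM′+λI)⁻¹(y−μ̂), identical to the normal-equations
  ridge solution, which an oracle test verifies to 1e−8. Fixed effects
  reduce to the intercept (no covariates are defined). Training population =
  the cycle's parents with nursery phenotypes, trained once per scenario
  (retraining per cycle is a flag, default off). GEBV replaces the
  phenotypic criterion at F5 for mass/bulk/SSD and at F2 and F4 for the
  pedigree methods; "F3:4" in the source description is ambiguous between
  one and two events — we select at F4 on F3-derived families. The marker
  panel excludes QTL loci by default (markers must tag QTLs through LD); an
  oracle panel with markers on the QTLs exists for calibration tests.
  If the REML search fails on degenerate input, a fixed λ equal to the
  marker count is used and recorded on the fit object.

## Reported statistics

Per cycle, on the recycle set (cycle 0 = initial parents):

* **Adjusted fitness** (F − TG_l)/(TG_h − TG_l) × 100 on the oriented scale,
  averaged over individuals (the aggregation order is not specified
  upstream; we average individual fitnesses). **Adjusted gain** is its first
  difference; sums telescope exactly.
* **Fixation**: a QTL is fixed-favorable iff every individual is homozygous
  favorable; percentages over the trait's QTL count. Non-decreasing in a
  closed selfing system.
* **Hamming distance**: mean over individuals of allele count away from the
  all-favorable ideotype, over QTL loci by default ("all loci" being
  ambiguous, a flag extends it to markers).
* **Additive variance**: sample variance of genotypic values; the relative
  series is anchored at 100% in cycle 0.
* **Effective population size**: Ne = 1/(2ΔF) with ΔF the one-step
  proportional decline in expected heterozygosity (gene diversity) between
  consecutive cycles. The original engine's Ne formula is unpublished; the
  heterozygosity-decay estimator is the textbook choice and recovers census
  size within 15% on Wright–Fisher replicates. Non-positive declines yield
  NA, never infinity.
* **Cycles to 95% cumulative gain** uses linear interpolation of the
  cumulative-gain path between integer cycles (fractional answers like 1.02
  are impossible otherwise); all gain in cycle one gives 0.95.
* **PCA**: run-level cycle-1 statistics (gain, Hamming, fixation, variance,
  Ne) standardized to zero mean and unit variance before decomposition
  (whether the original analysis standardized is unstated; with mixed units
  it must), constant columns dropped with a warning.

## Numerical and engineering choices

Truncation selection is deterministic given criterion values; exact ties
break by a seeded uniform draw. Proportional selection always keeps at least
one plant (or family). Degenerate cases error early with actionable
messages: zero founder variance ("use a wider founder set"), constant
training phenotypes, empty harvests, all-fixed burn-ins. The grid engine
derives per-run seeds by a stable 31-bit hash of the master seed and cell
coordinates, so any cell reruns identically in isolation; founder pools and
parent draws are seeded per run (not per cell), so all strategies and
frameworks of a run start from the same parents — paired comparisons with
lower variance. `(config, seed)` determines every output byte.

Problem sizes in the tests and acceptance script are desk-scale choices of
this package: a 110-marker map emulator (same 11 groups and 2041 cM), census
600, 10–20 runs, 5 cycles. The full-scale grid (1010 markers, census 2000,
50 runs × 10 cycles, all 180 scenarios) runs through the same code paths via
`scenario_config()` defaults.

## Known limitations

Single trait per run (no index selection or trait correlations); no
genotype-by-environment interaction beyond environment-specific error
variance; no QTL-effect uncertainty (published point effects are taken as
truth, and effect R² weights are deliberately unused); closed system only —
no germplasm introductions; bulk breeding's "natural selection" is neutral
by default; calendar arithmetic ignores the cost and logistics differences
between frameworks (genotyping costs, winter-nursery fees), which is
precisely the dimension a breeder would weigh next.
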