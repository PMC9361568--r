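---
title: "Models and methods in admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in admixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkit)
```

admixkit studies how two intertwined inputs — the recombination map and the
admixture history of a cohort — propagate through downstream
population-genetic analyses: local-ancestry calling, identity-by-descent
(IBD) based inference of recent effective population size ($N_e$), and
haplotype-based selection scans. Because the real cohorts these analyses
target are access-restricted, the package is built around a synthetic-data
channel whose ground truth is exact: every tract, IBD segment and allele in
a simulated cohort is known by construction. This vignette documents the
models, the parameter choices, and the places where a design was genuinely
open.

## Hotspot-punctuated genetic maps

`synth_map()` draws hotspot centres from a homogeneous Poisson process
(`hotspot_rate` per Mb) and overlays intervals of width `hotspot_width_bp`
at `intensity_fold` times the background rate. The defaults
(background 2e-9 per bp per generation = 0.2 cM/Mb, 10 hotspots/Mb, 2 kb
wide, 100-fold) give maps whose total length is roughly 0.6 cM/Mb with
about two thirds of the genetic length concentrated in hotspots — the
qualitative regime of fine-scale human maps, where most crossover activity
sits in narrow hotspots over a low background.

`derive_sibling_map()` models a second population's map: each hotspot is
kept independently with probability `shared_fraction`, and private hotspots
are added so the expected count is preserved. For a fixed seed, retention
is coupled across `shared_fraction` values (kept sets are nested, private
additions are quantile-coupled), so a series of siblings converges
monotonically to the source map. That coupling is what makes "candidate
overlap is monotone in map sharing" a well-posed single-seed experiment
rather than an average over many map draws.

Crossovers are sampled by inverting the cumulative map: counts are Poisson
with mean equal to the map length in Morgans, positions uniform on the cM
axis. There is no crossover interference; for the block-length scales the
package works at (cM and above), the Poisson model is the standard choice.

## The admixture simulator and its truth channels

`simulate_admixture()` is a forward-time random-mating simulator over one
chromosome. Founders come from `generate_founders()`: allele frequencies
per ancestry follow the Balding–Nichols model around a shared ancestral
frequency (uniform on [0.05, 0.95]) with differentiation set by `fst`, and
haplotypes are independent Bernoulli draws — founders carry no internal LD.
Continuous gene flow follows a schedule of events (source ancestry, start
generation, per-generation fraction): at every offspring generation each
parental slot is filled by a migrant diploid with the event's probability
(events are mutually exclusive per slot; fractions must sum below 1), else
by a random resident; selfing is excluded. Under this model the expected
present-day fraction of a single source with fraction $f$ active for $T$
generations is exactly $1-(1-f)^T$; `expected_ancestry_fractions()` gives
the general closed form, which the test-suite verifies by simulation.

Every haplotype is represented as a founder-block mosaic, spliced exactly
through each meiosis. Two truth channels fall out of that representation:

* **truth tracts** (`cohort_tracts()`): founder blocks mapped to founder
  ancestry, merged into maximal same-ancestry intervals that tile the
  chromosome exactly;
* **truth IBD** (`extract_true_ibd()`): maximal intervals over which two
  haplotypes descend from the same founder haplotype.

Migrant pools may be whole previously simulated cohorts
(`migrant_pools`), which lets source populations carry their own drift
history — the construction used to validate per-ancestry $N_e$ recovery.

What the generator does **not** emulate: mutation (sites are fixed at
founding), background LD within source populations, phasing error, and
crossover interference. Consequences for interpretation are noted per
analysis below.

## Scoring local ancestry

`lai_accuracy()` scores inferred tracts against truth by interval
intersection. Accuracy is genome-length-weighted (bp), not marker-weighted;
bp weighting is invariant to marker density, and the synthetic channel has
no preferred marker set. Both averaging conventions (over the pooled genome
and the mean of per-individual accuracies) are reported, since they differ
in unbalanced cohorts and the convention used by published accuracy figures
is often unstated. Haplotypes are scored as phased: the simulator controls
phase, so there is no switch-error ambiguity; a diploid-unordered mode is a
documented extension point rather than a silent default. `corrupt_tracts()`
emulates a local-ancestry caller's miscalls as Poisson-seeded windows
(default 500 kb) whose labels rotate to another alphabet label; it is the
package's stand-in for an external caller when exercising the scoring and
IBD-labelling stages.

## From IBD segments to recent $N_e$

The pipeline stage mirrors the ancestry-specific IBD workflow: merge gapped
segments (`merge_ibd_gaps()`), label each segment with an ancestry
(`assign_ibd_ancestry()`), partition by label dropping segments under 3 cM
(`partition_by_ancestry()`, the conventional minimum reliable IBD length),
and fit a recent-size trajectory per ancestry (`fit_ne()`).

Segment labelling uses dual-coverage thresholding: a segment gets ancestry
$X$ when both haplotypes carry $X$ over at least `min_fraction` (default
0.9) of its length, with ties and sub-threshold segments labelled
`unassigned`. Segments are labelled whole, never split at ancestry switch
points — splitting would distort the length spectrum that the $N_e$ model
consumes. Whether one or both haplotypes must match, and over what
fraction, is genuinely open in the published workflow descriptions; both
knobs are exposed, with the conservative both-haplotypes default.

The spectrum model is the standard coalescent moment relation. A haplotype
pair coalescing $g$ generations ago accumulates IBD segments of genetic
length $u$ (Morgans) with density $L\,(2g)^2 e^{-2gu}$ over an analysed
length of $L$ Morgans, and the coalescence mass per generation under a
piecewise-constant diploid trajectory $N_g$ is
$q_g = \tfrac{1}{2N_g}\prod_{k<g}(1-\tfrac{1}{2N_k})$.
`expected_spectrum()` evaluates expected bin counts in closed form. Three
numerical/model choices matter:

* **Finite-chromosome law** (`chrom_cm`). The interior approximation above
  ignores chromosome ends; it is accurate when bins are short relative to
  chromosomes, and it is the default. When fitting spectra whose bins
  (3–20 cM) are *not* small against the chromosomes (35 cM in the
  validation experiments), the exact law — the $(L_c - u)$ position factor,
  two end-segment terms, and the whole-chromosome no-recombination atom —
  is available and used; the approximation alone biases fits by tens of
  percent in that regime.
* **Close-kin floor** (`g_floor`). The reporting grid starts at generation
  4 to keep family structure out of the recent estimates, but the *data*
  contain segments from generation 1–3 coalescences. `fit_ne()` therefore
  models coalescence mass from generation 1, tying the sizes below the grid
  to the first grid value. Without this, the handful of near-relative
  segments in the open tail bin crushes the estimate at generation 4.
* **Ancient closure** (`ancient`). Mass beyond generation 50 is closed with
  a constant epoch at the last grid size (default) or truncated.

Fitting minimizes the Poisson negative log-likelihood over $\log N_g$ plus
a squared-difference smoothness penalty (default weight 200, a moderate
value that keeps 47 free epochs from chasing bin noise at realistic segment
counts while leaving constant trajectories unbiased). The start point is a
flat trajectory matched to the total count by the method of moments, so the
fit is deterministic; convergence is declared at a relative objective
change of 1e-6. `bootstrap_ne()` resamples genomic chunks (chromosomes)
with replacement and reports percentile intervals around the full-data fit.

**Calibrating pedigree truth IBD.** Founder-block IBD is not identical to
coalescent-model IBD: when a crossover moves a lineage onto the parent's
other haplotype, that haplotype may itself descend from the same founder,
so the apparent segment continues. The probability of such re-sharing is,
to first order, the mean pairwise founder-sharing fraction $\pi$ — directly
measurable from the complete truth IBD as total shared length over
`n_pairs * genome_cm` (`founder_sharing_fraction()`). Validation workflows
therefore deflate segment and chromosome lengths by $1-\pi$ before
fitting. Simulation depth is a balance: deeper pedigrees raise $\pi$
(length inflation), shallower ones truncate old coalescences whose short
segments the model expects. The validation experiments use 80 generations,
where the missing-mass term is under 4% and $\pi \approx 0.18$ at
$N = 200$; with the deflation, constant-size recovery lands within ~20%
and a two-source admixed design (sizes 200 and 500) recovers both sources
comfortably within the ±35% band the tests assert.

The per-ancestry pair count uses `effective_pairs()`: all haplotype pairs
scaled by the squared mean ancestry fraction — the dual-coverage analogue
of restricting the genome to ancestry-$X$-by-both-haplotypes territory.
This convention is logged in stage metadata; it is a modelling decision,
not an inherited one.

## Merging recent and distant demographies

`merge_trajectories()` concatenates an IBD-based recent trajectory
(generations 4–50) with a distant one (from sequential-coalescent
inference, starting around generation 260) into one piecewise-constant
demography. The domains must not overlap; the gap is bridged either by
holding the last recent value (plain-concatenation semantics) or, by
default, log-linearly in log-generation ("geometric"), whose value at the
gap's log-midpoint is the geometric mean of the boundary values. Both
trajectories are taken as diploid $N_e$; a years timescale is accepted only
with an explicit generation time.

## Map comparison

`bin_rates()` averages rates into physical bins (default 2 kb) via
cumulative-cM differences — exact regardless of interval alignment, with
bin-cM conservation tested to 1e-9. Bins without map coverage are missing,
not zero: zero-filling would manufacture rank agreement between maps.
`spearman_matrix()` compares binned *rates* (rank correlation of cumulative
positions would be degenerate — they are monotone by construction); rank
correlation deliberately discards rate magnitude, so any monotone
rescaling of one map leaves the matrix unchanged. `cluster_order()` applies
average-linkage clustering to $1-\rho$ with label-sorted input for
deterministic ordering. `call_hotspots()` flags runs at `fold` times the
length-weighted median rate in 100-kb flanks (defaults fold 10, minimum
width 500 bp — "hotspot" has no universal operational definition, so the
thresholds follow common practice and stay exposed), and
`hotspot_concordance()` matches two call sets by 50% reciprocal overlap.

## The iHS scan and map sensitivity

`ehh()` computes extended haplotype homozygosity by partition refinement
among carriers: at distance $d$,
$EHH = \sum_h \binom{n_h}{2} / \binom{n}{2}$ over distinct extended
haplotypes. `ihh()` integrates the curve over genetic distance
(trapezoids), truncated by linear interpolation at the 0.05 cutoff
crossing; physical gaps over 20 kb have their trapezoid scaled by
`20 kb / gap`, and gaps over 200 kb censor the core — the defaults the
widely used scan tools document, all exposed. The score is
`ihs_unstd = ln(iHH_ancestral / iHH_derived)`, so positive standardized
scores mark extended derived haplotypes; sign conventions differ between
implementations, and top-|iHS| results are convention-invariant.
Standardization is within 20 equal-width derived-frequency bins (the
statistic's original formulation; under-filled bins merge with their
nearest neighbour). Monomorphic sites are dropped before the walk — they
cannot split haplotypes, and as curve nodes they would only distort the
trapezoids.

Two practical notes for simulated cohorts. First, EHH decay in this
simulator is driven by founder-block boundaries (founders carry no LD), so
the statistic behaves like an IBD-sharing profile — appropriate for
studying *map sensitivity*, which only requires that the integrand be fixed
while the measure (the map) changes. Second, in shallow pedigrees many
cores never decay below the cutoff before the data end; scans used for the
dual-map comparison therefore score data-end-truncated curves
(`require_decay = FALSE`) rather than censoring them, which is symmetric
across maps. The default for single-map scans keeps the conventional censoring
behaviour.

Because EHH curves do not depend on the map, `ihs_curves()` computes them
once and `ihs_scores()` integrates the cached curves against each map —
the dual-map study costs one walk plus cheap integrations.

`compare_runs()` intersects two scans' sites, takes each run's top 1% by
|standardized iHS| (ties at the threshold included), annotates hits with
deduplicated gene symbols (flank 0 by default; both choices exposed), and
reports shared/unique gene counts plus the per-SNP Pearson correlation.
The map-sensitivity experiment in the acceptance suite scans one cohort
(20 Mb, 3,000 sites, 100 haplotypes) against sibling maps at shared
fractions 0.2–1.0: gene overlap rises monotonically with map sharing while
per-SNP correlation stays above 0.8 from 0.8 sharing up — the qualitative
signature that fine-scale map differences move the tails of a selection
scan long before they move its bulk.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order from a single
config (R list or YAML), validating every stage's inputs before anything
runs; any stage input can be an externally produced file in the documented
dialects (windowed local-ancestry tables, IBD caller tables, GEN/NE
tables, HapMap-format or interval maps), so real tool outputs can be
post-processed without invoking those tools. Each stage writes a JSON
manifest with parameters, derived seed and output checksums; identical
configs reproduce identical outputs bit for bit. All randomness flows
through per-stage seeds derived from the single top-level seed.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen to make the statistical checks sharp but cheap:
gene-flow calibration over 20–24 seeds of 60-diploid cohorts; truth-IBD
equivalence on 100 random 20-haplotype cohorts; spectrum-model Monte Carlo
at 1e5 replicates; constant-size recovery at $N=200$ with 100 sampled
diploids over ten 35-cM chromosomes (six in the acceptance script); the
two-source design at sizes 200/500 over six chromosomes; and the dual-map
scan on a 20-Mb chromosome with 3,000 sites. Passing them shows the
machinery is correct under its own model assumptions; it does not certify
performance on real data, where phasing error, LD structure in the
sources, and caller-specific artefacts enter.

## Known limitations

* Single chromosome per simulation run; multi-chromosome cohorts are
  independent runs combined downstream (matching the per-chromosome tool
  chain the pipeline mirrors).
* Founder panels are drawn with replacement for migrants; with small
  panels this inflates IBD sharing, which is realistic for genuinely small
  source populations but should be kept in mind when choosing panel sizes.
* The $N_e$ model assumes the interior/finite-chromosome segment laws
  above; no error model for IBD detection is included (truth IBD or
  external caller output only).
* iHS on unphased data, XP-EHH and related statistics are out of scope.
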