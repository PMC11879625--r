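---
title: "Island size and genome-wide diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Island size and genome-wide diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isledv)
```

## The scientific setting

Island biogeography predicts that larger islands sustain larger
populations, and population-genetic theory predicts that larger
populations retain more genetic diversity: under neutrality an
individual's expected heterozygosity is θ = 4·Ne·μ per site, runs of
homozygosity (ROH) shorten and thin out as Ne grows, and weakly
deleterious insertions such as endogenous retroviruses (ERVs) are purged
more efficiently when 2·Ne·s is large. `isledv` implements the analysis
layer that connects these quantities when the data are *one diploid
individual per island*: there is no population sample, so every metric
must be computable from a single genome plus an all-sites VCF.

The pipeline has five analysis stages and one generative stage:

1. **genotype filtering** (`read_sites()`, `apply_filters()`,
   `build_callable_mask()`),
2. **heterozygosity** (`tally_windows()`, `genome_heterozygosity()`,
   `heterozygosity_variability()`),
3. **ROH calling** (`call_roh_windows()`, `merge_segments()`,
   `summarize_roh()`),
4. **ERV insertion post-processing** (`resolve_overlaps()`,
   `filter_erv_calls()`, `count_hom_nonref()`),
5. **demographic summaries** (`unscale_trajectory()`, `recent_ne()`,
   `harmonic_mean_ne()`), and
6. the **island statistics layer** (`assemble_table()`,
   `simple_regression()`, `correlation_matrix()`, `lasso_select()`),

plus a **synthetic archipelago generator** with exact ground truth
(`simulate_archipelago()` and friends) that lets every stage be validated
with no external data. The exported functions and the two drivers
(`analyze_archipelago()`, `analyze_archipelago_dir()`) are the package's
interface; there is no shell executable.

## Genotype filters

Sites stream from an all-sites VCF (invariant records included — they are
the denominator of per-site heterozygosity). Four thresholds apply, in
the VCFtools semantics:

| rule | default | level | action |
|---|---|---|---|
| minimum site QUAL | 20 | site | record dropped |
| maximum mean DP (over non-missing calls) | 30 | site | record dropped |
| minimum GQ | 20 | genotype | call set missing |
| minimum DP | 5 | genotype | call set missing |

Choices the file format does not decide for us:

* A *called* genotype whose GQ or DP is absent fails conservatively (set
  missing): a call we cannot audit is not counted.
* Multiallelic records are retained and their heterozygous calls count as
  heterozygous; observed heterozygosity is defined over genotyped sites,
  not over biallelic SNPs. `apply_filters(snps_only = TRUE)` restricts to
  biallelic SNPs for users who want the narrower definition.
* Filtering is idempotent, and all internal coordinates are 0-based
  half-open with conversion only at I/O boundaries (VCF 1-based, BED
  0-based).

## Heterozygosity and its variability

Genome-wide observed heterozygosity is the pooled ratio
Σ n_het / Σ n_genotyped over all windows, including partial terminal
windows — it is therefore invariant to the window width, which the test
suite asserts. "Variability in heterozygosity" is not a standardized
quantity; we define it as the sample standard deviation (n − 1
denominator) of per-window heterozygosity over *full-width* 25 kbp
windows with at least 80% of sites genotyped — the same windowing and
genotyped-fraction rule the ROH caller uses, so the two metrics are
computed on the same support. Partial windows are excluded because
unequal window support inflates the spread; the coefficient of variation
is emitted alongside (`stat = "cv"`) for scale-free comparisons, since
the SD of a rate scales with its mean.

## The windowed ROH rule

A 25 kbp window is a ROH window iff it is full-width, contains **zero**
heterozygous genotypes, and has ≥ 80% of its span genotyped (20+ kbp of
25 kbp). Boundary behaviour is exact: 19,999 genotyped sites fail,
20,000 qualify. Consecutive qualifying windows merge into maximal
segments; *any* non-qualifying window — including one failing only the
genotyped-fraction rule — terminates a run, which is the conservative
reading when the data do not say whether data-poor windows may bridge
runs. `merge_segments(bridge_missing = TRUE)` lets data-poor (but not
heterozygous) windows be skipped without terminating the run; bridged
gaps are never added to segment length.

Both a merged-segment count and the raw qualifying-window count are
reported. The two diverge in meaning once ROH saturate a genome: total
length is proportional to the window count by construction, but the
merged-segment count behaves like p·(1 − p) in the per-window qualifying
probability p — it rises, peaks near p = 0.5 and falls again as runs
coalesce. On archipelagos whose smallest islands are deeply inbred
(f_roh ≈ 0.8 under the default generator), the count–length correlation
across islands is therefore strong (r ≈ 0.9) but not perfect; this is a
property of the statistic, not noise.

## ERV insertion post-processing

MELT-style calls arrive with an element family, a percent divergence
from the family consensus, an integer ASSESS evidence flag and the
FILTER column. Processing order is overlap resolution, then filters:

1. **Overlap resolution.** Calls within ±100 bp are clustered
   transitively (single linkage — the description of the rule does not
   specify chained overlaps, and transitivity is the deterministic
   choice). A cluster containing more than one family collapses to its
   single most similar call (minimum divergence, ties broken by earlier
   position then lexicographic family, for determinism); single-family
   clusters are left alone.
2. **Filters.** A call survives iff ASSESS < 3, FILTER = PASS and at
   most 25% of sample genotypes are missing. "25% missing data" counts
   *sample genotypes*, not alleles; 4 of 16 missing (exactly 25%) is
   kept, 5 of 16 is removed.

The per-individual statistic is the raw count of homozygous
non-reference genotypes among surviving calls; missing genotypes adjust
neither numerator nor denominator.

## Demographic summaries

MSMC2 emits times in per-site mutation units and coalescence rates λ.
With per-generation mutation rate μ_g = μ_year · g:

* t_years = (scaled time / μ_g) · g,
* Ne = 1 / (2 · μ_g · λ),

the standard MSMC2 conventions, pinned by a round-trip test
(`unscale_trajectory()` ∘ `rescale_trajectory()` = identity to 1e-12).
Defaults are μ = 3.16e-9 substitutions/site/year and a 1-year generation
time, appropriate for a small passerine.

Two scalars summarize a trajectory. `recent_ne()` returns the epoch
containing time zero; the most recent epoch of a coalescent HMM is noisy,
so `skip_first = TRUE` substitutes the next epoch, but the default keeps
it because no principled exclusion rule exists. `harmonic_mean_ne()`
returns horizon / Σ (Δt_i / Ne_i) with epochs clipped to the horizon
(default 200,000 years) and the final epoch treated as unbounded; the
harmonic mean is the right average because drift compounds inversely with
Ne. Coverage gaps are an error, never an extrapolation.

## Island statistics

Island size enters every model as log10(area in km²) — the
diversity–area relationship is multiplicative, and the species–area
tradition works on the log scale. Simple regressions are ordinary least
squares with Pearson r and a two-sided p-value; when an outlier is
declared, fits with and without it are reported side by side rather than
silently choosing one. Raw p-values match the single-regression
presentation; a Holm-corrected column is added for readers who want
family-wise control. Correlations use pairwise-complete observations
(the correlogram convention), with constant columns flagged as undefined
instead of propagating NaN.

The LASSO (α = 1) selects direct correlates among the collinear
metrics. With island-scale n (8–16), k-fold CV is both unstable and
nondeterministic, so λ is chosen by leave-one-out CV by default;
`nfolds` and a fold seed are exposed for users who insist. Predictors
are standardized to zero mean/unit SD so coefficients are comparable;
the response is centred but not scaled (its units are interpretable).
Complete cases only — with n this small, imputation would dominate the
fit. The solver is glmnet with a 1e-14 convergence threshold; the test
suite checks the returned solution against an independent
coordinate-descent implementation and the L1 subgradient (KKT)
conditions at the selected λ.

## The synthetic archipelago

The generator exists so that the full pipeline can be exercised and
*validated* — each component's output is checked against the parameters
that generated it.

**Genotypes.** A full sequential coalescent is unnecessary for
window-scale statistics, so each chromosome is partitioned into tracts
with independent Exponential(mean 50 kbp) lengths; each tract draws a
pairwise TMRCA T ~ Exponential(rate 1/(2Ne)) generations and places
heterozygous sites at per-site probability min(2·μ_g·T, 1). This yields
E[het] = 4·Ne·μ_g exactly, and long low-T tracts produce multi-window
ROH. What it does *not* reproduce: the heavy-tailed spatial
autocorrelation of real coalescent trees, linked selection,
recombination-rate variation, or gene flow — so passing tests show the
*pipeline* is correct, not that real genomes behave this simply.
Quality artifacts (low QUAL, high depth, low GQ, low DP, uncalled
genotypes) are planted at known positions with a fixed precedence, so
the filter stage can be audited label by label.

**ERVs.** Each locus starts at frequency q0 = 0.2 in every island and
drifts for 4,000 generations under Wright–Fisher binomial sampling with
genic selection s = −1e-4 against the insertion. These defaults put the
smallest default island (Ne = 1,000) at |2Ne·s| = 0.2 — effectively
neutral, fixing ≈ 17% of loci — and the largest (Ne = 400,000, simulated
at the cap) at |2Ne·s| = 80, where insertions are purged: the
drift–selection gradient the ERV analysis is meant to detect.
Populations above the Wright–Fisher cap (10,000) are rescaled to the cap
with s scaled up to hold 2·Ne·s constant, preserving the
selection–drift balance at desk scale. Evidence artifacts (ASSESS ≥ 3,
non-PASS, >25% missing, cross-family duplicate calls within 100 bp at
higher divergence) are planted with known labels.

**Demography.** Each island's true trajectory is piecewise constant
(current Ne for 50 kyr, 1.5× for 50–200 kyr, 2× beyond — a mild
post-glacial expansion signal); the scaled tables are produced by the
exact inverse of the unscaling conversion, optionally with multiplicative
log-normal noise (sd 0.1) on λ.

**Defaults and sizes.** Eight islands spanning 10–4,000 km² with
Ne = 100 · area (individuals per km²), giving Ne from 1e3 to 4e5 and
θ from 1.3e-5 to 5.1e-3. The per-individual genome is 100 Mbp (60 + 40
Mbp chromosomes) — a macrochromosome-scale subset chosen so that the
between-tract sampling error of genome-wide heterozygosity
(≈ θ·√(3·ℓ/G) ≈ 4% with tract mean ℓ = 50 kbp) is small against the
33-fold θ gradient, while a full simulate-and-analyze cycle stays under
a minute. Heterozygosity-recovery checks use a 20 Mbp constant-Ne
genome. All randomness derives from one master seed via stable
per-component stream hashing (`derive_seed()`), so a written archipelago
is byte-identical across runs of the same seed.

One modelling choice was left open by the science: the Ne–area exponent
(`ne_b`). Density compensation on small islands argues for b < 1; b = 1
is the neutral default and the exponent is configurable.

## Numerical and degenerate-input conventions

* Zero genotyped sites make heterozygosity an error, not 0.
* Fewer than 2 qualifying windows make the het SD an error.
* Fewer than 3 complete cases make a regression an error; fewer than 5, a
  LASSO error; more folds than cases suggests leave-one-out.
* Non-positive λ, empty trajectories, coverage gaps, unsorted inputs and
  positions beyond the declared chromosome length are errors.
* Divergence ties in ERV overlap resolution break by position then family
  name, so re-runs are bit-identical.
* Harmonic means are computed with epoch clipping, exact for
  piecewise-constant trajectories (verified against 1-year-grid
  integration in the tests).

## Known limitations

* One individual per island: no within-island π, no site-frequency
  spectra; the heterozygosity of a single genome *is* the diversity
  estimate, as in the underlying study design.
* The tract model ignores recombination structure within tracts, so ROH
  length distributions (as opposed to totals and counts) should not be
  over-interpreted on synthetic data.
* MSMC2 inference itself is out of scope; the package consumes its
  output format and cannot detect gene-flow artifacts in trajectories.
* Regression and LASSO treat islands as independent; no phylogenetic or
  spatial correction is applied.
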