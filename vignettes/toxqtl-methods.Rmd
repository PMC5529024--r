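---
title: "Methods and design of the toxqtl pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the toxqtl pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`toxqtl` maps natural variation in drug response from high-throughput
*C. elegans* phenotyping data: trait normalisation, linkage mapping on
recombinant inbred advanced intercross lines (RIAILs), kinship-corrected
association mapping on wild isolates, Spearman fine mapping, a Tajima's D
selection scan, and allele-enrichment statistics for pooled CRISPR
editing. This vignette records the models, the parameters that matter,
and the design decisions taken where the methodology left genuine
choices.

## Phenotype model

The sorter measures per-animal body length (time of flight, TOF) and
per-well brood counts. `summarizeWells()` reduces each well to the
10/25/50/75/90th length quantiles and the brood count divided by the
number of animals sorted. Quantiles use linear interpolation between
order statistics (`stats::quantile` type 7): the dominant default in
scientific software, chosen because the assay protocol itself does not
pin down a definition.

Normalisation runs in a fixed order: **summarize → assay regression →
outlier pruning → control regression**, mirroring the assay-processing
narrative of plate-based HTA pipelines. Assay regression
(`phenotype ~ assay`) removes day/block shifts; control regression
(`phenotype ~ control phenotype`) removes growth variation visible in
the vehicle-only condition, leaving a drug-specific residual trait. Both
are ordinary least squares, so each is idempotent on its own output and
the control residuals are exactly uncorrelated with the control values.
Whether pruning precedes or follows control regression is not fully
determined by the protocol narrative; the package defaults to
prune-first and exposes `prune_before_control = FALSE`.

Outlier pruning flags values strictly outside
`[Q25 − 2·IQR, Q75 + 2·IQR]`, quartiles computed once, one pass, never
iterated. If **more than** 5% of strains are flagged, nothing is
removed — mass exceedance is treated as signal. At the exact boundary
(1 of 20 strains) pruning still applies; the escape clause exists for
the many-outlier case, and the strict inequality is the reading
consistent with pruning a single extreme strain in a 20-strain panel.
Bubble/contamination calling (an SVM plus visual inspection in the
original tooling) is not reproducible from data alone; it is replaced by
an explicit boolean `exclude` flag on well records.

Broad-sense heritability uses `lme4::lmer(value ~ 1 + (1|strain))` —
REML on the one-way random-effects model, the same fit a practitioner
would write — rather than a bespoke variance-ratio profiler; for
balanced designs it agrees with the ANOVA moment estimator
`(MSB − MSW)/k` to numerical precision (tested), REML clamps the genetic
variance at zero, and a zero-total-variance input returns H² = 0 with a
flag. The estimate is invariant to affine trait rescaling.

Heterozygote gating for dominance assays calls an animal heterozygous
when its fluorescence lies strictly between the 95th percentile of the
dark parent and the 5th percentile of the bright parent; overlapping
gates raise an error asking for manual gates rather than guessing.
Strain comparisons use `aov` + `TukeyHSD` (studentized range,
Tukey–Kramer harmonic-mean correction for unbalanced groups).

## Linkage mapping

The scan statistic is the correlation LOD,
`LOD = −n·ln(1 − r²)/(2·ln 10)`, with the trait standardized to mean 0,
variance 1 before scanning. Missing genotypes are handled
pairwise-complete per marker, the natural choice for a
correlation-based statistic. Exactly one peak is retained per
chromosome (the maximum; sub-peaks are not reported). Confidence
intervals are the maximal contiguous marker run with
`LOD ≥ peak − 1.5`.

Permutation thresholds permute strain labels with rows moved as units
across all traits, preserving trait–trait correlation; the default
threshold is the 95th percentile of the per-permutation genome-wide
maximum LOD over 1000 permutations. A second mode implements the
expected/observed peak-ratio criterion; because "peak" at a candidate
threshold is ambiguous, the package documents its reading
(chromosome-wise maxima above the candidate) and makes no claim to
reproduce any particular published cutoff, which depended on the real
marker correlation structure.

Variance explained inverts the LOD formula
(`ve = 1 − 10^(−2·LOD/n)`) and is reported both raw and as a fraction
of broad-sense heritability.

## Mixed-model association

Kinship is the VanRaden realized relationship on −1/+1 inbred coding:
columns centered by allele frequency, cross-product scaled by
`2·Σ p(1−p)`, so a fully inbred panel has diagonal ≈ 2 (= 1 + f).
Because frequencies are estimated within the sample, off-diagonals
carry a small `−2/n` centering offset — visible in tiny panels,
negligible at realistic sizes.

`emmaReml()` maximizes the restricted likelihood of
`y = Xβ + u + e`, `u ~ N(0, σ²_g K)`, `e ~ N(0, σ²_e I)` through one
eigendecomposition of `S(K + I)S` (`S` the fixed-effect projection;
adding `I` separates the null space exactly) followed by a grid of 100
intervals on `log₁₀ δ ∈ [−5, 5]`, `δ = σ²_e/σ²_g`, with local
refinement by `optimize` at tolerance 1e−10. The grid bounds cover
variance ratios from 1e−5 to 1e5; an optimum pinned at the upper bound
means "no detectable genetic variance" and degrades gracefully to OLS
behaviour. The per-marker test is a t-test on the GLS coefficient at
that marker's own REML optimum (the exact, P3D = FALSE regime; a
P3D = TRUE mode reuses the null-model δ for speed). Markers below 5%
minor allele frequency — computed on the phenotyped strains — are
dropped before testing; the genome-wide threshold is Bonferroni
α/m on the −log10 scale.

Regions of interest: the ROI half-width is calibrated by simulating a
trait with 20% variance explained at every eligible marker, finding the
most-correlated marker of the panel, and taking the smallest width
capturing 95% of the rank distances. Significant SNVs on one chromosome
separated by at most that width merge into one region, which is then
extended by the width on both sides and clipped at chromosome ends. Peak
reporting breaks p-value ties to the leftmost position.

## Fine mapping

"Kinship-corrected phenotype" is not a uniquely defined object; the
package's default subtracts the null-model BLUP of the polygenic effect,
`y − β̂₀ − K(K + δ̂I)⁻¹(y − β̂₀)`, and a `whiten` switch instead
multiplies by `(K + δ̂I)^(−1/2)` for fully exchangeable residuals. Both
are exposed because they answer slightly different questions (removing
predicted polygenic values vs. decorrelating the noise).

Variant ranking uses Spearman's rho with average ranks — genotype
vectors are binary, so ties are the rule, which is also why the exact
p-value is computed by full enumeration of the rank permutation
distribution (n ≤ 8; the two-sided p is the fraction of permutations
with |rho| at least the observed) rather than a no-ties formula; larger
n uses the Student-t approximation. Effect classes (HIGH/MODERATE/...)
are consumed from the input annotation; no effect prediction is
performed.

## Tajima's D

`tajimasD()` implements the standard statistic with its usual
normalizing constants; π is accumulated site-wise over non-missing
calls and the constants use the nominal sample size. Windows advance in
SNV-rank units (300-SNV windows, 100-SNV steps by default) and never
span chromosomes. The reference strain ("outgroup = N2") is excluded
from the sample before computing S and π — the statistic needs no
polarization, so exclusion simply keeps the reference haplotype out of
the within-sample diversity; an include switch exists.

## Pooled CRISPR enrichment

Allele counting is exact full-span matching against the wild-type and
edited amplicon sequences — by design, not as a shortcut: the edit is a
known substitution in a fixed amplicon and anything else (indels,
errors) is deliberately uncounted. The headline contrast compares each
drug's post-treatment counts with the no-drug post-treatment counts
(the post-vs-pre contrast is also exposed). The two-sided Fisher p sums
the probabilities of all fixed-margin tables no more likely than the
observed one — stated explicitly because two-sided conventions differ.
The power helper shows why depletion of a rare edit is hard to detect:
at sub-percent editing fractions, even deep amplicon sequencing leaves
the binomial noise on a handful of edited reads dominant.

## Synthetic data: what it emulates and what it does not

* **RIAIL genotypes** — crossovers are a Poisson process on the genetic
  map with no interference; the expected breakpoint count per chromosome
  is the map length in Morgans times `1 + n_intercross_generations`
  (selfing-only panels carry one meiosis-equivalent). The construction
  history of real panels (generation count, map function) is not
  published detail, so both are parameters; the default of 10 intercross
  generations matches an advanced-intercross design. Chromosomes are the
  six *C. elegans* linkage groups at ~50 cM each.
* **Wild panels** — Balding–Nichols: per-marker ancestral frequencies
  uniform on (0.1, 0.9), per-subpopulation frequencies Beta-distributed
  at the stated Fst-like divergence, inbred strains drawn independently
  per site. An optional founder-mosaic mode (a handful of founder
  haplotypes per subpopulation, recombinant strain mosaics) adds the
  long shared haplotypes of a selfing species, which is what makes ROI
  calibration non-trivial; site-independent mode remains the default.
  The simulator does **not** emulate a neutral site-frequency spectrum —
  marker panels are ascertained common variants — so absolute Tajima's D
  levels on simulated panels are shifted positive and only relative,
  within-panel structure is meaningful.
* **Phenotypes** — a sum of standardized QTL genotypes at stated
  variance fractions, an optional polygenic term from all markers, and
  Gaussian noise; realized variance explained matches the request within
  sampling error (tested by Monte Carlo).
* **Well records** — strain effects in TOF units plus per-assay shifts
  and a control condition coupled by a stated coefficient; no plate-edge
  effects, no optics model.
* **Read counts** — deterministic selection recursion
  `f' = f·wᵍ/(f·wᵍ + 1 − f)` with binomial sampling at stated depth.

Passing tests on these generators demonstrates statistical correctness
of the machinery — calibration under the null, parameter recovery,
oracle agreement — not that real sorter data are free of the artefacts
(bubbles, contamination, batch idiosyncrasies) the generators do not
model.

Every generator takes an explicit seed, draws from one seeded stream per
call, restores the caller's RNG state, and is bit-reproducible.

## Problem sizes

The package's own verification runs use: a 250-line × 500-marker panel
with 1000-permutation thresholds and 200 null scans for calibration; 100
replicates for QTL-recovery (a 20%-VE QTL localized within its
1.5-LOD-drop interval); dense brute-force REML grids (1e5 δ-points) on
n ≤ 12 fixtures; 1e4 neutral coalescent samples for the Tajima null; and
full enumeration oracles for Fisher and Spearman tests. The acceptance
script scales the study conditions as 265 RIAILs × 1454 markers, 138
wild isotypes, and 2×10⁵-read amplicon depth, sizes chosen so
Monte-Carlo error is small against the quantities reported.

## Known limitations

* Single-QTL scans only: no composite interval mapping, no multi-QTL
  models, no genotype imputation between markers.
* No LOCO kinship and no permutation thresholds for the mixed-model
  scan (Bonferroni only, matching the association-mapping convention
  used here).
* The peak-ratio threshold mode documents its own reading of an
  ambiguous criterion and should not be compared numerically against
  cutoffs derived from other readings.
* Exact-match allele counting ignores indel outcomes entirely; it
  quantifies the two specified alleles, nothing else.
* The founder-mosaic LD model is a caricature: real selfing populations
  have heterogeneous haplotype ages and swept regions that it does not
  attempt to capture.
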