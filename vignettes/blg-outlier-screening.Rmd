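---
title: "Methods: screening milk for low-expression BLG alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening milk for low-expression BLG alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blgscreen)
```

# The problem

β-lactoglobulin (BLG) is the dominant whey protein in bovine milk. The two
common protein isoforms, A and B, are encoded by alleles that also differ in
transcription level, and rarer regulatory sub-alleles — in particular a
synonymous G>A change on the B haplotype, here called B′ — can halve the
milk concentration of the B isoform without changing the protein itself.
Because the B′ protein is chemically identical to B, the variant is
invisible to protein typing and must be found as a *quantitative outlier*:
a cohort of cows whose B-isoform concentration is far below what their
protein genotype predicts, traced back through the pedigree to a carrier
sire, and confirmed at the RNA level.

`blgscreen` implements that discovery chain as composable tibble-in,
tibble-out functions, together with a seeded generator that produces every
input the chain consumes. This vignette records the models, the defaults
and the design decisions.

# Isoform quantification from charge-state envelopes

Under electrospray ionisation an intact ~18.3 kDa protein appears as a
series of multiply-protonated ions. For a neutral average mass $M$ and
charge $n$,

$$ m/z = \frac{M + n\,m_p}{n}, \qquad m_p = 1.00728\ \text{Da}, $$

and inversely $M = n\,(m/z) - n\,m_p$. The assay quantifies each isoform by
summing the extracted intensities at its 10+–13+ signals. Choices made
here:

* **Proton-mass convention.** The adduct mass is taken as the average
  proton mass 1.00728 Da; this reproduces all eight diagnostic m/z values
  to one decimal from the panel's neutral masses.
* **Panel neutral masses** default to the values obtained by deconvoluting
  the diagnostic m/z themselves (A: 18361.05 Da, B: 18274.99 Da). These
  differ by roughly 2 Da from sequence-derived literature masses of the two
  isoforms; the panel is internally consistent and the constructor enforces
  agreement between mass, charge and m/z to ±0.05.
* **Extraction window** ±1.0 m/z (configurable). It must exceed the
  1-decimal rounding of the printed positions and the peak width, while
  staying below half the ~6.6 m/z A–B envelope gap at 13+, the tightest
  separation in the scheme; the constructor warns if windows of different
  isoforms collide at a shared charge state.
* **Spectra are profiles, not centroids**; extraction sums every grid point
  inside the window, matching the "sum the signals" definition of the
  assay. Window boundaries are applied with a 10⁻⁹ m/z tolerance so that
  grid points nominally on the boundary are treated identically for every
  peak.
* **Calibration** is linear through the origin from one reference pair per
  isoform: 180 arb units ↔ 4.8 g/L (A, the mean for AA milks) and 80 arb
  units ↔ 3.4 g/L (B, the mean for BB milks). The B channel cannot
  distinguish the B protein from the rare C isoform; C-carrying milks
  therefore inflate `B_units`, and C carriers are excluded downstream from
  genotype-sensitive analyses.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream property is demonstrated.

* **Haplotypes and pedigree.** Four haplotypes A, B, B′, C. Default
  population frequencies are A 0.55, B 0.435, B′ 0.015 (the 1–2 % range
  reported for Friesian-type populations) and C 0 — C-carriers are
  generated only when a test needs the exclusion logic, since every
  analysis removes them. Each cow draws one haplotype from her sire (fair
  Mendelian coin) and one from the population; a configurable fraction of
  sires is forced to the carrier genotype {B, B′}.
* **Expression model.** Expected expression per allele copy is `base_A`
  for A, `base_A·rho_B` for B and `base_A·rho_B·rho_Bprime` for B′, with
  defaults `rho_B = 0.642` and `rho_Bprime = 0.419` (the RNA-level ratios).
  C expresses at the B level. Channel concentrations are allele sums times
  per-channel response factors, tuned by default so AA milks average
  180 arb units and BB milks 80.
* **Noise.** Concentrations receive mean-one multiplicative lognormal noise
  (concentrations are positive and dispersion scales with level). The
  screen-scale CV is not identifiable from the published group means alone,
  so it is a free parameter with default 0.15 — a value that keeps the
  AA/AB/BB clusters visibly separate, as in real screens. Design effects
  (herd, plate, birth year, breed) are additive Gaussian intercepts in arb
  units, zero by default.
* **The carrier-sire preset** (`simulate_sire99()`) reproduces the half-sib
  segregation design: 576 daughters of one {B, B′} sire, dam pool 41 % A,
  so ~230 daughters are AB heterozygous and split roughly evenly by the
  transmitted sire allele. Per-allele B-channel contributions are drawn
  from truncated normals with the group statistics 54.0 ± 8.7 (B) and
  25.9 ± 6.1 (B′) arb units. Two deliberate choices: (1) the preset
  calibrates to the *protein-level* group statistics, whose implied B′:B
  ratio (≈ 0.48) differs from the RNA-level 0.419 — protein concentration
  need not track mRNA one-to-one; (2) the draws are Gaussian rather than
  lognormal because the segregation analysis fits a two-Gaussian mixture,
  and a misspecified (skewed) generator would make the EM component means
  asymptotically biased — the recovery property would then be testing the
  bias of a deliberately wrong model rather than the estimator. Truncation
  at zero is 4+ SDs from either mean and has no practical effect.
* **Spectra.** Gaussian peaks (default SD 0.5 m/z, not derivable from the
  printed assay description) at the panel's diagnostic positions, equal
  area per charge state, on a 0.05 m/z grid over 1400–1900. The grid step
  divides the 1-decimal peak positions exactly, so every peak is sampled
  symmetrically and noiseless round-trip quantification recovers abundance
  ratios to numerical precision (≤ 10⁻⁶ relative, verified in tests).
* **RNA-seq allele counts.** A lognormal library factor (CV 0.3) scales
  both the total library and the per-site Poisson depth (default mean
  1000×); at each heterozygous diagnostic SNP the alternate count is
  binomial with the allelic fraction implied by the expression model, e.g.
  0.419/1.419 ≈ 0.295 for the B′ allele in a BB′ cow. Allele conventions:
  the two missense SNPs carry the A-lineage allele as `ref`; the G>A site
  carries G (B) as `ref` and A (B′) as `alt`.
* **Milk composition.** Per-cow components are drawn around genotype-group
  means with SD = SEM·√n from the group table. Casein and true protein are
  *not* drawn independently: the per-cow casein number is drawn around the
  group ratio and multiplied by the drawn true protein. In real milk casein
  and true protein are strongly correlated, which is exactly why the
  published casein-number SEMs (~0.004) are an order of magnitude tighter
  than independent draws would produce; independent draws would destroy
  the B′B′ > BB > AA ordering that the data show. Crude protein is true
  protein plus a non-negative whey draw, enforcing
  casein ≤ true protein ≤ crude protein by construction.

What the generator does **not** emulate: linkage disequilibrium between
scan variants, selection and non-random mating in the pedigree, seasonal
and lactation-stage trends, mapping bias in allele counts, and
heavy-tailed measurement artefacts. Passing tests therefore demonstrate
estimator correctness under the stated statistical structure, not
robustness to every feature of field data.

# Screening and segregation

Genotype calls use a presence floor (default 10 arb units — about an order
of magnitude below the single-allele signal of either channel) and, within
AB calls, a B:A ratio cut of 0.45 for the low-B flag: the normal
heterozygous ratio under the default calibration is ≈ 0.6 and the
low-expression group sits near 0.29, so 0.45 bisects the gap. Within BB,
the low flag uses a quantile of the BB cluster (default 5 %) because a
fixed ratio is unavailable without an A signal. Outlier cohorts take a
fixed count `k` per class (the screen design used 180), ranked by B:A
ratio (AB) or B signal (BB) with lexicographic tie-breaks for
determinism.

Sire enrichment reports, per sire, his daughters in the cohort and an
upper-tail hypergeometric probability given his total daughters and the
cohort and population sizes. The ranked count table is the primary output;
the p-value formalises what is otherwise descriptive counting.

The segregation mixture is a two-component univariate Gaussian mixture fit
by EM. Numerical choices: initialisation by a median split (deterministic
and safe under unimodality), a variance floor of
max(10⁻¹², 10⁻⁶·var(x)) against degenerate spikes, convergence when the
log-likelihood improves by < 10⁻⁸, monotonicity asserted at every
iteration, components reported in descending mean order so labels are
permutation-stable. The bimodality verdict compares the mixture to the
single-Gaussian MLE via 2·Δloglik. This statistic is non-regular under the
null, so no chi-square reference applies; the default decision threshold
of 10 was chosen once against seeded unimodal simulations (null statistics
typically < 5) and is far exceeded in segregating families (≈ 56 in the
preset at its default size, n ≈ 231 heterozygous daughters).

# Allele-specific expression

Class assignment maps the two missense SNPs to the A/B protein lineage
(their alt doses must agree — they are in complete linkage in this system;
disagreement is flagged `inconsistent` rather than guessed) and splits
B-lineage alleles into B/B′ by the G>A site. Expression is normalised by
each animal's total read count relative to the cohort average.

Allelic ratios are estimated as read-weighted pooled count ratios
(Σalt/Σref across animals), with animal-level bootstrap SDs; a
per-animal-mean mode is available. For the B′-vs-B contrast two estimators
are provided and neither is privileged:

* **within-BB′**: alt/ref at the G>A site inside BB′ heterozygotes — a
  direct within-animal contrast.
* **AB′-vs-AB**: the B-lineage/A count ratio at the missense site in AB′
  animals divided by the same ratio in AB animals. Because the A allele is
  the common reference in both classes, the quotient of the two
  *odds*-type ratios estimates B′/B consistently; a quotient of allelic
  *fractions* (alt/(alt+ref)) would not, which is why the odds form is
  used. A default per-site depth filter of 20 reads keeps unstable
  fractions out of the pool.

Both estimators recover a generating ratio of 0.419 within two bootstrap
SDs at depth 1000 with the published class sizes (14 BB′, 19 AB′, 190 AB),
and the within-class B-vs-A ratio recovers 0.642; these are exercised in
the test suite and the acceptance script.

# Association scan

The analysis is two-stage: phenotypes are first adjusted by a linear mixed
model (fixed: birth year, breed; random intercepts: herd, plate; REML via
`lme4`), then the centred residuals are scanned per variant. The two-stage
form keeps the per-variant cost trivial at desk scale and mirrors the
pre-adjustment convention of large-scale dairy scans; it is an
approximation to a joint per-variant mixed model. Random factors with
fewer than three observed levels are demoted to fixed effects.

The GRM is VanRaden's centred, frequency-scaled cross-product,
$G = ZZ'/(2\sum_j p_j(1-p_j))$, with per-variant mean imputation of
missing dosages. When a GRM is supplied, the scan fits the polygenic
variance ratio once by REML through an eigendecomposition of $G$
(profiling out the intercept and residual variance, optimising the log
variance ratio over ±10), then tests each variant by generalised least
squares in the rotated coordinates; with an identity GRM this reproduces
the plain least-squares scan to machine precision. Wald p-values use the
t distribution with n − 2 degrees of freedom; monomorphic variants return
`p = NA`. LOCO builds the GRM from all chromosomes except the one being
scanned, so polygenic control never absorbs the tested signal. Note that
sample-frequency centring shrinks realised relatedness slightly: simulated
parent–offspring pairs average ≈ 0.48 rather than 0.50 at n = 60.

The Bonferroni threshold is α/(variants × traits); at α = 0.01 over
16,122,289 variants and three traits this is 2.07 × 10⁻¹⁰.

# Milk composition

Filters drop samples with SCC > 400,000 cells/mL, missing genotypes, and
(by default) C-allele carriers, logging each exclusion with its reason.
Group summaries report mean and SEM (sample SD/√n, n−1 denominator — this
convention reproduces the worked 1.38 ± 0.24 g/L example from three
values). The group casein number is the ratio of group means (27.4/32.3 →
0.85), matching the published table arithmetic; a per-cow-ratio mode
exists behind a flag. Pairwise comparisons after the one-way ANOVA use
Tukey's HSD — the published analysis names only "ANOVA" with letter codes,
and Tukey is the standard choice for all-pairs letter displays — with a
hand-rolled insert-and-absorb compact letter display, validated in tests
against an independent implementation and against the defining property
(two groups share a letter iff their adjusted p ≥ α).

# Problem sizes and limitations

The test suite and acceptance script run the chain at deliberately modest
sizes chosen to exercise every estimator well inside a single-CPU session:
populations of 10³–2×10⁴ cows for frequency and classification properties,
the 576-daughter carrier-sire preset, published class sizes (98/191/19/
70/14) for ASE, 500 animals × 1000 variants for scan calibration, 5000
variants for GRM properties, and the 28/64/29 composition groups.

Known limitations: the mixture is fixed at two components; no C-specific
MS channel exists (C is folded into B by design); the scan does not model
LD, imputation, or multi-breed structure; the AB′-vs-AB estimator assumes
equal A-allele expression across the two classes; and all acceptance-level
recoveries are demonstrated under the generator's statistical assumptions
stated above.
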