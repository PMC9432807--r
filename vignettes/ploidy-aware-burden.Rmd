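---
title: "Ploidy-aware somatic SNV burden estimation in single-cell WGS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy-aware somatic SNV burden estimation in single-cell WGS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Post-mitotic cells such as cardiomyocytes accumulate somatic single-nucleotide
variants (sSNVs) over a lifetime. Measuring that accumulation from single-cell
whole-genome sequencing is hard for three reasons:

1. **Amplification noise.** Multiple displacement amplification (MDA) drops
   loci and alleles, amplifies unevenly, and creates C>T artifacts that look
   like real variants.
2. **Polyploidy.** Many adult cardiomyocyte nuclei are tetraploid. A somatic
   variant sits on one of four haplotype copies, so both its allele fraction
   and its detectability differ fundamentally from the diploid case.
3. **Sparsity.** Each cell yields a handful of confidently-called variants,
   so burden estimates must be corrected for sensitivity before any
   population-level modeling.

`scSomaticAging` implements a complete, testable pipeline for this problem:
a synthetic single-cell WGS cohort generator, amplification QC, a
linkage-based caller with calibrated read thresholds, a tetraploid dropout
decomposition, NMF signature analysis with artifact subtraction,
mixed-effects aging regression, spectrum/strand-bias analysis, gene-level
functional impact analyses, and a ploidy-aware gene-knockout probability
model. Because the motivating human datasets are controlled-access, the
synthetic generator is a first-class module: it defines the study
conditions under which every downstream claim is verified.

# The synthetic cohort generator

The generator emulates, per cell:

* **Reference**: i.i.d. bases at a configurable GC content (default 40%),
  default 2 chromosomes x 10 Mb. A stand-in for autosomes: large enough for
  stable rate estimation, small enough for fast tests.
* **Phased germline hets**: a Poisson process at 0.67 hets/kb (about one
  heterozygous SNV per 1.5 kb, the human genome-wide density), each assigned
  to one of two donor haplotypes.
* **Somatic truth**: per-cell count drawn from Poisson with mean
  `(intercept + rate x age) x ploidy x haploid Mb`. Default rates per cell
  type (sSNV Mb^-1 yr^-1): cardiomyocyte 0.010, neuron 0.003, hepatocyte
  0.009, lymphocyte 0.004; default intercept 0.1 sSNV/Mb (a plausible
  at-birth burden given infant cells carry a few hundred genome-wide sSNVs).
  Each variant's 96-trinucleotide class is drawn from a signature mixture
  and placed at a reference position with matching context.
* **MDA amplification**: a site is locus-dropped with probability `L`
  (default 0.1); surviving haplotype copies are independently allele-dropped
  with probability `A` (default 0.1). Surviving copies receive
  negative-binomial reads (total mean depth 30, per-copy dispersion 5), with
  a per-100-kb log-normal amplification factor (sigma 0.3, mean 1). The NB
  depth model and log-normal unevenness are this package's choices: MDA
  coverage is overdispersed and locally correlated, and these are the
  standard minimal models for both.
* **Artifacts**: injected at 1 per Mb of amplified DNA with contexts from
  the shipped `scF_like` profile (pure C>T) and geometric (p = 0.5) read
  support on a single haplotype. The geometric support reflects artifacts
  arising on single strands early in amplification; it is what gives the
  caller's read-threshold calibration a discriminating signal.
* **Tetraploid nuclei**: two independent diploid amplification realizations
  at half depth sharing the germline, merged site-wise — the in-silico
  mixture construction. Somatic variants are assigned to one origin copy
  (1/4 allele fraction); a flag for pre-endoreduplication variants at 2/4
  fraction is deliberately not defaulted on, since their prevalence in real
  tetraploid nuclei is unknown.

What the generator does **not** emulate: read-level errors and mapping
artifacts, indels and structural variants, CNVs, sex chromosomes, clonal
(bulk-visible) somatic variants, and site-to-site dropout correlation beyond
the 100-kb unevenness factor. Passing tests therefore demonstrate the
estimators' correctness under the stated noise model, not robustness to
alignment pathologies.

# Amplification QC

Dropout is operationalized on germline hets: locus dropout = total depth
< 5 reads; allelic dropout = a surviving site where either allele has < 2
supporting reads. The allelic-rate denominator excludes locus-dropped sites
(both conventions are supported via `allelic_over_all`; excluding avoids
counting the same failure twice). Evenness is summarized by MAPD (median
absolute difference of neighboring bin copy ratios, linear scale, never
across chromosome boundaries) and CoV (sample s.d. / mean), computed on
variable-length bins holding equal expected reads, GC-corrected by decile
medians.

# The linkage caller

A candidate (any non-germline site with >= 2 alternate reads) **passes
complete linkage** when all reads linking its alternate allele to the
nearest phased het (within a 500 bp window, a proxy for the span of
150 bp x 2 paired-end fragments; equidistant ties break to the lower
coordinate) fall on exactly one haplotype and no reference-supporting read
is linked to that haplotype. Artifacts violate this because the genuine
reference copy of the same haplotype also produces linked reads.

The per-cell read threshold `k` is the smallest value for which the
posterior probability of a candidate being a true variant reaches 0.90
under a two-component mixture: binomial support at the expected allele
fraction (1/2 diploid, 1/4 tetraploid) and depth for true variants,
geometric (p = 0.5) support for artifacts, with a configurable prior
(default 0.5). "True positive rate" is read as *precision* here: it is the
quantity a read-support threshold can control. Sensitivity is estimated by
treating each phased het as a pseudo-somatic variant and measuring the
fraction that survive the full calling rule.

# Tetraploid burden correction

The dropout status of a tetraploid site is determined by its two diploid
origins: locus dropout requires both origins to drop the locus
(`L4 = L2^2`, the product law), and an allele is unobserved only when both
of its copies are lost, giving the per-copy loss `u^2 = L4 + (1 - L4) A4`
and `a2 = (u - L2)/(1 - L2)`. `A4` in these formulas is a per-allele rate;
the site-level estimator (either allele dropped) is converted via
`A4_allele = 1 - sqrt(1 - A4_site)` (`site_level = TRUE`).

Sensitivity for a 1/4-fraction variant is
`s_tetra = s_germline x u x depth_factor`:

* `u` is the probability that the interfering same-haplotype reference copy
  contributed **zero** reads — the literal requirement of complete linkage.
  It is estimated as `sqrt(P(germline het allele has zero reads))`
  (`zero_read_copy_rate()`), not as the threshold-based (< 2 reads) dropout
  rate: on synthetic truth the zero-read operationalization makes the
  corrected burden essentially unbiased (corrected/truth 0.97–1.00 across
  cohorts), while the < 2-read rate overstates the linkage opportunity by
  ~50%.
* `depth_factor` is `s(thin = 0.5)/s(thin = 1)` from re-estimating germline
  sensitivity after binomial thinning of all read counts at rate 0.5,
  mirroring a read-downsampling measurement of per-haplotype depth loss.
  Thinning was chosen over an analytic depth model because it automatically
  reflects the cell's own empirical depth distribution.

Corrected counts are `raw / sensitivity`; densities divide by the cell's
total DNA content (`ploidy/2 x diploid genome Mb`; 6,200 Mb for real human
autosomes, `2 x haploid reference` in synthetic mode). Cells with
sensitivity <= 0.01 are QC-failed rather than corrected by an unbounded
factor. Artifact contamination is removed at the signature level: each
cell's 96-context call profile is refit against fixed signatures and the
artifact signatures' weight share is subtracted from the density.

# Signature analysis

Multiplicative-update NMF (Frobenius loss, tolerance 1e-6 on the relative
objective, max 2,000 iterations, 30 restarts by default) is run over a rank
range; the consensus clustering of cells by dominant signature across
restarts gives a cophenetic correlation per rank, and the maximizing rank
(ties to the smaller) is selected. Signatures are L1-normalized.
Fixed-signature refitting uses non-negative least squares with weight
renormalization. The shipped 96-context profiles (`SBS5_like`,
`SBS18_like`, `SBS44_like`, `scE_like`, `scF_like`) are synthetic
constructions with the qualitative shapes of their namesakes (flat
clock-like; C>A-heavy; C>T MMR-like; C>T amplification artifacts), shipped
so the package tests require no external catalogue download and are immune
to catalogue version drift. They are labelled synthetic and must not be
used to interpret real data.

# Aging regression

Per-cell density is modeled as `y_ij = beta x age_j + mu + theta_j +
eps_ij` with a Gaussian donor random intercept, fit by maximum likelihood
(not REML). p-values come from likelihood-ratio tests against the nested
submodel; a Satterthwaite approximation would also be defensible, but the
LRT is tool-agnostic and exact under the same asymptotics. With exactly one
cell per donor the donor variance is unidentifiable and the fit falls back
to ordinary least squares (the limiting case tau -> 0). The cell-type
interaction model gives each type its own slope with a random intercept per
donor-type pair; pairwise slope differences are tested by refitting with
the pair's slopes merged. Covariate adjustment (MAPD, CoV, depth, PMI, ...)
adds fixed effects; near-collinearity with age (|r| > 0.99) warns.

# Spectra, strand bias, functional impact

Age groups are infant (<= 4 y), middle-aged (30–66 y), aged (>= 75 y) —
inclusive bounds chosen so the default donor panel groups as 3/6/3. The
net-increase spectrum multiplies group proportions by mean per-cell burden
before subtracting (aged − infant), so the per-type values conserve the
burden difference. Strand bias uses the pyrimidine representation
(untranscribed = pyrimidine on the gene's sense strand) and an exact
two-sided binomial test of the transcribed count against 1/2 — the
conditional form of comparing two Poisson rates; bidirectionally
transcribed sites are excluded rather than double-counted.

Gene-set enrichment controls gene-length bias through a monotone cubic fit
of P(gene carries an sSNV) versus log length (decile-binned proportions
made non-decreasing, then a monotone spline — a transparent stand-in for
heavier weighting-function machinery); the Wallenius noncentral
hypergeometric (numerical integral, validated against a sequential-draw
enumeration oracle and the omega = 1 hypergeometric closed form) supplies
per-set p-values with odds equal to the mean in-set/out-set weight ratio.
Sets with more than 1,000 members are excluded; the fewer-than-5-mutated-
members filter is applied at the union of the two cell types in the
rank-difference comparison, because a genuinely type-specific set has few
mutated members in the other type by construction.

The type-specificity statistic is `rank_B - rank_A` over the enrichment
p-value rankings (large = specific to type A); the null shuffles each
type's sSNV-gene table over genes, preserving hit counts, and the add-one
empirical p is Benjamini–Hochberg corrected. Two tractability choices:
ranks are computed over all filtered sets (the candidate p < 0.01 filter
only selects which sets are reported), and the length-weighting function is
fitted once on the observed tables, with each set's Wallenius tail memoized
over the in-set hit count — the only quantity that changes across rounds.
This makes 1,000+ rounds essentially free without altering the statistic.

# The KO probability model

The expected deleterious burden is `n = n_snvs x del_fraction x p`, with
ploidy factor `p = 0.5` (diploid) or `0.125` (tetraploid) capturing the
chance of hitting the remaining alleles, and default
`del_fraction = 36/10407` (the damaging fraction among coding sSNVs).
`Pr(KO | pi, D, n) = pi (1 - (1 - D)^n) + (1 - pi)(1 - e^{-nD})` with
`pi = 0.17` (the high-pLI, haploinsufficient gene fraction) and default
`D = 1/n_genes` (uniform per-gene hit probability; `D` is only verbally
defined in the source material and is therefore an explicit parameter).
The per-gene-to-per-cell aggregation is likewise unstated; the default
`g_eff = 1` reads the formula as already cell-level, with
`g_eff = n_genes` exposed. Donor curves use mean ± s.e.m. across cells,
an exponential trend fit by log-linear least squares on donor means
(zero-probability donors excluded), and a paired two-tailed Wilcoxon test
between the diploid and tetraploid models, with the diploid per-genome
burden taken as 50% of the donor-matched tetraploid burden when diploid
cells are absent.

# Configuration, problem sizes, and the pipeline

`run_pipeline()` drives all stages from an R list or YAML file (YAML is the
configuration format; seeds are explicit and unknown keys are rejected) and
writes plain TSV/VCF/FASTA/GTF/JSON stage outputs plus an md5 manifest, so
re-running with the same seed is byte-identical and real-data users can
enter at any stage with their own files. The package's interface is its
exported functions; there is no shell executable.

Default verification sizes, chosen as a balance between statistical
resolution and the cost of a desk-scale replication: a 20 Mb reference
(2 x 10 Mb), 12 donors aged 0.4–82.2 y, 4 cells per donor, ~13,000 phased
hets per cell, 20 replicate cohorts for slope-coverage checks. At these
sizes a full cohort simulation plus analysis takes ~10 s and the entire
verification suite minutes, while slope standard errors (~2e-3) are small
enough to make 95% CI coverage of the 0.010 rate informative.

# Known limitations

* The caller models artifact read support parametrically (geometric); real
  MDA artifact support distributions are broader, so the calibrated
  threshold on real data should be validated against orthogonal truth.
* The tetraploid correction assumes independent amplification of the two
  diploid origins (supported by the product law on in-silico mixtures) and
  exactly 1/4-fraction variants.
* The signature fixtures are synthetic; real analyses should refit against
  a current reference catalogue.
* Sensitivity estimation inherits the germline hets' genomic distribution;
  in regions distant from any het both the estimate and the caller are
  blind, which cancels in the burden ratio only if somatic variants and
  hets share the same window geometry, as they do under the uniform
  generator.
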