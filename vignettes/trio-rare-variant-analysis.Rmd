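---
title: "Trio-aware rare-variant enrichment and polygenic risk partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-aware rare-variant enrichment and polygenic risk partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

Systemic lupus erythematosus (SLE) is a heterogeneous autoimmune disease
with a heritability around 0.66.  Common risk variants found by
association studies explain part of that risk; a separate set of roughly
two dozen genes causes monogenic SLE or SLE-like interferonopathies when
disrupted outright.  `triorare` implements a family-trio analysis of the
middle ground: patients who carry both an inherited polygenic background
*and* an ultra-rare, possibly damaging variant in a monogenic-SLE gene —
a "second hit" adding to the inherited load.

The pipeline has five analysis stages plus a synthetic-cohort generator:

1. **Trio genotype refinement** — child genotype posteriors from PL
   likelihoods and a Mendelian transmission prior, with Q20 flagging.
2. **Genotype risk score** — a random forest trained on case/control
   genotypes; the score of a sample is the percentage of trees voting
   "case".  Parents are partitioned into the higher- and lower-scoring
   parent of each family.
3. **Panel enrichment** — MAF-binned, annotation-stratified counting of
   rare-variant observations in a 22-gene panel, normalised against a
   reference cohort and tested exactly.
4. **Prioritisation** — ultra-rare non-silent panel variants filtered by
   deleteriousness annotations into a candidate report.
5. **Clinical comparison** — ACR sub-phenotype frequencies in candidate
   carriers versus the rest of the cohort.

Because the study design this emulates has no public reusable data, the
generator is a first-class component: it states a scaled-down world with
known ground truth, and every downstream stage is validated by parameter
recovery against that truth.

# The synthetic world

## Liability model

Affection is a liability threshold process.  For individual $j$ with
dosages $g_{ij}$ at markers $i$,

$$L_j = \sum_i w_i g_{ij} - \mu_G + k_j\,\beta_r + \varepsilon_j,
  \qquad \varepsilon_j \sim N(0, \sigma_e^2),$$

where $k_j$ counts injected deleterious panel alleles,
$\beta_r = 0.5$ is their per-allele effect (a "small-to-medium" effect,
chosen once), and $\mu_G$ centres the population genetic score.  A child
is affected when $L_j$ exceeds `liability_threshold` (default 1.645;
with the default variance components the total liability variance is
near 1, so the threshold is read on roughly the standard-normal scale
and crossing it is a ~5% event).  Families are rejection-sampled until
the child is affected; parents are redrawn after 40 failed
transmissions, because a family whose parents both drew low burdens
cannot plausibly produce an affected child and child-only resampling
stalls there.  A configurable cap (`max_resample`) turns pathological
configurations into an explicit error naming the threshold.

## Sparse risk architecture

Causal markers are drawn from the low-frequency end of the marker panel
(MAF $\le 0.15$) and carry positive half-normal weights
$|N(0, \texttt{effect\_size\_sd}^2)|$.  This is a deliberate and
load-bearing choice.  With a symmetric Gaussian burden (weights of both
signs on common markers) the two parents of an affected child have
*equal* burden variance, and the child correlates equally with the
higher- and the lower-scoring parent — the one-parent inheritance
structure cannot exist even in truth space.  A sparse positive-allele
burden is right-skewed and floor-compressed: most genomes carry few risk
alleles and sit near the score floor, while the informative variance is
concentrated in high-burden genomes.  It is also the more faithful
model of an immune-targeted genotyping panel, which is designed around
loci with real, often low-frequency, risk associations.  The defaults
(`n_causal_markers = 40`, `effect_size_sd = 0.33`) put the genetic share
of liability variance in the vicinity of the reported heritability.

## One-parent burden concentration

In `one_parent_fraction` of families one designated parent carries the
elevated polygenic burden.  The designated parent's causal allele
frequencies are exponentially tilted,

$$p_i' = \frac{p_i e^{\theta w_i}}{p_i e^{\theta w_i} + 1 - p_i},
  \qquad \theta \sim N(2.5,\ 1.25^2)\ \text{truncated at } 0,$$

which shifts the mean burden by roughly $\theta \cdot \mathrm{var}(G)$
while *adding* between-family variance through the heterogeneous
$\theta$.  An earlier design conditioned the designated parent on the
top quintile of the burden distribution; implementation proved it wrong:
truncation makes the high-burden parent nearly constant, so the patient
correlation flows to the *other* parent — the opposite of the structure
being modelled.  The tilt constants were calibrated once against the
qualitative targets the emulated study prints (higher parents scoring
like patients and lower parents like controls; a strong
higher-parent/patient correlation next to a weak lower-parent one;
designated-parent recovery of at least 80%) and are fixed constants of
the stated world, not user knobs.

When a designated parent exists, injected rare panel variants transmit
from the *other* parent: the generator encodes the second-hit
hypothesis, and the carrier-split correlation contrast
(`carrier_correlation_report()`) recovers it.

## Rare-variant layers

Rare variation is represented at per-genome observation rates (one
observation = one variant × carrier) rather than full genomic realism.
Ultra-rare variants (reference MAF $\le$ 0.1%) are private to a cohort;
higher-frequency bins come from a shared segregating-site pool built
deterministically from the master seed, so case and reference cohorts
sample the same sites.  Background (non-panel) rates per genome — 30
ultra-rare non-silent coding, 25/20/25 in the higher bins, 8/7/6/8 for
promoters, plus silent variants — are fixed constants of the scaled-down
world (real genomes carry far more; only ratios matter downstream).
Panel rates in the non-enriched strata are about 1% of background.
Patients receive ultra-rare deleterious panel injections at rate
`panel_rare_rate_background * (panel_enrichment_factor - 1)` on top of
the neutral background rate, so their total panel load is background ×
enrichment.  The default background rate of 0.14/genome makes a
71-patient cohort carry about 20 ultra-rare panel observations at
2× enrichment, matching the scale of the emulated study.  One injection
is converted to a homozygous nonsense genotype by default, mirroring a
complement C1q deficiency case; injected missense variants receive
damaging-range annotation scores by construction, neutral variants
benign-range scores, so prioritisation sensitivity can be asserted
exactly.

The reference generator accepts a calling-efficiency `deflation`: each
private reference observation is retained with that probability,
emulating a conventional pipeline that misses singletons a trio-aware
pipeline rescues.  This gives the normalisation step a real signal to
correct: a 0.8 deflation must be recovered as a factor of 1/0.8 = 1.25.

## What the generator does not emulate

Read-level data, sequencing error models, INDELs and CNVs, X-linked
inheritance, linkage disequilibrium between markers, population
stratification, and untransmitted parental rare variants (the enrichment
cohort is the patients, so parents only carry what they transmit).  A
green recovery test therefore establishes that the statistics recover
the stated generative structure — not that they are robust to artefacts
the generator does not produce.

# Trio genotype refinement

The child posterior combines the PL likelihood triple with a Mendelian
transmission prior: an allele transmitted from a parent with dosage $g$
is the alternate with probability $(g/2)(1-\epsilon) + (1-g/2)\epsilon$,
with de novo leak $\epsilon = 10^{-8}$ per allele (the order of the
human per-site mutation rate; the emulated pipeline delegates this to
its caller, so the value is a package default, documented and
switchable).  The call is the maximum-posterior genotype;
quality is $-10\log_{10}(1 - \max \text{posterior})$, and calls below
Q20 are flagged `LOWGP`.  Two conventions are deliberate:

* **"Below Q20" is strict** — a posterior of exactly 0.99 (phred 20) is
  not flagged; the comparison carries a $10^{-9}$ numerical guard
  because $-10\log_{10}(1-0.99)$ lands a few ulps under 20.
* **Flagging marks, it does not remove.**  Downstream stages choose; the
  enrichment counter excludes flagged sites by default.
* Ties in the posterior break deterministically toward the lower
  dosage.

When a parent genotype is missing the prior falls back to Hardy–Weinberg
at a supplied population frequency and the output records the fallback.

# The risk score

No random-forest implementation ships with the pre-installed stack, so
the package carries a compact classification forest in C++ (bootstrap
bagging, per-split feature subsampling, gini splits).  Genotype dosages
take only the values 0/1/2, so the split search is exact over the two
thresholds 0.5 and 1.5.  Training is deterministic given the seed; the
model stores its marker list and training mean dosages.  Scoring imputes
markers missing from the input to the training mean (counted per
sample), refuses to score below 90% marker overlap (the analysis design
assumes near-complete overlap), and refuses a sample with no observed
genotypes at all.

Scores are percentages of trees voting "case".  Because training samples
memorise their own labels, the generator provides *separate* training
and comparison control cohorts: every score that is ever compared
(patients, parents, controls) is out-of-sample.  Parent partitioning
breaks exact ties lexicographically by sample id and flags them.
Correlations are Pearson with exact t-distribution p values
(`stats::cor.test`), reported undefined for zero-variance input.

# The enrichment statistic

**Counting unit.**  One observation per variant × carrier; a homozygote
counts once in the default carrier mode (an `allele` mode counts it
twice).  This matches a study design that reports "21 variants in 18
patients" with one homozygote counted once.  For coding strata only
non-silent (missense, nonsense) variants count; promoter variants form
their own stratum; MAF bins default to (0, 0.001], (0.001, 0.01],
(0.01, 0.05], (0.05, 0.5] with an inclusive upper edge, and variants
absent from the reference (MAF 0) fall in the lowest bin.

**Normalisation.**  Variant-calling sensitivity differs between a
trio-aware case pipeline and a conventional reference pipeline,
inflating case counts relative to the reference — most strongly for
private variants.  Within each stratum the factor

$$f = \frac{\text{case background obs} / N_\text{case}}
           {\text{ref background obs} / N_\text{ref}}$$

estimates that differential from genome-wide counts *outside* the panel
(so the panel signal cannot contaminate its own correction), and the
corrected reference panel count is $c^* = f \cdot \text{ref panel obs}$.

**Why not a panel-versus-background 2×2.**  The seemingly natural table
(case panel, case background; scaled ref panel, scaled ref background)
cannot carry this correction: an odds ratio is invariant to any uniform
rescaling of a row, so a calling-sensitivity factor applied to the
reference row cancels identically.  And replacing count columns with
genome-count exposures saturates in common-MAF strata, where every
genome carries several observations.  The statistically appropriate
comparison of two observation *rates* with genome exposures is the
exact conditional Poisson test: given $n = a + \mathrm{round}(c^*)$,
under no enrichment $a \sim \mathrm{Binomial}(n,\ N_\text{case} /
(N_\text{case} + N_\text{ref}))$, and the two-sided p sums all outcomes
no more probable than the observed one — the same minimum-likelihood
convention as the Fisher exact test, of which this is the
large-background limit.  The generic `fisher_exact_2x2()` (hypergeometric
summation, Haldane–Anscombe display correction on zero cells) remains
the test used wherever a genuine 2×2 arises, e.g. the clinical
comparison, and both exact tests are pinned to brute-force enumeration
oracles in the test suite.

**Reported quantities.**  The odds ratio is reported as the rate ratio
$a / E$ with $E = c^* N_\text{case}/N_\text{ref}$ — at these rates odds
and rate ratios coincide to the reported precision, and this is exactly
the quantity the excess arithmetic inverts:
$\text{excess} = a\,(1 - 1/\mathrm{OR})$, $\text{expected} = a /
\mathrm{OR}$ (this inversion reproduces the printed example of 21
observed at OR 2.07 giving an excess of 10.9).  `signed_log_p` is
$-\log_{10} p$ signed by enrichment/depletion.  Multiple testing uses
Bonferroni across testable strata with the corrected $\alpha$ recorded
on every row.  A stratum with no reference background information is
reported untestable, never silently dropped.

# Prioritisation

Candidates are panel-coding, non-silent, ultra-rare (reference MAF
$\le 0.001$) variants passing the flagged-site policy.  The damaging
call uses the predictor tools' published conventions — SIFT $< 0.05$
("D"), PolyPhen2 $\ge 0.85$ ("D") — plus a DANN cutoff of 0.96; the DANN
value is a calibrated configuration constant chosen so that
clearly-damaging annotation profiles (e.g. 0.999 / 0.0 / 1.0) pass while
a profile like 0.362 / 0.699 / 0.001 fails on scores alone.  Nonsense
variants are always damaging.  A score-negative variant is retained only
when a free-text evidence note is supplied (`other_evidence`): such
judgements (structural proximity to known disease mutations) are human
calls and are never auto-assigned.  Missing predictor scores count as
non-damaging for that predictor and are logged.  The report carries the
carrier, zygosity, parent of origin and (optionally) the carrier's risk
score; a candidate seen in more than one family violates the
private-variant contract and is logged, not dropped.

# Clinical comparison

Per ACR criterion, a two-sided Fisher exact test compares carriers of
heterozygous candidates with non-carriers.  Disjoint groups are the
default because overlapping groups break the exact test; a
carriers-versus-entire-cohort mode exists for descriptive frequencies.
Bonferroni multiplies by the number of criteria tested and caps at 1.  A
criterion with no variance in the whole cohort reports p = 1 with a
flag.

# Numerical choices and determinism

* One master seed; every stochastic operation derives a child seed from
  (master, operation label, index) via a 31-bit string hash, so cohorts
  are reproducible per family and stages can rerun independently.
* Pipeline TSV artifacts carry provenance headers (tool version, config
  hash, seed) and no timestamps: reruns with the same seed are
  byte-identical.
* Exact-test p values use a $(1 + 10^{-7})$ relative guard when summing
  outcome probabilities "no more probable than observed", the standard
  defence against ties broken by floating-point noise.
* Tie-breaks: refinement toward lower dosage; parent partition by
  sample id; forest leaf votes "case" at proportion $\ge 0.5$.

# Known limitations

The forest is a minimal implementation (no out-of-bag estimates, no
class weights, no missing-value surrogates); scores are comparable
within a run, not across models, and absolute score levels depend on
the marker panel, so no clinical meaning attaches to them.  The
enrichment test conditions on the corrected reference count as if it
were a Poisson draw with known exposure; uncertainty in the
normalisation factor itself is ignored, which is acceptable while
background counts dwarf panel counts (they do, by two orders of
magnitude, in every stated scenario).  Patient score bimodality is not
asserted anywhere: whether it emerges depends on the risk architecture,
and the package makes no claim that it must.
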