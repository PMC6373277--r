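# triorare

Trio-aware rare-variant enrichment and polygenic risk partitioning for
systemic lupus erythematosus (SLE).

## What this is for

SLE risk has two known genetic layers: a polygenic background of common
risk alleles, and rare high-impact mutations in ~22 genes that cause
monogenic SLE or SLE-like interferonopathies.  In parent-offspring trios
with an affected child, both layers can be traced to their parent of
origin.  `triorare` is for statistical geneticists who want to run, or
stress-test, that family-trio analysis end to end:

- **trio genotype refinement** — child genotype posteriors from PL
  likelihoods and a Mendelian transmission prior with de novo leak
  ε, phred-scaled quality, strict `< Q20` flagging (`LOWGP`);
- **genotype risk score** — a random-forest case/control score
  (percent of trees voting case), per-family partition of parents into
  higher/lower risk, correlation reports;
- **panel enrichment** — the core statistic: per-stratum (annotation
  class × MAF bin) counts of variant×carrier observations in the gene
  panel, a cross-cohort calling-rate normalisation factor
  `f = (case background rate)/(reference background rate)`, and an
  exact conditional test of the observed panel count against the
  corrected expectation `E = f · ref_panel · N_case/N_ref`, with
  `OR = observed/E`, `excess = observed·(1 − 1/OR)`, signed log-p
  profiles and Bonferroni correction;
- **prioritisation** — ultra-rare (MAF ≤ 0.1%) non-silent panel variants
  filtered by SIFT (< 0.05), PolyPhen2 (≥ 0.85) and DANN (≥ 0.96), with
  nonsense always damaging;
- **clinical comparison** — Fisher exact contrasts of the 11 binary ACR
  criteria between candidate carriers and non-carriers.

There is no public reusable dataset for this design, so the package
ships a synthetic trio-cohort generator (`simulate_cohort()`,
`simulate_reference()`) with a ground-truth ledger: liability-threshold
affection, a designated high-burden parent in most families, injected
ultra-rare deleterious panel variants transmitted from the *other*
parent, and a SweGen-like reference cohort with an optional
singleton-calling deflation for the normalisation step to recover.  See
the methods vignette (`vignettes/trio-rare-variant-analysis.Rmd`) for
the model and every calibrated constant.

## Worked example

A paper-like scenario: 71 trio families, a 1000-genome reference with
0.9 singleton-calling deflation, 2× ultra-rare panel enrichment.

```r
library(triorare)

cfg     <- sim_config(seed = 1)                 # 71 families, 1000 ref genomes
cohort  <- simulate_cohort(cfg)
ref     <- simulate_reference(cfg, deflation = 0.9)

refined <- refine_trios(cohort)                 # trio posterior refinement

model  <- train_risk_model(
  common_genotypes(cohort, c("control_training", "case_training")),
  rep(0:1, each = cfg$n_controls), ntree = 500, mtry = 50,
  seed = derive_seed(1, "acceptance_rf"))
scores <- cohort_risk_scores(model, cohort, refined = refined$dosage)
corr   <- correlation_report(scores, partition_parents(scores))

enr    <- panel_enrichment_analysis(cohort, ref)
cand   <- filter_candidates(cohort, scores = scores)
```

Output of this exact run (seed 1):

```
[refine] 11 child calls changed, 2 flagged LOWGP
[score] group means: patients 61.3%, higher_parents 63.5%,
        lower_parents 37.4%, all_parents 50.4%, controls 37.7%
[score] correlations: patient_vs_higher_parent r=0.746,
        patient_vs_lower_parent r=0.329
[enrich] ultra-rare non-silent panel: obs=29 exp=8.6 OR=3.35
         p=2.13e-07 excess=20.4
[prioritize] 13 candidates (12 het / 1 hom) in 12 patients
[clinical] smallest p: renal 0.0061 (corrected 0.0671)
```

Reading it: the lower-risk parents score like population controls
(37.4% vs 37.7%) while the higher-risk parents score like the patients —
the polygenic burden is concentrated in one parent, and the patient's
score correlates strongly with that parent (r = 0.75) but weakly with
the other (r = 0.33).  On top of that background, ultra-rare non-silent
variants in the monogenic-SLE panel are enriched relative to the
calling-corrected reference expectation (29 observed vs 8.6 expected
here; the OR fluctuates seed to seed around the generating factor of 2
at this cohort size).  Prioritisation keeps the score-damaging subset —
including the one injected homozygous nonsense — and none of the
heterozygous carriers has nephritis, a contrast that is nominally but
not Bonferroni-significant across the 11 ACR criteria.

The same pipeline is scriptable:

```sh
Rscript inst/cli/triorare.R --stage all --preset paper_like --seed 1 --out-dir out/
```

which writes `trios.vcf`, `trios.ped`, `panel.bed`, annotation /
phenotype / reference TSVs, per-stage result TSVs (all with provenance
headers; reruns with the same seed are byte-identical) and a plain-text
report.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the whole paper-like analysis from scratch against the installed
package — cohort and reference simulation, trio refinement, risk-score
training and partitioning, panel enrichment with normalisation,
prioritisation and the ACR comparison — logging each stage's summary to
stderr and writing the JSON results object to `--out`.
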