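---
title: "Diagnostic variant prioritisation for clinical WGS: models, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic variant prioritisation for clinical WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsdx)
```

## The problem this package addresses

Children referred to clinical genetics with congenital anomalies or
unexplained developmental delay are conventionally investigated with
chromosomal microarray (CMA) first, followed by hypothesis-driven single-gene
or panel sequencing. Whole-genome sequencing (WGS) can capture copy-number
variants (CNVs), structural variants (SVs) and sequence-level variants (SNVs,
indels) in one assay, but turning ~3.5 million variant calls per genome into
a defensible molecular diagnosis requires a reproducible filtering and
ranking discipline. `wgsdx` implements that discipline as a tested pipeline:

1. **Small-variant prioritisation** — rare-variant filtering, ordered quality
   / frequency / impact / disease-association tiers, mode-of-inheritance
   (MOI) categorisation including compound-heterozygote candidates, and a
   simplified ACMG classification producing a ranked candidate list per case.
2. **CNV/SV handling** — read-depth segment and junction-event filtering,
   fragment merging, control-frequency and gene/exon annotation, rule-based
   classification, and the CMA-vs-WGS concordance procedure (reciprocal
   overlap, breakpoint windows).
3. **Secondary findings** — a screen of the 56-gene medically actionable
   panel honouring per-case consent.
4. **Cohort statistics** — diagnostic yield with Wilson confidence
   intervals, Yates-corrected two-proportion chi-squared comparisons,
   subgroup yields through phenotype-ontology closure, multi-locus and
   combined-actionability counts.
5. **Synthetic data** — a deterministic generator that emulates every input
   the pipeline consumes, with a ground-truth manifest used by the
   recovery tests.

## Thresholds and what they mean

All numeric thresholds live in one configurable object
(`threshold_config()`):

| parameter | default | meaning |
|---|---|---|
| `rare_freq_max` | 0.05 | a variant is *rare* when its maximum allele frequency across all configured databases is below 5% |
| `sv_support_min` | 20 | minimum discordant mate pairs supporting a junction SV |
| `reciprocal_overlap_min` | 0.50 | reciprocal overlap defining CNV equivalence |
| `segdup_cover_exclude` | 0.70 | CNVs covered at least this much by segmental duplications are excluded from concordance |
| `cnv_freq_exclude` | 0.03 | CNVs at or above this frequency in either platform are excluded |
| `breakpoint_window` | 10 kb | distance within which a WGS breakpoint counts as near an array boundary |
| `quality_min_depth`, `quality_min_gq` | 20, 30 | quality tier 1 cutoffs |
| `splice_delta_min` | 0.2 | absolute splice-prediction delta treated as damaging |

The frequency rule aggregates across databases by the **maximum** (the most
conservative retention rule): a variant common in any one database is not
rare. Raising `rare_freq_max` can only add variants, never remove them; this
monotonicity is property-tested.

Quality tiers deserve a caveat: the clinical workflow this models mentions
"tier 2 analytic quality" without ever defining it, so the cutoffs here
(tier 1: depth ≥ 20, GQ ≥ 30, allele fraction 0.3–0.7 for hets or ≥ 0.85 for
homs; tier 2: depth ≥ 10) are explicit stand-ins, and configurable.

## Inheritance-model reasoning in a proband-only design

Variants are grouped per gene within a case and interpreted against the
gene's documented modes of inheritance: dominant gene + het (or hom) →
`AD_het`; recessive gene + hom → `AR_hom`; recessive gene + two or more
distinct het positions → `AR_compound_het_candidate`; X-linked gene +
hemizygous male → `XL_hemizygous`; recessive gene + lone het →
`carrier_only`, which never produces a candidate diagnosis on its own.
Without parental genotypes the phase of a compound-het pair is unknowable,
so pairs carry an explicit `phase_unknown` flag rather than a phasing guess.
X-linked handling is implemented even though cohorts of this kind may
contain none, because the sorting criterion requires it. Genes absent from
the disease table are processed with no MOI restriction and flagged
`novel_gene`; they rank below mode-compatible candidates.

## The simplified ACMG rule table

Full ACMG sequence-variant interpretation has 28 criteria and requires
curated evidence this package does not model. The deliberate reduction used
here (first match wins) is:

1. loss-of-function variant in a gene with an established LoF mechanism,
   absent from every population database → **pathogenic**;
2. asserted pathogenic (either assertion source, no conflicting benign
   assertion) and MOI-compatible → **pathogenic**;
3. LoF in a known disease gene, MOI-compatible → **likely pathogenic**;
4. asserted likely-pathogenic, MOI-compatible → **likely pathogenic**;
5. novel missense with a damaging predictor majority, MOI-compatible, with
   phenotype overlap → **likely pathogenic**;
6. otherwise **VUS**.

Rule 5 requires the damaging-predictor majority on purpose: without it,
every rare novel missense in a phenotype-compatible disease gene would be
reported likely pathogenic, and the synthetic cohort's diagnostic yield
saturates at 100%, which no real cohort shows. "Damaging majority" means at
least half of the *available* predictors (of four modelled) call the variant
damaging; high conservation (phyloP-like score ≥ 2) is an alternative route
into impact tier 2 but not, by itself, into rule 5.

Candidates are totally ordered by (assertion category, impact tier, disease
tier, MOI compatibility, phenotype match, frequency tier), with genomic
coordinate as the final tie-break so that reruns are bit-identical. For a
compound-het pair the pair's class is the *weaker* of the two variants'
classes — both alleles must qualify for a recessive diagnosis.

## Phenotype matching

Clinician adjudication of phenotype fit is replaced by a deterministic
score: the ancestor closures (in an HPO-like DAG) of the case's terms and
of the gene's disease terms are intersected, and the intersection size is
normalised by the case-closure size. The ontology root is excluded from
both closures — every term set trivially contains the root, so leaving it
in would make all scores positive and the "phenotype overlap" condition
vacuous. Identical term sets score 1; terms from disjoint branches score 0;
a child term scores positively against its own ancestor.

## CNV concordance procedure

Read-depth CNVs (copy state ≠ 2, non-hypervariable, autosomes + X) are the
platform comparable to CMA, so concordance uses them alone; junction SVs
stay in a separate stream. Both call sets are pruned of records covered
≥ 70% by segmental duplications (coverage of the CNV by the union of segdup
intervals — segdups are small and numerous, so reciprocal overlap would be
meaningless) and of records at ≥ 3% frequency in either data set. Dataset
frequency is computed by same-state reciprocal-overlap matching against the
other samples of the same platform; the query's own case never counts
toward its own frequency, otherwise any private CNV in a cohort of n would
have frequency 1/n and, for n ≤ 33, be excluded as "common".

A CMA call is *detected* when a same-case, same-state read-depth record has
reciprocal overlap ≥ 0.5 against the CMA **outer** probe interval; the
greatest overlap wins and ties break on coordinate. Breakpoint agreement is
two-levelled: *within boundary* when the WGS start lies in
[outer_start, inner_start] and the end in [inner_end, outer_end] (the probe
uncertainty windows), and *within window* when both WGS breakpoints are
within 10 kb of those windows; the first implies the second, and the
implication is asserted as an invariant.

Fragmented read-depth calls (one biological event split by the caller) are
merged when same-case, same-chromosome, same-state records are separated by
at most 10 kb; merging is idempotent and changes covered bases only by the
filled gaps.

## What the synthetic generator emulates — and what it does not

The generator (`simulate_cohort()`) states a fixed world calibrated to the
per-genome workload of the platform modelled, at full scale:

* ~20,014 exonic/splicing small variants per genome, with a class mixture
  (45% missense, 40% synonymous, 1% LoF, plus in-frame indel, ncRNA,
  splice-region and UTR classes);
* ~248 read-depth CNVs (log-normal sizes, median 10 kb, 28% placed over
  exons) and ~1,604 junction SVs (median 495 bp, clamped to 50–75,000 bp,
  2% exonic), plus decoy rows: diploid segments, hypervariable-region
  segments, chromosome-Y segments, under-supported and
  non-deletion/duplication junction events;
* ~498 rare damaging events per genome. The rare-variant rate is **solved
  analytically** from the class mixture so that the expected count of
  rare × (LoF ∪ damaging-missense ∪ splice-damaging) variants equals 498 —
  it is a calibration of the stated world, not a fit to any observed test
  outcome;
* planted causal scenarios (dominant LoF, recessive homozygous, compound
  het, asserted missense, X-linked hemizygous, syndromic-region CNV) whose
  annotations guarantee pipeline eligibility: frequency absent from all
  databases, damaging predictors, case phenotype terms drawn from the
  disease gene's profile. Planted CNVs get a microarray call with
  probe-jittered inner/outer boundaries (inner inside the true breakpoints,
  outer outside, offsets uniform within 5 kb) and are emitted as two
  fragments for a configurable fraction of cases to exercise merging;
* a 100-sample control cohort realised from 30 polymorphic CNV loci, a 5%
  segmental-duplication track, a hypervariable track (kept clear of the
  syndromic zone so planted pathogenic CNVs are never masked by the
  hypervariable exclusion), and the fixed phenotype ontology.

Everything is deterministic under `(config, seed)`; per-case seeds are
derived from the cohort seed.

The generator does **not** emulate: nucleotide-level sequence context, LD
or population structure between sites, annotation error, platform-specific
artefacts beyond the modelled decoy classes, or — importantly —
**diagnostic specificity of the background**. Background variants can and
do produce pathogenic/likely-pathogenic candidates in undiagnosed cases, so
the synthetic cohort's overall yield runs above the 34% of a real cohort. A
green recovery test therefore establishes *sensitivity* (100% of planted
scenarios are recovered at pathogenic/likely-pathogenic rank) and
calibration of the stated counts, not the cohort-level yield figure.

The packaged 100-case cohort table used for the worked-example subgroup
yield is likewise a labelled synthetic stand-in: the source study prints
only marginal counts (57 cases with developmental delay, 22 of them
diagnosed; 26% secondary-findings opt-out), never per-case profiles, so
membership was reconstructed deterministically to match those marginals.

## Statistical choices

* **Two-proportion χ²** is implemented by explicit 2×2 formula with Yates
  continuity correction **on** by default: the correction reproduces the
  published yield p-values (1.42×10⁻⁵ for 34/100 vs 8/100; 0.0009 for
  34/100 vs 13/100) exactly, the uncorrected statistic does not. The
  uncorrected statistic equals the squared pooled two-proportion z — an
  algebraic identity checked numerically in the tests. Degenerate tables
  (a zero margin) return p = 1 with a warning rather than NaN.
* **Binomial CIs** use the Wilson score interval, which reproduces the
  published 25–44% for 34/100 after integer rounding; its empirical
  coverage at n = 100, p = 0.34 is property-tested into [94%, 96.5%].
* **De novo rate**: the printed tables give 16 distinct de novo cases while
  the prose states 15% and 14/34. `origin_summary()` reports the computed
  value together with a note that NA origins make it a minimum, rather than
  forcing any printed number.

## Numerical and degenerate-input conventions

VCF positions are 1-based; every internal interval is 0-based half-open,
converted at the I/O boundary. Reciprocal overlap of records on different
chromosomes is 0 by definition (documented, not an error). Empty control
sets yield frequency 0 with a warning. Readers reject malformed rows with
line numbers instead of coercing. Ranking ties always resolve by
(chromosome, position).

## Known limitations

* The ACMG reduction is six rules, not the full framework; class boundaries
  for unusual evidence combinations differ from expert curation.
* Proband-only design: compound-het phase is unknown, de novo status cannot
  be established by the pipeline itself, and uniparental heterodisomy and
  methylation disorders are undetectable by construction.
* Concordance "detected" uses same-state reciprocal overlap ≥ 0.5 against
  the CMA outer interval; the source workflow never states its criterion,
  so published concordance percentages (84%, 52%, 78%/87%) are not
  reproduced here — they depend on access-controlled genomes and are
  replaced by property-based checks on planted ground truth.
* The background small-variant model is generative (annotations drawn
  jointly with classes), not a re-annotation of simulated sequence.
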