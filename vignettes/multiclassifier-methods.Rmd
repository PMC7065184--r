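---
title: "Methods: molecular classification and genomic analysis of multiple-classifier endometrial carcinomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-classifier endometrial carcinoma analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcec)
```

## The problem

Endometrial carcinomas (EC) are routinely assigned one of four molecular
classes using surrogate markers for the TCGA genomic subtypes: *POLE*
exonuclease-domain mutation (POLEmut, ultramutated), mismatch-repair
deficiency on IHC or MSI assay (MMRd, hypermutated), abnormal p53
immunostaining or *TP53* mutation (p53abn, copy-number high / serous-like),
and no specific molecular profile (NSMP, copy-number low). A few percent of
tumours carry more than one classifying feature — most commonly abnormal p53
on top of MMRd or POLEmut — and these "multiple-classifier" tumours are a
real clinical problem because the individual features point to opposite
treatment intensities.

`mcec` implements the full analysis used to resolve this question as a
reusable, tested pipeline:

1. rule-based scoring of each marker axis and resolution of every tumour to
   exactly one class (`score_p53_ihc()`, `score_mmr_ihc()`, `assess_pole()`,
   `filter_tp53()`, `resolve_class()`, `tabulate_cohort()`);
2. 96-channel trinucleotide mutational catalogs with a cosine-based sample
   distance (`build_catalog()`, `spectrum_distance()`);
3. fraction of genome altered (FGA) from copy-number segments and its
   absolute-difference distance (`fraction_genome_altered()`,
   `scna_distance()`);
4. a combined Euclidean metric, hierarchical clustering, and assignment of
   multiple-classifier queries to single-classifier reference groups
   (`build_distance_matrix()`, `assign_groups()`, `association_test()`);
5. Kaplan–Meier / log-rank survival comparison with reverse-KM follow-up
   (`km_estimate()`, `logrank_test()`, `reverse_km_followup()`);
6. a seeded synthetic cohort generator so the whole pipeline is exercised
   end to end without controlled-access data (`generate_cohort()`).

The numbered scripts under `analysis/` run these stages as a narrative
workflow; `run_pipeline()` chains them into one report.

## Classification rules

**p53 IHC.** Abnormal (mutation-pattern) staining is strong nuclear
expression in *more than* 75% of tumour nuclei (the threshold is strict:
exactly 75% scores wildtype), complete absence of nuclear staining with
intact internal control, or cytoplasmic staining. An abrupt, regionally
abnormal area occupying at least 10% of tumour volume is scored
`subclonal_abnormal`; it counts as p53abn for classification but is flagged
separately, because subclonality is itself informative (it marks the *TP53*
hit as a late, subclonal event). A regional area under 10% scores wildtype.
Complete absence without internal control, or an unclassifiable pattern, is
inconclusive; an inconclusive stain falls back to *TP53* sequencing when
available (any retained variant counts as abnormal).

**MMR IHC.** Deficient means loss of nuclear staining for at least one of
MLH1/PMS2/MSH2/MSH6 with positive internal control. Abrupt complete regional
loss scores `subclonal_deficient` and counts as deficient. Heterogeneous or
patchy staining (a pre-analytic artefact) and stains without internal
control are never evidence of deficiency. When no MMR IHC exists, an MSI-H
call counts as MMRd; when both exist and disagree, IHC wins and the
discordance is recorded in the sample's rationale (no published resolution
rule exists for this conflict, so the choice is exposed in the output rather
than hidden).

**POLE.** Pathogenicity is decided by a configurable whitelist of
exonuclease-domain hotspots (`default_pole_whitelist()`: P286R, V411L,
A456P, S459F, P436R, S297F, F367S, L424I, M295R) plus an explicit
per-variant `pathogenic` flag, so verdicts from an external pathogenicity
score can be injected. An explicit `non_pathogenic` review verdict overrides
the whitelist. The whitelist ships only the variants this analysis itself
names; it deliberately does not re-implement any external scoring scheme.

**TP53 variant filter.** Variants benign by SIFT, neutral by VEP, or
clinically benign are excluded; (likely) pathogenic and VUS are retained;
variants with wholly unknown annotations are retained as VUS (matching the
inclusion rule used for the sequencing-based cohort).

**Resolution.** The raw classifier set is a subset of
\{POLEmut, MMRd, p53abn\}; multiple-classifier tumours resolve by the
priority POLEmut > MMRd > p53abn. The priority encodes the core biological
conclusion: a *TP53* mutation arising on an ultramutated or hypermutated
background is a passenger event and should not drive the classification.
Every rule that fires is appended to an ordered rationale, so each call is
auditable. The resolution is total: every classifiable sample gets exactly
one class, and samples missing a whole marker axis are returned as
`unclassifiable` with the reason.

Reported percentages use half-up rounding (default one decimal) so that
printed values like 1.8% are reproduced deterministically.

## Distances and clustering

SNVs are classified into the standard 96 pyrimidine-centred categories
(6 substitutions x 16 flanking contexts); purine-strand records are
reverse-complemented, so catalogs are strand-invariant. The canonical
channel order is substitution-major with alphabetical flanks and is fixed
for serialisation.

The mutational-change distance between samples is $(1 - \cos(p_a, p_b))/2$
on catalog proportion vectors, with range $[0, 0.5]$. The source text for
this metric is typographically ambiguous between $(1-\cos)/2$ and
$1 - \cos/2$; we default to the former because a distance must vanish on
identical samples ($1 - \cos/2$ is $0.5$ there), and expose the alternate
reading behind `spectrum_distance(method = "one-minus-half-cos")`. Neither
reading actually spans $[0, 1]$ for non-negative catalogs.

FGA is the fraction of genome length in segments with $|\log_2 R|$ above a
threshold (default 0.2, a common practice value; configurable). The default
denominator is the total segmented length, which is robust to SEG files
that do not tile the genome; a whole-genome denominator and integer
copy-number mode are available. The SCNA distance is the absolute FGA
difference — the simplest metric on $[0,1]$ consistent with using the
per-sample fraction as the copy-number descriptor (the pairwise form is an
interpretive choice; the source states only the per-sample quantity).

The combined metric is the Euclidean norm $\sqrt{d_{mut}^2 + d_{scna}^2}$
of the two scalars. The mutational component is *not* rescaled to $[0,1]$
by default (`normalize = TRUE` does so), so the SCNA axis carries somewhat
more weight — which matches how strongly copy-number burden separates the
serous-like class in practice.

Clustering is agglomerative with complete linkage by default (the default
of the heatmap function the original analysis plotted with; configurable to
average/single). The published analysis reads group membership off a
heatmap; we formalise it as: cut the dendrogram into $k$ clusters
($k$ = number of reference groups by default), assign each query the
majority reference label in its cluster, fall back to the nearest labelled
neighbour when the cluster has no labelled member, and break majority ties
by the smaller mean distance to the tied groups' labelled members. This
rule is deterministic and permutation-invariant; outputs label which rule
fired for each query. It is one defensible formalisation of visual
co-clustering, not the only one.

The association between query type and assigned group is tested on the
co-assignment contingency table: two-sided Fisher's exact test for 2x2
tables with any expected cell at or below 5, otherwise Pearson's
chi-squared without continuity correction. All-zero rows/columns are
dropped first (they carry no information and make the statistic undefined).

## Survival

Kaplan–Meier curves are estimated per group and read at 60 months (5-year
rates); groups are compared with the log-rank test, with pairwise tests
against the single-classifier p53abn group. Comparisons are restricted to
stage I (exact match on \{I, IA, IB\}) because the p53abn group is
stage-shifted relative to the multiple-classifier groups. Median follow-up
uses the reverse Kaplan–Meier method (censoring indicator inverted). Ties
between events and censorings at the same time follow the standard
events-first convention. Point estimates only; Greenwood confidence bands
were not needed for any reported quantity.

The estimators themselves are delegated to the `survival` package; the test
suite independently cross-checks them against hand-computed product-limit
and observed-minus-expected tables, and checks the log-rank type-I error by
simulation.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating structure the analysis
assumes, at desk scale. Defaults (all config-exposed; none of the genomic
magnitudes are published values, they are chosen once to mimic the TCGA
subtype separation):

| parameter | POLEmut | MMRd | p53abn | NSMP |
|---|---|---|---|---|
| median SNV burden (log-normal, sdlog 0.3) | 5000 | 1200 | 60 | 40 |
| expected indels (Poisson) | 20 | 150 | 5 | 5 |
| FGA Beta shape (mean) | (2,38) (0.05) | (2,38) (0.05) | (12,12) (0.50) | (2,38) (0.05) |
| TP53 hotspot probability | 0.08 | 0.08 | 0.315 | 0.315 |
| P(multiple TP53 variants) | 0.75 | 0.364 | 0.027 | 0.027 |
| 5-year RFS | 0.941 | 0.922 | 0.708 | 0.93 |

Spectrum weights concentrate POLEmut mass on T[C>A]T and T[C>T]G over a
C>A-tilted base, MMRd mass on C>T at CpG with a T>C component, and give the
copy-number classes a flat, mildly CpG-boosted background. The hotspot,
multiplicity, subclonal-staining (0.5 for queries) and survival parameters
follow the observed rates in the published cohorts; the p53abn Beta shape
(12,12) keeps the SCNA-high class concentrated around FGA 0.5, as in TCGA
serous-like tumours. Multiple-classifier queries receive their driver
class's genomics plus 1–3 retained passenger TP53 variants and an abnormal
p53 stain that is subclonal with probability 0.5.

Mechanics worth knowing: SNV tables are emitted half on the purine strand
(catalogs must be strand-invariant); indel rows are carried in the SNV table
but never enter the 96-channel catalog; segment sets are constructed so the
measured FGA equals the drawn Beta target exactly (the crossing segment is
split); survival times are exponential with the hazard solved from the
5-year target (`solve_exponential_rate()`), censoring uniform on 24–144
months (accrual-style follow-up with a median around 7 years). The toy
genome is 2 chromosomes x 100 Mb, which keeps SEG arithmetic and context
handling fast. One seed threads through all draws: identical seed + config
gives byte-identical files.

What the generator does *not* emulate: realistic mutational-signature
mixtures beyond channel-level enrichment, intra-tumour heterogeneity,
assay noise (misread IHC, failed stains — the default noise is zero, so
classification recovers the generating class essentially always), genomic
position effects, or stage-dependent hazards. Passing tests therefore show
that the pipeline's logic and arithmetic are correct and that the method
separates groups whose generative separation matches the assumed structure —
not that it would achieve any particular accuracy on real tumours.

## Numerical choices and problem sizes

* Cosine values are clamped to $[-1, 1]$ before the distance to absorb
  floating-point drift; distance matrices are symmetrised exactly.
* Catalogs with zero classifiable SNVs make the spectrum distance undefined
  and raise an error rather than returning a silent 0.
* Ambiguous bases (N) and context/ref mismatches skip the record and are
  counted in `n_skipped`.
* Default analysis sizes: 20 references per class and 20 queries per
  combination per cohort; the clustering recovery checks pool 20 seeded
  cohorts (800 queries), and survival recovery uses 500 subjects per group
  with a minimum-follow-up censoring window (60–180 months) so the 60-month
  read-out is fully informative. These sizes keep every stage comfortably
  inside interactive runtimes while leaving Monte-Carlo error well below the
  effect sizes of interest.
* `k` for the tree cut defaults to the number of reference groups; when a
  wide class splits before a pair of tight classes merges, the majority /
  nearest-neighbour fallback still yields a deterministic assignment.

## Known limitations

* The group-assignment rule formalises a visual heatmap reading; different
  defensible rules (e.g. k-nearest-neighbour on the raw metric) could move
  individual borderline queries.
* FGA ignores ploidy and allele-specific copy number; segmentation itself is
  out of scope.
* The classifier encodes no histotype or grade information, and IHC inputs
  are already-scored observations, not images.
* Survival modelling is single-event exponential in the generator and
  non-parametric in the analysis; competing risks and covariate adjustment
  are out of scope.
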