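---
title: "Clonality, purity and mutational signatures from ctDNA variant calls"
author: "plasmaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality, purity and mutational signatures from ctDNA variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaclone)
```

## The problem

Targeted sequencing of circulating tumour DNA (ctDNA) in advanced cancer
returns, per patient, a list of variant calls with variant allele
frequencies (VAF) and gene-level plasma copy numbers. Because plasma mixes
tumour-derived and normal DNA in unknown proportions, none of these
numbers is interpretable on its own: a 2% VAF may be a truncal mutation in
a low-shedding tumour or a minor subclone in a high-shedding one, and a
plasma copy number of 2.5 may hide a high-level amplification diluted by
normal DNA. `plasmaclone` implements the analysis layer that converts raw
cohort call tables into purity-aware quantities — cancer fractions, clonal
dominance, adjusted copy number — and the cohort-level statistics built on
them, together with a synthetic-cohort generator that makes every stage
testable against known ground truth.

## Models and procedures

### Germline filtering and pathogenicity

Panels without matched germline sequencing report germline polymorphisms
among the somatic calls. A call is removed as likely germline when its VAF
falls within 50 ± 2% (the heterozygous band) **and** its population allele
frequency exceeds 0.001% — both conditions, so a rare private variant at
VAF 50% is retained. The filter partitions its input exactly and is
idempotent; `filter_germline()` returns both halves.

Pathogenicity is a three-branch rule over user-supplied annotation tables
(`classify_pathogenic()`): membership of a hotspot/oncogenicity set, a
recurrence count of at least `recurrence_min` (default 3) in a key
breast-cancer gene (ESR1, HER2, PIK3CA, EGFR, RB1, FGFR2), or a splice
variant class. The annotation tables are inputs, not bundled data: the
upstream databases (OncoKB, CancerHotspots, COSMIC) are not
redistributable, and pinning them as files is what makes a run
reproducible. MAPK-pathway alterations are a fixed gene list plus FGFR2/3
fusions and copy number strictly above 3 in five amplification-prone
genes.

### Cancer fraction and clonal dominance

The maximum somatic VAF in a sample (mVAF) is taken as the truncal
anchor: assuming the top-VAF mutation is heterozygous, copy-neutral and
present in every tumour cell, each mutation's **cancer fraction** is

$$\mathrm{CF} = \frac{\mathrm{VAF}}{\mathrm{mVAF}},$$

a proxy for the fraction of tumour cells carrying it. Mutations with CF ≥
0.5 are *clonally dominant*, below 0.5 *subclonal*; ties at exactly 0.5
are dominant. Samples with a single retained call are *not assessable* —
one call cannot anchor itself. Copy-number calls never enter the mVAF.
The assumptions fail under loss of heterozygosity or focal amplification
of the anchor gene; at cohort scale these distortions tend to average
out in heavily pre-treated breast cancer, but individual CFs should be
read with that caveat.

Gene-level dominance (`gene_dominance_test()`) compares a gene's CF
distribution against all other genes. Reports of this analysis sometimes
name a "Wilcoxon signed-rank test" for what is an unpaired comparison;
the package uses the coherent unpaired form (two-sided
Mann–Whitney/rank-sum). Polyclonality
(`polyclonality_summary()`) counts carriers with one versus several
pathogenic mutations per gene; hotspot-level CF variation uses
Kruskal–Wallis with the inclusion rule "≥ 3 mutations, or any indel".
Benjamini–Hochberg correction is applied within each analysis family (one
family per analysis panel, not globally); reports in this area mix
corrected and uncorrected values across similar panels, so the family
boundaries are a package convention, stated in each output.

### Purity-adjusted plasma copy number

With tumour fraction $T = 2\,\mathrm{mVAF}/100$ (clamped to 1 when mVAF
exceeds 50%, where the heterozygous assumption has already failed), the
observed plasma copy number mixes tumour and normal DNA as
$\mathrm{obs} = 2(1-T) + T \cdot \mathrm{CN}$, inverted by

$$\mathrm{adjusted} = \frac{\mathrm{obs} - 2(1-T)}{T}.$$

Copy-neutral genes are a fixed point for every $T$; $T = 1$ is the
identity. Negative adjusted values, which arise when purity is
overestimated, are floored at zero with the raw value retained.
`amplification_roc()` evaluates the strict `adjusted > threshold` call
against tissue labels with a full threshold sweep, trapezoidal AUC, and
Clopper–Pearson 95% intervals at the operating threshold (default 2.0).
The interval method is a package choice; the exact binomial interval is
conservative and standard, and the method used is recorded in the result
object so downstream reports stay unambiguous.

### Mutation catalogues and signature refitting

SNVs are indexed into the 96 strand-collapsed trinucleotide channels,
purine-reference calls being reverse-complemented first. For
clonal-versus-subclonal comparison, all SNVs regardless of pathogenicity
are aggregated per dominance class, deduplicated by site within each
class; a site dominant in one patient and subclonal in another counts
once in each set.

`fit_exposures()` is a greedy forward-selection refitter in the style of
iterative signature deconvolution: each round line-searches (golden
section on [0, 1], absolute tolerance 1e-4) the single best weight
addition over all signatures, renormalises exposures to sum ≤ 1, and
stops when the relative squared-error improvement drops below `tol`
(1e-3); weights below 0.06 are then zeroed and the rest refitted. The
internals of the original fitter are not fully specified anywhere, so the
line-search and stopping rules here are the package's own, validated by
recovery tests on sampled mixtures. Bootstrap uncertainty
(`bootstrap_exposures()`) draws 90% of the mutation set per iteration,
200 iterations, **without replacement** by default — drawing a fixed
fraction of the data is fractional subsampling, not a classical
bootstrap; `replace = TRUE` gives the with-replacement variant.
`compare_conditions()` flags a signature as differing between conditions
when the two-sided Mann–Whitney p on the bootstrap vectors is below 0.05
**and** the interquartile ranges are disjoint, the convention used in
ctDNA signature reports.

APOBEC consensus sites are T(C>G)T, T(C>G)A and T(C>A)N on either strand
(`is_apobec_site()`), and `apobec_dominance_analysis()` cross-tabulates
dominance against APOBEC status with a two-sided Fisher test.

The package ships `synthetic_signature_matrix()`: five synthetic
signatures in COSMIC v2 layout and naming (ageing-like C>T at NpCpG,
APOBEC-like C>T and C>G at TpCpN, a transversion-skewed broad profile,
and a flat profile with mild T>C preference). These are deliberately
sharp caricatures for testing and simulation — they are **not** the
COSMIC signatures, which are not redistributable; real analyses should
load the genuine matrix with `read_signature_matrix()`.

## The synthetic cohort generator

`generate_cohort()` emits a cohort with ground truth, deterministic per
seed. Its defaults are the study conditions the analyses assume:

* 800 patients; subtype mix 64.4% HR+HER2−, 9.1% HER2+ (split evenly
  HR+/HR−), 17.3% TNBC, remainder unknown.
* Per-gene driver prevalences matching the frequencies reported for
  advanced breast cancer ctDNA cohorts (TP53 44.1%, PIK3CA 34.9%, ESR1
  33.1%, GATA3 11.0%, ARID1A 7.8%, PTEN 6.9%) plus a long tail of panel
  genes chosen so the product of
  miss-probabilities leaves ~7% of patients without any alteration —
  reproducing the ~93% cohort detection rate. Passenger calls arise only
  in patients with at least one driver: a patient whose tumour sheds too
  little DNA to call drivers yields no calls at all.
* One truncal mutation per mutated patient sets the mVAF, drawn
  log-normal (median 10%, sdlog 1, truncated to 0.1–80%); other mutations
  draw CF ~ Beta(1.2, 2.5), populating both dominance classes.
* VAF measurement noise is additive truncated-Gaussian with σ = 0.25
  percentage points, a realistic figure for duplex error-corrected
  sequencing at clinical depths.
* ESR1 and PIK3CA carriers can be multi-hit (extra-mutation probabilities
  0.3 and 0.12 per draw), with hotspot spectra anchored at fixed
  synthetic coordinates shared across patients, so site deduplication and
  polyclonality behave as on real data.
* Germline contaminants appear in 10% of patients at VAF ~ N(50, 1) with
  population AF above the filter cut-off; the analytic survival of the
  ±2% filter band is 2Φ(−2) ≈ 4.55%.
* Novel/passenger SNVs draw trinucleotide contexts from an
  APOBEC/background channel mixture whose APOBEC weight depends on
  subtype and dominance class; HR+HER2− defaults are 0.10 for dominant
  and 0.40 for subclonal mutations, so APOBEC processes dominate late
  subclonal evolution as observed in ER+ disease.
* Observed HER2 plasma copy number follows the purity mixing model with
  true CN 10 in tissue-amplified patients, 2 otherwise, and Gaussian
  observation noise σ = 0.5.

What the generator does **not** emulate: real panel footprints and
trinucleotide territory, LOH and focal CN distortion of VAFs, clonal
haematopoiesis, sequencing-depth-dependent VAF error, survival structure,
and the correlated co-mutation patterns of real tumours beyond the
configured prevalences. Passing recovery tests on this cohort therefore
demonstrates the correctness of the computations under their stated
assumptions, not the biological accuracy of those assumptions.

## Numerical and design choices

* VAF and population AF are both held in percent; fraction-scaled inputs
  convert only via an explicit reader flag, never by guessing.
* Coordinates are 1-based fully-closed (MAF convention, GRCh37); indels
  are excluded from context-dependent operations but kept in counting and
  association analyses.
* Two-sided Fisher tests use the probability-mass convention (sum of
  hypergeometric masses ≤ the observed table's). Chi-squared tests are
  uncorrected by default: the reported group-wise p = 0.04 on the
  3/41-vs-8/32 table reproduces only without the Yates correction
  (with it, ≈ 0.08).
* Zero-margin tables: Fisher returns p = 1 with a warning (no
  information); chi-squared errors (undefined).
* mVAF is computed over all retained somatic calls by default; a
  `pathogenic_only` switch restricts it, since the source does not state
  which set anchored its denominators.
* Ties at CF = 0.5 are dominant; dominance is per mutation, not a
  per-patient consensus.
* Simulation sizes in the test-suite were chosen to give stable
  operating-characteristic estimates at the default cohort size
  (100-seed replicates for the signature-comparison checks, 200
  replicates for null calibration of the rank tests).

## Known limitations

* **The conventional clonal-vs-subclonal flagging rule does not control
  its false-positive rate.** The rule highlights a signature when the
  Mann–Whitney p over the two bootstrap exposure vectors is < 0.05 and
  the IQRs are disjoint. Both ingredients measure *within-set* resampling
  spread, but the null difference between two disjoint mutation sets'
  point estimates has SD $\sqrt{2}\,\sigma(n)$, while 90% subsampling
  without replacement gives a bootstrap SD of only
  $\sqrt{1/0.9 - 1}\,\sigma(n) \approx 0.33\,\sigma(n)$. Disjoint IQRs
  therefore trigger at roughly $0.45\,\sigma$ against a null spread of
  $1.41\,\sigma$, flagging 60–75% of truly-null signatures — and the
  ratio is independent of mutation-set size, so no cohort scale fixes it.
  The package implements the rule as practised (it has ample power for
  the large APOBEC shifts it is used to show) and reports this
  property honestly in its acceptance suite rather than silently
  replacing the rule; a calibrated alternative would bootstrap the
  *difference* or use a two-sample test on mutation-level data.
* Cancer fractions inherit every violation of the truncal-anchor
  assumption (LOH, CN gain at the anchor locus, non-truncal top VAF).
* The purity model is linear and gene-level; no segment-level inference.
* Signature refitting is to a provided reference set only; no de-novo
  extraction.
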