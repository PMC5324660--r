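---
title: "Methods: the varwarden cohort variant warehouse"
author: "varwarden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the varwarden cohort variant warehouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varwarden)
```

# The problem

Gene-panel and exome sequencing of disease cohorts produces, per patient,
hundreds of variant calls of which at most one or two explain the
phenotype. Interpreting them requires information that lives in different
places: population allele frequencies, in-silico effect predictions,
prior clinical-significance assertions, the inheritance structure of the
cohort itself, and the clinical phenotypes of other carriers of the same
variant. `varwarden` is a scriptable warehouse that keeps all of these in
one store and automates the two interpretation aids that benefit most
from cohort scale:

* **inheritance-mode-stratified case-control odds ratios** — a variant
  causal for a dominant disorder should be enriched specifically among
  probands of apparently dominant families, and a recessive one among
  recessive/sporadic probands; and
* **averaged carrier phenotypes** — the mean and spread of each clinical
  field over all carriers of a variant (or of any variant in a gene),
  against which a new patient can be compared.

Both feed ACMG/AMP-style evidence codes, which the package combines into
a pathogenicity verdict.

# Store model and variant identity

The central object is the S4 class `VariantWarehouse`: a sample sheet,
genotype observations, a deduplicated variant registry, an annotation
table and per-sample clinical profiles. Persistence
(`saveWarehouse()` / `loadWarehouse()`) is a plain-text snapshot
directory — TSV tables plus a JSON config — chosen so a store needs no
database server, can be versioned, and can be inspected with standard
tools.

Variant identity is the ANNOVAR description convention: 1-based inclusive
`(contig, start, end, ref, alt)` with `-` for the absent allele of an
indel and shared leading context bases stripped
(`normalizeVariant()`). VCF input is assumed multi-allelic-split per alt
allele referenced by the genotype; the importer does this itself when a
genotype indexes two alts (`1/2` produces two observations). Two explicit
policies cover what upstream formats leave open:

* only `PASS`/`.` FILTER records are ingested by default
  (`filter_pass_only`), since stored observations feed carrier counts and
  low-quality calls would bias them; this is configurable;
* genotypes with missing alleles (`./.`, `0/.`) are never stored — a
  half-call is not evidence of carriage.

Chromosome names are harmonized to a configured convention
(`chr`-prefixed by default) so mixed-source cohorts join correctly.
One proband per family is designated at import (the first affected
sample of a family, unless flagged explicitly); family-level carrier
counting depends on it.

# Annotation

`parseAnnotationTable()` reads tab-separated ANNOVAR/wANNOVAR output. The
binding of header names to semantic slots is configuration
(`annovarColumnMap()`) because ANNOVAR headers vary by version; the
shipped default covers refGene-style tables. Three conventions matter
downstream:

* **missing is not zero**: a `.` frequency stays missing and is treated
  as "absent/rare" by the filters. The MAF rules remove variants
  *observed* above a threshold; absence from a panel is not such an
  observation.
* **splice score** is `max(ada, rf)` of the two dbscSNV scores — the
  permissive reading when only "a splicing score" is specified; both
  scores are retained columns in the source table, so a stricter policy
  is a one-line column-map change.
* **clinical-significance labels** parse by case-insensitive containment;
  same-polarity compounds (`Pathogenic/Likely_pathogenic`) map to the
  more conservative label, cross-polarity or explicitly conflicting
  strings map to `other` and are never treated as prior-pathogenic.

# The filtering cascade

`applyCohortFilter()` applies four rules, in order, to the unique-variant
registry:

1. variants previously reported pathogenic or likely pathogenic are
   exempt from rules 2–3, regardless of frequency;
2. remove variants above the MAF threshold (default 1%) in **any**
   checked population panel;
3. remove intronic and synonymous variants whose splice score is below
   the rescue threshold (default 0.6) or missing;
4. remove variants observed only in controls.

The exemption deliberately does **not** extend to rule 4: a control-only
variant has no case carrier to interpret, whatever its prior label. The
splice rescue defaults to intronic and synonymous classes
(`spliceRescueRegions`); UTR variants can be opted in, but by default
UTRs fall outside rule 3 entirely (they are neither intronic nor
synonymous), which matches how the per-case funnel treats them as
non-coding.

`caseFunnel()` is the per-patient diagnostic cascade with stage counts:
all observed variants, public-panel MAF (1000 Genomes/ESP6500/ExAC
slots), exonic surface, protein-affecting (synonymous dropped unless
splice-rescued), and in-house-control MAF. Prior-pathogenic variants
bypass the stages and are appended to the survivor set, so the printed
stage counts always describe the frequency/effect path alone.
"Protein-affecting" is the enumeration missense, nonsense, stoploss and
all frameshift/non-frameshift indel and block-substitution classes.

# Association statistics

`buildContingency()` counts carrier probands of one inheritance stratum
(`AD_or_mitochondrial` or `AR_or_sporadic`) against controls — one
proband per family, unknown-inheritance cases excluded from both strata.
A variant set is counted as a unit (a sample carrying any member is a
carrier), which is how cis pairs and compound-heterozygote groupings are
analyzed. Allele counting (het = 1, hom = 2, denominators 2N) is
available by configuration, as is folding a frequency-only control panel
into the control cells as `round(AF * 2N)` carriers under a
no-homozygote assumption appropriate for rare variants.

`associationStats()` computes:

* the odds ratio `ad/(bc)`, with the Haldane–Anscombe +0.5 correction on
  all four cells applied **only** when a zero cell exists (flagged in the
  result);
* the Woolf log-normal 95% interval
  `exp(ln OR ± z · sqrt(1/a + 1/b + 1/c + 1/d))` on the corrected cells,
  with `z` from the normal quantile rather than a hard-coded 1.96; the
  exact conditional interval is available via `ciMethod = "exact"`;
* a two-sided Fisher exact P by hypergeometric enumeration: the sum of
  the probabilities of all same-margin tables whose probability does not
  exceed the observed table's, with a relative tolerance of 1e-7 on the
  comparison so floating-point ties count as ties.

The evidence flag (`ps4Assess()`) is true when the odds ratio reaches the
fivefold threshold **and** the interval excludes 1.0. Tables with fewer
than ten carriers in total additionally carry a small-count warning —
odds ratios from single-digit carrier counts are fragile, and the warning
is surfaced rather than suppressed.

Degenerate inputs: a table with no non-carriers anywhere (`b = d = 0`)
is an error; empty margins in the Fisher test return P = 1.

# Phenotype aggregation

`aggregatePhenotype()` averages the clinical profiles of a carrier set at
variant, variant-set or gene scope. Numeric fields aggregate to mean and
sample standard deviation (n − 1 denominator; the SD is reported missing
when fewer than two carriers have a value, never as 0). The published
notion of an "averaged phenotype" is defined only for numeric data; this
package's explicit reading for the other types is: categorical fields
aggregate to frequency tables, series-valued fields (audiogram-style
x–y curves) pointwise on a shared x-grid. The grid is declared by the
first sample carrying the field; later samples on a different grid are
linearly interpolated onto it and flagged, so an aggregate discloses
which carriers were resampled. Gene-level aggregation defaults to pooling
carriers of any annotated variant of the gene and can be restricted to
filter survivors. `compareCase()` reports per-field z-scores where the SD
is defined.

Clinical capacity is 9 series, 40 numeric and 20 categorical fields per
cohort, enforced at import.

# Evidence codes and combination

Codes are (label, polarity, strength) triples, so the cosegregation code
`PM7` — supporting-level cosegregation (`PP1`) upgraded to moderate — is
representable without special-casing. Automatic assignment
(`assignAutoEvidence()`):

* `PM2` when every configured population frequency is missing or zero;
* `PP3` when the in-silico consensus is unanimous over at least
  `minTools` (default 3) called tools — for a variant set, every member
  must be unanimous;
* `PS4` from the odds-ratio flag (an association result is required;
  requesting evidence without one is an error, not a silent omission);
* `PM3` only from a recorded in-trans assertion with a prior pathogenic
  partner — phase is not inferable from unphased single-sample VCFs, so
  it is accepted only as recorded segregation data;
* `PP1`, upgraded to `PM7` at `upgradeFamilies` co-segregating families.
  The upgrade threshold defaults to 3 families: the worked examples
  upgrade at 5 and 4 families without stating a rule, so the default is
  the largest threshold consistent with both.

`combineEvidence()` implements the published ACMG/AMP combining table
over strength counts (the rules are spelled out in the function's help
page). Two deliberate readings: any evidence set where both a
pathogenic-side and a benign-side combination fire is *uncertain*
(conflicting evidence), and two very-strong codes classify as pathogenic
even though the published table does not enumerate that cell — the
combiner must be monotone in added pathogenic evidence.

# Synthetic cohorts

`generateCohort()` emulates the study design, not the biology: one
single-sample VCF per proband/control, carrier status drawn as
independent Bernoulli trials with stratum-specific probabilities, an
annotation table in ANNOVAR format, and numeric clinical fields drawn
from shifted normals for carriers of a designated variant. A truth table
records every draw, and a fixed seed determines all output bytes. What it
does **not** emulate: linkage between variants, realistic site spectra,
sequencing error, relatedness beyond the one-proband-per-family design,
or missingness patterns in clinical data. Passing tests on these cohorts
therefore validate the bookkeeping and the statistics, not robustness to
real-data artifacts.

`case1Profile()` / `case2Profile()` are deterministic fixtures whose
index sample's annotation profile drives the case funnel through the
stage sequences 333 → 15 → 6 → 5 → 2 and 392 → 24 → 10 → 8 → 5,
with additional carrier families of the surviving variants for the
variant-view and evidence paths.

# Numerical choices and problem sizes

* Report percentages round half-up to one decimal (`roundHalfUp()`), the
  presentation convention of the field's summary tables; `round()`'s
  banker's rounding would print 1.25% as 1.2%.
* The Fisher implementation is verified in the test suite against an
  independent from-scratch `lchoose` enumeration (exhaustively for all
  2×2 tables with total ≤ 60; agreement within 1e-10) and against
  `stats::fisher.test` on sampled larger tables.
* Parameter recovery is checked on 200 replicates of a 1,000-proband /
  3,000-control cohort at carrier probabilities 0.02 vs 0.004 (true odds
  ratio ≈ 5.08): the median estimate must fall within 25% of truth and
  the evidence flag must fire in more than half the replicates. These
  sizes keep the default test run in tens of seconds while leaving the
  binomial noise realistic.
* Registry and join operations are exercised at the 26,073-variant scale
  of the worked-example breakdown; everything is vectorized data-frame
  work and runs in seconds.

# Known limitations

* No multiple-testing correction across association scans — the scan
  mirrors the source workflow, which applies none; treat scan-wide
  small P values accordingly.
* The odds-ratio machinery assumes one observation row per sample and
  variant; pedigree structure beyond proband designation (e.g. sibling
  non-independence) is not modeled.
* Benign-side ACMG automation is limited to label parsing; BA1/BS
  frequency logic and PVS1 loss-of-function logic are out of scope.
* The store is single-writer; there is no concurrency control beyond the
  snapshot-directory model.
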