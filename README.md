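# varwarden

A scriptable cohort variant warehouse for clinical sequencing
interpretation: unified management of sequencing variants and
per-patient clinical data, automatic rare-variant filtering,
inheritance-mode-stratified case-control odds ratios, carrier-phenotype
aggregation, and ACMG/AMP evidence combination.

## Who this is for

Groups running gene-panel or exome diagnostics over a growing cohort of
cases and in-house controls. Each patient contributes a single-sample
VCF and a clinical record; the warehouse deduplicates variants across
the cohort, round-trips ANNOVAR-style annotation, and turns cohort scale
into interpretation evidence: how enriched is this variant among
dominant-family probands versus controls, and what do its other carriers
look like clinically?

## The statistics at the core

For a variant (or a cis/compound-het variant set), carriers are counted
among the probands of one inheritance stratum (apparently
autosomal-dominant/mitochondrial, or apparently recessive/sporadic
— one proband per family) against controls, giving a 2×2 table
`(a, b; c, d)`. The package computes

* the odds ratio `OR = ad / bc`, with the Haldane–Anscombe +0.5
  correction on all cells when any cell is zero;
* the Woolf 95% confidence interval
  `exp(ln OR ± z_{α/2} √(1/a + 1/b + 1/c + 1/d))`;
* a two-sided Fisher exact P by hypergeometric enumeration.

Strong case-control evidence (the PS4-style flag) requires `OR ≥ 5` with
a confidence interval excluding 1.0. Evidence codes — absence from
population panels (PM2), unanimous in-silico consensus (PP3), recorded
in-trans pathogenic partner (PM3), cosegregation (PP1, upgraded to the
moderate-strength PM7 at ≥ 3 families), and the odds-ratio flag (PS4) —
are combined under the ACMG/AMP rules into pathogenic / likely
pathogenic / uncertain / likely benign / benign.

## Worked example

The bundled fixture generator builds a dominant-inheritance index case
observing 333 variants, plus four further carrier families of the two
surviving variants:

```r
library(varwarden)

p1 <- case1Profile()          # writes VCFs + ANNOVAR table to a tempdir
wh <- loadCaseProfile(p1)     # import -> update registry -> annotate

funnelCounts(caseFunnel(wh, p1$indexId))
#>          observed        public_maf     coding_region protein_affecting
#>               333                15                 6                 5
#>       inhouse_maf
#>                 2
```

Of 333 observed variants, 15 are rare in the public panels, 6 are
exonic, 5 protein-affecting, and 2 survive the in-house frequency check
— the diagnostic shortlist. Association statistics for a 2×2 carrier
table (here 10/100 case probands vs 5/100 controls):

```r
r <- associationStats(list(a = 10, b = 90, c = 5, d = 95))
show(r)
#> AssociationResult [unstratified, proband_carrier]
#>   table: a=10 b=90 c=5 d=95
#>   OR = 2.111  95% CI (0.695, 6.416)  P = 0.2828
#>   PS4 support: FALSE
```

The odds ratio is 2.1 — carriage is twice as likely among probands —
but the interval spans 1.0, so it is not evidence. Combining evidence
codes:

```r
verdict(combineEvidence(c("PS4", "PM7", "PP3")))   # strong + moderate + supporting
#> [1] "likely_pathogenic"
verdict(combineEvidence(c("PM2", "PM3", "PM7")))   # three moderates
#> [1] "likely_pathogenic"
```

A thin command-line dispatcher over the same functions is installed at
`inst/scripts/varwarden.R` (`import`, `update`, `export-annovar`,
`annotate`, `filter-cohort`, `filter-case`, `assoc`, `summary`,
`case-view`, `variant-view`) with the store as a plain-text snapshot
directory.

## Scope

The warehouse consumes VCF 4.x and ANNOVAR/wANNOVAR output; it does not
run alignment, variant calling or the annotators themselves, and splice
scores are consumed, not computed. See the methods vignette
(`vignettes/variant-warehouse-methods.Rmd`) for the model, parameter
defaults, design decisions and known limitations.
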