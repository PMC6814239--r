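# acmgscore

Pathogenicity assessment and prioritisation of annotated exome variants
for cohort studies. `acmgscore` is aimed at researchers holding a
multi-sample annotated exome (ANNOVAR table or VCF, or VEP VCF) for a
cohort sharing a phenotype, who want ACMG/AMP-style variant
classification without hand-curating every variant, enrichment evidence
without sequencing control samples, and reports they can filter and rank.

## What it computes

**ACMG criteria.** The 19 evidence criteria derivable from annotations
(PVS1, PS1, PS3, PM1, PM2, PM4, PM5, PP2, PP3, PP5, BA1, BS1, BS2, BS3,
BP1, BP3, BP4, BP6, BP7) are assigned per variant from normalized
annotation fields and small, user-replaceable lookup tables, plus PS2
from trio data and PS4 from cohort enrichment.

**A continuous posterior probability of pathogenicity.** Categorical
tiers hide how much evidence accumulated, so each criteria set is also
mapped through the Bayesian points framework: one very strong criterion
carries odds `O_PVSt = 350`, and with scale `X = 2` supporting, moderate
and strong evidence contribute exponents 1/8, 1/4 and 1/2 (benign
evidence the same with negative sign):

```
OddsPath = O ^ (nPP/8 + nPM/4 + nPS/2 + nPVS − nBP/8 − nBS/2)
P        = OddsPath · P0 / ((OddsPath − 1) · P0 + 1),   P0 = 0.10
```

Verdicts use inclusive thresholds, 0.80/0.35 by default (0.85/0.20 as
the stricter alternative).

**Control-free enrichment (PS4).** A control minor allele frequency
`MAF_c = y × 10⁻ˣ` is extrapolated to integer counts `n_c = ⌈y⌉` affected
among `10ˣ/2` control individuals — deliberately overstating the control
frequency — and each variant's cohort carriers are tested with a
one-sided Fisher's exact test. PS4 requires OR ≥ 20, p ≤ 0.001 and at
least two cohort carriers.

**Trio handling and reports.** De novo variants (carrier child, both
parents confidently reference) receive PS2; healthy parents are removed
from downstream statistics. Reports include the main classified table,
gene-list / pathway / gene-description filters, per-sample rankings and
a per-gene burden score `Σ Pᵢ × Nᵢ` over variants with `Pᵢ > 0.80`, with
advisory warnings for FLAGS genes, very long genes and suspiciously
ubiquitous variants.

## Worked example

The package ships a synthetic-cohort generator with exact ground truth;
it also serves as a quick demonstration (10 samples, one trio, 12
variants):

```r
library(acmgscore)
library(dplyr)

fx     <- generate_cohort(dir = tempfile("demo"))   # writes TSV + 2 VCFs + pedigree
cohort <- read_annovar_table(fx$paths$annovar_tsv)
ped    <- read_pedigree(fx$paths$pedigree)
res    <- classify_cohort(cohort, pedigree = ped)

select(tidy(res), gene, criteria, acmg_class, posterior, n_carriers)
#>    gene    criteria     acmg_class        posterior n_carriers
#>  1 BRCA2   PVS1;PM2     likely_pathogenic   0.994            1
#>  2 TP53    PS1;PM2;PP2  likely_pathogenic   0.949            1
#>  3 TP53    PM2;PM5;PP2  VUS                 0.812            1
#>  4 OR4F5   BA1          benign              0                6
#>  5 ALDH2   BS1;BP4      likely_benign       0.00285          2
#>  6 SAMD11  BP7          VUS                 0.0507           1
#>  7 MUC16   PS4;PM2;PP3  likely_pathogenic   0.949            5
#>  8 BRCA2   PVS1;PS2;PM2 pathogenic          1.000            1
#>  9 RET     PM1;PM2;PP3  VUS                 0.812            1
#> 10 NOC2L   PM2;PM4      VUS                 0.675            1
#> 11 PLEKHN1 BP3          VUS                 0.0507           1
#> 12 KLHL17  PM2;PP5      VUS                 0.500            1
```

Row 7 is the enrichment case: 5 of 8 post-strip samples carry an allele
whose control frequency is 3.23 × 10⁻⁵, extrapolated to 4/49 996 control
individuals (OR ≈ 2.1 × 10⁴, p ≪ 0.001), so PS4 joins PM2 and PP3 and
the posterior reaches 0.95. Row 8 is the de novo stopgain in the trio
child (PVS1 + PS2 + PM2 → pathogenic, posterior 0.9997). Note row 3: a
categorical VUS whose posterior (0.81) already crosses the lenient
pathogenic threshold — exactly the nuance the continuous scale adds.

The gene burden report ranks genes by probability-weighted carrier
counts and flags known artifact-prone genes:

```r
gene_burden(res)
#>   gene  burden n_variants_counted warnings
#> 1 MUC16  4.75                   1 "flags_gene;long_gene"
#> 2 BRCA2  1.99                   2 ""
#> 3 TP53   1.76                   2 ""
#> 4 RET    0.812                  1 ""
```

Filtered views keep the main report's format:

```r
main <- report_table(res)
filter_by_pathway(main, "Pathways in cancer")
filter_by_disease_term(main, "autosomal dominant")
```

A thin command-line wrapper over the same pipeline lives at
`inst/cli/acmgscore-sort.R`:

```sh
Rscript inst/cli/acmgscore-sort.R -i cohort.annovar.tsv -o report/ \
    --tab --by_gene --by_sample --trio pedigree.tsv
```

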