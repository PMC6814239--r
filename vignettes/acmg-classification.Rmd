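---
title: "Methods: ACMG criteria, Bayesian posterior probability and cohort enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ACMG criteria, Bayesian posterior probability and cohort enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgscore)
library(dplyr)
```

# What the package computes

Given a cohort of exome variants annotated by ANNOVAR or VEP, `acmgscore`
assigns the ACMG/AMP evidence criteria that can be derived from
annotations alone, converts each criteria set into the categorical
five-tier class via the published combining rules, and — because the
categorical tiers hide how much evidence actually accumulated — also maps
every criteria set onto a continuous posterior probability of
pathogenicity with a Bayesian points framework. Around that core it
provides control-free case-enrichment testing (PS4), trio de novo
detection (PS2), and cohort-level reporting (filtered views, per-sample
rankings, gene burden scores).

## The variant model

Both input dialects are normalized onto one tabular model: one row per
(decomposed) alternate allele, with canonical columns for the gene,
region and consequence class, protein change, ClinVar assertions, domain
and repeat context, splice-impact score, a map of population allele
frequencies, a map of in-silico predictor calls, and per-sample
genotypes. A genotype carrying the allele once is `het`, twice `hom_alt`;
a genotype with any missing allele (`./1`) is `missing` and never counts
as a carrier — carrier-based statistics should under- rather than
over-count under genotype dropout. Coordinates are taken as given
(1-based); indels are not re-normalized because no criterion consults the
exact breakpoint representation.

## Criteria assignment

Nineteen criteria are derivable from annotations and bundled lookup
tables; the seven that require case-level evidence an annotated file
cannot carry (PM3, PM6, PP1, PP4, BS4, BP2, BP5) are never assigned.
Every threshold lives in `acmg_config()`:

| parameter | default | role |
|---|---|---|
| `rare_threshold` | 1e-4 | PM2: every population frequency absent or below |
| `ba1_threshold` | 0.05 | BA1 stand-alone benign frequency |
| `bs1_threshold` | 0.01 | BS1 frequency cut-off |
| `bs2_hom_count` | 0 | BS2 fires above this reported homozygote count |
| `pp3_fraction` / `bp4_fraction` | 0.5 | fraction of available predictors voting deleterious / benign |
| `min_predictors` | 2 | predictor panel size before PP3/BP4 are considered |
| `splice_threshold` | 0.6 | splice-impact score below which a synonymous change earns BP7 (dbscSNV convention) |

Two design points deserve comment. ClinVar evidence is split by review
status: assertion-backed records (criteria provided, expert panel,
practice guideline) feed the strong criteria PS3/BS3, while
no-assertion records feed the supporting PP5/BP6 — mirroring the
strong-versus-supporting intent of the original definitions. And PS1
("same amino-acid change as an established pathogenic variant, different
nucleotide change") is driven by a residue-level lookup table
(`gene`, `protein_pos`, `ref_aa`, `alt_aa`); because the table carries no
nucleotide information the different-nucleotide clause is not verified,
which can over-assign PS1 to the known nucleotide change itself. The
bundled table is a small curated example and should be replaced with a
project-appropriate one for production use; PM5 uses the same table for
novel substitutions at a known residue.

## From criteria to probability

The Bayesian framework treats one very strong criterion as odds of
pathogenicity `O_PVSt` (default 350) and scales the other strength levels
exponentially: with scale `X = 2`, supporting, moderate and strong
evidence contribute exponents of 1/8, 1/4 and 1/2 respectively. Benign
evidence enters the same exponent negatively (strong benign at −1/2,
supporting benign at −1/8) — the framework's symmetric extension, chosen
so that net-benign evidence pulls the posterior below the prior:

$$\mathrm{OddsPath} = O^{\,n_{PP}/X^3 + n_{PM}/X^2 + n_{PS}/X + n_{PVS}
 - n_{BP}/X^3 - n_{BS}/X}, \qquad
P = \frac{\mathrm{OddsPath} \cdot P_0}{(\mathrm{OddsPath}-1) P_0 + 1}$$

with prior `P_0 = 0.10`. The exponent is evaluated in log space and
saturates to 0/1 beyond ±700 log-units, so extreme evidence loads cannot
overflow. With no evidence `OddsPath` is exactly 1 and the posterior
equals the prior. Stand-alone BA1 overrides everything: the posterior is
forced to 0 and the class to benign, with the conflict preserved in the
evidence notes.

Verdict thresholds are inclusive on both sides; the defaults (0.80
pathogenic / 0.35 benign) are the lenient operating point, with
0.85 / 0.20 as the stricter alternative. Exactly at a cut-off, a variant
is inside the verdict.

### Categorical rules and conflicts

`combine_categorical()` implements the published combining rules
verbatim. A class of VUS is returned when *both* a pathogenic-side and a
benign-side rule fire; stray evidence that satisfies no combining rule
(say, a single PS next to two BS) does not block the side whose rule
fires. This matches the stand-alone-benign precedent: BA1 plus strong
pathogenic evidence is benign, not VUS.

The two scales agree where agreement can be expected. Enumerating all
evidence vectors with counts up to four, every configuration whose
evidence points in a single direction and is labelled pathogenic scores
strictly above every single-direction configuration labelled likely
benign. Under strongly *mixed* evidence the categorical rules are known
to order incoherently — a very strong criterion plus two supporting
benign criteria is labelled likely benign by rule yet carries posterior
≈ 0.95 — which is precisely the argument for reporting the continuous
posterior alongside the tier. The package therefore asserts categorical/
posterior consistency over single-direction evidence, and over the full
mixed enumeration asserts the weaker ordering that the pathogenic label
never scores below the weakest likely-pathogenic configuration.

## Control-free enrichment (PS4)

Public frequency databases report a control minor allele frequency
`MAF_c`, not counts. Writing `MAF_c = y × 10^-x` with `1 ≤ y < 10` (the
normalization is performed on the decimal representation, so a printed
mantissa like 3.23 is exact), the control is extrapolated to

$$n_c = \lceil y \rceil \text{ affected individuals}, \qquad
N_c = 10^x/2 - n_c \text{ unaffected},$$

e.g. `MAF_c = 3.23e-5` gives `n_c = 4` against `N_c = 49996`. Rounding
the mantissa *up* deliberately overstates the control carrier frequency,
so the resulting odds ratio is never larger than the one computed from
the unrounded expected count — the test errs toward missing enrichment
rather than inventing it. The approximation assumes `MAF_c < 0.05` and
mostly heterozygous carriers; at or above 0.05 PS4 is not evaluated
(such variants meet BA1/BS1 instead). A variant absent from the chosen
database is treated as minimally observed — one carrier among
`default_control_individuals` (50 000) — again overstating the control
frequency.

Each variant's cohort carriers versus non-carriers are tested against
`(n_c, N_c)` with a one-sided Fisher's exact test (exact hypergeometric
upper tail; the odds ratio is the plain cross-product ratio, reported as
infinite when the control cell is empty — an infinite ratio passes the
gate). PS4 requires all three of: odds ratio ≥ 20, p ≤ 0.001, and at
least 2 cohort carriers. Homozygous cohort carriers count once
(carrier-level test), and no multiple-testing correction is applied
across variants. Cohorts of fewer than two samples skip PS4 with a
warning.

## Trios

A pedigree table (sample, trio id, role, affected) switches on trio
handling: a variant is de novo in a trio when the child carries the
allele and both parents are confidently homozygous reference — a missing
parental genotype blocks the call for that trio, trading sensitivity for
protection against dropout-driven false PS2. PS2 is assigned if any trio
qualifies, with per-trio detail retained, and counts as an ordinary
strong criterion. Healthy parents are then removed before any
cohort-level statistic, so PS4 and burden reflect only potentially
affected individuals; affected parents stay.

## Reports

The gene burden score is the sum over a gene's variants of posterior ×
carrier count, restricted to variants with posterior strictly above 0.80
(a variant at exactly 0.80 is excluded). Burden warnings are advisory
text and never alter the score: membership in the bundled FLAGS list
(frequently mutated exome genes), coding length above `long_gene_kb`
(default 15 kb), and any counted variant carried by more than 90% of
samples (typical of poorly mapped or pseudoautosomal regions). Filtered
reports (gene list, bundled offline pathway snapshot, free-text
gene-description search) are row subsets of the main report with
identical columns. The per-sample report ranks each sample's carried
variants by descending posterior, ties broken by position, keeping by
default those at or above the pathogenic threshold. Pathway enrichment
of pathogenic genes calls the EnrichR web service through an injectable
HTTP layer; the workbook output format is a directory of TSV sheets.

## The synthetic-data generator

`generate_cohort()` emits the same 10-sample, 12-variant cohort in three
dialects (ANNOVAR table, ANNOVAR-annotated VCF, VEP-annotated VCF) plus a
one-trio pedigree, together with an exact truth object. Each blueprint
row names an evidence recipe — truncating-in-LoF-gene, known hotspot
residue, common allele, cohort-enriched (5/10 carriers at control MAF
3.23e-5, chosen to exercise the worked extrapolation), de novo
truncating, domain missense, in-frame indels in and out of repeat
context, and a reputable-source-only record. Genotypes are written
deterministically from the blueprint, so expected criteria, classes,
posteriors, PS4 flags, de novo calls and burdens are known exactly;
`random_cohort()` is the separate randomized mode used to fuzz
invariants. The generator emulates annotation structure, not biology: no
linkage, no sequencing error, no realistic site-frequency spectrum. A
green end-to-end fixture run demonstrates that the engine computes the
intended function of its inputs across dialects — not that those inputs
resemble any particular patient cohort.

## Numerical choices and test scales

Decimal-string mantissa normalization (rather than binary floating
point) keeps the count extrapolation bit-exact for printed frequencies.
The Fisher p-value is the exact tail, validated in the test suite
against a brute-force binomial-coefficient enumeration over every 2×2
table with total up to 200 (agreement within 1e-12) and against the
conditional exact test; the enrichment stringency property is checked on
a grid of 30 control frequencies spanning 1e-6–0.049 crossed with cohort
sizes 10 and 20. Posterior identities are checked exhaustively for all
evidence vectors with counts ≤ 4. These sizes keep the full suite under
two minutes on a single core while covering every discrete regime the
methods distinguish.

## Limitations

Criteria depending on unavailable evidence are never assigned, so
categorical classes tend to be conservative relative to a manual
curation that can weigh segregation or phenotype specificity. The
bundled gene/domain/residue tables are deliberately small, user-
replaceable defaults, not a curated knowledge base. PS4's extrapolation
inherits the biases of the chosen frequency database, and the burden
score is a sum of probabilities — a screening statistic, not a formal
association test.
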