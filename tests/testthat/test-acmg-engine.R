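# Per-criterion predicates and engine-level invariants. Each case crafts a
# variant carrying exactly the evidence under test against the bundled
# reference tables (TP53 is LoF-intolerant and missense-constrained; BRCA2
# LoF-intolerant; TTN truncating-mechanism; MUC16 none of these).

test_that("truncating and splicing variants in LoF genes earn PVS1", {
  expect_true("PVS1" %in% criteria_of(gene = "BRCA2", exonic_func = "stopgain"))
  expect_true("PVS1" %in% criteria_of(gene = "BRCA2",
                                      exonic_func = "frameshift deletion"))
  expect_true("PVS1" %in% criteria_of(gene = "BRCA2", func_region = "splicing",
                                      exonic_func = NA_character_))
  # not a LoF-mechanism gene
  expect_false("PVS1" %in% criteria_of(gene = "MUC16", exonic_func = "stopgain"))
  # not a null variant
  expect_false("PVS1" %in% criteria_of(gene = "BRCA2",
                                       exonic_func = "nonsynonymous SNV"))
})

test_that("a rare truncating variant in a LoF gene gets exactly PVS1+PM2", {
  expect_setequal(criteria_of(gene = "BRCA2", exonic_func = "stopgain"),
                  c("PVS1", "PM2"))
})

test_that("known and novel substitutions at pathogenic residues split PS1/PM5", {
  # bundled table holds TP53 R175H
  same <- criteria_of(gene = "TP53", aa_change = "p.R175H")
  expect_true("PS1" %in% same)
  expect_false("PM5" %in% same)
  other <- criteria_of(gene = "TP53", aa_change = "p.R175L")
  expect_true("PM5" %in% other)
  expect_false("PS1" %in% other)
  # unrelated residue: neither
  neither <- criteria_of(gene = "TP53", aa_change = "p.G105D")
  expect_false(any(c("PS1", "PM5") %in% neither))
  # three-letter notation parses the same way
  expect_true("PS1" %in% criteria_of(gene = "TP53", aa_change = "p.Arg175His"))
})

test_that("ClinVar assertions split into strong (PS3/BS3) and supporting (PP5/BP6)", {
  backed <- criteria_of(clinvar_sig = "Pathogenic",
                        clinvar_status = "reviewed_by_expert_panel")
  expect_true("PS3" %in% backed)
  expect_false("PP5" %in% backed)
  unbacked <- criteria_of(clinvar_sig = "Pathogenic",
                          clinvar_status = "no_assertion_criteria_provided")
  expect_true("PP5" %in% unbacked)
  expect_false("PS3" %in% unbacked)
  # "no_assertion_criteria_provided" must not match as assertion-backed
  expect_false("BS3" %in% criteria_of(clinvar_sig = "Benign",
                                      clinvar_status = "no_assertion_criteria_provided"))
  expect_true("BP6" %in% criteria_of(clinvar_sig = "Benign",
                                     clinvar_status = NA_character_))
  expect_true("BS3" %in% criteria_of(clinvar_sig = "Benign",
                                     clinvar_status = "criteria_provided,_multiple_submitters"))
  # "pathogenicity" inside conflicting-interpretation strings is not "pathogenic"
  none <- criteria_of(clinvar_sig = "Conflicting_interpretations_of_pathogenicity",
                      clinvar_status = "criteria_provided,_conflicting_interpretations")
  expect_false(any(c("PS3", "PP5") %in% none))
})

test_that("domain and frequency criteria follow their thresholds", {
  expect_true("PM1" %in% criteria_of(domain_annotation = "Protein_kinase_domain"))
  expect_false("PM1" %in% criteria_of(domain_annotation = "Zinc_finger_C2H2"))
  expect_false("PM1" %in% criteria_of(domain_annotation = "Protein_kinase_domain",
                                      exonic_func = "stopgain"))
  # PM2: absent or uniformly rare
  expect_true("PM2" %in% criteria_of())
  expect_true("PM2" %in% criteria_of(pop_freqs = c(gnomad_exome = 5e-5)))
  expect_false("PM2" %in% criteria_of(pop_freqs = c(gnomad_exome = 5e-5,
                                                    exac = 2e-4)))
  # BA1 / BS1 ladder, mutual exclusion with PM2
  common <- criteria_of(pop_freqs = c(gnomad_exome = 0.12))
  expect_true("BA1" %in% common)
  expect_false(any(c("PM2", "BS1") %in% common))
  mid <- criteria_of(pop_freqs = c(gnomad_exome = 0.02))
  expect_true("BS1" %in% mid)
  expect_false("BA1" %in% mid)
})

test_that("protein-length and repeat-region evidence separates PM4 from BP3", {
  pm4 <- criteria_of(exonic_func = "nonframeshift deletion")
  expect_true("PM4" %in% pm4)
  expect_true("PM4" %in% criteria_of(exonic_func = "stoploss"))
  bp3 <- criteria_of(exonic_func = "nonframeshift insertion",
                     repeat_region = TRUE,
                     pop_freqs = c(gnomad_exome = 1e-3))
  expect_true("BP3" %in% bp3)
  expect_false("PM4" %in% bp3)
  # domain annotation blocks BP3
  expect_false("BP3" %in% criteria_of(exonic_func = "nonframeshift insertion",
                                      repeat_region = TRUE,
                                      domain_annotation = "Protein_kinase_domain"))
})

test_that("in-silico predictor votes drive PP3/BP4 with a minimum panel", {
  del2 <- criteria_of(predictor_calls = c(sift = "deleterious",
                                          polyphen_hvar = "deleterious"))
  expect_true("PP3" %in% del2)
  tol2 <- criteria_of(predictor_calls = c(sift = "tolerated",
                                          polyphen_hvar = "tolerated"))
  expect_true("BP4" %in% tol2)
  # one predictor is not enough
  expect_false(any(c("PP3", "BP4") %in%
                     criteria_of(predictor_calls = c(sift = "deleterious"))))
  # split vote at the default 0.5 fraction satisfies both thresholds
  split <- criteria_of(predictor_calls = c(sift = "deleterious",
                                           polyphen_hvar = "tolerated"))
  expect_true(all(c("PP3", "BP4") %in% split))
})

test_that("gene-level missense context separates PP2 from BP1", {
  expect_true("PP2" %in% criteria_of(gene = "TP53"))
  expect_true("BP1" %in% criteria_of(gene = "TTN"))
  expect_false("PP2" %in% criteria_of(gene = "TTN"))
})

test_that("synonymous variants without splice impact earn BP7", {
  expect_true("BP7" %in% criteria_of(exonic_func = "synonymous SNV"))
  expect_true("BP7" %in% criteria_of(exonic_func = "synonymous SNV",
                                     splice_pred = 0.1))
  expect_false("BP7" %in% criteria_of(exonic_func = "synonymous SNV",
                                      splice_pred = 0.9))
  expect_false("BP7" %in% criteria_of(exonic_func = "nonsynonymous SNV"))
})

test_that("reported homozygotes in population data trigger BS2", {
  expect_true("BS2" %in% criteria_of(hom_count = 3))
  expect_false("BS2" %in% criteria_of(hom_count = 0))
  expect_false("BS2" %in% criteria_of())
})

test_that("assignment is deterministic and stays within the closed criteria set", {
  coh <- random_cohort(n_variants = 120, n_samples = 4, seed = 42)
  a <- assign_criteria(coh, test_tables())
  b <- assign_criteria(coh, test_tables())
  expect_identical(a$criteria, b$criteria)
  never <- c("PM3", "PM6", "PP1", "PP4", "BS4", "BP2", "BP5")
  for (cr in a$criteria) {
    expect_true(all(cr %in% setdiff(c("PVS1", paste0("PS", 1:4),
                                      paste0("PM", 1:5), paste0("PP", 2:5),
                                      "BA1", paste0("BS", 1:3),
                                      paste0("BP", c(1, 3, 4, 6, 7))), never)))
    expect_false(any(never %in% cr))
    expect_false(all(c("BA1", "PM2") %in% cr))
    expect_false(all(c("BA1", "PS4") %in% cr))
  }
  # every assigned criterion carries an evidence note
  expect_true(all(mapply(function(cr, ev) setequal(cr, names(ev)),
                         a$criteria, a$evidence)))
})

test_that("adding unrelated evidence never removes assigned criteria", {
  coh <- random_cohort(n_variants = 80, n_samples = 4, seed = 7)
  base <- assign_criteria(coh, test_tables())
  # adding a ClinVar assertion only touches PS3/PP5
  richer <- coh
  richer$clinvar_sig <- ifelse(is.na(coh$clinvar_sig), "Pathogenic", coh$clinvar_sig)
  richer$clinvar_status <- ifelse(is.na(coh$clinvar_sig),
                                  "reviewed_by_expert_panel", coh$clinvar_status)
  grown <- assign_criteria(richer, test_tables())
  ok <- mapply(function(old, new) all(old %in% new), base$criteria, grown$criteria)
  expect_true(all(ok))
  # adding a homozygote count only touches BS2
  richer2 <- coh
  richer2$hom_count <- ifelse(is.na(coh$hom_count), 2, coh$hom_count)
  grown2 <- assign_criteria(richer2, test_tables())
  ok2 <- mapply(function(old, new) all(old %in% new), base$criteria, grown2$criteria)
  expect_true(all(ok2))
})

test_that("empty reference tables silently disable the criteria that need them", {
  empty_dir <- withr::local_tempdir()
  tabs <- reference_tables(empty_dir)
  got <- assign_criteria(make_variant(gene = "BRCA2", exonic_func = "stopgain",
                                      aa_change = "p.R175H"),
                         tabs)$criteria[[1]]
  expect_false(any(c("PVS1", "PS1", "PM5", "PP2", "BP1") %in% got))
  expect_true("PM2" %in% got)
})
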