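# Synthetic annotated cohorts with known ground truth. Each blueprint row
# names an evidence recipe; the generator emits the same cohort in three
# dialects (ANNOVAR table, ANNOVAR-annotated VCF, VEP-annotated VCF) plus
# a trio pedigree, together with the expected criteria, classes,
# enrichment flags, de novo calls and gene burdens for direct assertion.
# Genotypes come straight from the blueprint — no sampling noise — so the
# truth object is exact; random_cohort() provides a separate randomized
# mode for property tests.

# Evidence recipes. Expected criteria are frozen here by hand from the
# criteria definitions; genes are chosen for their bundled-table
# memberships (e.g. TP53 is both LoF-intolerant and missense-constrained).
FIXTURE_RECIPES <- list(
  lof_rare = list(
    gene = "BRCA2", func_region = "exonic", exonic_func = "stopgain",
    ref = "C", alt = "T", aa_change = "p.Q100*",
    expected_criteria = c("PVS1", "PM2"), expected_class = "likely_pathogenic"
  ),
  known_residue = list(
    gene = "TP53", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "G", alt = "A", aa_change = "p.R175H",
    expected_criteria = c("PS1", "PM2", "PP2"),
    expected_class = "likely_pathogenic"
  ),
  novel_at_residue = list(
    gene = "TP53", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "G", alt = "T", aa_change = "p.R175L",
    expected_criteria = c("PM2", "PM5", "PP2"), expected_class = "VUS"
  ),
  common = list(
    gene = "OR4F5", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "A", alt = "G", control_maf = 0.12,
    expected_criteria = "BA1", expected_class = "benign"
  ),
  benign_evidence = list(
    gene = "ALDH2", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "G", alt = "A", control_maf = 0.02, predictors = "tolerated",
    expected_criteria = c("BS1", "BP4"), expected_class = "likely_benign"
  ),
  silent = list(
    gene = "SAMD11", func_region = "exonic", exonic_func = "synonymous SNV",
    ref = "C", alt = "T", control_maf = 5e-4,
    expected_criteria = "BP7", expected_class = "VUS"
  ),
  enriched = list(
    gene = "MUC16", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "T", alt = "C", control_maf = 3.23e-5, predictors = "deleterious",
    expected_criteria = c("PS4", "PM2", "PP3"),
    expected_class = "likely_pathogenic", expected_ps4 = TRUE
  ),
  de_novo_lof = list(
    gene = "BRCA2", func_region = "exonic", exonic_func = "stopgain",
    ref = "G", alt = "T", aa_change = "p.E500*",
    expected_criteria = c("PVS1", "PS2", "PM2"),
    expected_class = "pathogenic", expected_de_novo = TRUE
  ),
  domain_missense = list(
    gene = "RET", func_region = "exonic", exonic_func = "nonsynonymous SNV",
    ref = "C", alt = "G", domain = "Protein_kinase_domain",
    predictors = "deleterious",
    expected_criteria = c("PM1", "PM2", "PP3"), expected_class = "VUS"
  ),
  inframe = list(
    gene = "NOC2L", func_region = "exonic",
    exonic_func = "nonframeshift deletion", ref = "ACTG", alt = "A",
    expected_criteria = c("PM2", "PM4"), expected_class = "VUS"
  ),
  repeat_inframe = list(
    gene = "PLEKHN1", func_region = "exonic",
    exonic_func = "nonframeshift insertion", ref = "A", alt = "AGCG",
    control_maf = 1e-3, repeat_region = TRUE,
    expected_criteria = "BP3", expected_class = "VUS"
  ),
  reported_pathogenic = list(
    gene = "KLHL17", func_region = "exonic",
    exonic_func = "nonsynonymous SNV", ref = "T", alt = "G",
    clinvar_sig = "Pathogenic",
    clinvar_status = "no_assertion_criteria_provided",
    expected_criteria = c("PM2", "PP5"), expected_class = "VUS"
  )
)

#' Default fixture blueprint
#'
#' Twelve variants covering truncating, hotspot-residue, common/benign,
#' enriched, de novo, domain, in-frame and reputable-source evidence
#' recipes over a 10-sample cohort with one trio (child `S08`, healthy
#' parents `S09`/`S10`).
#'
#' @return A tibble, one row per planned variant, with the recipe name,
#'   position, carrier samples and expected-outcome bookkeeping.
#' @export
fixture_blueprints <- function() {
  tibble::tibble(
    id = sprintf("v%02d", 1:12),
    pattern = names(FIXTURE_RECIPES),
    chrom = "1",
    pos = 1000L * (1:12),
    carriers = list("S01", "S02", "S03",
                    c("S01", "S02", "S03", "S04", "S05", "S06"),
                    c("S04", "S05"), "S06",
                    c("S01", "S02", "S03", "S04", "S05"),
                    "S08", "S07", "S01", "S02", "S03")
  )
}

#' Default fixture pedigree (one trio, healthy parents)
#' @return A pedigree tibble.
#' @export
fixture_pedigree <- function() {
  tibble::tibble(
    sample = c("S08", "S09", "S10"),
    trio_id = "T1",
    role = c("child", "father", "mother"),
    affected = c(TRUE, FALSE, FALSE)
  )
}

CRITERIA_WEIGHTS <- function(X) c(
  PVS = 1, PS = 1 / X, PM = 1 / X^2, PP = 1 / X^3,
  BS = -1 / X, BP = -1 / X^3
)

# Truth-side posterior arithmetic, written out independently of the
# classifier module (same published formula, separately unit-tested).
truth_posterior <- function(criteria, prior = 0.10, odds = 350, X = 2) {
  if ("BA1" %in% criteria) return(0)
  w <- CRITERIA_WEIGHTS(X)
  expo <- sum(vapply(criteria, function(cr) {
    cls <- sub("[0-9]+$", "", cr)
    if (cls == "BA") 0 else unname(w[cls])
  }, numeric(1)))
  op <- odds^expo
  op * prior / ((op - 1) * prior + 1)
}

#' Generate a synthetic annotated cohort with ground truth
#'
#' @param blueprints Blueprint tibble, see [fixture_blueprints()]. Custom
#'   rows may override `control_maf` per variant; a combination that
#'   contradicts the recipe's expected criteria (e.g. demanding PM2 next
#'   to a common allele) is rejected.
#' @param n_samples Cohort size (default 10; sample names `S01`, ...).
#' @param dir Output directory; created if needed. When `NULL` nothing is
#'   written and only the in-memory cohort and truth are returned.
#' @param control_maf Optional named numeric overriding the recipe control
#'   frequency per variant id.
#' @return List with `cohort` (the in-memory truth cohort), `truth`
#'   (per-variant expected criteria/class/posterior/PS4/de novo),
#'   `burden_truth`, `pedigree`, and `paths` to the written files
#'   (`annovar_tsv`, `annovar_vcf`, `vep_vcf`, `pedigree`).
#' @export
generate_cohort <- function(blueprints = fixture_blueprints(),
                            n_samples = 10, dir = NULL,
                            control_maf = NULL) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  ped <- fixture_pedigree()
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(blueprints))) {
    bp <- blueprints[i, ]
    rc <- FIXTURE_RECIPES[[bp$pattern]]
    if (is.null(rc)) {
      rlang::abort(paste0("unknown fixture pattern: ", bp$pattern),
                   class = "acmgscore_spec_error")
    }
    maf <- rc$control_maf %||% NA_real_
    if (!is.null(control_maf) && bp$id %in% names(control_maf)) {
      maf <- unname(control_maf[[bp$id]])
    }
    expected <- rc$expected_criteria
    # Contradiction screen: the stated evidence must be producible.
    if ("PM2" %in% expected && !is.na(maf) && maf >= 1e-4) {
      rlang::abort(sprintf("blueprint %s demands PM2 but control MAF %g is not rare",
                           bp$id, maf), class = "acmgscore_spec_error")
    }
    if ("BA1" %in% expected && (is.na(maf) || maf <= 0.05)) {
      rlang::abort(sprintf("blueprint %s demands BA1 without a common allele", bp$id),
                   class = "acmgscore_spec_error")
    }
    if (all(c("BA1", "PM2") %in% expected)) {
      rlang::abort(sprintf("blueprint %s demands mutually exclusive BA1 and PM2", bp$id),
                   class = "acmgscore_spec_error")
    }

    carriers <- bp$carriers[[1]]
    gts <- stats::setNames(rep("hom_ref", n_samples), samples)
    gts[intersect(carriers, samples)] <- "het"
    if (isTRUE(rc$expected_de_novo)) {
      gts[ped$sample[ped$role %in% c("father", "mother")]] <- "hom_ref"
    }

    preds <- if (is.null(rc$predictors)) {
      stats::setNames(character(), character())
    } else {
      c(sift = rc$predictors, polyphen_hvar = rc$predictors)
    }
    freqs <- if (is.na(maf)) {
      stats::setNames(numeric(), character())
    } else {
      c(gnomad_exome = maf)
    }

    rows[[i]] <- tibble::tibble(
      chrom = bp$chrom, pos = bp$pos, ref = rc$ref, alt = rc$alt,
      gene = rc$gene, func_region = rc$func_region,
      exonic_func = rc$exonic_func,
      aa_change = rc$aa_change %||% NA_character_,
      clinvar_sig = rc$clinvar_sig %||% NA_character_,
      clinvar_status = rc$clinvar_status %||% NA_character_,
      domain_annotation = rc$domain %||% NA_character_,
      repeat_region = rc$repeat_region %||% NA,
      splice_pred = NA_real_, hom_count = NA_real_,
      pop_freqs = list(freqs), predictor_calls = list(preds),
      genotypes = list(gts)
    )
    truth[[i]] <- tibble::tibble(
      id = bp$id, gene = rc$gene,
      expected_criteria = list(sort(expected)),
      expected_class = rc$expected_class,
      expected_posterior = truth_posterior(expected),
      expected_ps4 = isTRUE(rc$expected_ps4),
      expected_de_novo = isTRUE(rc$expected_de_novo)
    )
  }
  cohort <- as_cohort(dplyr::bind_rows(rows), samples = samples)
  truth <- dplyr::bind_rows(truth)

  # Burden truth over the post-strip sample set, same published formula.
  healthy_parents <- ped$sample[ped$role %in% c("father", "mother") & !ped$affected]
  kept <- setdiff(samples, healthy_parents)
  bt <- tibble::tibble(
    gene = truth$gene,
    posterior = truth$expected_posterior,
    carriers = vapply(cohort$genotypes, function(g) {
      sum(g[kept] %in% c("het", "hom_alt"))
    }, integer(1))
  )
  bt <- bt[bt$posterior > 0.80, ]
  burden_truth <- bt |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(burden = sum(.data$posterior * .data$carriers),
                     n_variants_counted = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$burden), .data$gene)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      annovar_tsv = file.path(dir, "cohort.annovar.tsv"),
      annovar_vcf = file.path(dir, "cohort.annovar.vcf"),
      vep_vcf = file.path(dir, "cohort.vep.vcf"),
      pedigree = file.path(dir, "pedigree.tsv")
    )
    write_fixture_annovar_tsv(cohort, paths$annovar_tsv)
    write_fixture_annovar_vcf(cohort, paths$annovar_vcf)
    write_fixture_vep_vcf(cohort, paths$vep_vcf)
    ped_out <- ped
    ped_out$affected <- as.integer(ped_out$affected)
    readr::write_tsv(ped_out, paths$pedigree)
  }
  list(cohort = cohort, truth = truth, burden_truth = burden_truth,
       pedigree = ped, paths = paths)
}

# --- dialect writers -------------------------------------------------------

fixture_gt_string <- function(state) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[state]
}

pred_letter <- function(call, tool) {
  if (is.na(call)) return(NA_character_)
  if (tool == "sift") unname(c(deleterious = "D", tolerated = "T")[call])
  else unname(c(deleterious = "D", tolerated = "B")[call])
}

write_fixture_annovar_tsv <- function(cohort, path) {
  samples <- cohort_samples(cohort)
  get_pred <- function(f, tool) {
    vapply(cohort$predictor_calls, function(p) {
      if (tool %in% names(p)) pred_letter(p[[tool]], tool) else NA_character_
    }, character(1))
  }
  tab <- tibble::tibble(
    Chr = cohort$chrom, Start = cohort$pos,
    End = cohort$pos + nchar(cohort$ref) - 1L,
    Ref = cohort$ref, Alt = cohort$alt,
    `Func.refGene` = cohort$func_region,
    `Gene.refGene` = cohort$gene,
    `ExonicFunc.refGene` = cohort$exonic_func,
    `AAChange.refGene` = ifelse(is.na(cohort$aa_change), NA,
                                paste0(cohort$gene, ":NM_000000:exon1:c.1A>G:",
                                       cohort$aa_change)),
    gnomAD_exome_ALL = vapply(cohort$pop_freqs, function(f) {
      if ("gnomad_exome" %in% names(f)) format(f[["gnomad_exome"]], scientific = FALSE)
      else NA_character_
    }, character(1)),
    SIFT_pred = get_pred(cohort$predictor_calls, "sift"),
    Polyphen2_HVAR_pred = get_pred(cohort$predictor_calls, "polyphen_hvar"),
    CLNSIG = cohort$clinvar_sig,
    CLNREVSTAT = cohort$clinvar_status,
    Interpro_domain = cohort$domain_annotation,
    genomicSuperDups = ifelse(cohort$repeat_region %in% TRUE, "Score=0.99", NA),
    dbscSNV_ADA_SCORE = cohort$splice_pred
  )
  for (s in samples) {
    tab[[s]] <- vapply(cohort$genotypes, function(g) fixture_gt_string(g[[s]]),
                       character(1))
  }
  readr::write_tsv(tab, path, na = ".")
}

fixture_maf_string <- function(f) {
  if ("gnomad_exome" %in% names(f)) format(f[["gnomad_exome"]], scientific = FALSE)
  else NA_character_
}

write_fixture_annovar_vcf <- function(cohort, path) {
  samples <- cohort_samples(cohort)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=Func.refGene,Number=.,Type=String,Description=\"Func.refGene annotation\">",
    "##INFO=<ID=Gene.refGene,Number=.,Type=String,Description=\"Gene.refGene annotation\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=.,Type=String,Description=\"ExonicFunc.refGene annotation\">",
    "##INFO=<ID=AAChange.refGene,Number=.,Type=String,Description=\"AAChange.refGene annotation\">",
    "##INFO=<ID=gnomAD_exome_ALL,Number=1,Type=Float,Description=\"gnomAD exome allele frequency\">",
    "##INFO=<ID=SIFT_pred,Number=1,Type=String,Description=\"SIFT prediction\">",
    "##INFO=<ID=Polyphen2_HVAR_pred,Number=1,Type=String,Description=\"PolyPhen-2 HVAR prediction\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"ClinVar significance\">",
    "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"ClinVar review status\">",
    "##INFO=<ID=Interpro_domain,Number=.,Type=String,Description=\"InterPro domain\">",
    "##INFO=<ID=genomicSuperDups,Number=.,Type=String,Description=\"Segmental duplication\">",
    "##INFO=<ID=dbscSNV_ADA_SCORE,Number=1,Type=Float,Description=\"dbscSNV ada score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(cohort)), function(i) {
    kv <- c(
      Func.refGene = cohort$func_region[i],
      Gene.refGene = cohort$gene[i],
      ExonicFunc.refGene = if (is.na(cohort$exonic_func[i])) NA else
        gsub(" ", "_", cohort$exonic_func[i]),
      AAChange.refGene = if (is.na(cohort$aa_change[i])) NA else
        paste0(cohort$gene[i], ":NM_000000:exon1:c.1A>G:", cohort$aa_change[i]),
      gnomAD_exome_ALL = fixture_maf_string(cohort$pop_freqs[[i]]),
      SIFT_pred = {
        p <- cohort$predictor_calls[[i]]
        if ("sift" %in% names(p)) pred_letter(p[["sift"]], "sift") else NA
      },
      Polyphen2_HVAR_pred = {
        p <- cohort$predictor_calls[[i]]
        if ("polyphen_hvar" %in% names(p)) pred_letter(p[["polyphen_hvar"]], "polyphen")
        else NA
      },
      CLNSIG = cohort$clinvar_sig[i],
      CLNREVSTAT = cohort$clinvar_status[i],
      Interpro_domain = cohort$domain_annotation[i],
      genomicSuperDups = if (isTRUE(cohort$repeat_region[i])) "Score=0.99" else NA,
      dbscSNV_ADA_SCORE = if (is.na(cohort$splice_pred[i])) NA else
        format(cohort$splice_pred[i])
    )
    kv <- kv[!is.na(kv)]
    info <- paste(sprintf("%s=%s", names(kv), unname(kv)), collapse = ";")
    gts <- vapply(samples, function(s) fixture_gt_string(cohort$genotypes[[i]][[s]]),
                  character(1))
    paste(c(cohort$chrom[i], cohort$pos[i], ".", cohort$ref[i], cohort$alt[i],
            ".", "PASS", info, "GT", gts), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
}

VEP_CSQ_FIELDS <- c("Allele", "Consequence", "SYMBOL", "Protein_position",
                    "Amino_acids", "gnomAD_AF", "SIFT", "PolyPhen",
                    "CLIN_SIG", "DOMAINS", "repeat_region", "ada_score")

vep_consequence_for <- function(func_region, exonic_func, ref, alt) {
  if (isTRUE(grepl("splicing", func_region))) return("splice_donor_variant")
  switch(exonic_func,
    "stopgain" = "stop_gained",
    "stoploss" = "stop_lost",
    "startloss" = "start_lost",
    "nonsynonymous SNV" = "missense_variant",
    "synonymous SNV" = "synonymous_variant",
    "frameshift insertion" = "frameshift_variant",
    "frameshift deletion" = "frameshift_variant",
    "nonframeshift insertion" = "inframe_insertion",
    "nonframeshift deletion" = "inframe_deletion",
    "intergenic_variant"
  )
}

vep_pred_string <- function(call, tool) {
  if (is.na(call)) return(NA_character_)
  if (tool == "sift") {
    unname(c(deleterious = "deleterious(0.01)", tolerated = "tolerated(0.8)")[call])
  } else {
    unname(c(deleterious = "probably_damaging(0.99)", tolerated = "benign(0.01)")[call])
  }
}

write_fixture_vep_vcf <- function(cohort, path) {
  samples <- cohort_samples(cohort)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           paste(VEP_CSQ_FIELDS, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(cohort)), function(i) {
    aa <- parse_aa_change(cohort$aa_change[i])
    p <- cohort$predictor_calls[[i]]
    fields <- c(
      Allele = cohort$alt[i],
      Consequence = vep_consequence_for(cohort$func_region[i],
                                        cohort$exonic_func[i],
                                        cohort$ref[i], cohort$alt[i]),
      SYMBOL = cohort$gene[i],
      Protein_position = if (is.null(aa)) "" else as.character(aa$pos),
      Amino_acids = if (is.null(aa)) "" else paste0(aa$ref, "/", aa$alt),
      gnomAD_AF = fixture_maf_string(cohort$pop_freqs[[i]]) %|NA|% "",
      SIFT = if ("sift" %in% names(p)) vep_pred_string(p[["sift"]], "sift") else "",
      PolyPhen = if ("polyphen_hvar" %in% names(p)) {
        vep_pred_string(p[["polyphen_hvar"]], "polyphen")
      } else "",
      CLIN_SIG = if (is.na(cohort$clinvar_sig[i])) "" else
        tolower(cohort$clinvar_sig[i]),
      DOMAINS = cohort$domain_annotation[i] %|NA|% "",
      repeat_region = if (isTRUE(cohort$repeat_region[i])) "1" else "",
      ada_score = if (is.na(cohort$splice_pred[i])) "" else
        format(cohort$splice_pred[i])
    )
    fields[is.na(fields)] <- ""
    info <- paste0("CSQ=", paste(fields, collapse = "|"))
    gts <- vapply(samples, function(s) fixture_gt_string(cohort$genotypes[[i]][[s]]),
                  character(1))
    paste(c(cohort$chrom[i], cohort$pos[i], ".", cohort$ref[i], cohort$alt[i],
            ".", "PASS", info, "GT", gts), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
}

`%|NA|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Random annotated cohort for property tests
#'
#' Draws annotation fields and genotypes at random (reproducibly under the
#' given seed). Unlike [generate_cohort()] there is no truth object; this
#' mode exists to fuzz the engine's invariants.
#'
#' @param n_variants,n_samples Cohort dimensions.
#' @param seed Random seed.
#' @return An `acmg_cohort` tibble.
#' @export
random_cohort <- function(n_variants = 50, n_samples = 6, seed = 1L) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  genes <- c("BRCA2", "TP53", "RET", "MUC16", "OR4F5", "SAMD11", "NOC2L", "APC")
  funcs <- c("stopgain", "nonsynonymous SNV", "synonymous SNV",
             "nonframeshift insertion", "nonframeshift deletion",
             "frameshift deletion", "unknown")
  n <- n_variants
  rows <- tibble::tibble(
    chrom = sample(c("1", "2", "X"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sample(genes, n, replace = TRUE),
    func_region = sample(c("exonic", "splicing", "intronic"), n,
                         replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    exonic_func = sample(funcs, n, replace = TRUE),
    aa_change = ifelse(stats::runif(n) < 0.3,
                       sprintf("p.R%dH", sample.int(300, n, replace = TRUE)),
                       NA_character_),
    clinvar_sig = sample(c(NA, "Pathogenic", "Benign", "Uncertain_significance"),
                         n, replace = TRUE),
    clinvar_status = sample(c(NA, "criteria_provided,_single_submitter",
                              "no_assertion_criteria_provided",
                              "reviewed_by_expert_panel"), n, replace = TRUE),
    domain_annotation = sample(c(NA, "Protein_kinase_domain",
                                 "Zinc_finger_C2H2"), n, replace = TRUE),
    repeat_region = sample(c(NA, TRUE, FALSE), n, replace = TRUE),
    splice_pred = ifelse(stats::runif(n) < 0.2, stats::runif(n), NA_real_),
    hom_count = ifelse(stats::runif(n) < 0.1, sample(0:5, n, replace = TRUE),
                       NA_real_)
  )
  rows$ref <- ifelse(rows$ref == rows$alt, paste0(rows$ref, "A"), rows$ref)
  rows$pop_freqs <- lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (!k) return(stats::setNames(numeric(), character()))
    stats::setNames(signif(stats::runif(k)^6, 3),
                    sample(c("gnomad_exome", "gnomad_genome", "exac",
                             "thousand_genomes"), k))
  })
  rows$predictor_calls <- lapply(seq_len(n), function(i) {
    k <- sample(0:4, 1)
    if (!k) return(stats::setNames(character(), character()))
    stats::setNames(sample(c("deleterious", "tolerated"), k, replace = TRUE),
                    sample(c("sift", "polyphen_hvar", "lrt", "fathmm"), k))
  })
  rows$genotypes <- lapply(seq_len(n), function(i) {
    stats::setNames(sample(c("hom_ref", "het", "hom_alt", "missing"), n_samples,
                           replace = TRUE, prob = c(0.7, 0.2, 0.05, 0.05)),
                    samples)
  })
  as_cohort(rows, samples = samples)
}
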