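# Assignment of the automatically derivable ACMG/AMP evidence criteria.
# Each criterion is its own predicate over one normalized variant plus the
# reference tables; criteria needing trio or cohort evidence (PS2, PS4) are
# attached by their own modules. Criteria whose evidence an annotated file
# cannot carry (PM3, PM6, PP1, PP4, BS4, BP2, BP5) are never assigned.

TRUNCATING_FUNCS <- c("stopgain", "frameshift insertion", "frameshift deletion",
                      "startloss")
INFRAME_FUNCS <- c("nonframeshift insertion", "nonframeshift deletion")

ASSIGNABLE_CRITERIA <- c("PVS1", "PS1", "PS2", "PS3", "PS4",
                         "PM1", "PM2", "PM4", "PM5",
                         "PP2", "PP3", "PP5",
                         "BA1", "BS1", "BS2", "BS3",
                         "BP1", "BP3", "BP4", "BP6", "BP7")

# ClinVar review-status split: assertion-backed statuses feed the strong
# functional criteria (PS3/BS3); statuses without assertion criteria feed
# the supporting reputable-source criteria (PP5/BP6).
clinvar_assertion_backed <- function(status) {
  !is.na(status) &&
    !grepl("no_assertion|no_classification|no_interpretation", status, ignore.case = TRUE) &&
    grepl("criteria_provided|expert_panel|practice_guideline", status, ignore.case = TRUE)
}

clinvar_says <- function(sig, what) {
  !is.na(sig) && grepl(paste0("\\b", what, "\\b"), sig, ignore.case = TRUE)
}

#' Assign ACMG criteria to every variant of a cohort
#'
#' Evaluates the 19 annotation-derivable criteria predicates per variant
#' and records a short justification for each assigned criterion. The
#' result gains a `criteria` list-column (character vectors) and an
#' `evidence` list-column (named justifications).
#'
#' @param cohort A cohort tibble from the readers or [as_cohort()].
#' @param tables Reference tables, see [reference_tables()].
#' @param config Thresholds, see [acmg_config()].
#' @return The cohort with `criteria` and `evidence` columns added.
#' @export
#' @examples
#' fx <- generate_cohort(dir = tempfile("fx"))
#' assign_criteria(fx$cohort)$criteria
assign_criteria <- function(cohort, tables = reference_tables(),
                            config = acmg_config()) {
  res <- purrr::pmap(
    list(cohort$gene, cohort$func_region, cohort$exonic_func, cohort$aa_change,
         cohort$pop_freqs, cohort$predictor_calls, cohort$clinvar_sig,
         cohort$clinvar_status, cohort$domain_annotation, cohort$repeat_region,
         cohort$splice_pred, cohort$hom_count),
    function(gene, func_region, exonic_func, aa_change, pop_freqs,
             predictor_calls, clinvar_sig, clinvar_status, domain_annotation,
             repeat_region, splice_pred, hom_count) {
      assign_criteria_one(
        list(gene = gene, func_region = func_region, exonic_func = exonic_func,
             aa_change = aa_change, pop_freqs = pop_freqs,
             predictor_calls = predictor_calls, clinvar_sig = clinvar_sig,
             clinvar_status = clinvar_status,
             domain_annotation = domain_annotation,
             repeat_region = repeat_region, splice_pred = splice_pred,
             hom_count = hom_count),
        tables, config)
    })
  cohort$criteria <- purrr::map(res, "criteria")
  cohort$evidence <- purrr::map(res, "evidence")
  cohort
}

#' Evaluate the criteria predicates for a single variant
#'
#' @param v Named list of normalized annotation fields (one cohort row).
#' @param tables,config See [assign_criteria()].
#' @return `list(criteria = <character>, evidence = <named character>)`.
#' @export
assign_criteria_one <- function(v, tables = reference_tables(),
                                config = acmg_config()) {
  notes <- character()
  add <- function(crit, note) notes[[crit]] <<- note

  freqs <- v$pop_freqs
  maxf <- if (length(freqs)) max(freqs) else NA_real_
  aa <- parse_aa_change(v$aa_change)
  pa <- tables$pathogenic_aa
  aa_hits <- if (!is.null(aa) && nrow(pa)) {
    pa[pa$gene %in% v$gene & pa$protein_pos == aa$pos & pa$ref_aa == aa$ref, ]
  } else pa[0, ]

  calls <- v$predictor_calls
  calls <- calls[calls %in% c("deleterious", "tolerated")]
  n_avail <- length(calls)
  n_del <- sum(calls == "deleterious")
  n_tol <- sum(calls == "tolerated")

  nonsyn <- identical(v$exonic_func, "nonsynonymous SNV")
  truncating <- isTRUE(v$exonic_func %in% TRUNCATING_FUNCS) ||
    isTRUE(grepl("splicing", v$func_region))

  # --- pathogenic side -----------------------------------------------------
  if (truncating && isTRUE(v$gene %in% tables$lof_intolerant)) {
    add("PVS1", sprintf("null variant (%s) in LoF-mechanism gene %s",
                        v$exonic_func %||% v$func_region, v$gene))
  }
  ps1 <- nrow(aa_hits) > 0 && aa$alt %in% aa_hits$alt_aa && aa$ref != aa$alt
  if (ps1) {
    add("PS1", sprintf("%s reproduces known pathogenic residue change %s", v$gene, v$aa_change))
  }
  if (clinvar_says(v$clinvar_sig, "pathogenic") &&
      clinvar_assertion_backed(v$clinvar_status)) {
    add("PS3", sprintf("ClinVar '%s' with assertion-backed review (%s)",
                       v$clinvar_sig, v$clinvar_status))
  }
  if (nonsyn && !is.na(v$domain_annotation %||% NA) &&
      !(v$domain_annotation %in% tables$benign_domains)) {
    add("PM1", sprintf("missense in functional domain '%s'", v$domain_annotation))
  }
  if (length(freqs) == 0 || all(freqs < config$rare_threshold)) {
    add("PM2", if (length(freqs) == 0) "absent from population databases"
        else sprintf("all population frequencies < %g", config$rare_threshold))
  }
  if (isTRUE(v$exonic_func %in% c(INFRAME_FUNCS, "stoploss")) &&
      !isTRUE(v$repeat_region)) {
    add("PM4", sprintf("protein-length change (%s) outside a repeat region", v$exonic_func))
  }
  if (!ps1 && nrow(aa_hits) > 0 && !(aa$alt %in% aa_hits$alt_aa) && aa$ref != aa$alt) {
    add("PM5", sprintf("novel change at residue %s%d with known pathogenic substitution(s) %s",
                       aa$ref, aa$pos, paste(unique(aa_hits$alt_aa), collapse = "/")))
  }
  if (nonsyn && isTRUE(v$gene %in% tables$missense_constrained)) {
    add("PP2", sprintf("missense in missense-constrained gene %s", v$gene))
  }
  if (n_avail >= config$min_predictors && n_del / n_avail >= config$pp3_fraction) {
    add("PP3", sprintf("%d/%d in-silico predictors deleterious", n_del, n_avail))
  }
  if (clinvar_says(v$clinvar_sig, "pathogenic") &&
      !clinvar_assertion_backed(v$clinvar_status)) {
    add("PP5", sprintf("ClinVar '%s' without assertion criteria", v$clinvar_sig))
  }

  # --- benign side ---------------------------------------------------------
  ba1 <- !is.na(maxf) && maxf > config$ba1_threshold
  if (ba1) {
    add("BA1", sprintf("population frequency %.4g > %.2g", maxf, config$ba1_threshold))
  }
  if (!ba1 && !is.na(maxf) && maxf > config$bs1_threshold) {
    add("BS1", sprintf("population frequency %.4g > %g", maxf, config$bs1_threshold))
  }
  if (!is.na(v$hom_count %||% NA) && v$hom_count > config$bs2_hom_count) {
    add("BS2", sprintf("%g homozygotes reported in population data", v$hom_count))
  }
  if (clinvar_says(v$clinvar_sig, "benign") && clinvar_assertion_backed(v$clinvar_status)) {
    add("BS3", sprintf("ClinVar '%s' with assertion-backed review (%s)",
                       v$clinvar_sig, v$clinvar_status))
  }
  if (nonsyn && isTRUE(v$gene %in% tables$truncating_mechanism)) {
    add("BP1", sprintf("missense in truncating-mechanism gene %s", v$gene))
  }
  if (isTRUE(v$exonic_func %in% INFRAME_FUNCS) && isTRUE(v$repeat_region) &&
      is.na(v$domain_annotation %||% NA)) {
    add("BP3", "in-frame indel in repeat region without domain annotation")
  }
  if (n_avail >= config$min_predictors && n_tol / n_avail >= config$bp4_fraction) {
    add("BP4", sprintf("%d/%d in-silico predictors benign", n_tol, n_avail))
  }
  if (clinvar_says(v$clinvar_sig, "benign") && !clinvar_assertion_backed(v$clinvar_status)) {
    add("BP6", sprintf("ClinVar '%s' without assertion criteria", v$clinvar_sig))
  }
  if (identical(v$exonic_func, "synonymous SNV") &&
      (is.na(v$splice_pred %||% NA) || v$splice_pred < config$splice_threshold)) {
    add("BP7", "synonymous change without predicted splice impact")
  }

  crits <- intersect(ASSIGNABLE_CRITERIA, names(notes))
  list(criteria = crits, evidence = notes[crits])
}

#' Append a criterion to selected cohort rows
#'
#' Used by the trio (PS2) and enrichment (PS4) modules; enforces the
#' stand-alone exclusions (PS4 is never attached next to BA1).
#' @noRd
add_criterion <- function(cohort, rows, crit, notes) {
  for (j in seq_along(rows)) {
    i <- rows[j]
    cur <- cohort$criteria[[i]]
    if (crit == "PS4" && "BA1" %in% cur) next
    if (!crit %in% cur) {
      cohort$criteria[[i]] <- intersect(ASSIGNABLE_CRITERIA, c(cur, crit))
      ev <- cohort$evidence[[i]]
      ev[[crit]] <- notes[j]
      cohort$evidence[[i]] <- ev
    }
  }
  cohort
}
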