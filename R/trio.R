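# Trio handling: de novo detection (PS2) and removal of healthy parents
# from downstream cohort analyses.

#' Read and validate a pedigree table
#'
#' Tab-delimited with header columns `sample`, `trio_id`, `role`
#' (`father` / `mother` / `child`) and `affected` (0/1). Every trio must
#' have exactly one father, one mother and one child.
#'
#' @param path Path to the pedigree TSV.
#' @return A validated pedigree tibble with logical `affected`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read pedigree: ", path),
                 class = "acmgscore_input_error")
  }
  ped <- readr::read_tsv(path, col_types = "ccci", progress = FALSE)
  req <- c("sample", "trio_id", "role", "affected")
  missing_cols <- setdiff(req, names(ped))
  if (length(missing_cols)) {
    rlang::abort(paste0("pedigree is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "acmgscore_format_error")
  }
  ped$affected <- as.logical(ped$affected)
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree tibble
#'
#' @param ped Tibble with `sample`, `trio_id`, `role`, `affected`.
#' @param samples Optional cohort sample names; when given, every pedigree
#'   sample must be present in the cohort.
#' @return The pedigree, invisibly.
#' @export
validate_pedigree <- function(ped, samples = NULL) {
  bad_role <- setdiff(unique(ped$role), c("father", "mother", "child"))
  if (length(bad_role)) {
    rlang::abort(paste0("unknown pedigree role(s): ", paste(bad_role, collapse = ", ")),
                 class = "acmgscore_format_error")
  }
  counts <- dplyr::count(ped, .data$trio_id, .data$role)
  full <- tidyr::complete(counts,
                          trio_id = unique(ped$trio_id),
                          role = c("father", "mother", "child"),
                          fill = list(n = 0L))
  if (any(full$n != 1L)) {
    bad <- unique(full$trio_id[full$n != 1L])
    rlang::abort(paste0("each trio needs exactly one father, mother and child; malformed: ",
                        paste(bad, collapse = ", ")),
                 class = "acmgscore_format_error")
  }
  if (!is.null(samples)) {
    absent <- setdiff(ped$sample, samples)
    if (length(absent)) {
      rlang::abort(paste0("pedigree samples missing from cohort: ",
                          paste(absent, collapse = ", ")),
                   class = "acmgscore_format_error")
    }
  }
  invisible(ped)
}

#' Detect de novo variants across trios
#'
#' A variant is de novo in a trio when the child carries the alternate
#' allele (het or hom_alt) and both parents are confidently homozygous
#' reference. A missing parental genotype blocks the call for that trio —
#' conservative against genotype dropout. The variant-level flag is true
#' if any trio qualifies; per-trio detail is kept in `de_novo_trios`.
#'
#' Adds columns `de_novo` (logical) and `de_novo_trios` (list of trio ids)
#' and, when a `criteria` column is present, merges PS2 into qualifying
#' variants.
#'
#' @param cohort A cohort tibble.
#' @param pedigree A validated pedigree tibble, see [read_pedigree()].
#' @return The cohort with de novo columns (and PS2 where detected).
#' @export
detect_de_novo <- function(cohort, pedigree) {
  validate_pedigree(pedigree, cohort_samples(cohort))
  trios <- split(pedigree, pedigree$trio_id)
  hits <- purrr::map(cohort$genotypes, function(g) {
    qualifying <- purrr::keep(trios, function(tr) {
      child  <- g[[tr$sample[tr$role == "child"]]]
      father <- g[[tr$sample[tr$role == "father"]]]
      mother <- g[[tr$sample[tr$role == "mother"]]]
      child %in% c("het", "hom_alt") && father == "hom_ref" && mother == "hom_ref"
    })
    names(qualifying)
  })
  cohort$de_novo <- lengths(hits) > 0
  cohort$de_novo_trios <- hits
  if ("criteria" %in% names(cohort)) {
    rows <- which(cohort$de_novo)
    cohort <- add_criterion(cohort, rows, "PS2",
                            vapply(hits[rows], function(h) {
                              sprintf("de novo in trio(s) %s", paste(h, collapse = ", "))
                            }, character(1)))
  }
  cohort
}

#' Remove healthy parents from a cohort
#'
#' Drops samples whose pedigree role is father or mother and who are not
#' affected; affected parents stay. Idempotent. Downstream carrier counts
#' (PS4, burden) then reflect only potentially affected individuals.
#'
#' @param cohort A cohort tibble.
#' @param pedigree A validated pedigree tibble.
#' @return The cohort with the reduced sample set.
#' @export
strip_healthy_parents <- function(cohort, pedigree) {
  drop <- pedigree$sample[pedigree$role %in% c("father", "mother") & !pedigree$affected]
  keep <- setdiff(cohort_samples(cohort), drop)
  cohort$genotypes <- purrr::map(cohort$genotypes, ~ .x[keep])
  attr(cohort, "samples") <- keep
  cohort
}
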