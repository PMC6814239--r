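#' Variant cohort tibbles
#'
#' A cohort is an ordinary tibble with one row per (decomposed) alternate
#' allele and a fixed set of normalized annotation columns, so it composes
#' with dplyr verbs. Per-sample genotypes live in the `genotypes`
#' list-column as a named character vector per variant (states `hom_ref`,
#' `het`, `hom_alt`, `missing`), with the same sample names in the same
#' order for every variant. Multi-valued annotations (`pop_freqs`,
#' `predictor_calls`) are named list-columns keyed by canonical database /
#' tool labels.
#'
#' @param variants A tibble holding at least the canonical columns
#'   (`chrom`, `pos`, `ref`, `alt`, `gene`, `func_region`, `exonic_func`,
#'   `aa_change`, `pop_freqs`, `predictor_calls`, `clinvar_sig`,
#'   `clinvar_status`, `domain_annotation`, `repeat_region`, `splice_pred`,
#'   `hom_count`, `genotypes`). Missing canonical columns are added empty.
#' @param samples Character vector of sample names, in genotype order.
#' @return A `acmg_cohort` tibble.
#' @export
as_cohort <- function(variants, samples = NULL) {
  variants <- tibble::as_tibble(variants)
  defaults <- list(
    gene = NA_character_, func_region = NA_character_,
    exonic_func = NA_character_, aa_change = NA_character_,
    clinvar_sig = NA_character_, clinvar_status = NA_character_,
    domain_annotation = NA_character_, repeat_region = NA,
    splice_pred = NA_real_, hom_count = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(variants)) variants[[nm]] <- defaults[[nm]]
  }
  if (!"pop_freqs" %in% names(variants)) {
    variants$pop_freqs <- rep(list(stats::setNames(numeric(), character())), nrow(variants))
  }
  if (!"predictor_calls" %in% names(variants)) {
    variants$predictor_calls <- rep(list(stats::setNames(character(), character())), nrow(variants))
  }
  if (!"genotypes" %in% names(variants)) {
    variants$genotypes <- rep(list(stats::setNames(character(), character())), nrow(variants))
  }
  if (is.null(samples)) {
    samples <- if (nrow(variants)) names(variants$genotypes[[1]]) else character()
  }
  validate_cohort(variants, samples)
  structure(variants,
            samples = samples,
            class = c("acmg_cohort", class(tibble::tibble())))
}

validate_cohort <- function(variants, samples) {
  req <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    rlang::abort(paste0("cohort is missing required columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "acmgscore_format_error")
  }
  if (nrow(variants)) {
    if (any(variants$pos < 1, na.rm = TRUE)) {
      rlang::abort("variant positions must be >= 1", class = "acmgscore_format_error")
    }
    same <- vapply(variants$genotypes, function(g) identical(names(g), samples), logical(1))
    if (!all(same)) {
      rlang::abort("all variants must carry genotypes for the same ordered sample set",
                   class = "acmgscore_format_error")
    }
    bad_freq <- vapply(variants$pop_freqs, function(f) {
      length(f) > 0 && any(f < 0 | f > 1, na.rm = TRUE)
    }, logical(1))
    if (any(bad_freq)) {
      rlang::abort("population frequencies must lie in [0, 1]",
                   class = "acmgscore_format_error")
    }
  }
  invisible(TRUE)
}

#' Sample names of a cohort
#' @param x A cohort tibble.
#' @return Character vector of sample names (genotype order).
#' @export
cohort_samples <- function(x) {
  s <- attr(x, "samples")
  if (!is.null(s)) return(s)
  if (nrow(x) && "genotypes" %in% names(x)) return(names(x$genotypes[[1]]))
  character()
}

#' Decode a diploid VCF genotype string against one alternate allele
#'
#' Genotypes are re-expressed against a single alt allele index so that
#' decomposed multi-allelic records keep consistent carrier semantics: a
#' genotype containing the allele once is `het`, twice `hom_alt`, not at
#' all `hom_ref`. Any missing allele (`./1`) or a non-diploid call yields
#' `missing` — conservative for carrier counting.
#'
#' @param gt Genotype strings such as `"0/1"`, `"1|1"`, `"./."`.
#' @param alt_index Integer allele index the record was decomposed to.
#' @return Character vector of states.
#' @export
decode_genotype <- function(gt, alt_index = 1L) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% MISSING_SENTINELS) return("missing")
    g <- stringr::str_split(g, ":")[[1]][1]
    alleles <- stringr::str_split(g, "[/|]")[[1]]
    if (length(alleles) != 2L) return("missing")
    if (any(alleles == ".")) return("missing")
    n_alt <- sum(alleles == as.character(alt_index))
    c("hom_ref", "het", "hom_alt")[n_alt + 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.acmg_cohort <- function(x, ...) {
  n_s <- length(cohort_samples(x))
  cat(sprintf("# A variant cohort: %d variants x %d samples\n", nrow(x), n_s))
  NextMethod()
}
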