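#' Read an annotated multi-sample VCF into a cohort
#'
#' Supports two annotation dialects: ANNOVAR (`key=value` INFO entries such
#' as `Func.refGene=...;ExonicFunc.refGene=...`) and VEP (a `CSQ` INFO
#' field whose sub-field layout is declared in the `##INFO=<ID=CSQ,...>`
#' header line). Multi-allelic records are decomposed into one row per
#' alternate allele, with every sample genotype re-expressed against that
#' allele. Non-diploid genotypes trigger a record-level warning and are set
#' to `missing`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param dialect `"annovar"` or `"vep"`.
#' @return An `acmg_cohort` tibble.
#' @export
read_annotated_vcf <- function(path, dialect = c("annovar", "vep")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read VCF: ", path), class = "acmgscore_input_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- if (ncol(vcf@gt) > 1) colnames(vcf@gt)[-1] else character()
  gt <- if (length(samples)) vcfR::extract.gt(vcf, element = "GT") else NULL

  csq_format <- NULL
  if (dialect == "vep") {
    meta <- vcf@meta
    csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
    if (!length(csq_line)) {
      rlang::abort("VEP dialect requires a ##INFO=<ID=CSQ,...> header describing the CSQ format",
                   class = "acmgscore_format_error")
    }
    fmt <- stringr::str_match(csq_line[1], "Format:\\s*([A-Za-z0-9_|]+)")[, 2]
    if (is.na(fmt)) {
      rlang::abort("CSQ header lacks a Format: field list", class = "acmgscore_format_error")
    }
    csq_format <- stringr::str_split(fmt, "\\|")[[1]]
  }

  rows <- list()
  warned_nondiploid <- FALSE
  for (i in seq_len(nrow(fix))) {
    alts <- stringr::str_split(fix$ALT[i], ",")[[1]]
    info <- fix$INFO[i]
    for (k in seq_along(alts)) {
      gts <- if (!is.null(gt)) gt[i, , drop = TRUE] else stats::setNames(character(), character())
      raw_gt <- as.character(gts)
      nondip <- !is.na(raw_gt) & !grepl("^\\.$", raw_gt) &
        vapply(raw_gt, function(g) {
          length(stringr::str_split(stringr::str_split(g, ":")[[1]][1], "[/|]")[[1]]) != 2L
        }, logical(1))
      if (any(nondip) && !warned_nondiploid) {
        rlang::warn("non-diploid genotypes encountered; set to missing")
        warned_nondiploid <- TRUE
      }
      states <- decode_genotype(raw_gt, alt_index = k)
      names(states) <- samples
      ann <- if (dialect == "annovar") {
        parse_annovar_info(info)
      } else {
        parse_vep_csq(info, csq_format, ref = fix$REF[i], alt = alts[k])
      }
      ann$chrom <- fix$CHROM[i]
      ann$pos <- as.integer(fix$POS[i])
      ann$ref <- fix$REF[i]
      ann$alt <- alts[k]
      ann$genotypes <- list(states)
      rows[[length(rows) + 1L]] <- ann
    }
  }
  if (!length(rows)) {
    return(as_cohort(tibble::tibble(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()),
                     samples = samples))
  }
  out <- dplyr::bind_rows(rows)
  as_cohort(out, samples = samples)
}

# One ANNOVAR INFO string -> one-row tibble of canonical annotation fields
# (reusing the tabular column normalization).
parse_annovar_info <- function(info) {
  if (is.na(info) || info == ".") {
    return(build_cohort_row_from_pairs(stats::setNames(character(), character())))
  }
  entries <- stringr::str_split(info, ";")[[1]]
  has_eq <- grepl("=", entries, fixed = TRUE)
  keys <- sub("=.*$", "", entries[has_eq])
  vals <- decode_annovar_info_value(sub("^[^=]*=", "", entries[has_eq]))
  build_cohort_row_from_pairs(stats::setNames(vals, keys))
}

build_cohort_row_from_pairs <- function(pairs) {
  # Underscore-encoded consequence strings come back to spaces via the
  # exonic-func normalizer inside the column builder.
  df <- tibble::as_tibble(c(as.list(pairs),
                            list(Chr = ".", Start = "1", Ref = ".", Alt = "x")))
  coh <- build_cohort_from_columns(df, c(chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt"))
  row <- tibble::as_tibble(coh)
  row$chrom <- NULL; row$pos <- NULL; row$ref <- NULL; row$alt <- NULL
  row$genotypes <- NULL
  row
}

# One VEP CSQ INFO field -> one-row tibble of canonical fields for a given
# alt allele. Picks the CSQ block whose Allele matches the alt (falling
# back to the first block), maps sub-fields through the same normalization
# table as ANNOVAR columns.
parse_vep_csq <- function(info, csq_format, ref, alt) {
  empty <- build_cohort_row_from_pairs(stats::setNames(character(), character()))
  if (is.na(info)) return(empty)
  m <- stringr::str_match(info, "(?:^|;)CSQ=([^;]+)")[, 2]
  if (is.na(m)) return(empty)
  blocks <- stringr::str_split(m, ",")[[1]]
  fields <- lapply(blocks, function(b) {
    v <- stringr::str_split(b, "\\|")[[1]]
    length(v) <- length(csq_format)
    stats::setNames(v, csq_format)
  })
  allele_match <- vapply(fields, function(f) identical(unname(f["Allele"]), alt), logical(1))
  f <- if (any(allele_match)) fields[[which(allele_match)[1]]] else fields[[1]]
  f[is.na(f) | f == ""] <- NA_character_
  getf <- function(nm) if (nm %in% names(f)) f[[nm]] else NA_character_

  fr <- map_vep_consequence(getf("Consequence"), ref, alt)
  aa <- NA_character_
  if (!is.na(getf("Amino_acids")) && !is.na(getf("Protein_position"))) {
    aas <- stringr::str_split(getf("Amino_acids"), "/")[[1]]
    if (length(aas) == 2) {
      aa <- paste0("p.", aas[1], getf("Protein_position"), aas[2])
    }
  }
  pairs <- f[!names(f) %in% c("Allele", "Consequence", "SYMBOL", "Gene",
                              "Protein_position", "Amino_acids", "Feature")]
  row <- build_cohort_row_from_pairs(pairs[!is.na(pairs)])
  row$gene <- parse_chr(getf("SYMBOL"))
  row$func_region <- fr[1]
  row$exonic_func <- fr[2]
  row$aa_change <- aa
  row
}
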