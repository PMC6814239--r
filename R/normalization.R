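# Column-name and value normalization shared by the ANNOVAR table reader,
# the ANNOVAR-dialect VCF reader and the VEP CSQ reader. Annotated files in
# the wild spell the same annotation many ways; everything is mapped onto
# one uniform variant model and unmapped columns ride along untouched.

# Population-frequency columns -> canonical database label.
FREQ_COLUMN_MAP <- c(
  "ExAC_ALL"           = "exac",
  "ExAC_nontcga_ALL"   = "exac_nontcga",
  "gnomAD_exome_ALL"   = "gnomad_exome",
  "gnomAD_genome_ALL"  = "gnomad_genome",
  "gnomAD_AF"          = "gnomad_exome",   # VEP
  "gnomADg_AF"         = "gnomad_genome",  # VEP
  "AF"                 = "af",
  "MAX_AF"             = "max_af",
  "1000g2015aug_all"   = "thousand_genomes",
  "esp6500siv2_all"    = "esp6500",
  "Kaviar_AF"          = "kaviar"
)

# In-silico predictor columns -> canonical tool label.
PREDICTOR_COLUMN_MAP <- c(
  "SIFT_pred"               = "sift",
  "SIFT"                    = "sift",            # VEP
  "Polyphen2_HDIV_pred"     = "polyphen_hdiv",
  "Polyphen2_HVAR_pred"     = "polyphen_hvar",
  "PolyPhen"                = "polyphen_hvar",   # VEP
  "LRT_pred"                = "lrt",
  "MutationTaster_pred"     = "mutation_taster",
  "MutationAssessor_pred"   = "mutation_assessor",
  "FATHMM_pred"             = "fathmm",
  "PROVEAN_pred"            = "provean",
  "MetaSVM_pred"            = "metasvm",
  "MetaLR_pred"             = "metalr",
  "M-CAP_pred"              = "mcap",
  "fathmm-MKL_coding_pred"  = "fathmm_mkl"
)

SPLICE_COLUMNS  <- c("dbscSNV_ADA_SCORE", "dbscSNV_RF_SCORE", "ada_score", "rf_score")
REPEAT_COLUMNS  <- c("genomicSuperDups", "rmsk", "repeat_region")
HOMCOUNT_COLUMNS <- c("nhomalt", "Hom", "ExAC_Hom", "gnomAD_exome_nhomalt")
CLNSIG_COLUMNS  <- c("CLNSIG", "CLINSIG", "CLIN_SIG", "clinvar_sig")
CLNSTAT_COLUMNS <- c("CLNREVSTAT", "clinvar_status")
DOMAIN_COLUMNS  <- c("Interpro_domain", "DOMAINS")

#' Normalize one raw predictor value to a categorical call
#'
#' Maps each tool's native coding (letters for ANNOVAR dbNSFP columns,
#' worded calls for VEP) onto deleterious / tolerated / unknown.
#' @noRd
normalize_predictor_call <- function(tool, value) {
  if (is.na(value)) return("unknown")
  v <- tolower(stringr::str_remove(value, "\\(.*\\)$"))  # VEP "deleterious(0.01)"
  del <- switch(tool,
    sift              = v %in% c("d", "deleterious", "deleterious_low_confidence"),
    polyphen_hdiv     = ,
    polyphen_hvar     = v %in% c("d", "p", "probably_damaging", "possibly_damaging"),
    lrt               = v == "d",
    mutation_taster   = v %in% c("a", "d"),
    mutation_assessor = v %in% c("h", "m"),
    fathmm            = v == "d",
    provean           = v == "d",
    metasvm           = v == "d",
    metalr            = v == "d",
    mcap              = v == "d",
    fathmm_mkl        = v == "d",
    v %in% c("d", "deleterious", "damaging")
  )
  tol <- switch(tool,
    sift              = v %in% c("t", "tolerated", "tolerated_low_confidence"),
    polyphen_hdiv     = ,
    polyphen_hvar     = v %in% c("b", "benign"),
    lrt               = v == "n",
    mutation_taster   = v %in% c("n", "p"),
    mutation_assessor = v %in% c("l", "n"),
    fathmm            = v == "t",
    provean           = v == "n",
    metasvm           = v == "t",
    metalr            = v == "t",
    mcap              = v == "t",
    fathmm_mkl        = v == "n",
    v %in% c("t", "n", "b", "tolerated", "benign")
  )
  if (isTRUE(del)) "deleterious" else if (isTRUE(tol)) "tolerated" else "unknown"
}

# ANNOVAR VCF INFO values encode reserved characters; underscores stand in
# for spaces in consequence strings.
decode_annovar_info_value <- function(x) {
  x <- stringr::str_replace_all(
    x, c("\\\\x3b" = ";", "\\\\x3d" = "=", "\\\\x2c" = ",", "\\\\x20" = " ")
  )
  x
}

# Canonical consequence-class vocabulary (ANNOVAR spelling).
EXONIC_FUNC_LEVELS <- c(
  "nonsynonymous SNV", "synonymous SNV", "stopgain", "stoploss", "startloss",
  "frameshift insertion", "frameshift deletion",
  "nonframeshift insertion", "nonframeshift deletion", "unknown"
)

normalize_exonic_func <- function(x) {
  if (is.na(x)) return(NA_character_)
  v <- stringr::str_replace_all(x, "_", " ")
  if (v %in% EXONIC_FUNC_LEVELS) v else x
}

# VEP Sequence Ontology consequences -> (func_region, exonic_func).
# Ordered most to least severe; the first match in a '&'-joined list wins.
VEP_CONSEQUENCE_MAP <- list(
  splice_acceptor_variant = c("splicing", NA),
  splice_donor_variant    = c("splicing", NA),
  stop_gained             = c("exonic", "stopgain"),
  frameshift_variant      = c("exonic", "frameshift"),
  stop_lost               = c("exonic", "stoploss"),
  start_lost              = c("exonic", "startloss"),
  inframe_insertion       = c("exonic", "nonframeshift insertion"),
  inframe_deletion        = c("exonic", "nonframeshift deletion"),
  missense_variant        = c("exonic", "nonsynonymous SNV"),
  synonymous_variant      = c("exonic", "synonymous SNV"),
  `5_prime_UTR_variant`   = c("UTR5", NA),
  `3_prime_UTR_variant`   = c("UTR3", NA),
  intron_variant          = c("intronic", NA),
  upstream_gene_variant   = c("intergenic", NA),
  downstream_gene_variant = c("intergenic", NA),
  intergenic_variant      = c("intergenic", NA)
)

map_vep_consequence <- function(consequence, ref, alt) {
  if (is.na(consequence)) return(c(NA_character_, NA_character_))
  parts <- stringr::str_split(consequence, "&")[[1]]
  for (term in names(VEP_CONSEQUENCE_MAP)) {
    if (term %in% parts) {
      out <- VEP_CONSEQUENCE_MAP[[term]]
      if (identical(out[2], "frameshift")) {
        out[2] <- if (nchar(alt) > nchar(ref)) "frameshift insertion" else "frameshift deletion"
      }
      return(out)
    }
  }
  c("exonic", "unknown")
}
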