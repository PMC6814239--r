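#' Read an ANNOVAR-annotated variant table
#'
#' Reads a "multianno"-style tab- or comma-separated table into a cohort
#' tibble. Column names are matched against the known ANNOVAR dialect
#' spellings (frequency databases, dbNSFP predictor columns, ClinVar
#' columns, ...); anything unrecognized is preserved as a passthrough
#' column. Columns whose values look like diploid VCF genotypes (`0/1`,
#' `1|1`, ...) are taken as per-sample genotype columns.
#'
#' @param path Path to the annotated table.
#' @param delimiter Field delimiter; defaults to `","` for `.csv` files and
#'   `"\t"` otherwise.
#' @return An `acmg_cohort` tibble (see [as_cohort()]).
#' @export
#' @examples
#' fx <- generate_cohort(dir = tempfile("fx"))
#' coh <- read_annovar_table(fx$paths$annovar_tsv)
#' dplyr::count(coh, exonic_func)
read_annovar_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read annotated table: ", path),
                 class = "acmgscore_input_error")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  coord_map <- c(chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt")
  missing_cols <- coord_map[!coord_map %in% names(raw)]
  if (length(missing_cols)) {
    rlang::abort(paste0("no recognizable coordinate columns; missing: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "acmgscore_format_error")
  }
  build_cohort_from_columns(raw, coord_map)
}

# Shared between the table reader and the ANNOVAR-dialect VCF reader:
# takes a character data frame with ANNOVAR-style column names plus
# genotype columns, returns the canonical cohort.
build_cohort_from_columns <- function(raw, coord_map) {
  n <- nrow(raw)
  pick1 <- function(candidates) {
    hit <- intersect(candidates, names(raw))
    if (length(hit)) parse_chr(raw[[hit[1]]]) else rep(NA_character_, n)
  }
  pick_prefixed <- function(prefix) {
    hit <- grep(paste0("^", prefix, "\\."), names(raw), value = TRUE)
    if (length(hit)) parse_chr(raw[[hit[1]]]) else rep(NA_character_, n)
  }

  out <- tibble::tibble(
    chrom = parse_chr(raw[[coord_map[["chrom"]]]]),
    pos   = as.integer(parse_num(raw[[coord_map[["pos"]]]])),
    ref   = parse_chr(raw[[coord_map[["ref"]]]]),
    alt   = parse_chr(raw[[coord_map[["alt"]]]])
  )
  out$gene        <- pick_prefixed("Gene")
  out$func_region <- pick_prefixed("Func")
  out$exonic_func <- vapply(pick_prefixed("ExonicFunc"), normalize_exonic_func,
                            character(1), USE.NAMES = FALSE)
  aa_raw          <- pick_prefixed("AAChange")
  out$aa_change   <- vapply(aa_raw, extract_p_notation, character(1), USE.NAMES = FALSE)
  out$clinvar_sig    <- pick1(CLNSIG_COLUMNS)
  out$clinvar_status <- pick1(CLNSTAT_COLUMNS)
  out$domain_annotation <- pick1(DOMAIN_COLUMNS)

  rep_cols <- intersect(REPEAT_COLUMNS, names(raw))
  out$repeat_region <- if (length(rep_cols)) {
    present <- Reduce(`|`, lapply(rep_cols, function(cl) !is_absent(raw[[cl]])))
    hit <- Reduce(`|`, lapply(rep_cols, function(cl) !is_absent(raw[[cl]]) &
                                !tolower(as.character(raw[[cl]])) %in% c("false", "0")))
    ifelse(present, hit, NA)
  } else rep(NA, n)

  spl_cols <- intersect(SPLICE_COLUMNS, names(raw))
  out$splice_pred <- if (length(spl_cols)) {
    mat <- vapply(spl_cols, function(cl) parse_num(raw[[cl]]), numeric(n))
    mat <- matrix(mat, nrow = n)
    apply(mat, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  } else rep(NA_real_, n)

  hom_cols <- intersect(HOMCOUNT_COLUMNS, names(raw))
  out$hom_count <- if (length(hom_cols)) parse_num(raw[[hom_cols[1]]]) else rep(NA_real_, n)

  freq_cols <- intersect(names(FREQ_COLUMN_MAP), names(raw))
  freq_vals <- lapply(freq_cols, function(cl) parse_num(raw[[cl]]))
  out$pop_freqs <- lapply(seq_len(max(n, 0)), function(i) {
    v <- vapply(freq_vals, `[[`, numeric(1), i)
    names(v) <- unname(FREQ_COLUMN_MAP[freq_cols])
    v[!is.na(v)]
  })

  pred_cols <- intersect(names(PREDICTOR_COLUMN_MAP), names(raw))
  pred_vals <- lapply(pred_cols, function(cl) parse_chr(raw[[cl]]))
  out$predictor_calls <- lapply(seq_len(max(n, 0)), function(i) {
    tools <- unname(PREDICTOR_COLUMN_MAP[pred_cols])
    v <- vapply(seq_along(pred_cols), function(j) {
      normalize_predictor_call(tools[j], pred_vals[[j]][i])
    }, character(1))
    names(v) <- tools
    v[v != "unknown" | FALSE]
  })

  # Genotype columns: unrecognized columns whose non-missing values are all
  # diploid GT strings.
  recognized <- unique(c(unname(coord_map), "End",
                         grep("^(Gene|Func|ExonicFunc|AAChange)\\.", names(raw), value = TRUE),
                         CLNSIG_COLUMNS, CLNSTAT_COLUMNS, DOMAIN_COLUMNS,
                         REPEAT_COLUMNS, SPLICE_COLUMNS, HOMCOUNT_COLUMNS,
                         names(FREQ_COLUMN_MAP), names(PREDICTOR_COLUMN_MAP)))
  rest <- setdiff(names(raw), recognized)
  gt_rx <- "^[0-9.][/|][0-9.](:.*)?$"
  is_gt_col <- vapply(rest, function(cl) {
    vals <- as.character(raw[[cl]])
    keep <- !is_absent(vals)
    any(grepl(gt_rx, vals)) && all(grepl(gt_rx, vals[keep]))
  }, logical(1))
  sample_cols <- rest[is_gt_col]
  passthrough <- rest[!is_gt_col]

  out$genotypes <- lapply(seq_len(max(n, 0)), function(i) {
    g <- vapply(sample_cols, function(cl) as.character(raw[[cl]][i]), character(1))
    stats::setNames(decode_genotype(g, 1L), sample_cols)
  })
  for (cl in passthrough) out[[cl]] <- parse_chr(raw[[cl]])

  as_cohort(out, samples = sample_cols)
}
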