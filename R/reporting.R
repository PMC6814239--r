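# Cohort reports: the main classified table, filtered views, the
# by-sample ranking and the by-gene burden score.

#' Flatten a classification result into the main report table
#'
#' Columns are ordered coordinates, gene, criteria, categorical class,
#' posterior, enrichment fields, then passthrough annotations; rows are
#' sorted deterministically by (chrom, pos, ref, alt).
#'
#' @param result An `acmg_result` from [classify_cohort()].
#' @return A plain tibble.
#' @export
report_table <- function(result) {
  x <- tibble::as_tibble(result)
  x$criteria <- vapply(x$criteria, paste, character(1), collapse = ";")
  x$evidence <- vapply(x$evidence, function(e) {
    paste(sprintf("%s:%s", names(e), unname(e)), collapse = " | ")
  }, character(1))
  if ("de_novo_trios" %in% names(x)) {
    x$de_novo_trios <- vapply(x$de_novo_trios, paste, character(1), collapse = ";")
  }
  x$n_carriers <- vapply(x$genotypes, function(g) sum(g %in% c("het", "hom_alt")),
                         integer(1))
  x$carrier_samples <- vapply(x$genotypes, function(g) {
    paste(names(g)[g %in% c("het", "hom_alt")], collapse = ";")
  }, character(1))
  x$genotypes <- NULL
  x$pop_freqs <- vapply(result$pop_freqs, function(f) {
    paste(sprintf("%s=%g", names(f), unname(f)), collapse = ";")
  }, character(1))
  x$predictor_calls <- vapply(result$predictor_calls, function(p) {
    paste(sprintf("%s=%s", names(p), unname(p)), collapse = ";")
  }, character(1))
  front <- intersect(c("chrom", "pos", "ref", "alt", "gene", "criteria",
                       "acmg_class", "posterior", "odds_path", "prob_verdict",
                       "cohort_carriers", "cohort_noncarriers", "control_n",
                       "control_N", "odds_ratio", "p_value", "ps4",
                       "de_novo", "de_novo_trios", "n_carriers",
                       "carrier_samples"),
                     names(x))
  x <- dplyr::relocate(x, dplyr::all_of(front))
  dplyr::arrange(x, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Write a report (or a set of report sheets)
#'
#' `tsv` and `csv` write a single delimited file. `sheets` writes a
#' workbook-style directory with one TSV per named table.
#'
#' @param x A tibble, an `acmg_result`, or (for `format = "sheets"`) a
#'   named list of tibbles.
#' @param path Output file (or directory for `sheets`).
#' @param format One of `"tsv"`, `"csv"`, `"sheets"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "csv", "sheets")) {
  format <- match.arg(format)
  as_table <- function(t) {
    t <- if (inherits(t, "acmg_result")) report_table(t) else tibble::as_tibble(t)
    if (all(c("chrom", "pos", "ref", "alt") %in% names(t))) {
      t <- dplyr::arrange(t, .data$chrom, .data$pos, .data$ref, .data$alt)
    }
    t
  }
  if (format == "sheets") {
    if (!is.list(x) || is.data.frame(x)) x <- list(main = x)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(x)) {
      readr::write_tsv(as_table(x[[nm]]), file.path(path, paste0(nm, ".tsv")), na = ".")
    }
    return(invisible(path))
  }
  tab <- as_table(x)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  tryCatch(writer(tab, path, na = "."),
           error = function(e) {
             rlang::abort(paste0("cannot write report to ", path, ": ",
                                 conditionMessage(e)),
                          class = "acmgscore_io_error")
           })
  invisible(path)
}

#' Gene burden score per gene
#'
#' For each gene, sums posterior probability x carrier count over the
#' gene's variants whose posterior exceeds the burden floor (a variant at
#' exactly the floor is excluded). Genes with no qualifying variant are
#' absent. Advisory warnings never alter the score: `flags_gene` for
#' frequently mutated exome genes, `long_gene` when the coding length
#' exceeds the configured cut-off, `excess_carriers` when any counted
#' variant is carried by more than `carrier_warn_fraction` of samples
#' (typical of poorly mapped or pseudoautosomal regions).
#'
#' @param result An `acmg_result`.
#' @param tables Reference tables (FLAGS list, gene lengths).
#' @param config Thresholds, see [acmg_config()].
#' @return Tibble with `gene`, `burden`, `n_variants_counted`, `warnings`
#'   (semicolon-joined), sorted by descending burden.
#' @export
gene_burden <- function(result, tables = reference_tables(),
                        config = attr(result, "config") %||% acmg_config()) {
  n_samples <- length(cohort_samples(result))
  df <- tibble::tibble(
    gene = result$gene,
    posterior = result$posterior,
    carriers = vapply(result$genotypes, function(g) sum(g %in% c("het", "hom_alt")),
                      integer(1))
  )
  df <- dplyr::filter(df, !is.na(.data$gene), .data$posterior > config$burden_floor)
  if (!nrow(df)) {
    return(tibble::tibble(gene = character(), burden = double(),
                          n_variants_counted = integer(), warnings = character()))
  }
  out <- df |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      burden = sum(.data$posterior * .data$carriers),
      n_variants_counted = dplyr::n(),
      max_carrier_fraction = if (n_samples > 0) max(.data$carriers) / n_samples else 0,
      .groups = "drop"
    )
  lengths_tbl <- tables$gene_lengths
  out$warnings <- vapply(seq_len(nrow(out)), function(i) {
    w <- character()
    g <- out$gene[i]
    if (g %in% tables$flags) w <- c(w, "flags_gene")
    kb <- lengths_tbl$coding_kb[match(g, lengths_tbl$gene)]
    if (!is.na(kb) && kb > config$long_gene_kb) w <- c(w, "long_gene")
    if (out$max_carrier_fraction[i] > config$carrier_warn_fraction) {
      w <- c(w, "excess_carriers")
    }
    paste(w, collapse = ";")
  }, character(1))
  out$max_carrier_fraction <- NULL
  dplyr::arrange(out, dplyr::desc(.data$burden), .data$gene)
}

#' Per-sample ranked report
#'
#' For every sample, the variants that sample carries, ranked by
#' descending posterior (ties broken by chrom then pos) and truncated to
#' `top_k`. By default only variants at or above the pathogenic threshold
#' are kept. Samples with no qualifying variant are still listed with an
#' empty variant table.
#'
#' @param result An `acmg_result`.
#' @param top_k Maximum variants per sample (default `Inf`).
#' @param min_posterior Minimum posterior to include; defaults to the
#'   result's pathogenic threshold.
#' @return A nested tibble: `sample`, `n_variants`, `variants` (list of
#'   tibbles).
#' @export
by_sample_report <- function(result, top_k = Inf, min_posterior = NULL) {
  th <- attr(result, "thresholds") %||% prob_thresholds()
  if (is.null(min_posterior)) min_posterior <- th$pathogenic
  samples <- cohort_samples(result)
  base <- tidy(result)
  per_sample <- purrr::map(samples, function(s) {
    carries <- vapply(result$genotypes, function(g) {
      g[[s]] %in% c("het", "hom_alt")
    }, logical(1))
    rows <- base[carries & base$posterior >= min_posterior, ]
    rows <- dplyr::arrange(rows, dplyr::desc(.data$posterior), .data$chrom, .data$pos)
    utils::head(rows, n = top_k)
  })
  tibble::tibble(sample = samples,
                 n_variants = vapply(per_sample, nrow, integer(1)),
                 variants = per_sample)
}

#' Filter a report to a gene list
#'
#' @param report A report tibble with a `gene` column.
#' @param genes Character vector of gene symbols or the path of a text
#'   file with one symbol per line. Matching is case-insensitive. An empty
#'   gene list is an error (distinct from no matches, which yields a
#'   header-only report).
#' @return The matching rows, same columns as the input.
#' @export
filter_by_genes <- function(report, genes) {
  if (length(genes) == 1 && !is.null(genes) && file.exists(genes)) {
    genes <- readr::read_lines(genes, progress = FALSE)
    genes <- trimws(genes)
    genes <- genes[nzchar(genes)]
  }
  if (!length(genes)) {
    rlang::abort("empty gene list", class = "acmgscore_input_error")
  }
  dplyr::filter(report, toupper(.data$gene) %in% toupper(genes))
}

#' Filter a report to the genes of a named pathway
#'
#' Uses the bundled offline pathway snapshot; an unknown pathway name is an
#' error listing near matches.
#'
#' @param report A report tibble with a `gene` column.
#' @param pathway_name Pathway name, matched case-insensitively.
#' @param pathway_table Tibble `pathway`, `gene`; defaults to the bundled
#'   snapshot.
#' @return The matching rows.
#' @export
filter_by_pathway <- function(report, pathway_name,
                              pathway_table = reference_tables()$pathways) {
  known <- unique(pathway_table$pathway)
  hit <- known[tolower(known) == tolower(pathway_name)]
  if (!length(hit)) {
    near <- utils::head(known[order(utils::adist(tolower(pathway_name), tolower(known)))], 3)
    rlang::abort(paste0("unknown pathway '", pathway_name, "'; did you mean: ",
                        paste(near, collapse = ", "), "?"),
                 class = "acmgscore_input_error")
  }
  filter_by_genes(report, pathway_table$gene[pathway_table$pathway == hit[1]])
}

#' Filter a report by a free-text gene-description term
#'
#' Keeps rows whose gene description contains the term
#' (case-insensitive substring, e.g. "autosomal dominant").
#'
#' @param report A report tibble with a `gene` column.
#' @param term Non-empty search term.
#' @param gene_descriptions Tibble `gene`, `description`; defaults to the
#'   bundled table.
#' @return The matching rows.
#' @export
filter_by_disease_term <- function(report, term,
                                   gene_descriptions = reference_tables()$gene_descriptions) {
  if (is.null(term) || !nzchar(trimws(term))) {
    rlang::abort("empty search term", class = "acmgscore_input_error")
  }
  hits <- gene_descriptions$gene[
    stringr::str_detect(tolower(gene_descriptions$description),
                        stringr::fixed(tolower(term)))]
  dplyr::filter(report, toupper(.data$gene) %in% toupper(hits))
}

#' Pathway enrichment of pathogenic genes via the EnrichR web service
#'
#' Submits the genes carrying variants above the pathogenic threshold and
#' returns the service's ranked term table. Purely optional: a network
#' failure produces a warning and `NULL`, never an error. The HTTP layer
#' is injectable (`fetch`) so the interface is testable offline.
#'
#' @param genes Character vector of gene symbols.
#' @param library Enrichment library name (default
#'   `"GO_Biological_Process_2018"`).
#' @param fetch Function `(genes, library) -> data.frame`; defaults to the
#'   EnrichR REST client (requires network and jsonlite).
#' @return A tibble of ranked terms, or `NULL` when skipped.
#' @export
pathway_enrichment <- function(genes, library = "GO_Biological_Process_2018",
                               fetch = NULL) {
  genes <- unique(genes[!is.na(genes)])
  if (!length(genes)) {
    rlang::warn("no pathogenic genes; pathway enrichment skipped")
    return(NULL)
  }
  if (is.null(fetch)) fetch <- enrichr_fetch
  out <- tryCatch(fetch(genes, library), error = function(e) {
    rlang::warn(paste0("pathway enrichment unavailable: ", conditionMessage(e)))
    NULL
  })
  if (is.null(out)) return(NULL)
  tibble::as_tibble(out)
}

# Minimal EnrichR REST client (addList then enrich). Network-only path,
# exercised in tests exclusively through the `fetch` injection point.
enrichr_fetch <- function(genes, library) {
  if (!requireNamespace("httr", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the EnrichR client needs the httr and jsonlite packages")
  }
  base <- "https://maayanlab.cloud/Enrichr"
  added <- httr::POST(paste0(base, "/addList"),
                      body = list(list = paste(genes, collapse = "\n"),
                                  description = "acmgscore gene list"))
  httr::stop_for_status(added)
  user_list <- jsonlite::fromJSON(httr::content(added, as = "text",
                                                encoding = "UTF-8"))$userListId
  res <- httr::GET(paste0(base, "/enrich"),
                   query = list(userListId = user_list, backgroundType = library))
  httr::stop_for_status(res)
  terms <- jsonlite::fromJSON(httr::content(res, as = "text",
                                            encoding = "UTF-8"))[[library]]
  if (!length(terms)) return(tibble::tibble())
  tibble::tibble(
    rank = vapply(terms, function(t) as.numeric(t[[1]]), numeric(1)),
    term = vapply(terms, function(t) as.character(t[[2]]), character(1)),
    p_value = vapply(terms, function(t) as.numeric(t[[3]]), numeric(1)),
    z_score = vapply(terms, function(t) as.numeric(t[[4]]), numeric(1)),
    combined_score = vapply(terms, function(t) as.numeric(t[[5]]), numeric(1)),
    genes = vapply(terms, function(t) paste(unlist(t[[6]]), collapse = ";"),
                   character(1)),
    adjusted_p_value = vapply(terms, function(t) as.numeric(t[[7]]), numeric(1))
  )
}

#' Bar chart of the top gene-burden entries
#'
#' @param burden Tibble from [gene_burden()].
#' @param top_n Number of genes to show (default 15).
#' @return A ggplot object.
#' @export
plot_gene_burden <- function(burden, top_n = 15) {
  df <- utils::head(burden, top_n)
  df$flagged <- nzchar(df$warnings)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$burden),
                                   y = .data$burden, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene burden score", fill = "warning") +
    ggplot2::theme_minimal()
}
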