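#' Load the bundled reference tables used by criteria assignment
#'
#' All tables are plain text and user-replaceable; an empty or absent table
#' simply means the criteria that need it never fire.
#'
#' * `lof_intolerant` — genes where loss of function is an established
#'   disease mechanism (feeds PVS1); one symbol per line.
#' * `missense_constrained` — genes with low benign missense variation
#'   (PP2).
#' * `truncating_mechanism` — genes where truncation, not missense, causes
#'   disease (BP1).
#' * `pathogenic_aa` — known pathogenic residue substitutions, TSV with
#'   columns `gene`, `protein_pos`, `ref_aa`, `alt_aa` (PS1/PM5). The
#'   bundled copy is a small curated example set.
#' * `benign_domains` — protein domains without established pathogenic
#'   variation (suppresses PM1).
#' * `flags` — frequently mutated genes in public exomes (burden warning).
#' * `pathways` — offline pathway-to-gene snapshot, TSV `pathway`, `gene`.
#' * `gene_descriptions` — TSV `gene`, `description` for term filtering.
#' * `gene_lengths` — TSV `gene`, `coding_kb` for the long-gene warning.
#'
#' @param dir Directory holding the table files; defaults to the copies
#'   shipped with the package.
#' @return A named list of character vectors and tibbles.
#' @export
reference_tables <- function(dir = system.file("extdata", package = "acmgscore")) {
  read_lines_tbl <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(character())
    x <- readr::read_lines(p, progress = FALSE)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  read_tsv_tbl <- function(f, types) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, col_types = types, progress = FALSE, comment = "#")
  }
  list(
    lof_intolerant       = read_lines_tbl("lof_intolerant_genes.txt"),
    missense_constrained = read_lines_tbl("missense_constrained_genes.txt"),
    truncating_mechanism = read_lines_tbl("truncating_mechanism_genes.txt"),
    benign_domains       = read_lines_tbl("benign_domains.txt"),
    flags                = read_lines_tbl("flags_genes.txt"),
    pathogenic_aa        = read_tsv_tbl("pathogenic_aa_changes.tsv", "cicc") %||%
      tibble::tibble(gene = character(), protein_pos = integer(),
                     ref_aa = character(), alt_aa = character()),
    pathways             = read_tsv_tbl("pathways.tsv", "cc") %||%
      tibble::tibble(pathway = character(), gene = character()),
    gene_descriptions    = read_tsv_tbl("gene_descriptions.tsv", "cc") %||%
      tibble::tibble(gene = character(), description = character()),
    gene_lengths         = read_tsv_tbl("gene_lengths.tsv", "cd") %||%
      tibble::tibble(gene = character(), coding_kb = double())
  )
}

#' Criteria-assignment thresholds
#'
#' Every cut-off used by the criteria predicates and the PS4 enrichment
#' gates, overridable per call.
#'
#' @param rare_threshold PM2 rarity cut-off on every population frequency
#'   (default 1e-4).
#' @param ba1_threshold Stand-alone benign frequency (default 0.05).
#' @param bs1_threshold BS1 frequency cut-off (default 0.01).
#' @param bs2_hom_count BS2 fires when the reported homozygote count
#'   exceeds this (default 0).
#' @param pp3_fraction,bp4_fraction Minimum fraction of available in-silico
#'   predictors calling deleterious (PP3) / tolerated (BP4); default 0.5.
#' @param min_predictors Predictors with a usable call required before
#'   PP3/BP4 are considered (default 2).
#' @param splice_threshold Splice-impact score below which a synonymous
#'   variant earns BP7 (default 0.6, the dbscSNV convention).
#' @param ps4_or,ps4_p,ps4_min_carriers PS4 gates: odds ratio >= 20,
#'   one-sided Fisher p <= 0.001, and at least 2 cohort carriers.
#' @param default_control_individuals Control cohort size assumed when a
#'   variant is absent from the chosen frequency database (default 50000);
#'   absence is treated as one minimally observed carrier.
#' @param burden_floor Posterior probability a variant must exceed to count
#'   toward the gene burden (default 0.80; a variant at exactly the floor
#'   is excluded).
#' @param carrier_warn_fraction Carrier fraction above which a burden entry
#'   is flagged as a possible mapping artifact (default 0.9).
#' @param long_gene_kb Coding length (kb) above which the long-gene burden
#'   warning is raised (default 15).
#' @param ... Ignored; forces full argument names.
#' @return Named list of thresholds.
#' @export
acmg_config <- function(rare_threshold = 1e-4,
                        ba1_threshold = 0.05,
                        bs1_threshold = 0.01,
                        bs2_hom_count = 0,
                        pp3_fraction = 0.5,
                        bp4_fraction = 0.5,
                        min_predictors = 2,
                        splice_threshold = 0.6,
                        ps4_or = 20,
                        ps4_p = 0.001,
                        ps4_min_carriers = 2,
                        default_control_individuals = 50000,
                        burden_floor = 0.80,
                        carrier_warn_fraction = 0.9,
                        long_gene_kb = 15,
                        ...) {
  list(rare_threshold = rare_threshold, ba1_threshold = ba1_threshold,
       bs1_threshold = bs1_threshold, bs2_hom_count = bs2_hom_count,
       pp3_fraction = pp3_fraction, bp4_fraction = bp4_fraction,
       min_predictors = min_predictors, splice_threshold = splice_threshold,
       ps4_or = ps4_or, ps4_p = ps4_p, ps4_min_carriers = ps4_min_carriers,
       default_control_individuals = default_control_individuals,
       burden_floor = burden_floor,
       carrier_warn_fraction = carrier_warn_fraction,
       long_gene_kb = long_gene_kb)
}
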