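#' Classify an annotated cohort end to end
#'
#' The full engine: optional trio handling (PS2 assignment on the complete
#' sample set, then removal of healthy parents), criteria assignment,
#' cohort-enrichment PS4 testing, and conversion of each criteria set into
#' the categorical ACMG class plus the Bayesian posterior probability of
#' pathogenicity.
#'
#' @param cohort A cohort tibble from [read_annovar_table()],
#'   [read_annotated_vcf()] or [as_cohort()].
#' @param tables Reference tables, see [reference_tables()].
#' @param config Thresholds, see [acmg_config()].
#' @param params Bayesian model parameters, see [model_params()].
#' @param thresholds Posterior decision thresholds, see
#'   [prob_thresholds()].
#' @param pedigree Optional pedigree tibble (see [read_pedigree()]).
#' @param control_db Control frequency database label for PS4; `NULL`
#'   disables enrichment testing.
#' @return An `acmg_result` tibble: the cohort plus `criteria`,
#'   `evidence`, enrichment columns, `acmg_class`, `posterior`,
#'   `odds_path`, `prob_verdict` (and de novo columns when a pedigree was
#'   given).
#' @export
#' @examples
#' fx <- generate_cohort(dir = tempfile("fx"))
#' res <- classify_cohort(fx$cohort, pedigree = fx$pedigree)
#' dplyr::select(tidy(res), gene, acmg_class, posterior)
classify_cohort <- function(cohort,
                            tables = reference_tables(),
                            config = acmg_config(),
                            params = model_params(),
                            thresholds = prob_thresholds(),
                            pedigree = NULL,
                            control_db = "gnomad_exome") {
  cohort <- assign_criteria(cohort, tables, config)
  if (!is.null(pedigree)) {
    cohort <- detect_de_novo(cohort, pedigree)
    cohort <- strip_healthy_parents(cohort, pedigree)
  }
  if (!is.null(control_db) && length(cohort_samples(cohort)) >= 2) {
    cohort <- assign_ps4(cohort, control_db, config)
  }
  cls <- purrr::map(cohort$criteria, classify_criteria,
                    params = params, thresholds = thresholds)
  cohort$acmg_class   <- purrr::map_chr(cls, "category")
  cohort$posterior    <- purrr::map_dbl(cls, "posterior")
  cohort$odds_path    <- purrr::map_dbl(cls, "odds_path")
  cohort$prob_verdict <- purrr::map_chr(cls, "prob_verdict")
  structure(cohort,
            samples = cohort_samples(cohort),
            params = params, thresholds = thresholds, config = config,
            class = unique(c("acmg_result", class(cohort))))
}

#' @rdname classify_cohort
#' @param x An `acmg_result`.
#' @param ... Unused.
#' @method tidy acmg_result
#' @export
tidy.acmg_result <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt, gene = x$gene,
    criteria = vapply(x$criteria, paste, character(1), collapse = ";"),
    acmg_class = x$acmg_class, posterior = x$posterior,
    prob_verdict = x$prob_verdict,
    n_carriers = vapply(x$genotypes, function(g) {
      sum(g %in% c("het", "hom_alt"))
    }, integer(1))
  )
}

#' @rdname classify_cohort
#' @method glance acmg_result
#' @export
glance.acmg_result <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_samples = length(cohort_samples(x)),
    n_pathogenic = sum(x$acmg_class == "pathogenic"),
    n_likely_pathogenic = sum(x$acmg_class == "likely_pathogenic"),
    n_vus = sum(x$acmg_class == "VUS"),
    n_likely_benign = sum(x$acmg_class == "likely_benign"),
    n_benign = sum(x$acmg_class == "benign"),
    n_ps4 = if ("ps4" %in% names(x)) sum(x$ps4) else 0L,
    n_de_novo = if ("de_novo" %in% names(x)) sum(x$de_novo) else 0L,
    mean_posterior = mean(x$posterior)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Posterior-probability overview plot
#'
#' Histogram of per-variant posterior probabilities coloured by categorical
#' class, with the decision thresholds marked.
#'
#' @param object An `acmg_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acmg_result
#' @export
autoplot.acmg_result <- function(object, ...) {
  th <- attr(object, "thresholds") %||% prob_thresholds()
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior, fill = .data$acmg_class)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(th$benign, th$pathogenic),
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "posterior probability of pathogenicity",
                  y = "variants", fill = "ACMG class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.acmg_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "# ACMG classification: %d variants, %d samples (P %d / LP %d / VUS %d / LB %d / B %d)\n",
    g$n_variants, g$n_samples, g$n_pathogenic, g$n_likely_pathogenic,
    g$n_vus, g$n_likely_benign, g$n_benign))
  NextMethod()
}
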