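# Control-free case-enrichment testing (PS4). A public-database minor
# allele frequency is extrapolated to integer control counts, deliberately
# overestimating the control carrier frequency, and each variant's cohort
# carrier frequency is tested against them with a one-sided Fisher's exact
# test.

#' Extrapolate integer control counts from a control allele frequency
#'
#' The control MAF is normalized in decimal scientific notation,
#' `MAF = y x 10^-x` with `1 <= y < 10`; the number of affected control
#' individuals is `n_c = ceiling(y)` and the unaffected count is
#' `N_c = 10^x / 2 - n_c` (individuals, assuming rare variants are mostly
#' heterozygous). Rounding the mantissa *up* overstates the control carrier
#' frequency, which makes the downstream enrichment test conservative.
#' Normalization works on the printed decimal representation, so e.g.
#' `3.23e-5` yields exactly `y = 3.23`, `x = 5`.
#'
#' @param maf Control minor allele frequency; must lie in (0, 0.05). Above
#'   0.05 the heterozygosity assumption fails (such variants meet BA1/BS1
#'   instead) and a domain error is raised.
#' @return A `control_counts` list: `maf`, `y`, `x`, `n_c`, `N_c`.
#' @export
#' @examples
#' maf_to_counts(3.23e-5)  # n_c = 4, N_c = 49996
maf_to_counts <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) ||
      maf <= 0 || maf >= 0.05) {
    rlang::abort("control MAF must lie strictly between 0 and 0.05",
                 class = "acmgscore_domain_error")
  }
  # Decimal (not binary) normalization so printed mantissas are exact.
  sci <- formatC(maf, format = "e", digits = 12)
  parts <- stringr::str_split(sci, "e")[[1]]
  y <- round(as.numeric(parts[1]), 9)
  x <- -as.integer(parts[2])
  if (y >= 10) { y <- y / 10; x <- x - 1 }  # defensive; formatC normalizes
  n_c <- as.integer(ceiling(y))
  N_c <- 10^x / 2 - n_c
  structure(list(maf = maf, y = y, x = x, n_c = n_c, N_c = N_c),
            class = "control_counts")
}

#' Count cohort carriers and non-carriers of a variant
#'
#' Carriers are samples with a het or hom_alt genotype; non-carriers are
#' hom_ref; missing genotypes are excluded from both.
#'
#' @param genotypes Named character vector of genotype states for one
#'   variant (see [decode_genotype()]).
#' @return List with `carriers` and `noncarriers`.
#' @export
cohort_carrier_counts <- function(genotypes) {
  list(carriers = sum(genotypes %in% c("het", "hom_alt")),
       noncarriers = sum(genotypes == "hom_ref"))
}

#' One-sided Fisher's exact test for cohort enrichment
#'
#' Tests the 2x2 table `[a carriers, b non-carriers; c control affected,
#' d control unaffected]` for enrichment in the cohort row. The p-value is
#' the exact upper hypergeometric tail (probability of a table at least as
#' enriched in the cohort); the odds ratio is the plain cross-product ratio
#' `(a d)/(b c)`, reported as `Inf` when `b c = 0` with `a d > 0`.
#' Degenerate margins give `p = 1` and an odds ratio of 0, which can never
#' satisfy the PS4 gates.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(odds_ratio = 0, p_value = 1))
  }
  p <- stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else 0
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p)
}

#' Test one variant for cohort enrichment and decide PS4
#'
#' Composes [maf_to_counts()], [cohort_carrier_counts()] and
#' [fisher_one_sided()]. PS4 is granted only when the odds ratio, the
#' p-value and the minimum-carrier gates all pass. A variant absent from
#' the chosen control database is treated as minimally observed there
#' (1 affected among `default_control_individuals`); a control frequency
#' at or above 0.05 leaves PS4 unevaluated.
#'
#' @param genotypes Named genotype-state vector for the variant.
#' @param control_maf Control-database allele frequency, or `NA` if the
#'   variant is absent from the database.
#' @param config Thresholds, see [acmg_config()].
#' @return An `enrichment_result` list: `cohort_carriers`,
#'   `cohort_noncarriers`, `control_n`, `control_N`, `odds_ratio`,
#'   `p_value`, `ps4`, `note`.
#' @export
enrichment_test <- function(genotypes, control_maf = NA_real_,
                            config = acmg_config()) {
  cc <- cohort_carrier_counts(genotypes)
  n_samples <- length(genotypes)
  if (n_samples < 2) {
    return(structure(list(cohort_carriers = cc$carriers,
                          cohort_noncarriers = cc$noncarriers,
                          control_n = NA_real_, control_N = NA_real_,
                          odds_ratio = NA_real_, p_value = NA_real_,
                          ps4 = FALSE, note = "single-sample cohort; PS4 skipped"),
                     class = "enrichment_result"))
  }
  if (!is.na(control_maf) && (control_maf <= 0 || control_maf >= 0.05)) {
    return(structure(list(cohort_carriers = cc$carriers,
                          cohort_noncarriers = cc$noncarriers,
                          control_n = NA_real_, control_N = NA_real_,
                          odds_ratio = NA_real_, p_value = NA_real_,
                          ps4 = FALSE,
                          note = "control MAF outside (0, 0.05); PS4 not evaluated"),
                     class = "enrichment_result"))
  }
  if (is.na(control_maf)) {
    n_c <- 1L
    N_c <- config$default_control_individuals - 1L
    note <- "absent from control database; treated as minimally observed"
  } else {
    ctl <- maf_to_counts(control_maf)
    n_c <- ctl$n_c
    N_c <- ctl$N_c
    note <- sprintf("control MAF %.4g extrapolated to %d/%d individuals",
                    control_maf, n_c, as.integer(n_c + N_c))
  }
  ft <- fisher_one_sided(cc$carriers, cc$noncarriers, n_c, N_c)
  ps4 <- ft$odds_ratio >= config$ps4_or &&
    ft$p_value <= config$ps4_p &&
    cc$carriers >= config$ps4_min_carriers
  structure(list(cohort_carriers = cc$carriers,
                 cohort_noncarriers = cc$noncarriers,
                 control_n = n_c, control_N = N_c,
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 ps4 = ps4, note = note),
            class = "enrichment_result")
}

#' Assign PS4 across a cohort
#'
#' Runs [enrichment_test()] on every variant against the selected control
#' frequency database and appends PS4 to the criteria of qualifying
#' variants (never next to BA1). Adds the enrichment columns
#' `cohort_carriers`, `cohort_noncarriers`, `control_n`, `control_N`,
#' `odds_ratio`, `p_value`, `ps4`.
#'
#' @param cohort A cohort tibble that already has a `criteria` column.
#' @param control_db Canonical label of the control frequency database
#'   (e.g. `"gnomad_exome"`, `"exac"`); see [reference_tables()] docs for
#'   the normalization map.
#' @param config Thresholds, see [acmg_config()].
#' @return The cohort with enrichment columns added and PS4 merged into
#'   `criteria`.
#' @export
assign_ps4 <- function(cohort, control_db = "gnomad_exome",
                       config = acmg_config()) {
  if (length(cohort_samples(cohort)) < 2) {
    rlang::warn("fewer than two samples; PS4 skipped for all variants")
  }
  res <- purrr::map2(cohort$genotypes, cohort$pop_freqs, function(g, f) {
    maf <- if (control_db %in% names(f)) unname(f[[control_db]]) else NA_real_
    enrichment_test(g, maf, config)
  })
  cohort$cohort_carriers    <- purrr::map_int(res, ~ as.integer(.x$cohort_carriers))
  cohort$cohort_noncarriers <- purrr::map_int(res, ~ as.integer(.x$cohort_noncarriers))
  cohort$control_n  <- purrr::map_dbl(res, "control_n")
  cohort$control_N  <- purrr::map_dbl(res, "control_N")
  cohort$odds_ratio <- purrr::map_dbl(res, "odds_ratio")
  cohort$p_value    <- purrr::map_dbl(res, "p_value")
  ps4 <- purrr::map_lgl(res, "ps4")
  if ("criteria" %in% names(cohort)) {
    hit <- which(ps4)
    cohort <- add_criterion(cohort, hit, "PS4",
                            purrr::map_chr(res[hit], function(r) {
                              sprintf("cohort %d/%d carriers vs control %g/%g (OR %.3g, p %.3g)",
                                      r$cohort_carriers,
                                      r$cohort_carriers + r$cohort_noncarriers,
                                      r$control_n, r$control_N + r$control_n,
                                      r$odds_ratio, r$p_value)
                            }))
    ps4 <- purrr::map_lgl(cohort$criteria, ~ "PS4" %in% .x)
  }
  cohort$ps4 <- ps4
  cohort
}
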