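# Shared fixture builders for the test suite. Everything is constructed in
# code; nothing is read from disk except files the tests themselves write.

# One-row (or stacked) cohort with sensible defaults, overridable per field.
make_variant <- function(...,
                         chrom = "1", pos = 100L, ref = "A", alt = "G",
                         gene = "SAMD11", func_region = "exonic",
                         exonic_func = "nonsynonymous SNV",
                         aa_change = NA_character_,
                         pop_freqs = stats::setNames(numeric(), character()),
                         predictor_calls = stats::setNames(character(), character()),
                         clinvar_sig = NA_character_,
                         clinvar_status = NA_character_,
                         domain_annotation = NA_character_,
                         repeat_region = NA, splice_pred = NA_real_,
                         hom_count = NA_real_,
                         genotypes = c(S1 = "het", S2 = "hom_ref")) {
  as_cohort(tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    func_region = func_region, exonic_func = exonic_func,
    aa_change = aa_change, clinvar_sig = clinvar_sig,
    clinvar_status = clinvar_status, domain_annotation = domain_annotation,
    repeat_region = repeat_region, splice_pred = splice_pred,
    hom_count = hom_count,
    pop_freqs = list(pop_freqs), predictor_calls = list(predictor_calls),
    genotypes = list(genotypes), ...
  ))
}

# Criteria of a single crafted variant under the bundled tables.
criteria_of <- function(..., tables = test_tables(), config = acmg_config()) {
  coh <- make_variant(...)
  assign_criteria(coh, tables, config)$criteria[[1]]
}

test_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_tables()
    cache
  }
})

# Evidence-count constructor for the Bayesian model tests.
ec <- function(pvs = 0, ps = 0, pm = 0, pp = 0, bs = 0, bp = 0, ba1 = FALSE) {
  list(n_pvs = pvs, n_ps = ps, n_pm = pm, n_pp = pp, n_bs = bs, n_bp = bp,
       ba1 = ba1)
}

# Independent brute-force one-sided Fisher p: explicit sum of hypergeometric
# table probabilities at least as enriched in the cohort row.
brute_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  amin <- max(0L, c1 - (n - r1))
  amax <- min(r1, c1)
  av <- amin:amax
  pr <- exp(lchoose(r1, av) + lchoose(n - r1, c1 - av) - lchoose(n, c1))
  sum(pr[av >= a])
}

# A minimal hand-built classification result for the reporting tests.
fake_result <- function(genes, posteriors, carrier_lists, samples,
                        thresholds = prob_thresholds(),
                        config = acmg_config()) {
  n <- length(genes)
  gts <- lapply(carrier_lists, function(carr) {
    stats::setNames(ifelse(samples %in% carr, "het", "hom_ref"), samples)
  })
  x <- tibble::tibble(
    chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
    gene = genes,
    criteria = rep(list(character()), n),
    evidence = rep(list(stats::setNames(character(), character())), n),
    acmg_class = ifelse(posteriors >= 0.8, "likely_pathogenic", "VUS"),
    posterior = posteriors,
    odds_path = 1,
    prob_verdict = ifelse(posteriors >= thresholds$pathogenic, "pathogenic",
                          ifelse(posteriors <= thresholds$benign, "benign",
                                 "unknown")),
    pop_freqs = rep(list(stats::setNames(numeric(), character())), n),
    predictor_calls = rep(list(stats::setNames(character(), character())), n),
    genotypes = gts
  )
  structure(x, samples = samples, thresholds = thresholds, config = config,
            class = c("acmg_result", "acmg_cohort", class(tibble::tibble())))
}
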