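# Gene burden, by-sample ranking, filtered reports and the mocked
# pathway-enrichment interface.

test_that("gene burden sums posterior x carriers above the floor", {
  samples <- sprintf("S%d", 1:5)
  res <- fake_result(
    genes = c("GENE1", "GENE1", "GENE2", "GENE3"),
    posteriors = c(0.9, 0.85, 0.80, 0.79),
    carrier_lists = list(c("S1", "S2", "S3"), c("S1", "S2"), "S1", "S1"),
    samples = samples)
  gb <- gene_burden(res, test_tables())
  expect_equal(gb$gene, "GENE1")
  expect_equal(gb$burden, 0.9 * 3 + 0.85 * 2)
  expect_equal(gb$n_variants_counted, 2L)
  # a variant at exactly the floor is excluded, so GENE2 and GENE3 are absent
  expect_false(any(c("GENE2", "GENE3") %in% gb$gene))
})

test_that("burden warnings flag FLAGS genes, long genes and excess carriers", {
  samples <- sprintf("S%d", 1:4)
  res <- fake_result(
    genes = c("MUC16", "TP53", "BRCA2"),
    posteriors = c(0.95, 0.9, 0.99),
    carrier_lists = list("S1", c("S1", "S2", "S3", "S4"), "S2"),
    samples = samples)
  gb <- gene_burden(res, test_tables())
  w <- stats::setNames(gb$warnings, gb$gene)
  expect_match(w[["MUC16"]], "flags_gene")
  expect_match(w[["MUC16"]], "long_gene")
  expect_match(w[["TP53"]], "excess_carriers")  # 4/4 carriers
  expect_equal(w[["BRCA2"]], "")
  # warnings are advisory: scores are untouched
  expect_equal(unname(gb$burden[gb$gene == "TP53"]), 0.9 * 4)
})

test_that("burden totals are invariant to variant order", {
  fx <- generate_cohort()
  res <- classify_cohort(fx$cohort, pedigree = fx$pedigree)
  shuffled <- res[rev(seq_len(nrow(res))), ]
  attributes(shuffled)$samples <- attr(res, "samples")
  class(shuffled) <- class(res)
  expect_equal(gene_burden(res, test_tables()),
               gene_burden(shuffled, test_tables()))
  expect_equal(gene_burden(res, test_tables())[, 1:3],
               fx$burden_truth, ignore_attr = TRUE)
})

test_that("by-sample report ranks carried variants and keeps empty samples", {
  samples <- c("S1", "S2", "S3")
  res <- fake_result(
    genes = c("G1", "G2", "G3"),
    posteriors = c(0.9, 0.95, 0.9),
    carrier_lists = list(c("S1", "S2"), "S1", "S1"),
    samples = samples)
  bs <- by_sample_report(res)
  expect_equal(bs$sample, samples)
  expect_equal(bs$n_variants, c(3L, 1L, 0L))
  # S3 carries nothing above threshold but is still listed
  expect_equal(nrow(bs$variants[[3]]), 0L)
  # descending posterior, ties broken by position
  v1 <- bs$variants[[1]]
  expect_equal(v1$gene, c("G2", "G1", "G3"))
  expect_true(all(diff(v1$posterior) <= 0))
  # every listed row is carried by its sample
  for (i in seq_along(samples)) {
    rows <- bs$variants[[i]]
    if (nrow(rows)) {
      carried <- vapply(rows$pos, function(p) {
        g <- res$genotypes[[match(p, res$pos)]]
        g[[samples[i]]] %in% c("het", "hom_alt")
      }, logical(1))
      expect_true(all(carried))
    }
  }
  # truncation
  expect_equal(by_sample_report(res, top_k = 1)$n_variants, c(1L, 1L, 0L))
})

test_that("gene-list filtering is case-insensitive and errors on empty lists", {
  rep_tab <- tibble::tibble(gene = c("BRCA2", "TP53", "RET"), x = 1:3)
  expect_equal(filter_by_genes(rep_tab, "brca2")$gene, "BRCA2")
  expect_equal(filter_by_genes(rep_tab, c("TP53", "RET"))$x, 2:3)
  expect_equal(nrow(filter_by_genes(rep_tab, "NOPE")), 0)
  expect_identical(names(filter_by_genes(rep_tab, "NOPE")), names(rep_tab))
  expect_error(filter_by_genes(rep_tab, character()),
               class = "acmgscore_input_error")
  # file input
  p <- withr::local_tempfile()
  writeLines(c("tp53", ""), p)
  expect_equal(filter_by_genes(rep_tab, p)$gene, "TP53")
})

test_that("pathway filtering resolves bundled pathways and suggests near-misses", {
  rep_tab <- tibble::tibble(gene = c("BRCA2", "TP53", "ALDH2"), x = 1:3)
  hit <- filter_by_pathway(rep_tab, "Pathways in cancer")
  expect_setequal(hit$gene, c("BRCA2", "TP53"))
  err <- expect_error(filter_by_pathway(rep_tab, "Pathways in cancerr"),
                      class = "acmgscore_input_error")
  expect_match(conditionMessage(err), "Pathways in cancer")
  # no genes in report: header-only
  empty <- filter_by_pathway(rep_tab[0, ], "Mismatch repair")
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), names(rep_tab))
})

test_that("disease-term filtering searches bundled gene descriptions", {
  rep_tab <- tibble::tibble(gene = c("BRCA2", "MLH1", "ALDH2"), x = 1:3)
  dom <- filter_by_disease_term(rep_tab, "autosomal dominant")
  expect_setequal(dom$gene, c("BRCA2", "MLH1"))
  crc <- filter_by_disease_term(rep_tab, "colorectal cancer")
  expect_equal(crc$gene, "MLH1")
  expect_equal(nrow(filter_by_disease_term(rep_tab, "zebrafish fin")), 0)
  expect_error(filter_by_disease_term(rep_tab, "  "),
               class = "acmgscore_input_error")
})

test_that("filtered reports are row subsets with identical columns", {
  fx <- generate_cohort()
  res <- classify_cohort(fx$cohort, pedigree = fx$pedigree)
  main <- report_table(res)
  for (filt in list(filter_by_genes(main, c("TP53", "BRCA2")),
                    filter_by_pathway(main, "Pathways in cancer"),
                    filter_by_disease_term(main, "autosomal dominant"))) {
    expect_identical(names(filt), names(main))
    expect_true(all(do.call(paste, filt[c("chrom", "pos", "ref", "alt")]) %in%
                      do.call(paste, main[c("chrom", "pos", "ref", "alt")])))
  }
})

test_that("pathway enrichment passes through a mocked service and skips cleanly", {
  expect_warning(out <- pathway_enrichment(character()), "skipped")
  expect_null(out)

  seen <- NULL
  mock <- function(genes, library) {
    seen <<- list(genes = genes, library = library)
    data.frame(term = "GO:0006281 DNA repair", p_value = 1e-6)
  }
  tab <- pathway_enrichment(c("BRCA2", "TP53"), fetch = mock)
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$term, "GO:0006281 DNA repair")
  expect_equal(seen$genes, c("BRCA2", "TP53"))
  # default library is the GO biological-process set
  expect_equal(seen$library, "GO_Biological_Process_2018")

  failing <- function(genes, library) stop("no network")
  expect_warning(out2 <- pathway_enrichment("TP53", fetch = failing),
                 "unavailable")
  expect_null(out2)
})
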