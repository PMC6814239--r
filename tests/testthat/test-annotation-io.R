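# Readers and writers: ANNOVAR tables, annotated VCFs (both dialects),
# genotype decoding, multi-allelic decomposition and report round-trips.

write_mini_tsv <- function(path, freq = c(".", "0.002", "."),
                           header = c("Chr", "Start", "End", "Ref", "Alt",
                                      "Func.refGene", "Gene.refGene",
                                      "ExonicFunc.refGene", "gnomAD_exome_ALL",
                                      "SampleA", "SampleB")) {
  rows <- list(
    c("1", "100", "100", "A", "G", "exonic", "TP53", "stopgain", freq[1], "0/1", "0/0"),
    c("2", "200", "200", "C", "T", "exonic", "BRCA2", "nonsynonymous SNV", freq[2], "0/0", "1/1"),
    c("3", "300", "300", "G", "A", "exonic", "RET", "synonymous SNV", freq[3], "0/1", "0/1")
  )
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

test_that("ANNOVAR tables round-trip coordinates, genotypes and sentinels", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_mini_tsv(p)
  coh <- read_annovar_table(p)
  expect_equal(nrow(coh), 3)
  expect_equal(cohort_samples(coh), c("SampleA", "SampleB"))
  expect_equal(coh$exonic_func[1], "stopgain")
  # "." sentinel maps to an absent frequency, not zero
  expect_length(coh$pop_freqs[[1]], 0)
  expect_equal(coh$pop_freqs[[2]], c(gnomad_exome = 0.002))
  expect_equal(unname(coh$genotypes[[2]]), c("hom_ref", "hom_alt"))
  expect_equal(unname(coh$genotypes[[3]]), c("het", "het"))
})

test_that("a table without coordinate columns is rejected with the missing names", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr\tStart\tGene.refGene", "1\t100\tTP53"), p)
  err <- expect_error(read_annovar_table(p), class = "acmgscore_format_error")
  expect_match(conditionMessage(err), "Ref")
  expect_match(conditionMessage(err), "Alt")
  expect_error(read_annovar_table(file.path(tempdir(), "nope.tsv")),
               class = "acmgscore_input_error")
})

test_that("csv delimiter is inferred from the extension", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Chr,Start,End,Ref,Alt,Gene.refGene", "1,5,5,A,T,TP53"), p)
  coh <- read_annovar_table(p)
  expect_equal(coh$gene, "TP53")
  expect_equal(coh$pos, 5L)
})

test_that("diploid genotype strings decode against the requested allele", {
  expect_equal(decode_genotype(c("0/1", "0/0", "1/1", "./.", "./1", "1|0")),
               c("het", "hom_ref", "hom_alt", "missing", "missing", "het"))
  # re-expressed against allele 2 of a multi-allelic record
  expect_equal(decode_genotype(c("1/2", "0/2", "2/2", "0/1"), alt_index = 2),
               c("het", "het", "hom_alt", "hom_ref"))
  # non-diploid calls are conservative
  expect_equal(decode_genotype("0/1/1"), "missing")
})

write_mini_vcf <- function(path, alt = "G", gts = c("0/1", "0/0", "1/1"),
                           info = "Func.refGene=exonic;Gene.refGene=TP53;ExonicFunc.refGene=stopgain") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", ".", "A", alt, ".", "PASS", info, "GT", gts),
          collapse = "\t")
  ), path)
  path
}

test_that("VCF genotypes identify carriers", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p)
  coh <- read_annotated_vcf(p, "annovar")
  g <- coh$genotypes[[1]]
  expect_equal(names(g)[g %in% c("het", "hom_alt")], c("s1", "s3"))
  expect_equal(coh$gene, "TP53")
  expect_equal(coh$exonic_func, "stopgain")
})

test_that("multi-allelic records decompose and conserve carriers", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p, alt = "G,T", gts = c("1/2", "0/2", "0/0"))
  coh <- read_annotated_vcf(p, "annovar")
  expect_equal(nrow(coh), 2)
  expect_equal(coh$alt, c("G", "T"))
  carriers <- lapply(coh$genotypes, function(g) names(g)[g %in% c("het", "hom_alt")])
  # union over split alleles equals carriers of the original record
  expect_setequal(unique(unlist(carriers)), c("s1", "s2"))
  # allele-specific re-expression
  expect_equal(carriers[[1]], "s1")
  expect_setequal(carriers[[2]], c("s1", "s2"))
})

test_that("non-diploid genotypes warn and become missing", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p, gts = c("0/1/1", "0/0", "0/1"))
  expect_warning(coh <- read_annotated_vcf(p, "annovar"), "non-diploid")
  expect_equal(unname(coh$genotypes[[1]]), c("missing", "hom_ref", "het"))
})

test_that("VEP dialect requires the CSQ header and maps consequences", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p)  # no CSQ header line
  expect_error(read_annotated_vcf(p, "vep"), class = "acmgscore_format_error")

  p2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"... ",
           "Format: Allele|Consequence|SYMBOL|Protein_position|Amino_acids|gnomAD_AF|SIFT\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("7", "140753336", ".", "A", "T", ".", "PASS",
            "CSQ=T|missense_variant|BRAF|600|V/E|0.00001|deleterious(0.02)",
            "GT", "0/1"), collapse = "\t")
  ), p2)
  coh <- read_annotated_vcf(p2, "vep")
  expect_equal(coh$gene, "BRAF")
  expect_equal(coh$exonic_func, "nonsynonymous SNV")
  expect_equal(coh$aa_change, "p.V600E")
  expect_equal(coh$pop_freqs[[1]], c(gnomad_exome = 1e-5))
  expect_equal(unname(coh$predictor_calls[[1]]["sift"]), "deleterious")
})

test_that("fixture VCFs round-trip the generator's in-memory truth", {
  dir <- withr::local_tempdir()
  fx <- generate_cohort(dir = dir)
  for (rd in list(read_annovar_table(fx$paths$annovar_tsv),
                  read_annotated_vcf(fx$paths$annovar_vcf, "annovar"))) {
    expect_equal(nrow(rd), nrow(fx$cohort))
    expect_identical(rd$genotypes, fx$cohort$genotypes)
    expect_identical(rd$pop_freqs, fx$cohort$pop_freqs)
    expect_identical(rd$predictor_calls, fx$cohort$predictor_calls)
    expect_identical(rd$aa_change, fx$cohort$aa_change)
    expect_identical(rd$exonic_func, fx$cohort$exonic_func)
  }
})

test_that("reports write deterministically ordered rows and round-trip", {
  tab <- tibble::tibble(chrom = c("2", "1"), pos = c(5L, 9L),
                        ref = c("A", "C"), alt = c("T", "G"),
                        gene = c("B", "A"), posterior = c(0.5, 0.9))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, p, format = "tsv")
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(as.character(back$chrom), c("1", "2"))  # sorted on write
  expect_equal(back$posterior, c(0.9, 0.5))

  # empty cohort -> header-only file
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab[0, ], p2, format = "tsv")
  expect_equal(length(readLines(p2)), 1L)

  # workbook-style output: one sheet per table
  d <- withr::local_tempdir()
  write_report(list(main = tab, extra = tab[1, ]), d, format = "sheets")
  expect_setequal(list.files(d), c("main.tsv", "extra.tsv"))
})

test_that("report_table puts classification columns first and sorts rows", {
  fx <- generate_cohort()
  res <- classify_cohort(fx$cohort, pedigree = fx$pedigree)
  tab <- report_table(res)
  expect_equal(names(tab)[1:8],
               c("chrom", "pos", "ref", "alt", "gene", "criteria",
                 "acmg_class", "posterior"))
  expect_false(is.unsorted(tab$pos))
  expect_equal(nrow(tab), nrow(fx$cohort))
})
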