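test_that("VCF writing and reading round-trip the variant table", {
  v <- variant_table(
    variant_row(chrom = "1", pos = 100L, gene = "G1", genotype = "het",
                pop_af = 0.05, consequence = "missense", insilico = 0.91,
                assertion = "pathogenic"),
    variant_row(chrom = "2", pos = 200L, gene = "G2", genotype = "hom_alt",
                consequence = "stop_gained", splice_impact = FALSE),
    variant_row(chrom = "X", pos = 300L, gene = "G3", genotype = "hemi",
                pop_af = 0.2, consequence = "synonymous"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(variants_to_vcf(v), path)
  back <- read_variants(path, format = "vcf")
  expect_identical(nrow(back), 3L)
  expect_identical(attr(back, "n_skipped"), 0L)
  m <- match(paste(v$chrom, v$pos), paste(back$chrom, back$pos))
  expect_identical(back$genotype[m], v$genotype)
  expect_identical(back$gene[m], v$gene)
  expect_equal(back$pop_af[m], v$pop_af, tolerance = 1e-6)
  expect_identical(back$consequence[m], v$consequence)
  expect_identical(back$splice_impact[m], v$splice_impact)
  expect_identical(is.na(back$pop_af[m]), is.na(v$pop_af))
})

test_that("multiallelic records split per ALT with allele-indexed AF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t500\t.\tA\tC,T\t.\tPASS\tGENE=G1;AF=0.01,0.2\tGT\t1/2"), path)
  got <- read_variants(path, format = "vcf")
  expect_identical(nrow(got), 2L)
  expect_identical(got$chrom, c("1", "1"))
  expect_identical(got$ref, c("A", "A"))
  expect_setequal(got$alt, c("C", "T"))
  expect_equal(got$pop_af[got$alt == "C"], 0.01)
  expect_equal(got$pop_af[got$alt == "T"], 0.2)
  expect_identical(got$genotype, c("het", "het"))
})

test_that("missing AF values stay NA, distinct from zero", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t10\t.\tG\tA\t.\tPASS\tGENE=G1;AF=.\tGT\t0/1",
    "1\t20\t.\tG\tA\t.\tPASS\tGENE=G1\tGT\t0/1",
    "1\t30\t.\tG\tA\t.\tPASS\tGENE=G1;AF=0\tGT\t0/1"), path)
  got <- read_variants(path, format = "vcf")
  expect_identical(is.na(got$pop_af), c(TRUE, TRUE, FALSE))
  expect_identical(got$pop_af[3], 0)
})

test_that("tab-delimited variant tables read with row-level skip accounting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "CHROM\tPOS\tREF\tALT\tGT\tGENE\tAF\tCSQ",
    "1\t100\tG\tA\thet\tG1\t0.05\tmissense",
    "1\tnotanumber\tG\tA\thet\tG1\t0.05\tmissense",
    "2\t200\tG\tA\t1/1\tG2\t\tstop_gained"), path)
  expect_warning(got <- read_variants(path, format = "tsv"), "unparsable")
  expect_identical(nrow(got), 2L)
  expect_identical(attr(got, "n_skipped"), 1L)
  expect_identical(got$genotype, c("het", "hom_alt"))
  expect_true(is.na(got$pop_af[2]))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS\tREF\tALT\tGT\tAF",
               "1\t1\tG\tA\thet\t0.1"), bad)
  expect_error(read_variants(bad, format = "tsv"), "gene")
  expect_error(read_variants(path, format = "tsv",
                             field_map = c(af = "AF")),
               "missing required field")
})

test_that("the allele-frequency screen keeps missing and boundary frequencies", {
  v <- variant_table(
    variant_row(pos = 1L),                  # missing AF
    variant_row(pos = 2L, pop_af = 0.05),
    variant_row(pos = 3L, pop_af = 0.1),    # inclusive boundary
    variant_row(pos = 4L, pop_af = 0.2))
  kept <- filter_af(v, alpha = 0.1)
  expect_identical(kept$pos, c(1L, 2L, 3L))
  expect_identical(attr(kept, "n_removed"), 1L)
})

test_that("filter_af is idempotent and monotone in alpha", {
  set.seed(42)
  v <- do.call(variant_table, lapply(1:50, function(i) {
    variant_row(pos = i, pop_af = if (i %% 7 == 0) NA_real_ else runif(1))
  }))
  for (alpha in c(0, 0.05, 0.1, 0.5, 1)) {
    once <- filter_af(v, alpha)
    expect_equal(filter_af(once, alpha), once, ignore_attr = TRUE)
  }
  kept_n <- vapply(c(0, 0.1, 0.3, 0.7, 1),
                   function(a) nrow(filter_af(v, a)), numeric(1))
  expect_true(all(diff(kept_n) >= 0))
})

test_that("the inheritance screen applies mode-genotype compatibility per gene", {
  modes <- list(AR1 = "AR", AR2 = "AR", AR3 = "AR", AD1 = "AD",
                XL1 = "XLR", NOMODE = NULL, WEIRD = "MODE?")
  v <- variant_table(
    variant_row(gene = "AR1", pos = 1L, genotype = "het"),
    variant_row(gene = "AR2", pos = 2L, genotype = "het"),
    variant_row(gene = "AR2", pos = 3L, genotype = "het"),
    variant_row(gene = "AR3", pos = 4L, genotype = "hom_alt"),
    variant_row(gene = "AD1", pos = 5L, genotype = "het"),
    variant_row(gene = "XL1", pos = 6L, genotype = "het", chrom = "X"),
    variant_row(gene = "NOMODE", pos = 7L, genotype = "het"),
    variant_row(gene = "WEIRD", pos = 8L, genotype = "het"))
  expect_warning(out <- filter_inheritance(v, modes), "unknown inheritance mode")
  expect_false("AR1" %in% names(out))         # single het in AR gene
  expect_identical(nrow(out[["AR2"]]), 2L)    # putative compound het kept
  expect_identical(nrow(out[["AR3"]]), 1L)    # homozygous qualifies
  expect_identical(nrow(out[["AD1"]]), 1L)
  expect_identical(nrow(out[["XL1"]]), 1L)    # het qualifies, sex unknown
  expect_identical(nrow(out[["NOMODE"]]), 1L) # pass-through
  expect_identical(nrow(out[["WEIRD"]]), 1L)  # unknown mode = no data
  # with known sex, an XLR heterozygote no longer qualifies
  out2 <- suppressWarnings(filter_inheritance(v, modes, sex = "female"))
  expect_false("XL1" %in% names(out2))
})
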