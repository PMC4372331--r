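test_that("a toy variant TSV parses with SIFT values as given", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", gene_symbol = c("G1", "G1", "G2"),
    transcript_id = c("T1", "T2", "T3"), chrom = "chr1",
    pos = c(100L, 100L, 200L), ref_allele = "A", alt_allele = "G",
    sift_score = c("0.00", "0.04", "0.30")
  ), path)
  v <- read_variants(path)
  expect_equal(nrow(v), 3)
  expect_equal(sort(v$sift_score), c(0, 0.04, 0.30))
  expect_true(all(is.na(v$dbsnp_id)))
})

test_that("unparseable SIFT fields become missing scores, not errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", gene_symbol = "G1", transcript_id = c("T1", "T2"),
    chrom = "chr1", pos = 100L, ref_allele = "A", alt_allele = "G",
    sift_score = c(".", "0.02")
  ), path)
  v <- read_variants(path)
  expect_equal(sum(is.na(v$sift_score)), 1)
})

test_that("a missing required column is a configuration error naming it", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", transcript_id = "T1", chrom = "chr1", pos = 100L,
    ref_allele = "A", alt_allele = "G", sift_score = "0.01"
  ), path)
  expect_error(read_variants(path), "gene_symbol")
})

test_that("malformed coordinates raise a row-level error; indels are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", gene_symbol = "G1", transcript_id = "T1", chrom = "chr1",
    pos = c("100", "oops"), ref_allele = "A", alt_allele = "G",
    sift_score = "0.01"
  ), path)
  expect_error(read_variants(path), "coordinate")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", gene_symbol = "G1", transcript_id = c("T1", "T2"),
    chrom = "chr1", pos = c(100L, 200L), ref_allele = c("A", "AT"),
    alt_allele = c("G", "A"), sift_score = "0.01"
  ), path2)
  expect_message(v <- read_variants(path2), "non-SNV")
  expect_equal(nrow(v), 1)
})

test_that("dialects remap columns; ANNOVAR-style headers parse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    Sample = "S1", Gene.refGene = "G1", Transcript = "T1", Chr = "chr1",
    Start = 100L, Ref = "A", Alt = "G", SIFT_score = "0.03",
    avsnp = "rs1", AAChange = "p.K10R"
  ), path)
  v <- read_variants(path, dialect = annovar_dialect())
  expect_equal(v$gene_symbol, "G1")
  expect_equal(v$sift_score, 0.03)
  expect_equal(v$dbsnp_id, "rs1")
})

test_that("write then read round-trips a variant table; parsing is order-independent", {
  v <- random_variants(seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(v, path)
  back <- read_variants(path)
  expect_equal(
    dplyr::arrange(back, sample_id, chrom, pos, transcript_id, gene_symbol),
    dplyr::arrange(v, sample_id, chrom, pos, transcript_id, gene_symbol)
  )

  shuffled <- withr::with_seed(1, v[sample(nrow(v)), ])
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(v, p1)
  write_result_table(shuffled, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(read_variants(p1), read_variants(p2))
})

test_that("result tables are written deterministically, sorted by their key", {
  res <- tibble::tibble(gene_symbol = c("B", "A"), p_value = c(0.02, 0.5),
                        fdr = c(0.04, 0.5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(res, p1)
  write_result_table(res, p2)
  expect_identical(readLines(p1), readLines(p2))
  lines <- readLines(p1)
  expect_equal(length(lines), 3)  # header + 2 rows
  expect_match(lines[2], "^B")    # sorted by p ascending

  empty <- res[0, ]
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(empty, p3)
  expect_equal(readLines(p3), "gene_symbol\tp_value\tfdr")
})

test_that("duplicate annotation rows collapse keeping the minimum SIFT", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = "S1", gene_symbol = "G1", transcript_id = "T1", chrom = "chr1",
    pos = 100L, ref_allele = "A", alt_allele = "G",
    sift_score = c("0.04", "0.01")
  ), path)
  expect_message(v <- read_variants(path), "duplicate")
  expect_equal(v$sift_score, 0.01)
})

test_that("design files parse; duplicates and empty labels are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tER\tpopulation",
               "S1\tpos\tMEX", "S2\tneg\tMEX", "S3\t\tVIE", "S4\tpos\tVIE"),
             path)
  d <- read_design(path)
  expect_equal(nrow(d), 4)
  expect_true(is.na(d$ER[d$sample_id == "S3"]))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tER", "S1\tpos", "S1\tneg"), dup)
  expect_error(read_design(dup), "S1")
})

test_that("domain tables validate their intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    transcript_id = "T1", domain_db = "PfamA", domain_id = "PF00001",
    aa_start = 10L, aa_end = 5L
  ), path)
  expect_error(read_domains(path), "interval")
})

test_that("annotated VCF records map onto the canonical variant table", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene">',
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Tx">',
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT">',
    '##INFO=<ID=AACHANGE,Number=1,Type=String,Description="AA">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t.\tPASS\tGENE=G1;TRANSCRIPT=T1;SIFT=0.02;AACHANGE=p.K10R",
    "chr1\t200\t.\tC\tCT\t.\tPASS\tGENE=G1;TRANSCRIPT=T1;SIFT=0.50;AACHANGE=p.L20F"
  ), path)
  expect_message(v <- read_annotated_vcf(path, sample_id = "S9"), "non-SNV")
  expect_equal(nrow(v), 1)
  expect_equal(v$sample_id, "S9")
  expect_equal(v$sift_score, 0.02)
  expect_equal(v$dbsnp_id, "rs1")
})
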