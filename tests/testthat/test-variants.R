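vcf_header <- function(samples, panels = character(0)) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"f\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"s\">",
    "##INFO=<ID=POLYPHEN,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"c\">",
    vapply(panels, function(p) sprintf(
      "##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"af\">", p),
      character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_lines <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

test_that("a simple biallelic record yields one variant with alt counts", {
  path <- write_vcf_lines(c(
    vcf_header(c("s1", "s2")),
    "1\t100\trs1\tA\tG\t.\tPASS\tFUNC=nonsynonymous;SIFT=deleterious;POLYPHEN=probably_damaging;CADD=30\tGT\t0/1\t0/0"
  ))
  x <- read_annotated_vcf(path)
  expect_equal(n_variants(x), 1L)
  expect_equal(unname(x$geno[1, ]), c(1L, 0L))
  expect_equal(x$sites$id, "rs1")
  expect_equal(x$ann$functional_class, "nonsynonymous")
  expect_equal(x$ann$cadd_phred, 30)
})

test_that("multi-allelic records decompose with per-allele genotype recoding", {
  path <- write_vcf_lines(c(
    vcf_header(c("s1", "s2", "s3")),
    "2\t500\t.\tA\tT,C\t.\tPASS\tFUNC=nonsynonymous\tGT\t1/2\t0/1\t2|2"
  ))
  x <- read_annotated_vcf(path)
  expect_equal(n_variants(x), 2L)
  expect_equal(x$sites$alt, c("T", "C"))
  expect_equal(x$sites$id, c("2:500:A:T", "2:500:A:C"))
  # GT 1/2 contributes one copy to each decomposed allele
  expect_equal(unname(x$geno[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(x$geno[2, ]), c(1L, 0L, 2L))
  # phase dropped: 2|2 read as count 2
})

test_that("decomposition conserves per-sample non-reference allele counts", {
  set.seed(11)
  gts <- c("0/0", "0/1", "1/1", "1/2", "0/2", "2/2", "./.", "1|2", "2|0")
  recs <- vapply(1:30, function(r) {
    g <- sample(gts, 3, replace = TRUE)
    paste(c("3", 1000 + r, ".", "G", "A,C", ".", "PASS", ".", "GT", g),
          collapse = "\t")
  }, character(1))
  path <- write_vcf_lines(c(vcf_header(c("s1", "s2", "s3")), recs))
  x <- read_annotated_vcf(path)
  raw <- read.table(path, sep = "\t", comment.char = "#")
  for (r in 1:30) {
    for (s in 1:3) {
      gt <- raw[r, 9 + s]
      alleles <- strsplit(gt, "[/|]")[[1]]
      expected <- if (any(alleles == ".")) NA_integer_
                  else sum(alleles != "0")
      got <- x$geno[2 * r - 1, s] + x$geno[2 * r, s]
      expect_equal(got, expected)
    }
  }
})

test_that("missing GT FORMAT is a format error", {
  path <- write_vcf_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "1\t1\t.\tA\tG\t.\tPASS\t.\tDP\t10"
  ))
  expect_error(read_annotated_vcf(path), "GT")
})

test_that("sidecar TSV overrides INFO annotations and warns on orphans", {
  path <- write_vcf_lines(c(
    vcf_header("s1", panels = "gnomAD"),
    "1\t100\trs1\tA\tG\t.\tPASS\tFUNC=synonymous;SIFT=tolerated;AF_gnomAD=0.2\tGT\t0/1"
  ))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tfunctional_class\tsift\tpolyphen\tcadd_phred\taf_gnomAD",
    "1\t100\tA\tG\tnonsynonymous\tdeleterious\tprobably_damaging\t28\t0.0001",
    "9\t999\tT\tC\tsplicing\tunknown\tunknown\t5\t0.5"
  ), tsv)
  expect_warning(x <- read_annotated_vcf(path, tsv), "matched no variant")
  expect_equal(x$ann$functional_class, "nonsynonymous")
  expect_equal(x$ann$sift, "deleterious")
  expect_equal(x$ann$cadd_phred, 28)
  expect_equal(unname(x$panel_af[1, "gnomAD"]), 1e-4)
})

test_that("write -> read round-trips the data model", {
  set.seed(3)
  x <- random_variants(40, c("s1", "s2", "s3"))
  path <- tempfile(fileext = ".vcf")
  write_annotated_vcf(x, c("s1", "s2", "s3"), path)
  y <- read_annotated_vcf(path)
  expect_identical(unname(y$geno), unname(x$geno))
  expect_equal(y$sites$pos, x$sites$pos)
  expect_equal(y$ann$functional_class, x$ann$functional_class)
  expect_equal(y$ann$sift, x$ann$sift)
  expect_equal(y$ann$polyphen, x$ann$polyphen)
  expect_equal(y$ann$cadd_phred, x$ann$cadd_phred, tolerance = 1e-5)
  expect_equal(unname(y$panel_af), unname(x$panel_af), tolerance = 1e-5)
  # a second write of the re-read object is byte-identical
  path2 <- tempfile(fileext = ".vcf")
  write_annotated_vcf(y, c("s1", "s2", "s3"), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("writing with an unknown sample errors, naming it", {
  x <- random_variants(3, c("s1", "s2"))
  expect_error(write_annotated_vcf(x, c("s1", "ghost"), tempfile()),
               "ghost")
})

test_that("the variant container enforces its invariants", {
  sites <- data.frame(id = "v1", chrom = "1", pos = 10L, ref = "A",
                      alt = "T", stringsAsFactors = FALSE)
  ann <- data.frame(functional_class = "other", sift = "unknown",
                    polyphen = "unknown", cadd_phred = NA_real_,
                    stringsAsFactors = FALSE)
  expect_error(annotated_variants(
    within(sites, pos <- 0L), matrix(0L, 1, 1), ann), "pos")
  expect_error(annotated_variants(
    within(sites, alt <- "A"), matrix(0L, 1, 1), ann), "differ")
  expect_error(annotated_variants(sites, matrix(3L, 1, 1), ann), "0:2")
  expect_error(annotated_variants(sites, matrix(0L, 1, 1), ann,
                                  matrix(1.5, 1, 1)), "\\[0, 1\\]")
})
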