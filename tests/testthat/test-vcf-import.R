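test_that("normalization trims suffix then prefix and is a fixed point", {
  n <- normalize_variant("chr1", 100, "AT", "AC")
  expect_equal(n[c("pos", "ref", "alt")], list(pos = 101L, ref = "T", alt = "C"))
  expect_equal(normalize_variant("chr1", 100, "A", "G")$pos, 100L)
  expect_identical(normalize_variant("chr1", 100, "A", "G")$ref, "A")

  # trimming preserves the edit and reaches a minimal-length representation
  set.seed(42)
  for (i in 1:200) {
    len_r <- sample(1:6, 1); len_a <- sample(1:6, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), len_r, TRUE), collapse = "")
    alt <- paste(sample(c("A", "C", "G", "T"), len_a, TRUE), collapse = "")
    if (ref == alt) next
    pos <- sample(5:20, 1)
    n1 <- normalize_variant("chr1", pos, ref, alt)
    # fixed point
    n2 <- normalize_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_identical(n1, n2)
    # same edit on an embedding context
    ctx <- paste(sample(c("A", "C", "G", "T"), pos + len_r + 10, TRUE), collapse = "")
    ctx <- paste0(substr(ctx, 1, pos - 1), ref,
                  substr(ctx, pos + len_r, nchar(ctx)))
    expect_identical(apply_edit(ctx, pos, ref, alt),
                     apply_edit(ctx, n1$pos, n1$ref, n1$alt))
    # minimality: no further shared boundary bases beyond the 1-base floor
    shares_suffix <- nchar(n1$ref) > 1 && nchar(n1$alt) > 1 &&
      substr(n1$ref, nchar(n1$ref), nchar(n1$ref)) ==
      substr(n1$alt, nchar(n1$alt), nchar(n1$alt))
    shares_prefix <- nchar(n1$ref) > 1 && nchar(n1$alt) > 1 &&
      substr(n1$ref, 1, 1) == substr(n1$alt, 1, 1)
    expect_false(shares_suffix || shares_prefix)
  }
})

test_that("normalization of a deletion in a repeat run keeps the minimal alleles", {
  # CTT>CT is a 1-bp deletion in a T run; suffix-first trimming anchors it
  # at the original position with alleles CT>C
  n <- normalize_variant("chr1", 100, "CTT", "CT")
  expect_equal(nchar(n$ref) + nchar(n$alt), 3L)
  ctx <- "GGCTTGG"
  expect_identical(apply_edit(ctx, 3, "CTT", "CT"),
                   apply_edit(ctx, n$pos - 97, n$ref, n$alt))
})

test_that("multiallelic records split into per-allele projections", {
  rec <- list(chrom = "chr1", pos = 10L, ref = "A", alt = "G,T",
              gt = "1/2", ad = "2,8,9")
  parts <- split_multiallelic(rec)
  expect_length(parts, 2L)
  expect_identical(parts[[1]]$alt, "G")
  expect_identical(parts[[1]]$genotype, "het")
  expect_equal(c(parts[[1]]$ad_ref, parts[[1]]$ad_alt), c(2L, 8L))
  expect_identical(parts[[2]]$alt, "T")
  expect_identical(parts[[2]]$genotype, "het")
  expect_equal(c(parts[[2]]$ad_ref, parts[[2]]$ad_alt), c(2L, 9L))
  # union of splits covers every ALT exactly once
  expect_setequal(vapply(parts, `[[`, "", "alt"),
                  strsplit(rec$alt, ",")[[1]])

  single <- split_multiallelic(list(chrom = "chr1", pos = 10L, ref = "A",
                                    alt = "G", gt = "0/1", ad = "5,5"))
  expect_length(single, 1L)
  expect_identical(single[[1]]$genotype, "het")

  homref <- split_multiallelic(list(chrom = "chr1", pos = 10L, ref = "A",
                                    alt = "G,T", gt = "0/0", ad = NA))
  expect_identical(vapply(homref, `[[`, "", "genotype"), c("hom_ref", "hom_ref"))
})

test_that("genotype strings map to classes including half-calls and haploid X", {
  gt <- function(x, k = 1L) vardepot:::gt_class(x, k)
  expect_identical(gt("0/1"), "het")
  expect_identical(gt("1|1"), "hom_alt")
  expect_identical(gt("0/0"), "hom_ref")
  expect_identical(gt("./."), "missing")
  expect_identical(gt("."), "missing")
  expect_identical(gt("./1"), "het")     # half-call counts as het
  expect_identical(gt("1"), "hom_alt")   # haploid male X
  expect_identical(gt("1/2", 2L), "het")
  expect_identical(gt("2/2", 2L), "hom_alt")
})

test_that("GATK vector extraction takes QUAL/FORMAT/INFO and keeps FILTER verbatim", {
  rec <- list(qual = "541.3", filter = "VQSRTrancheSNP99.90to100.00",
              info = "QD=12.1;MQ=58.3;FS=1.2;BaseQRankSum=-0.31;MQRankSum=0.2;ReadPosRankSum=1.1",
              format = "GT:AD:GQ", sample = "0/1:12,6:99")
  g <- extract_gatk_fields(rec)
  expect_equal(g$qual, 541.3)
  expect_equal(g$gq, 99)
  expect_identical(g$ad, "12,6")
  expect_equal(g$qd, 12.1)
  expect_equal(g$mq, 58.3)
  expect_equal(g$fs, 1.2)
  expect_equal(g$base_q_rank_sum, -0.31)
  expect_identical(g$filter_status, "VQSRTrancheSNP99.90to100.00")

  no_qd <- extract_gatk_fields(list(qual = "10", filter = "PASS",
                                    info = "MQ=60", format = "GT", sample = "0/1"))
  expect_true(is.na(no_qd$qd))
  expect_warning(extract_gatk_fields(list(qual = "abc", filter = "PASS",
                                          info = "", format = "GT", sample = "0/1")),
                 "unparsable")
})

test_that("import splits, normalizes, stores and is idempotent on re-import", {
  st <- local_store()
  pid <- add_project(st, "p")
  add_sample(st, "S1", pid)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t50\tPASS\tQD=2\tGT:AD\t0/1:5,5",
    "chr1\t200\t.\tA\tG,T\t60\tPASS\t.\tGT:AD\t1/2:2,8,9",
    "chr1\t300\t.\tAT\tAC\t70\tPASS\t.\tGT:AD\t1/1:0,9"), vcf)
  s <- import_vcf(st, vcf, "hg19")
  expect_equal(s$n_records_read, 3L)
  expect_equal(s$n_variants_imported, 4L)   # biallelic split adds one
  expect_equal(s$n_multiallelic_split, 1L)
  vars <- get_variants(st)
  expect_equal(nrow(vars), 4L)
  # AT>AC arrived normalized to T>C at 301
  expect_true(any(vars$pos == 301 & vars$ref == "T" & vars$alt == "C"))

  again <- import_vcf(st, vcf, "hg19", overwrite = TRUE)
  expect_equal(nrow(get_variants(st)), 4L)  # zero new variant rows
  expect_equal(again$n_variants_imported, 4L)
})

test_that("a build conflict aborts the import before any write", {
  st <- local_store(build = "hg19")
  pid <- add_project(st, "p")
  add_sample(st, "S1", pid)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(import_vcf(st, vcf, "hg18"), "build conflict", class = "vdb_conflict")
  expect_equal(nrow(get_variants(st)), 0L)
})

test_that("hom-ref records are skipped by default and kept on request", {
  st <- local_store()
  pid <- add_project(st, "p")
  add_sample(st, "S1", pid)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0",
               "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0/1"), vcf)
  s <- import_vcf(st, vcf, "hg19")
  expect_equal(s$n_variants_imported, 1L)
  expect_match(s$skip_reasons, "non-variant=1")
  st2 <- local_store()
  pid2 <- add_project(st2, "p")
  add_sample(st2, "S1", pid2)
  s2 <- import_vcf(st2, vcf, "hg19", keep_homref = TRUE)
  expect_equal(s2$n_variants_imported, 2L)
})
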