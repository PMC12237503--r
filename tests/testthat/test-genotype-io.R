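test_that("encode_genotype implements the dosage definition", {
  expect_identical(encode_genotype(c("0/0", "0|1", "1/1")), c(0L, 1L, 2L))
  expect_identical(encode_genotype(c("./.", "./1", ".")), rep(NA_integer_, 3))
  expect_identical(encode_genotype("1", ploidy = 1), 1L)
  expect_identical(encode_genotype("0", ploidy = 1), 0L)
  # multiallelic residue never miscoded as dosage
  expect_identical(encode_genotype("1/2"), NA_integer_)
  expect_error(encode_genotype("0/1/1", ploidy = 2), "ploidy")
  expect_error(encode_genotype("0/x"), "malformed")
})

test_that("read_vcf encodes a hand-written VCF as specified", {
  path <- write_hand_vcf(withr::local_tempfile(fileext = ".vcf"))
  G <- read_vcf(path)
  expect_s3_class(G, "genotype_matrix")
  expect_identical(G$sample_ids, c("s1", "s2", "s3"))
  expect_identical(G$variant_ids, c("1:100:A:T", "1:200:C:G"))
  expect_equal(as.numeric(G$dosages[, 1]), c(0, 1, 2))
  # ./. (s2) and half-call ./1 (s3) are missing; stored dosage stays empty
  expect_equal(as.matrix(G$missing_mask),
               matrix(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), 3),
               ignore_attr = TRUE)
  expect_equal(as.numeric(G$dosages[, 2]), c(1, 0, 0))
})

test_that("read_vcf output is invariant to chunk_size and gzip compression", {
  co <- tiny_cohort(seed = 4, missing_rate = 0.05)
  plain <- withr::local_tempfile(fileext = ".vcf")
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(co, plain)
  write_vcf(co, gz)
  G1 <- read_vcf(plain, chunk_size = 1)
  G2 <- read_vcf(plain, chunk_size = 10000)
  G3 <- read_vcf(gz, chunk_size = 17)
  for (G in list(G2, G3)) {
    expect_identical(as.matrix(G$dosages), as.matrix(G1$dosages))
    expect_identical(as.matrix(G$missing_mask), as.matrix(G1$missing_mask))
    expect_identical(G$sample_ids, G1$sample_ids)
    expect_identical(G$variant_ids, G1$variant_ids)
  }
})

test_that("multiallelic policy: drop removes, split expands per ALT", {
  rec <- paste("1", "300", "v3", "A", "T,G", ".", "PASS", ".", "GT",
               "0/1", "1/2", "2/2", sep = "\t")
  path <- write_hand_vcf(withr::local_tempfile(fileext = ".vcf"), rec)
  expect_message(Gd <- read_vcf(path, multiallelic = "drop"), "multiallelic")
  expect_identical(ncol(Gd$dosages), 2L)
  Gs <- read_vcf(path, multiallelic = "split")
  expect_identical(ncol(Gs$dosages), 4L)
  expect_identical(Gs$variant_ids[3:4], c("1:300:A:T", "1:300:A:G"))
  expect_equal(as.numeric(Gs$dosages[, 3]), c(1, 1, 0))  # count of allele 1
  expect_equal(as.numeric(Gs$dosages[, 4]), c(0, 1, 2))  # count of allele 2
})

test_that("read_vcf error paths", {
  expect_error(read_vcf(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"),
             bad)
  expect_error(read_vcf(bad), "empty input")
  writeLines("not a vcf", bad)
  expect_error(read_vcf(bad))
  path <- write_hand_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_vcf(path, chunk_size = 0), "chunk_size")
})

test_that("alt allele frequencies match bcftools on the source VCF", {
  skip_if(Sys.which("bcftools") == "", "bcftools not on PATH")
  co <- tiny_cohort(seed = 9, missing_rate = 0.04)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co, path)
  G <- read_vcf(path)
  out <- system2("bcftools", c("+fill-tags", path, "--", "-t", "AF"),
                 stdout = TRUE, stderr = FALSE)
  af_line <- out[grepl("^1\t", out)]
  af <- as.numeric(sub(".*AF=([0-9.e+-]+).*", "\\1", af_line))
  expect_equal(unname(alt_allele_freq(G)), af, tolerance = 1e-5)
})

test_that("read_bed matches read_vcf on the same cohort and decodes the bit format", {
  co <- tiny_cohort(seed = 5, missing_rate = 0.03)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pre <- withr::local_tempfile()
  write_vcf(co, vcf)
  Gv <- read_vcf(vcf)
  write_plink(Gv, pre)
  Gb <- read_bed(pre)
  expect_identical(as.matrix(Gb$dosages), as.matrix(Gv$dosages))
  expect_identical(as.matrix(Gb$missing_mask), as.matrix(Gv$missing_mask))
  expect_identical(Gb$sample_ids, Gv$sample_ids)
  expect_identical(Gb$variant_ids, Gv$variant_ids)
})

test_that("read_bed decodes hand-built bytes per the published encoding", {
  # 1 sample, 2 variants: het then missing. SNP-major, 2 bits per sample:
  # 10 -> het (dosage 1), 01 -> missing. Byte for '10' = 0b00000010 = 2;
  # byte for '01' = 0b00000001 = 1.
  pre <- withr::local_tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x02, 0x01)), paste0(pre, ".bed"))
  writeLines(c("1\tv1\t0\t100\tT\tA", "1\tv2\t0\t200\tG\tC"), paste0(pre, ".bim"))
  writeLines("f1\ts1\t0\t0\t0\t-9", paste0(pre, ".fam"))
  G <- read_bed(pre)
  expect_equal(as.numeric(G$dosages[1, ]), c(1, 0))
  expect_equal(as.matrix(G$missing_mask)[1, ], c(FALSE, TRUE), ignore_attr = TRUE)

  # payload/dimension mismatch is a format error
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x02)), paste0(pre, ".bed"))
  expect_error(read_bed(pre), "does not match")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x02, 0x01)), paste0(pre, ".bed"))
  expect_error(read_bed(pre), "magic")
})

test_that("impute_missing honours both strategies and drops all-missing variants", {
  d <- matrix(c(0, 2, 0, 1, 1, 0, 0, 0, 0), nrow = 3)
  mask <- rbind(c(3, 1), c(1, 3), c(2, 3), c(3, 3))
  G <- genotype_matrix(d, missing_mask = mask)
  expect_warning(Gm <- impute_missing(G, "mean"), "all calls missing")
  expect_identical(n_missing(Gm), 0L)
  expect_equal(as.numeric(Gm$dosages[, 1]), c(0, 2, 1))  # mean of (0,2) = 1
  expect_equal(ncol(Gm$dosages), 2L)                      # all-missing col dropped
  expect_equal(as.numeric(Gm$dosages[, 2]), c(1, 1, 0))   # observed unchanged
  Gz <- suppressWarnings(impute_missing(G, "zero"))
  expect_identical(n_missing(Gz), 0L)
  expect_equal(as.numeric(Gz$dosages[, 1]), c(0, 2, 0))
  # empty mask: identity
  G0 <- genotype_matrix(d)
  expect_identical(impute_missing(G0), G0)
})

test_that("filter_maf thresholds on observed-call frequency and is idempotent", {
  # 10 diploid samples, one heterozygote -> p = 0.05
  d <- cbind(c(1, rep(0, 9)), c(rep(1, 10)), rep(0:1, 5))
  G <- genotype_matrix(d)
  expect_equal(alt_allele_freq(G), c(0.05, 0.5, 0.25), ignore_attr = TRUE)
  Gf <- filter_maf(G, 0.10)
  expect_identical(ncol(Gf$dosages), 2L)
  expect_false("var_1" %in% Gf$variant_ids)
  # p = 0.5 survives any threshold; column order preserved
  expect_identical(Gf$variant_ids, c("var_2", "var_3"))
  expect_identical(filter_maf(Gf, 0.10)$variant_ids, Gf$variant_ids)
  # min_maf = 0 is the identity
  expect_identical(filter_maf(G, 0)$variant_ids, G$variant_ids)
  expect_error(filter_maf(G, 0.7), "min_maf")
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(genotype_matrix(matrix(3, 1, 1), ploidy = 2), "ploidy")
  expect_error(genotype_matrix(matrix(0, 2, 1), sample_ids = c("a", "a")),
               "duplicate")
  expect_error(genotype_matrix(matrix(0, 2, 2), variant_ids = c("v", "v")),
               "duplicate")
  G <- genotype_matrix(matrix(c(0, 1, 2, 0), 2), ploidy = 2)
  expect_s4_class(G$dosages, "dgCMatrix")
  sub <- G[1, ]
  expect_identical(dim(sub), c(1L, 2L))
  expect_identical(sub$sample_ids, "sample_1")
})

test_that("label tables round-trip through delimited text", {
  lab <- sample_labels(c("a", "b", "c"), c("x", "x", "y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, path)
  lab2 <- read_labels(path)
  expect_identical(lab2$sample_id, lab$sample_id)
  expect_identical(lab2$label, lab$label)
  expect_identical(lab2$k, 2L)
  expect_error(sample_labels(c("a", "a"), c("x", "y")), "duplicate")
})
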