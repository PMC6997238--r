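# Database scanning and pgstat caching.

test_that("reference scan counts bases and N runs exactly", {
  fa <- write_fasta(c(">c1", "ACGTNNAC"))
  gs <- scan_reference(fa)
  expect_equal(gs$GLN, 8)
  expect_equal(gs$nGLN, 2)
  expect_equal(gs$contigs$length, 8L)
  expect_equal(gs$n_blocks$c1, data.frame(start = 4L, end = 6L))
})

test_that("N runs spanning line and chunk boundaries are merged", {
  # run crosses a line boundary; lowercase n counts as N
  fa <- write_fasta(c(">c1", "ACGTNN", "nNACGT", ">c2", "NNNN"))
  gs <- scan_reference(fa)
  expect_equal(gs$nGLN, 8)
  expect_equal(gs$n_blocks$c1, data.frame(start = 4L, end = 8L))
  expect_equal(gs$n_blocks$c2, data.frame(start = 0L, end = 4L))
  # a contig longer than one read chunk (5000 lines) still scans correctly,
  # against an independent per-character count
  set.seed(3)
  big_lines <- replicate(5200, paste(sample(c("A", "C", "G", "T", "N"), 40,
                                            replace = TRUE), collapse = ""))
  fa2 <- write_fasta(c(">big", big_lines))
  gs2 <- scan_reference(fa2)
  chars <- strsplit(paste(big_lines, collapse = ""), "")[[1]]
  expect_equal(gs2$GLN, length(chars))
  expect_equal(gs2$nGLN, sum(chars == "N"))
  expect_equal(gs2$GLN - gs2$nGLN, sum(chars != "N"))
})

test_that("reference scan rejects bad input and reads gzip transparently", {
  empty <- write_fasta(character())
  expect_error(scan_reference(empty), "empty")
  dup <- write_fasta(c(">c1", "ACGT", ">c1", "AC"))
  expect_error(scan_reference(dup), "duplicate contig")
  badchar <- write_fasta(c(">c1", "ACGJ"))
  expect_error(scan_reference(badchar), "J")
  plain <- write_fasta(c(">c1", "ACGTNNAC"))
  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "wt"); writeLines(c(">c1", "ACGTNNAC"), con); close(con)
  expect_equal(scan_reference(gz)$GLN, scan_reference(plain)$GLN)
})

test_that("coding BED scan computes modLen and enforces non-overlap", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t40"), bed)
  cm <- scan_coding_bed(bed)
  expect_equal(cm$modLen, 20)
  expect_equal(cm$intervals$chr1$start, c(10L, 30L))

  writeLines(c("chr1\t10\t20", "chr1\t15\t25"), bed)
  expect_error(scan_coding_bed(bed), "overlapping")
  writeLines("chr1\t20\t20", bed)
  expect_error(scan_coding_bed(bed), "start >= end")
  writeLines(character(), bed)
  expect_equal(scan_coding_bed(bed)$modLen, 0)
  # an empty coding model later refuses a positive coding-novel count
  expect_error(plan_coding_positions(scan_coding_bed(bed), CDN = 5),
               "modLen = 0")
})

test_that("known-db scan counts records; gzip gives the same count", {
  recs <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G")
  v <- write_vcf(recs)
  expect_equal(scan_known_db(v)$varNum, 5)
  expect_equal(scan_known_db(write_vcf(recs, gz = TRUE))$varNum, 5)
  expect_equal(scan_known_db(write_vcf(recs[0, ]))$varNum, 0)
})

test_that("common-db scan classifies by threshold and sums qualifying AFs", {
  v <- write_vcf(data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                            ref = "A", alt = "G",
                            info = c("AF=0.5", "AF=0.005", "AF=0.2")))
  st <- scan_common_db(v, "AF", CVT = 0.01)
  expect_equal(st$cvNum, 2)
  expect_equal(st$ecvNum, 0.7)
  # order invariance
  v2 <- write_vcf(data.frame(chrom = "chr1", pos = c(30L, 10L, 20L),
                             ref = "A", alt = "G",
                             info = c("AF=0.2", "AF=0.5", "AF=0.005")))
  expect_equal(scan_common_db(v2, "AF", 0.01)$ecvNum, st$ecvNum)
  # empty database
  e <- write_vcf(data.frame(chrom = character(), pos = integer()))
  st0 <- scan_common_db(e, "AF", 0.01)
  expect_equal(st0$cvNum, 0); expect_equal(st0$ecvNum, 0)
})

test_that("CAF-style lists drop the leading reference AF; plain tags do not", {
  v <- write_vcf(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                            info = "CAF=0.9,0.1"))
  st <- scan_common_db(v, "CAF", CVT = 0.01)
  expect_equal(st$ecvNum, 0.1)
  # multi-allelic: alt AFs are summed for classification
  v2 <- write_vcf(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G,T",
                             info = "CAF=0.8,0.15,0.05"))
  expect_equal(scan_common_db(v2, "CAF", 0.01)$ecvNum, 0.2)
  v3 <- write_vcf(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G,T",
                             info = "EUR_AF=0.15,0.05"))
  expect_equal(scan_common_db(v3, "EUR_AF", 0.01)$ecvNum, 0.2)
})

test_that("missing and malformed AF tags are handled as specified", {
  v <- write_vcf(data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
                            info = c("DP=3", "DP=9")))
  expect_error(scan_common_db(v, "AF", 0.01), "absent from every record")
  v2 <- write_vcf(data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
                             info = c("AF=0.5", "AF=oops")))
  expect_warning(st <- scan_common_db(v2, "AF", 0.01), "malformed")
  expect_equal(st$cvNum, 1)
})

test_that("pgstat caches round-trip exactly and go stale with the database", {
  fa <- write_fasta(c(">c1", "ACGTNNAC", ">c2", "GGCC"))
  gs <- scan_reference(fa)
  write_pgstat(gs, fa)
  expect_equal(read_pgstat(fa), gs)

  v <- write_vcf(data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                            info = "AF=0.25"))
  st <- scan_common_db(v, "AF", 0.01)
  write_pgstat(st, v)
  expect_equal(read_pgstat(v), st)

  expect_null(read_pgstat(tempfile()))   # no cache -> absent
  # stale cache: database touched after the cache was written
  Sys.setFileTime(v, Sys.time() + 60)
  expect_null(read_pgstat(v))
})

test_that("a streamed scan of a multi-chunk VCF matches a whole-file count", {
  n <- 25000L  # beyond one 20000-line chunk
  v <- write_vcf(data.frame(chrom = "chr1", pos = seq_len(n), ref = "A",
                            alt = "G", info = "AF=0.3"))
  expect_equal(scan_known_db(v)$varNum, n)
  st <- scan_common_db(v, "AF", 0.01)
  expect_equal(st$cvNum, n)
  expect_equal(st$ecvNum, 0.3 * n, tolerance = 1e-12)
})
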