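# Variant sampling, novel-variant instantiation, merging and VCF output.

test_that("per-haplotype genotype sampling follows exact Bernoulli algebra", {
  set.seed(1)
  expect_null(draw_genotype(0, 2))
  expect_equal(draw_genotype(1, 2), c(1L, 1L))
  expect_equal(draw_genotype(1, 1), 1L)
  # p = 0.5, diploid: P(het) = 0.5, P(hom) = 0.25, P(absent) = 0.25
  n <- 2e4
  res <- replicate(n, {
    g <- draw_genotype(0.5, 2)
    if (is.null(g)) "absent" else if (sum(g) == 2L) "hom" else "het"
  })
  tol <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(res == "het") - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(mean(res == "hom") - 0.25), tol)
  expect_lt(abs(mean(res == "absent") - 0.25), tol)
})

test_that("ploidy model reflects gender and sex-chromosome names", {
  ctgs <- c("chr1", "chr2", "chrX", "chrY", "chrM")
  m <- ploidy_model("male", ctgs)
  f <- ploidy_model("female", ctgs)
  expect_equal(unname(m[c("chr1", "chrX", "chrY")]), c(2L, 1L, 1L))
  expect_equal(unname(f[c("chr1", "chrX", "chrY")]), c(2L, 2L, 0L))
  expect_equal(unname(m["chrM"]), 2L)   # non-sex contigs treated as diploid
})

test_that("common sampling preserves relative AFs and respects the threshold", {
  # 3000 records at AF 0.4 and 3000 at 0.2, plus sub-threshold records
  n <- 3000L
  af <- c(rep(0.4, n), rep(0.2, n), rep(0.005, 200))
  db <- write_vcf(data.frame(chrom = "chr1", pos = seq_along(af),
                             id = c(rep("hi", n), rep("lo", n), rep("sub", 200)),
                             ref = "A", alt = "G",
                             info = sprintf("AF=%g", af)))
  pl <- ploidy_model("female", "chr1")
  set.seed(42)
  sel <- sample_common_variants(db, "AF", CVT = 0.01, paC = 1, ploidy = pl)
  expect_true(all(sel$af >= 0.01))                 # CVT floor
  expect_equal(min(sel$af), 0.2)
  hap <- function(ids) sum(sel$g1[sel$id %in% ids]) +
    sum(sel$g2[sel$id %in% ids], na.rm = TRUE)
  r <- hap("hi") / hap("lo")
  # delta-method 3-sigma band for the ratio of two binomial counts
  sd_r <- 2 * sqrt(0.6 / (2 * n * 0.4) + 0.8 / (2 * n * 0.2))
  expect_lt(abs(r - 2), 3 * sd_r)
  # expected haploid count = paC * ecvNum
  expect_lt(abs((hap("hi") + hap("lo")) / 2 - (n * 0.4 + n * 0.2)),
            3 * sqrt(n * (0.4 * 0.6 + 0.2 * 0.8)))
  expect_equal(nrow(sample_common_variants(db, "AF", 0.01, paC = 0, ploidy = pl)), 0)
})

test_that("non-common sampling is flat at paAF and excludes common records", {
  n <- 9000L
  info <- c(rep("CAF=0.5,0.5", 500), sprintf("CAF=%g,%g", 0.999, 0.001)[rep(1, n)])
  db <- write_vcf(data.frame(chrom = "chr1", pos = seq_along(info),
                             id = c(rep("com", 500), rep("rare", n)),
                             ref = "A", alt = "G", info = info))
  pl <- ploidy_model("female", "chr1")
  set.seed(9)
  sel <- sample_noncommon_variants(db, "CAF", CVT = 0.01, paAF = 0.2, ploidy = pl)
  expect_false(any(sel$id == "com"))               # common never drawn here
  hap1 <- sum(sel$g1)
  expect_lt(abs(hap1 - n * 0.2), 3 * sqrt(n * 0.2 * 0.8))
  expect_warning(
    sample_noncommon_variants(db, "CAF", 0.01, paAF = 1.4, ploidy = pl),
    "clipped")
})

test_that("SNV alternate-allele choice realizes the configured Ti/Tv ratio", {
  set.seed(4)
  n <- 3e4
  alt <- choose_alt_snv(rep("A", n), titv = 2)
  freq <- table(alt) / n
  expect_lt(abs(freq[["G"]] - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / n))
  expect_lt(abs(freq[["C"]] - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / n))
  expect_lt(abs(freq[["T"]] - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / n))
  # near-infinite ratio: transitions only
  expect_true(all(choose_alt_snv(c("A", "C", "G", "T"), 1e9) ==
                  c("G", "T", "A", "C")))
  # aggregate recovery on balanced random reference bases
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt2 <- choose_alt_snv(ref, titv = 3)
  is_ti <- paste0(ref, alt2) %in% c("AG", "GA", "CT", "TC")
  expect_lt(abs(sum(is_ti) / sum(!is_ti) - 3), 0.15)
})

test_that("indel lengths follow the truncated discrete power law with folding", {
  # head mass against an independent summation oracle
  k <- 1:10000
  p1 <- 1 / sum(k^(-1.8))
  expect_equal(p1, 0.5315, tolerance = 1e-3)   # hand-checked magnitude
  set.seed(8)
  n <- 2e5
  L <- sample_indel_length(n, 1.8, NIDL = 10000)
  expect_lt(abs(mean(L == 1) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # folding: lengths never exceed NIDL, remainder 0 maps to NIDL
  NIDL <- 7L
  Lf <- sample_indel_length(n, 1.8, NIDL)
  expect_true(all(Lf >= 1 & Lf <= NIDL))
  # folded pmf from the raw pmf, independently recomputed
  raw <- k^(-1.8) / sum(k^(-1.8))
  folded <- vapply(1:NIDL, function(j) {
    idx <- k > NIDL & (k %% NIDL == j %% NIDL)
    sum(raw[k == j]) + sum(raw[idx])
  }, 0)
  gof <- chisq.test(tabulate(Lf, NIDL), p = folded)
  expect_gt(gof$p.value, 0.001)
  expect_error(sample_indel_length(10, 1.0, 50), "PLalpha")
})

test_that("the exponent is recoverable from sampled lengths by truncated-zeta MLE", {
  set.seed(12)
  L <- sample_indel_length(1e5, 1.8, NIDL = 10000)
  expect_lt(abs(fit_indel_exponent(L) - 1.8), 0.01)
  L2 <- sample_indel_length(1e5, 2.4, NIDL = 10000)
  expect_lt(abs(fit_indel_exponent(L2) - 2.4), 0.02)
})

test_that("frameshift retention keeps multiples of 3 and filters the rest at FSR", {
  set.seed(6)
  expect_true(all(retain_coding_indel(c(3L, 6L, 300L), FSR = 0)))
  n <- 5e4
  kept <- retain_coding_indel(rep(c(1L, 2L, 4L), length.out = n), FSR = 0.25)
  expect_lt(abs(mean(kept) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("novel instantiation obeys the indel rate and the heterozygosity rule", {
  rr <- random_reference(c(chr1 = 20000L), seed = 21)
  pl <- ploidy_model("female", "chr1")
  prm <- resolved_params(NIDR = 0)
  set.seed(31)
  pos <- data.frame(contig = "chr1", pos = sample.int(19000L, 2000L))
  v <- instantiate_novel(pos, "noncoding", prm, rr$ref, pl)
  expect_true(all(nchar(v$ref) == 1 & nchar(v$alt) == 1))   # NIDR=0: all SNVs
  expect_true(all(v$ref != v$alt))
  expect_true(all(v$g1 + v$g2 == 1L))                        # heterozygous
  expect_true(all(v$source == "novel_noncoding"))
  # reference alleles match the genome
  expect_identical(toupper(substring(rr$ref$chr["chr1"], v$pos, v$pos)), v$ref)

  prm2 <- resolved_params(NIDR = 1, NIDL = 12, FSR = 1)
  set.seed(32)
  v2 <- instantiate_novel(pos, "coding", prm2, rr$ref, pl)
  is_del <- nchar(v2$ref) > 1
  expect_true(all(xor(is_del, nchar(v2$alt) > 1)))           # indels only
  expect_true(all(v2$end - v2$pos == ifelse(is_del, nchar(v2$ref) - 1L, 0L)))
  # deletion ref strings match the genome including the anchor
  del <- v2[is_del, ]
  expect_identical(toupper(substring(rr$ref$chr["chr1"], del$pos, del$end)),
                   del$ref)
})

test_that("coding frameshift indels are filtered at FSR inside instantiation", {
  rr <- random_reference(c(chr1 = 50000L), seed = 22)
  pl <- ploidy_model("female", "chr1")
  set.seed(33)
  pos <- data.frame(contig = "chr1", pos = sample.int(49000L, 20000L))
  prm <- resolved_params(NIDR = 1, NIDL = 12, FSR = 0.2)
  v <- instantiate_novel(pos, "coding", prm, rr$ref, pl)
  len <- ifelse(nchar(v$ref) > 1, nchar(v$ref) - 1L, nchar(v$alt) - 1L)
  f <- sum(len %% 3 != 0)       # frameshifting retained
  nf <- sum(len %% 3 == 0)      # non-frameshifting (always retained)
  # candidate odds frameshift:non-frameshift from the folded pmf
  k <- 1:10000
  raw <- k^(-1.8) / sum(k^(-1.8))
  fold <- vapply(1:12, function(j)
    sum(raw[k <= 12 & k == j]) +
      sum(raw[k > 12 & (k %% 12 == j %% 12)]), 0)
  q <- sum(fold[(1:12) %% 3 != 0])
  fsr_hat <- (f / nf) * ((1 - q) / q)
  expect_lt(abs(fsr_hat - 0.2), 0.05)   # generous 3-sigma band
})

test_that("merging drops lower-priority and later conflicting variants", {
  mk <- function(contig, pos, end, src, id = ".") {
    v <- variants_empty()
    v[1, ] <- list(contig, pos, id, strrep("A", end - pos + 1), "G",
                   end, 1L, 0L, src, NA_character_)
    v
  }
  known <- mk("chr1", 100L, 100L, "known", "k1")
  novel <- mk("chr1", 100L, 100L, "novel_noncoding", "n1")
  m <- merge_variants(variants_empty(), known, novel)
  expect_equal(m$id, "k1")                       # known beats novel

  sv <- mk("chr1", 90L, 120L, "sv", "s1")
  m2 <- merge_variants(sv, known, novel)
  expect_equal(m2$id, "s1")                      # SV footprint displaces both

  a <- rbind(mk("chr1", 10L, 10L, "known", "a"),
             mk("chr1", 50L, 52L, "known", "b"),
             mk("chr2", 5L, 5L, "known", "c"))
  m3 <- merge_variants(variants_empty(), a, variants_empty(),
                       contig_order = c("chr1", "chr2"))
  expect_equal(m3$id, c("a", "b", "c"))          # disjoint: all retained, sorted

  # same tier: earlier position wins; exact ties drop the later-processed
  t1 <- rbind(mk("chr1", 20L, 25L, "known", "first"),
              mk("chr1", 22L, 22L, "known", "inside"),
              mk("chr1", 30L, 30L, "known", "tie1"),
              mk("chr1", 30L, 30L, "known", "tie2"))
  m4 <- merge_variants(variants_empty(), t1, variants_empty())
  expect_equal(m4$id, c("first", "tie1"))
})

test_that("VCF output round-trips and conforms to the standard", {
  fa <- write_fasta(c(">chr1", strrep("ACGT", 25)))
  gs <- scan_reference(fa)
  v <- variants_empty()
  v[1, ] <- list("chr1", 5L, ".", "A", "G", 5L, 1L, 0L, "novel_noncoding", NA)
  v[2, ] <- list("chr1", 10L, "rs1", "CG", "C", 11L, 1L, 1L, "known", NA)
  v[3, ] <- list("chr1", 40L, "sv1", "T", "<DEL>", 90L, 0L, 1L, "sv",
                 "SVTYPE=DEL;END=90")
  out <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, gs, out, gender = "female")
  back <- read_simulated_vcf(out)
  expect_equal(back[c("contig", "pos", "ref", "alt", "g1", "g2", "source")],
               v[c("contig", "pos", "ref", "alt", "g1", "g2", "source")])
  expect_identical(attr(back, "gender"), "female")
  # conformance: an independent VCF parser reads the same records
  vv <- vcfR::read.vcfR(out, verbose = FALSE)
  expect_equal(nrow(vv@fix), 3L)
  expect_equal(as.integer(vv@fix[, "POS"]), c(5L, 10L, 40L))
  expect_equal(unname(vv@gt[, "SIMULATED"]), c("1|0", "1|1", "0|1"))
  # header-only file for an empty variant set
  out2 <- tempfile(fileext = ".vcf")
  write_variants_vcf(variants_empty(), gs, out2)
  expect_equal(nrow(read_vcf_records(out2)), 0)
  # unsorted input violates the contract
  expect_error(write_variants_vcf(v[c(2, 1, 3), ], gs, tempfile()), "sorted")
})
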