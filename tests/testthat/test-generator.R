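# Haplotype construction and coordinate mapping.

mkvar <- function(contig, pos, ref, alt, g1, g2, src = "novel_noncoding") {
  data.frame(contig = contig, pos = pos, id = ".", ref = ref, alt = alt,
             end = pos + nchar(ref) - 1L, g1 = g1, g2 = g2, source = src,
             info = NA_character_, stringsAsFactors = FALSE)
}

test_that("a heterozygous SNV edits exactly one haplotype", {
  fa <- write_fasta(c(">c1", "ACGT"))
  ref <- load_reference(fa)
  v <- mkvar("c1", 2L, "C", "T", 1L, 0L)
  h1 <- apply_variants(ref, v, 1L)
  h2 <- apply_variants(ref, v, 2L)
  expect_equal(as.character(h1$seq[["c1_hap1"]]), "ATGT")
  expect_equal(as.character(h2$seq[["c1_hap2"]]), "ACGT")
})

test_that("deletions shorten the haplotype and shift downstream coordinates", {
  fa <- write_fasta(c(">c1", "ACGTACGTACGT"))
  ref <- load_reference(fa)
  # 3-bp deletion anchored at pos 4 (removes ref bases 5-7)
  v <- mkvar("c1", 4L, "TACG", "T", 1L, 1L)
  h <- apply_variants(ref, v, 1L)
  expect_equal(Biostrings::width(h$seq), 9L)
  expect_equal(as.character(h$seq[[1]]), "ACGTTACGT")
  expect_equal(map_coordinate(h$map, "c1", 10L), 7L)   # offset -3 after the gap
  expect_true(is.na(map_coordinate(h$map, "c1", 6L)))  # deleted base
  expect_equal(map_coordinate(h$map, "c1", 4L), 4L)    # anchor unmoved
})

test_that("insertions lengthen the haplotype and shift downstream coordinates", {
  fa <- write_fasta(c(">c1", "ACGTACGTACGT"))
  ref <- load_reference(fa)
  v <- mkvar("c1", 4L, "T", "TGG", 1L, 0L)   # 2-bp insertion after pos 4
  h <- apply_variants(ref, v, 1L)
  expect_equal(Biostrings::width(h$seq), 14L)
  expect_equal(map_coordinate(h$map, "c1", 10L), 12L)
  expect_equal(map_coordinate(h$map, "c1", 4L), 4L)
  expect_error(map_coordinate(h$map, "c1", 99L), "out of range")
})

test_that("zero variants give an identity haplotype and identity map", {
  fa <- write_fasta(c(">c1", "ACGTACGT"))
  ref <- load_reference(fa)
  h <- apply_variants(ref, mkvar("c1", 1L, "A", "G", 1L, 0L)[0, ], 1L)
  expect_equal(as.character(h$seq[[1]]), "ACGTACGT")
  expect_equal(map_coordinate(h$map, "c1", 17 %% 8), 17 %% 8)
  expect_equal(h$map$c1$blocks,
               data.frame(ref_start = 1L, hap_start = 1L, length = 8L))
})

test_that("contract violations are rejected with position context", {
  fa <- write_fasta(c(">c1", "ACGTACGT"))
  ref <- load_reference(fa)
  expect_error(apply_variants(ref, mkvar("c1", 2L, "G", "T", 1L, 0L), 1L),
               "c1:2")                                  # ref mismatch
  two <- rbind(mkvar("c1", 2L, "CGT", "C", 1L, 0L),
               mkvar("c1", 3L, "G", "A", 1L, 0L))
  expect_error(apply_variants(ref, two, 1L), "overlap")
})

test_that("SV records are ignored at sequence level", {
  fa <- write_fasta(c(">c1", "ACGTACGT"))
  ref <- load_reference(fa)
  v <- rbind(mkvar("c1", 2L, "C", "A", 1L, 1L),
             mkvar("c1", 5L, "A", "<DEL>", 1L, 1L, src = "sv"))
  h <- apply_variants(ref, v, 1L)
  expect_equal(as.character(h$seq[[1]]), "AAGTACGT")
})

test_that("round-trip: identity off edits, length conservation, edit recovery", {
  set.seed(77)
  for (rep in 1:25) {
    L <- sample(200:400, 1)
    rr <- random_reference(stats::setNames(L, "c1"))
    ref_str <- rr$ref$chr[["c1"]]
    # random disjoint variants: SNVs, deletions, insertions
    pos <- sort(sample(seq(5, L - 30, by = 12), sample(3:8, 1)))
    kind <- sample(c("snv", "del", "ins"), length(pos), replace = TRUE)
    vars <- do.call(rbind, lapply(seq_along(pos), function(i) {
      p <- pos[i]
      anchor <- substring(ref_str, p, p)
      if (kind[i] == "snv")
        mkvar("c1", p, anchor, setdiff(c("A", "C", "G", "T"), anchor)[1],
              1L, sample(0:1, 1))
      else if (kind[i] == "del") {
        k <- sample(1:5, 1)
        mkvar("c1", p, substring(ref_str, p, p + k), anchor, 1L, 0L)
      } else {
        k <- sample(1:5, 1)
        mkvar("c1", p, anchor,
              paste0(anchor, paste(sample(c("A", "C", "G", "T"), k,
                                          replace = TRUE), collapse = "")),
              1L, 0L)
      }
    }))
    h <- apply_variants(rr$ref, vars, 1L)
    hap_str <- as.character(h$seq[[1]])
    # length conservation
    delta <- sum(nchar(vars$alt) - nchar(vars$ref))
    expect_equal(nchar(hap_str), L + delta)
    # identity at unedited positions through the map
    edited <- unlist(Map(seq, vars$pos, vars$end))
    unedited <- setdiff(seq_len(L), edited)
    mapped <- map_coordinate(h$map, "c1", unedited)
    expect_false(anyNA(mapped))
    expect_identical(substring(hap_str, mapped, mapped),
                     substring(ref_str, unedited, unedited))
    # independent edit-script walk recovers exactly the applied variants
    rec <- recover_edits(ref_str, hap_str, h$map$c1)
    applied <- vars[order(vars$pos), c("pos", "ref", "alt")]
    rownames(applied) <- rownames(rec) <- NULL
    expect_equal(rec, applied)
  }
})

test_that("output files round-trip and route sex chromosomes per ploidy", {
  dirp <- tempfile(); dir.create(dirp)
  fa <- write_fasta(c(">chr1", strrep("ACGT", 30),
                      ">chrX", strrep("GGCA", 30),
                      ">chrY", strrep("TTAC", 30)))
  gs <- scan_reference(fa)
  v <- variants_empty()
  v[1, ] <- list("chr1", 3L, ".", "G", "A", 3L, 1L, 0L, "novel_noncoding", NA)
  vcf <- file.path(dirp, "m.vcf")
  write_variants_vcf(v, gs, vcf, gender = "male")
  out <- pg_generate(vcf, fa, file.path(dirp, "m"), quiet = TRUE)
  h1 <- Biostrings::readDNAStringSet(file.path(dirp, "m.hap1.fa"))
  h2 <- Biostrings::readDNAStringSet(file.path(dirp, "m.hap2.fa"))
  expect_setequal(names(h1), c("chr1_hap1", "chrX_hap1"))
  expect_setequal(names(h2), c("chr1_hap2", "chrY_hap2"))
  # re-read FASTA equals the in-memory haplotype, wrapped at 60 columns
  expect_equal(as.character(h1[["chr1_hap1"]]),
               as.character(out$hap1$seq[["chr1_hap1"]]))
  expect_lte(max(nchar(readLines(file.path(dirp, "m.hap1.fa")))), 60L)
  # map table parses and starts with an identity block for unedited chrX
  m1 <- read.delim(file.path(dirp, "m.hap1.map.tsv"))
  expect_equal(m1$length[m1$contig == "chrX"], 120L)
  # female: X on both haplotypes, no Y anywhere
  write_variants_vcf(v, gs, file.path(dirp, "f.vcf"), gender = "female")
  pg_generate(file.path(dirp, "f.vcf"), fa, file.path(dirp, "f"), quiet = TRUE)
  f2 <- Biostrings::readDNAStringSet(file.path(dirp, "f.hap2.fa"))
  expect_setequal(names(f2), c("chr1_hap2", "chrX_hap2"))
})
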