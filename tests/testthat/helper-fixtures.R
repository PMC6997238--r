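# Shared helpers: tiny in-code fixtures and independent oracles.

write_fasta <- function(lines, path = tempfile(fileext = ".fa")) {
  writeLines(lines, path)
  path
}

# Minimal VCF writer: `records` is a data.frame with columns
# chrom, pos, id, ref, alt, info (missing columns filled with ".").
write_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                      extra_header = character(), gz = FALSE) {
  for (col in c("id", "ref", "alt", "info"))
    if (is.null(records[[col]])) records[[col]] <- rep(".", nrow(records))
  hdr <- c("##fileformat=VCFv4.2", extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- if (nrow(records))
    paste(records$chrom, records$pos, records$id, records$ref, records$alt,
          ".", ".", records$info, sep = "\t") else character()
  if (gz) {
    if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
    con <- gzfile(path, "wt"); writeLines(c(hdr, body), con); close(con)
  } else writeLines(c(hdr, body), path)
  path
}

# Resolved parameters with overrides, for direct use of simulator operations.
resolved_params <- function(..., seed = 1) {
  resolve_parameters(parameter_set(...), seed = seed)
}

# A uniform random N-free reference: returns a pg_reference plus genome stats.
random_reference <- function(lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- if (is.null(names(lengths))) paste0("chr", seq_along(lengths))
         else names(lengths)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  fa <- write_fasta(unlist(Map(function(nm, s) c(paste0(">", nm), s), nms, seqs)))
  list(path = fa, ref = load_reference(fa), stats = scan_reference(fa))
}

empty_coding_model <- function() {
  structure(list(intervals = list(), modLen = 0), class = "pg_coding_model")
}

# Independent edit-script oracle: re-derive the non-SV variants applied to a
# haplotype from the reference string, the edited string and the block
# coordinate map, without consulting the variant list.
recover_edits <- function(ref_str, hap_str, map_contig) {
  b <- map_contig$blocks
  out <- list()
  for (i in seq_len(nrow(b))) {
    # SNVs inside the block: position-wise comparison
    rs <- substring(ref_str, b$ref_start[i], b$ref_start[i] + b$length[i] - 1L)
    hs <- substring(hap_str, b$hap_start[i], b$hap_start[i] + b$length[i] - 1L)
    rb <- strsplit(rs, "")[[1]]; hb <- strsplit(hs, "")[[1]]
    mm <- which(rb != hb)
    for (j in mm)
      out[[length(out) + 1L]] <- data.frame(
        pos = b$ref_start[i] + j - 1L, ref = rb[j], alt = hb[j])
    # indel between this block and the next
    if (i < nrow(b)) {
      ref_gap_from <- b$ref_start[i] + b$length[i]
      ref_gap_to <- b$ref_start[i + 1L] - 1L
      hap_gap_from <- b$hap_start[i] + b$length[i]
      hap_gap_to <- b$hap_start[i + 1L] - 1L
      anchor_ref <- b$ref_start[i] + b$length[i] - 1L
      anchor <- substring(hap_str, b$hap_start[i] + b$length[i] - 1L,
                          b$hap_start[i] + b$length[i] - 1L)
      if (ref_gap_to >= ref_gap_from) {      # deletion
        out[[length(out) + 1L]] <- data.frame(
          pos = anchor_ref,
          ref = substring(ref_str, anchor_ref, ref_gap_to),
          alt = anchor)
      } else {                               # insertion
        out[[length(out) + 1L]] <- data.frame(
          pos = anchor_ref,
          ref = substring(ref_str, anchor_ref, anchor_ref),
          alt = substring(hap_str, b$hap_start[i] + b$length[i] - 1L,
                          hap_gap_to))
      }
    }
  }
  if (!length(out))
    return(data.frame(pos = integer(), ref = character(), alt = character()))
  d <- do.call(rbind, out)
  d[order(d$pos), , drop = FALSE]
}

# Footprint-overlap scan for one haplotype of a simulated variant set.
count_hap_overlaps <- function(variants, hap) {
  allele <- ifelse(is.na(variants$g2), variants$g1,
                   if (hap == 1L) variants$g1 else variants$g2)
  v <- variants[allele == 1L, , drop = FALSE]
  total <- 0L
  for (nm in unique(v$contig)) {
    d <- v[v$contig == nm, , drop = FALSE]
    ir <- IRanges::IRanges(start = d$pos, end = d$end)
    total <- total + (sum(IRanges::countOverlaps(ir, ir)) - length(ir)) / 2L
  }
  total
}

# One shared mid-size fixture dataset per test run (built lazily).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "diplosim-shared-fixture")
      cache <<- fixture_dataset(dir, genome_length = 5e5, n_contigs = 2,
                                n_known = 2000, common_fraction = 0.3,
                                n_svs = 20, sv_overlap_fraction = 0.2,
                                n_pathogenic = 40, seed = 424242)
    }
    cache
  }
})
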