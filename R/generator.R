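# Generation stage.
#
# The phased variants are applied to the reference, producing one FASTA per
# haplotype plus a block-wise coordinate map. Structural variants are skipped
# at sequence level (curated SV records rarely carry exact breakpoint
# sequence), so coordinate offsets come from small indels only.

#' Load a reference genome for sequence editing
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return An object of class `pg_reference`: list with `dna` (a
#'   [Biostrings::DNAStringSet]) and `chr` (named character vector of the
#'   same sequences, used for fast substring access).
#' @export
load_reference <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna)))
    stop("duplicate contig name in '", path, "'")
  structure(list(dna = dna,
                 chr = stats::setNames(as.character(dna), names(dna))),
            class = "pg_reference")
}

#' Apply phased variants to the reference for one haplotype
#'
#' Edits every variant whose genotype carries the alternate allele on the
#' requested haplotype (haplotype 1 is the left allele of the phased GT;
#' hemizygous single-allele genotypes are applied whenever the contig is part
#' of this haplotype). Records with `source == "sv"` are skipped. Reference
#' alleles are verified against the reference sequence; a mismatch or an
#' overlapping footprint is an error.
#'
#' @param reference `pg_reference` from [load_reference()].
#' @param variants variant data.frame (columns `contig`, `pos`, `ref`, `alt`,
#'   `g1`, `g2`, `source`), e.g. from [read_simulated_vcf()].
#' @param hap_index 1 or 2.
#' @param contigs contig names to build (default: all contigs of the
#'   reference).
#' @return list with `seq` (a [Biostrings::DNAStringSet] of edited contigs)
#'   and `map` (a `pg_coordmap`).
#' @export
apply_variants <- function(reference, variants, hap_index, contigs = NULL) {
  stopifnot(hap_index %in% c(1L, 2L))
  if (is.null(contigs)) contigs <- names(reference$dna)
  seqs <- list()
  maps <- list()
  for (nm in contigs) {
    ref_len <- nchar(reference$chr[[nm]])
    v <- variants[variants$contig == nm & variants$source != "sv", , drop = FALSE]
    allele <- ifelse(is.na(v$g2), v$g1,
                     if (hap_index == 1L) v$g1 else v$g2)
    v <- v[allele == 1L, , drop = FALSE]
    if (nrow(v)) {
      v <- v[order(v$pos), , drop = FALSE]
      rl <- nchar(v$ref)
      ends <- v$pos + rl - 1L
      if (any(v$pos < 1L) || any(ends > ref_len))
        stop("variant footprint outside contig '", nm, "'")
      obs <- toupper(substring(reference$chr[[nm]], v$pos, ends))
      bad <- which(obs != toupper(v$ref))
      if (length(bad))
        stop("reference allele mismatch at ", nm, ":", v$pos[bad[1]],
             " (expected '", v$ref[bad[1]], "', reference has '",
             obs[bad[1]], "')")
      if (nrow(v) > 1L && any(v$pos[-1L] <= ends[-nrow(v)]))
        stop("overlapping variant footprints on contig '", nm,
             "' (merge contract violated)")
      seqs[[paste0(nm, "_hap", hap_index)]] <- Biostrings::replaceAt(
        reference$dna[[nm]],
        IRanges::IRanges(start = v$pos, end = ends),
        v$alt)
      maps[[nm]] <- .build_map(v$pos, rl, nchar(v$alt), ref_len)
    } else {
      seqs[[paste0(nm, "_hap", hap_index)]] <- reference$dna[[nm]]
      maps[[nm]] <- list(blocks = data.frame(ref_start = 1L, hap_start = 1L,
                                             length = ref_len),
                         ref_len = ref_len, hap_len = ref_len)
    }
  }
  list(seq = Biostrings::DNAStringSet(seqs),
       map = structure(maps, class = "pg_coordmap"))
}

# Block map for one contig given sorted, disjoint edits.
# Offsets change only at indels; the first min(rl, al) bases of an edit stay
# in place, inserted bases extend the haplotype after them, deleted reference
# bases fall outside every block.
.build_map <- function(pos, rl, al, ref_len) {
  blocks <- list()
  block_start <- 1L   # ref coordinate where the open block began
  offset <- 0L        # hap = ref + offset within the open block
  for (i in seq_along(pos)) {
    if (rl[i] == al[i]) next                    # substitution: no offset change
    keep <- min(rl[i], al[i])                   # shared left-anchored bases
    block_end <- pos[i] + keep - 1L             # last ref base of the open block
    next_start <- pos[i] + rl[i]                # first ref base after the edit
    if (block_end >= block_start)
      blocks[[length(blocks) + 1L]] <-
        c(block_start, block_start + offset, block_end - block_start + 1L)
    offset <- offset + (al[i] - rl[i])
    block_start <- next_start
  }
  if (block_start <= ref_len)
    blocks[[length(blocks) + 1L]] <-
      c(block_start, block_start + offset, ref_len - block_start + 1L)
  m <- do.call(rbind, blocks)
  blocks_df <- data.frame(ref_start = as.integer(m[, 1]),
                          hap_start = as.integer(m[, 2]),
                          length = as.integer(m[, 3]))
  list(blocks = blocks_df, ref_len = as.integer(ref_len),
       hap_len = as.integer(ref_len + sum(al - rl)))
}

#' Map a reference coordinate to a haplotype coordinate
#'
#' @param cm `pg_coordmap` from [apply_variants()].
#' @param contig contig name.
#' @param ref_pos 1-based reference position(s).
#' @return integer vector of haplotype positions; `NA` where the reference
#'   base was deleted on this haplotype.
#' @export
#' @examples
#' # identity map on an unedited contig maps every position to itself
map_coordinate <- function(cm, contig, ref_pos) {
  m <- cm[[contig]]
  if (is.null(m)) stop("unknown contig '", contig, "'")
  if (any(ref_pos < 1L) || any(ref_pos > m$ref_len))
    stop("reference position out of range for contig '", contig, "'")
  b <- m$blocks
  idx <- findInterval(ref_pos, b$ref_start)
  hap <- rep(NA_integer_, length(ref_pos))
  inb <- idx > 0L & ref_pos < b$ref_start[pmax(idx, 1L)] + b$length[pmax(idx, 1L)]
  hap[inb] <- b$hap_start[idx[inb]] + (ref_pos[inb] - b$ref_start[idx[inb]])
  hap
}

#' Read a simulated VCF back into a variant data.frame
#'
#' Parses diplosim's own output (or any single-sample VCF with phased `GT`)
#' into the internal variant schema, recovering the `SRC` source tag and the
#' per-haplotype alleles.
#'
#' @param path VCF path.
#' @return variant data.frame; also carries the `gender` recorded in the
#'   header (attribute `gender`, may be `NA`).
#' @export
read_simulated_vcf <- function(path) {
  con <- open_text_input(path)
  hdr <- character()
  repeat {
    l <- readLines(con, n = 200L, warn = FALSE)
    if (!length(l)) break
    hdr <- c(hdr, l[startsWith(l, "##")])
    if (!all(startsWith(l, "#"))) break
  }
  close(con)
  gender <- sub("^##diplosim_gender=", "", grep("^##diplosim_gender=", hdr, value = TRUE))
  rec <- read_vcf_records(path)
  src_map <- c(COMMON = "common", KNOWN = "known", NOVEL_CD = "novel_coding",
               NOVEL_NC = "novel_noncoding", SV = "sv", PATHO = "pathogenic")
  src <- info_tag_value(rec$info, "SRC")
  source <- unname(src_map[src])
  source[is.na(source)] <- "known"
  gt <- if ("gt" %in% names(rec)) rec$gt else rep("1|1", nrow(rec))
  parts <- strsplit(gt, "|", fixed = TRUE)
  g1 <- as.integer(vapply(parts, `[[`, "", 1L))
  g2 <- as.integer(vapply(parts, function(x)
    if (length(x) >= 2L) x[2L] else NA_character_, ""))
  out <- data.frame(contig = rec$chrom, pos = rec$pos, id = rec$id,
                    ref = rec$ref, alt = rec$alt,
                    end = rec$pos + nchar(rec$ref) - 1L,
                    g1 = g1, g2 = g2, source = source, info = rec$info,
                    stringsAsFactors = FALSE)
  attr(out, "gender") <- if (length(gender)) gender else NA_character_
  out
}

#' Write haplotype FASTA files and coordinate maps
#'
#' Writes `<prefix>.hap1.fa` and `<prefix>.hap2.fa` (wrapped at 60 columns,
#' headers `<contig>_hap1` / `<contig>_hap2`) and the block coordinate maps
#' `<prefix>.hap1.map.tsv` / `<prefix>.hap2.map.tsv` (columns `contig`,
#' `ref_start`, `hap_start`, `length`).
#'
#' @param hap1,hap2 results of [apply_variants()] for haplotypes 1 and 2.
#' @param prefix output path prefix.
#' @return invisible character vector of the four file paths.
#' @export
write_outputs <- function(hap1, hap2, prefix) {
  paths <- c(paste0(prefix, ".hap1.fa"), paste0(prefix, ".hap2.fa"),
             paste0(prefix, ".hap1.map.tsv"), paste0(prefix, ".hap2.map.tsv"))
  Biostrings::writeXStringSet(hap1$seq, paths[1], width = 60L)
  Biostrings::writeXStringSet(hap2$seq, paths[2], width = 60L)
  for (i in 1:2) {
    m <- list(hap1, hap2)[[i]]$map
    tab <- do.call(rbind, lapply(names(m), function(nm)
      cbind(contig = nm, m[[nm]]$blocks)))
    if (is.null(tab))
      tab <- data.frame(contig = character(), ref_start = integer(),
                        hap_start = integer(), length = integer())
    utils::write.table(tab, paths[2 + i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
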