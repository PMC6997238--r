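# Streaming VCF access.
#
# Database scans must be single-pass and memory-bounded: national-scale variant
# databases (dbSNP-sized, 1e8+ records) cannot be held in memory. Records are
# therefore read through a connection in fixed-size line chunks and handed to a
# callback as a minimal 8-column data.frame. Whole-file readers (used only for
# the small structural/pathogenic databases and diplosim's own output) build on
# the same chunk reader.

.vcf_chunk_lines <- 20000L

# A connection that transparently reads gzip or plain text.
open_text_input <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "': no such file")
  gzfile(path, open = "rt")
}

# Split raw VCF data lines into the first 8 mandatory columns.
vcf_split_fields <- function(lines) {
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:8)
  if (length(f) < 8L) f <- c(f, rep(list(rep(NA_character_, length(lines))), 8L - length(f)))
  names(f) <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "info")
  f$pos <- as.integer(f$pos)
  data.table::setDF(f)
  f
}

#' Stream a VCF file chunk-by-chunk
#'
#' Reads a (possibly gzip/bgzip-compressed) VCF sequentially and calls
#' `callback(records)` once per chunk with a data.frame of the 8 mandatory
#' columns (`chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `filter`, `info`).
#' Only one chunk is in memory at a time.
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`).
#' @param callback function of one argument, called per chunk.
#' @param chunk_lines lines per chunk.
#' @return invisible count of data records seen.
#' @keywords internal
vcf_stream <- function(path, callback, chunk_lines = .vcf_chunk_lines) {
  con <- open_text_input(path)
  on.exit(close(con))
  n <- 0L
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (!length(lines)) break
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines)) {
      n <- n + length(lines)
      callback(vcf_split_fields(lines))
    }
  }
  invisible(n)
}

#' Read an entire (small) VCF into a data.frame
#'
#' Intended for diplosim's own output and for the structural/pathogenic
#' databases, which are orders of magnitude smaller than the known-variant
#' databases. Genotypes of the first sample, if present, are returned in a
#' `gt` column.
#'
#' @param path VCF file path.
#' @return data.frame with columns chrom, pos, id, ref, alt, qual, filter,
#'   info and (when a sample column exists) format, gt.
#' @export
read_vcf_records <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(data)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = character(),
                      filter = character(), info = character(),
                      stringsAsFactors = FALSE))
  }
  out <- vcf_split_fields(data)
  extra <- data.table::tstrsplit(data, "\t", fixed = TRUE)
  if (length(extra) >= 10L) {
    out$format <- extra[[9L]]
    out$gt <- extra[[10L]]
  }
  out
}

# Extract the raw value of an INFO tag; NA when the tag is absent.
# Flag-style tags (present without '=') yield "".
info_tag_value <- function(info, tag) {
  pat <- paste0("(?:^|;)", tag, "(?:=([^;]*))?(?:;|$)")
  m <- regexec(pat, info)
  vapply(regmatches(info, m), function(g) {
    if (length(g) == 0L) NA_character_ else g[2L]
  }, "")
}

# Parse background-population allele frequencies out of INFO tag values.
#
# Two dialects:
#   * plain alt-AF tags ("EUR_AF=0.12" or "EUR_AF=0.1,0.2" for multi-allelic
#     records): every element is an alt allele frequency;
#   * dbSNP "CAF"-style lists ("CAF=0.9,0.1"): the first element is the
#     reference allele frequency and is dropped.
# The dialect is keyed on the tag name being "CAF". Returns a list of numeric
# alt-AF vectors; entries that are absent or unparseable are NULL (absent) or
# NA (malformed).
parse_alt_af <- function(info, tag) {
  raw <- info_tag_value(info, tag)
  parts <- strsplit(raw, ",", fixed = TRUE)
  caf <- identical(tag, "CAF")
  lapply(seq_along(raw), function(i) {
    if (is.na(raw[i])) return(NULL)
    v <- suppressWarnings(as.numeric(sub("^\\.$", "NA", parts[[i]])))
    if (caf) v <- v[-1L]
    if (!length(v) || all(is.na(v))) return(NA_real_)
    v[is.na(v)] <- 0  # "." placeholders inside a multi-allelic list
    v
  })
}

# Standard VCF header for diplosim output.
vcf_header_lines <- function(contigs, sample_name, gender = NULL) {
  c("##fileformat=VCFv4.2",
    paste0("##source=diplosim-", as.character(utils::packageVersion("diplosim"))),
    if (!is.null(gender)) paste0("##diplosim_gender=", gender),
    sprintf("##contig=<ID=%s,length=%d>", contigs$name, contigs$length),
    paste0("##INFO=<ID=SRC,Number=1,Type=String,",
           "Description=\"Variant source: COMMON, KNOWN, NOVEL_CD, NOVEL_NC, SV or PATHO\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
}
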