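# Database scanning.
#
# The planner needs a handful of whole-database statistics (reference length
# and N content, coding length, known/common record counts, total common AF
# mass). All scans are sequential single passes over the (possibly gzipped)
# input so memory stays bounded regardless of database size, and results are
# cached next to the database in a "<file>.pgstat" text file so repeat runs
# skip the scan entirely.

.iupac_chars <- "ACGTURYSWKMBDHVNacgturyswkmbdhvn"

#' Scan a reference genome FASTA
#'
#' Streams the FASTA (plain or gzip-compressed), recording per-contig lengths,
#' the total length (`GLN`), the number of `N`/`n` bases (`nGLN`) and the
#' positions of all N-runs. N-runs mark unmeasured regions (telomeres,
#' centromeres) in which no variant may be placed.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return An object of class `pg_genome_stats`: list with `GLN`, `nGLN`,
#'   `contigs` (data.frame `name`, `length`) and `n_blocks` (named list of
#'   data.frames `start`, `end`, 0-based half-open intervals).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTNNAC"), fa)
#' gs <- scan_reference(fa)
#' gs$GLN   # 8
#' gs$nGLN  # 2
scan_reference <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))

  contig <- NULL
  contig_names <- character()
  contig_lengths <- integer()
  runs <- list()          # per-contig list of 2-col matrices (0-based half-open)
  cur_len <- 0L           # bases seen so far in current contig
  open_run <- NA_integer_ # 0-based start of an N-run still open at cur_len

  finish_contig <- function() {
    if (is.null(contig)) return()
    if (!is.na(open_run)) {
      runs[[contig]] <<- c(runs[[contig]], list(c(open_run, cur_len)))
      open_run <<- NA_integer_
    }
    contig_names <<- c(contig_names, contig)
    contig_lengths <<- c(contig_lengths, cur_len)
  }

  add_segment <- function(seg) {
    if (!nzchar(seg)) return()
    bad <- regmatches(seg, regexpr(paste0("[^", .iupac_chars, "]"), seg))
    if (length(bad) && nzchar(bad))
      stop("non-IUPAC character '", bad, "' in contig '", contig, "'")
    m <- gregexpr("[Nn]+", seg)[[1]]
    if (m[1] != -1L) {
      starts <- as.integer(m) - 1L + cur_len            # 0-based
      ends <- starts + attr(m, "match.length")
      if (!is.na(open_run) && starts[1] == cur_len) {
        starts[1] <- open_run
      } else if (!is.na(open_run)) {
        runs[[contig]] <<- c(runs[[contig]], list(c(open_run, cur_len)))
      }
      open_run <<- NA_integer_
      nlen <- cur_len + nchar(seg)
      if (ends[length(ends)] == nlen) {
        open_run <<- starts[length(starts)]
        starts <- starts[-length(starts)]
        ends <- ends[-length(ends)]
      }
      if (length(starts))
        runs[[contig]] <<- c(runs[[contig]], Map(c, starts, ends))
    } else if (!is.na(open_run)) {
      runs[[contig]] <<- c(runs[[contig]], list(c(open_run, cur_len)))
      open_run <<- NA_integer_
    }
    cur_len <<- cur_len + nchar(seg)
  }

  saw_any <- FALSE
  repeat {
    lines <- readLines(con, n = 5000L, warn = FALSE)
    if (!length(lines)) break
    saw_any <- TRUE
    is_hdr <- startsWith(lines, ">")
    bounds <- c(which(is_hdr), length(lines) + 1L)
    # leading sequence lines continue the current contig
    lead_end <- if (length(which(is_hdr))) which(is_hdr)[1] - 1L else length(lines)
    if (lead_end >= 1L) {
      if (is.null(contig) && any(nzchar(trimws(lines[seq_len(lead_end)]))))
        stop("sequence data before first FASTA header in '", path, "'")
      if (!is.null(contig))
        add_segment(paste(lines[seq_len(lead_end)], collapse = ""))
    }
    hdr_idx <- which(is_hdr)
    for (j in seq_along(hdr_idx)) {
      finish_contig()
      contig <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr_idx[j]])
      if (contig %in% contig_names || !is.null(runs[[contig]]) && contig %in% contig_names)
        stop("duplicate contig name '", contig, "' in '", path, "'")
      if (contig %in% contig_names)
        stop("duplicate contig name '", contig, "'")
      cur_len <- 0L
      runs[[contig]] <- list()
      seg_to <- bounds[match(hdr_idx[j], bounds) + 1L] - 1L
      if (seg_to > hdr_idx[j])
        add_segment(paste(lines[(hdr_idx[j] + 1L):seg_to], collapse = ""))
    }
  }
  finish_contig()
  if (!saw_any || !length(contig_names))
    stop("empty or headerless FASTA: '", path, "'")
  if (anyDuplicated(contig_names))
    stop("duplicate contig name '", contig_names[duplicated(contig_names)][1], "'")

  n_blocks <- lapply(contig_names, function(nm) {
    rr <- runs[[nm]]
    if (!length(rr))
      return(data.frame(start = integer(), end = integer()))
    m <- do.call(rbind, rr)
    data.frame(start = m[, 1], end = m[, 2])
  })
  names(n_blocks) <- contig_names
  structure(list(
    GLN = sum(as.numeric(contig_lengths)),
    nGLN = sum(vapply(n_blocks, function(b) sum(as.numeric(b$end - b$start)), 0)),
    contigs = data.frame(name = contig_names, length = contig_lengths,
                         stringsAsFactors = FALSE),
    n_blocks = n_blocks
  ), class = "pg_genome_stats")
}

#' Scan a coding-region BED file
#'
#' The coding model must be non-overlapping BED; only the first three columns
#' are used. Intervals are validated (start < end, no overlap within a
#' contig) and their total length (`modLen`) computed.
#'
#' @param path BED file (0-based half-open intervals).
#' @param genome optional `pg_genome_stats`; when given, contig names must
#'   resolve against it and intervals must lie within contig bounds.
#' @return An object of class `pg_coding_model`: list with `intervals` (named
#'   list of data.frames `start`, `end`, 0-based half-open, sorted) and
#'   `modLen`.
#' @export
scan_coding_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("cannot open '", path, "': no such file")
  lines <- readLines(open_text_input(path) -> con, warn = FALSE)
  close(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(structure(list(intervals = list(), modLen = 0),
                     class = "pg_coding_model"))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:3)
  if (length(f) < 3L || anyNA(f[[2L]]) || anyNA(f[[3L]]))
    stop("BED file '", path, "' must have at least 3 columns")
  bed <- data.frame(chrom = f[[1L]],
                    start = suppressWarnings(as.integer(f[[2L]])),
                    end = suppressWarnings(as.integer(f[[3L]])),
                    stringsAsFactors = FALSE)
  if (anyNA(bed$start) || anyNA(bed$end))
    stop("non-numeric BED coordinates in '", path, "'")
  if (any(bed$start < 0L)) stop("negative BED start in '", path, "'")
  if (any(bed$start >= bed$end))
    stop("BED interval with start >= end in '", path, "'")
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  intervals <- split(bed[c("start", "end")], bed$chrom)
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    rownames(iv) <- NULL
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("overlapping coding intervals on contig '", nm,
           "'; the coding BED must be non-overlapping")
    intervals[[nm]] <- iv
  }
  if (!is.null(genome)) {
    missing <- setdiff(names(intervals), genome$contigs$name)
    if (length(missing))
      stop("BED contig(s) not present in reference: ",
           paste(missing, collapse = ", "))
    for (nm in names(intervals)) {
      clen <- genome$contigs$length[genome$contigs$name == nm]
      if (any(intervals[[nm]]$end > clen))
        stop("BED interval beyond end of contig '", nm, "'")
    }
  }
  structure(list(intervals = intervals,
                 modLen = sum(vapply(intervals,
                                     function(iv) sum(as.numeric(iv$end - iv$start)), 0))),
            class = "pg_coding_model")
}

#' Scan the known-variant database
#'
#' Counts data records (`varNum`); one VCF line is one known variant
#' regardless of how many alternate alleles it lists.
#'
#' @param path VCF file, optionally gzip-compressed.
#' @return An object of class `pg_vardb_stats` with field `varNum`.
#' @export
scan_known_db <- function(path) {
  n <- vcf_stream(path, function(chunk) NULL)
  structure(list(varNum = as.numeric(n), cvNum = NA_real_, ecvNum = NA_real_,
                 pop_tag = NA_character_, CVT = NA_real_),
            class = "pg_vardb_stats")
}

#' Scan the common-variant database
#'
#' A record qualifies as common when the alternate-allele frequency of the
#' background population (summed over alternate alleles for multi-allelic
#' records) is at least `CVT`. Returns the number of qualifying records
#' (`cvNum`) and the sum of their qualifying alternate allele frequencies
#' (`ecvNum`), which is the expected number of common variants carried by one
#' haploid genome drawn from that population.
#'
#' @param path VCF file whose INFO field carries `pop_tag`.
#' @param pop_tag INFO tag holding the background-population AF (the `CAF`
#'   tag uses the dbSNP convention that the first value is the reference
#'   allele frequency; any other tag is read as plain alt-allele AFs).
#' @param CVT common-variant AF threshold (default 0.01).
#' @return An object of class `pg_vardb_stats` with fields `cvNum`, `ecvNum`
#'   (plus the `pop_tag`/`CVT` used).
#' @export
scan_common_db <- function(path, pop_tag, CVT = 0.01) {
  cvNum <- 0
  ecvNum <- 0
  n_tagged <- 0L
  n_malformed <- 0L
  n_records <- vcf_stream(path, function(chunk) {
    afs <- parse_alt_af(chunk$info, pop_tag)
    present <- !vapply(afs, is.null, TRUE)
    n_tagged <<- n_tagged + sum(present)
    sums <- vapply(afs, function(a) if (is.null(a)) NA_real_ else sum(a), 0)
    malformed <- present & is.na(sums)
    n_malformed <<- n_malformed + sum(malformed)
    ok <- present & !is.na(sums)
    q <- ok & sums >= CVT
    cvNum <<- cvNum + sum(q)
    ecvNum <<- ecvNum + sum(sums[q])
  })
  if (n_records > 0L && n_tagged == 0L)
    stop("INFO tag '", pop_tag, "' absent from every record in '", path, "'")
  if (n_malformed > 0L)
    warning(n_malformed, " record(s) with malformed '", pop_tag,
            "' values skipped in '", path, "'")
  structure(list(varNum = NA_real_, cvNum = cvNum, ecvNum = ecvNum,
                 pop_tag = pop_tag, CVT = CVT),
            class = "pg_vardb_stats")
}

# ---- pgstat caching ---------------------------------------------------------

pgstat_path <- function(db_path) paste0(db_path, ".pgstat")

#' Write scan statistics to a pgstat cache file
#'
#' The cache lives next to the database as `<database>.pgstat` (plain
#' `key<TAB>value` text) and lets later runs skip the scan.
#'
#' @param stats a `pg_genome_stats`, `pg_coding_model` or `pg_vardb_stats`.
#' @param db_path path of the scanned database file.
#' @return invisible cache path.
#' @export
write_pgstat <- function(stats, db_path) {
  out <- pgstat_path(db_path)
  num <- function(x) sprintf("%.17g", x)
  lines <- if (inherits(stats, "pg_genome_stats")) {
    c("type\tgenome",
      paste0("GLN\t", num(stats$GLN)),
      paste0("nGLN\t", num(stats$nGLN)),
      sprintf("contig\t%s\t%d", stats$contigs$name, stats$contigs$length),
      unlist(lapply(stats$contigs$name, function(nm) {
        b <- stats$n_blocks[[nm]]
        if (!nrow(b)) character() else sprintf("nblock\t%s\t%d\t%d", nm, b$start, b$end)
      })))
  } else if (inherits(stats, "pg_coding_model")) {
    c("type\tcoding",
      paste0("modLen\t", num(stats$modLen)),
      unlist(lapply(names(stats$intervals), function(nm) {
        iv <- stats$intervals[[nm]]
        sprintf("interval\t%s\t%d\t%d", nm, iv$start, iv$end)
      })))
  } else if (inherits(stats, "pg_vardb_stats")) {
    c("type\tvardb",
      paste0("varNum\t", num(stats$varNum)),
      paste0("cvNum\t", num(stats$cvNum)),
      paste0("ecvNum\t", num(stats$ecvNum)),
      paste0("pop_tag\t", stats$pop_tag),
      paste0("CVT\t", num(stats$CVT)))
  } else stop("unsupported statistics object of class ", class(stats)[1])
  writeLines(lines, out)
  invisible(out)
}

#' Read scan statistics back from a pgstat cache
#'
#' Returns `NULL` ("absent") when no cache exists or when the cache is older
#' than the database file (stale), in which case the caller rescans.
#'
#' @param db_path path of the database file whose cache to read.
#' @return the cached statistics object, or `NULL`.
#' @export
read_pgstat <- function(db_path) {
  cache <- pgstat_path(db_path)
  if (!file.exists(cache)) return(NULL)
  if (file.exists(db_path) && file.mtime(cache) < file.mtime(db_path))
    return(NULL)
  lines <- readLines(cache, warn = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(f, `[[`, "", 1L)
  val1 <- vapply(f, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
  type <- val1[key == "type"][1]
  get1 <- function(k) {
    v <- val1[key == k][1]
    if (is.na(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  if (identical(type, "genome")) {
    ci <- which(key == "contig")
    contigs <- data.frame(name = vapply(f[ci], `[[`, "", 2L),
                          length = as.integer(vapply(f[ci], `[[`, "", 3L)),
                          stringsAsFactors = FALSE)
    nb <- lapply(contigs$name, function(nm) data.frame(start = integer(), end = integer()))
    names(nb) <- contigs$name
    for (x in f[key == "nblock"]) {
      nb[[x[2L]]] <- rbind(nb[[x[2L]]],
                           data.frame(start = as.integer(x[3L]), end = as.integer(x[4L])))
    }
    structure(list(GLN = get1("GLN"), nGLN = get1("nGLN"),
                   contigs = contigs, n_blocks = nb),
              class = "pg_genome_stats")
  } else if (identical(type, "coding")) {
    ii <- f[key == "interval"]
    nms <- unique(vapply(ii, `[[`, "", 2L))
    intervals <- lapply(nms, function(nm) {
      sel <- ii[vapply(ii, `[[`, "", 2L) == nm]
      data.frame(start = as.integer(vapply(sel, `[[`, "", 3L)),
                 end = as.integer(vapply(sel, `[[`, "", 4L)))
    })
    names(intervals) <- nms
    structure(list(intervals = intervals, modLen = get1("modLen")),
              class = "pg_coding_model")
  } else if (identical(type, "vardb")) {
    structure(list(varNum = get1("varNum"), cvNum = get1("cvNum"),
                   ecvNum = get1("ecvNum"),
                   pop_tag = val1[key == "pop_tag"][1], CVT = get1("CVT")),
              class = "pg_vardb_stats")
  } else {
    NULL  # unrecognized cache: treat as absent
  }
}

# Scan with cache: returns stats, using a valid pgstat file when present.
# For the common database the cache must additionally match pop_tag and CVT.
scan_cached <- function(kind, path, pop_tag = NULL, CVT = NULL,
                        genome = NULL, quiet = FALSE) {
  cached <- read_pgstat(path)
  ok <- !is.null(cached) && switch(kind,
    genome = inherits(cached, "pg_genome_stats"),
    coding = inherits(cached, "pg_coding_model"),
    known  = inherits(cached, "pg_vardb_stats") && !is.na(cached$varNum),
    common = inherits(cached, "pg_vardb_stats") && !is.na(cached$cvNum) &&
             identical(cached$pop_tag, pop_tag) &&
             isTRUE(all.equal(cached$CVT, CVT))
  )
  if (ok) {
    if (!quiet) message("[diplosim] cache hit: ", pgstat_path(path))
    return(cached)
  }
  stats <- switch(kind,
    genome = scan_reference(path),
    coding = scan_coding_bed(path, genome = genome),
    known  = scan_known_db(path),
    common = scan_common_db(path, pop_tag = pop_tag, CVT = CVT)
  )
  write_pgstat(stats, path)
  stats
}
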