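# Synthetic test data.
#
# Builds complete miniature input datasets — reference FASTA with planted N
# runs, a non-overlapping coding BED, and the four variant databases — with
# known ground truth, so every pipeline stage can be exercised and calibrated
# without external downloads. Fixture reference alleles always match the
# planted reference sequence.

#' Generate a synthetic reference genome and coding BED
#'
#' Contigs are uniform random A/C/G/T. Each contig carries one planted N run
#' (totalling exactly `round(n_fraction * length)` N bases genome-wide)
#' placed in its first half, and its coding intervals are laid out in the
#' second half so coding sequence is never N.
#'
#' @param dir output directory (created if needed).
#' @param genome_length total genome length in bp.
#' @param n_contigs number of contigs (named `chr1`, `chr2`, ...).
#' @param n_fraction fraction of the genome planted as N runs.
#' @param coding_fraction fraction of the genome covered by coding intervals.
#' @param intervals_per_contig coding intervals per contig.
#' @param seed integer seed.
#' @return list with `fasta`, `bed` (paths) and `truth` (planted `GLN`,
#'   `nGLN`, `modLen`, per-contig N blocks and coding intervals).
#' @export
fixture_reference <- function(dir, genome_length = 1e6, n_contigs = 2,
                              n_fraction = 0.01, coding_fraction = 0.02,
                              intervals_per_contig = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(genome_length >= n_contigs * 1000)
  base_len <- floor(genome_length / n_contigs)
  lens <- rep(base_len, n_contigs)
  lens[n_contigs] <- genome_length - base_len * (n_contigs - 1)
  nms <- paste0("chr", seq_len(n_contigs))

  n_blocks <- list()
  intervals <- list()
  seqs <- character(n_contigs)
  for (i in seq_len(n_contigs)) {
    L <- lens[i]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # one N run in the first half of the contig
    n_len <- round(n_fraction * L)
    if (n_len > 0) {
      n_start0 <- sample.int(max(1L, floor(L / 2) - n_len - 10L), 1L) + 5L
      s[(n_start0 + 1):(n_start0 + n_len)] <- "N"
      n_blocks[[nms[i]]] <- data.frame(start = n_start0,
                                       end = n_start0 + n_len)
    } else {
      n_blocks[[nms[i]]] <- data.frame(start = integer(), end = integer())
    }
    # coding intervals, evenly spaced over the second half
    cod_total <- round(coding_fraction * L)
    k <- intervals_per_contig
    if (cod_total > 0 && k > 0) {
      iv_len <- floor(cod_total / k)
      lens_iv <- rep(iv_len, k)
      lens_iv[k] <- cod_total - iv_len * (k - 1)
      region_start <- ceiling(L / 2)
      gap <- floor((L - region_start - cod_total) / (k + 1))
      starts <- region_start + gap + c(0, cumsum(lens_iv[-k] + gap))
      intervals[[nms[i]]] <- data.frame(start = as.integer(starts),
                                        end = as.integer(starts + lens_iv))
    } else {
      intervals[[nms[i]]] <- data.frame(start = integer(), end = integer())
    }
    seqs[i] <- paste(s, collapse = "")
  }
  fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- nms
  Biostrings::writeXStringSet(dna, fasta, width = 60L)
  bed <- file.path(dir, "coding.bed")
  bed_df <- do.call(rbind, lapply(nms, function(nm)
    if (nrow(intervals[[nm]]))
      data.frame(chrom = nm, start = intervals[[nm]]$start,
                 end = intervals[[nm]]$end)
    else NULL))
  if (is.null(bed_df)) {
    file.create(bed)
  } else {
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(fasta = fasta, bed = bed,
       truth = list(
         GLN = genome_length,
         nGLN = sum(vapply(n_blocks, function(b)
           sum(as.numeric(b$end - b$start)), 0)),
         modLen = sum(vapply(intervals, function(iv)
           sum(as.numeric(iv$end - iv$start)), 0)),
         contigs = data.frame(name = nms, length = lens,
                              stringsAsFactors = FALSE),
         n_blocks = n_blocks, intervals = intervals, seqs = stats::setNames(seqs, nms)))
}

# Draw n distinct positions whose reference base is A/C/G/T, uniformly over
# the genome, excluding positions already in `used` (a character key set).
.fixture_positions <- function(truth, n, used = character()) {
  if (n == 0)
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      stringsAsFactors = FALSE))
  out <- NULL
  lens <- truth$contigs$length
  starts <- c(1, head(cumsum(as.numeric(lens)), -1) + 1)
  for (iter in seq_len(200L)) {
    need <- n - if (is.null(out)) 0L else nrow(out)
    if (need <= 0L) break
    g <- sample.int(truth$GLN, ceiling(need * 1.3))
    idx <- findInterval(g, starts)
    contig <- truth$contigs$name[idx]
    pos <- as.integer(g - starts[idx] + 1)
    base <- toupper(substring(truth$seqs[contig], pos, pos))
    ok <- base %in% c("A", "C", "G", "T")
    cand <- data.frame(contig = contig[ok], pos = pos[ok], ref = base[ok],
                       stringsAsFactors = FALSE)
    key <- paste(cand$contig, cand$pos)
    cand <- cand[!key %in% used & !duplicated(key), , drop = FALSE]
    used <- c(used, paste(cand$contig, cand$pos))
    out <- rbind(out, cand)
  }
  if (is.null(out) || nrow(out) < n)
    stop("fixture genome too small for the requested number of variants")
  out[seq_len(n), , drop = FALSE]
}

.write_fixture_vcf <- function(path, df, extra_header = character()) {
  hdr <- c("##fileformat=VCFv4.2", extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- if (nrow(df))
    paste(df$contig, df$pos, df$id, df$ref, df$alt, ".", ".", df$info,
          sep = "\t")
  else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Generate the four synthetic variant databases
#'
#' Builds a known-variant VCF (common and rare SNVs with a background AF tag),
#' the common-variant VCF (the records of the common group; with default AF
#' ranges all of them qualify at `CVT`), a structural-variant VCF (deletions
#' with `END`/`SVLEN`, including a controlled number of overlapping pairs)
#' and a ClinVar-style pathogenic VCF with a configurable class mix. All ref
#' alleles match the fixture reference. Returns the planted ground truth.
#'
#' @param dir output directory.
#' @param truth `truth` element returned by [fixture_reference()].
#' @param n_known number of known-variant records.
#' @param common_fraction fraction of known records in the common group.
#' @param af_common AF range (uniform) of common-group records. The default
#'   keeps the common database's total AF mass well above the requested
#'   common count at the default simulation scale, so corrected inclusion
#'   probabilities stay below 1 (the regime real genome-scale databases are
#'   in).
#' @param af_rare AF range of rare records (below the default `CVT`).
#' @param pop_tag background-population AF tag to write (`CAF` uses the
#'   dbSNP convention: first value is the reference AF).
#' @param n_svs number of SV records.
#' @param sv_overlap_fraction fraction of SV records planted as overlappers
#'   of another record (each reduces the group count by one).
#' @param n_pathogenic number of disease-db records.
#' @param pathogenic_fraction fraction of disease-db records with
#'   Pathogenic/Likely_pathogenic clinical significance.
#' @param CVT threshold used to compute the truth `cvNum`/`ecvNum`.
#' @param seed integer seed.
#' @return list of database paths plus `truth` (varNum, cvNum, ecvNum,
#'   sv_groups, n_qualifying_pathogenic, and the per-record AF table).
#' @export
fixture_variant_dbs <- function(dir, truth, n_known = 1000,
                                common_fraction = 0.2,
                                af_common = c(0.30, 0.50),
                                af_rare = c(1e-4, 0.009),
                                pop_tag = "CAF",
                                n_svs = 0, sv_overlap_fraction = 0,
                                n_pathogenic = 0, pathogenic_fraction = 0.5,
                                CVT = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_common <- round(n_known * common_fraction)

  pos <- .fixture_positions(truth, n_known)
  alt_of <- function(ref) vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
  pos$alt <- alt_of(pos$ref)
  # AFs are rounded to the precision written into the VCF so that planted
  # truth and scan results agree exactly
  af <- signif(c(stats::runif(n_common, af_common[1], af_common[2]),
                 if (n_known > n_common)
                   stats::runif(n_known - n_common, af_rare[1], af_rare[2])), 6)
  pos$af <- af
  pos$group <- rep(c("common", "rare"), c(n_common, n_known - n_common))
  pos$id <- sprintf("fx%06d", seq_len(n_known))
  pos$info <- if (identical(pop_tag, "CAF"))
    sprintf("CAF=%.6g,%.6g", 1 - af, af)
  else sprintf("%s=%.6g", pop_tag, af)
  ord <- order(match(pos$contig, truth$contigs$name), pos$pos)
  pos <- pos[ord, , drop = FALSE]

  known_vcf <- file.path(dir, "known.vcf")
  .write_fixture_vcf(known_vcf, pos)
  common_group <- pos[pos$group == "common", , drop = FALSE]
  common_vcf <- file.path(dir, "common.vcf")
  .write_fixture_vcf(common_vcf, common_group)

  # structural variants: non-overlapping base deletions plus planted overlappers
  sv_vcf <- file.path(dir, "sv.vcf")
  n_ov <- round(n_svs * sv_overlap_fraction)
  n_base <- n_svs - n_ov
  stopifnot(n_ov <= n_base || n_svs == 0)
  if (n_svs > 0) {
    c1 <- truth$contigs$name[1]
    L1 <- truth$contigs$length[1]
    slot <- floor(L1 / (n_base + 1))
    if (slot < 60)
      stop("fixture genome too small for ", n_svs, " structural variants")
    # SV lengths scale with the available slot so groups never touch
    off_max <- min(40L, floor(slot / 10))
    max_len <- min(500L, slot - off_max - 5L)
    min_len <- min(50L, max_len)
    base_start <- slot * seq_len(n_base)  # well-separated anchors
    base_len <- sample(min_len:max_len, n_base, replace = TRUE)
    ov_idx <- if (n_ov > 0) sample.int(n_base, n_ov) else integer()
    ov_start <- base_start[ov_idx] + sample(seq_len(off_max), n_ov, replace = TRUE)
    ov_len <- sample(min_len:max_len, n_ov, replace = TRUE)
    sv <- data.frame(
      contig = c1,
      pos = c(base_start, ov_start),
      id = sprintf("sv%04d", seq_len(n_svs)),
      ref = toupper(substring(truth$seqs[c1], c(base_start, ov_start),
                              c(base_start, ov_start))),
      alt = "<DEL>",
      info = sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d",
                     c(base_start + base_len, ov_start + ov_len),
                     c(base_len, ov_len)),
      stringsAsFactors = FALSE)
    sv <- sv[order(sv$pos), , drop = FALSE]
    .write_fixture_vcf(sv_vcf, sv,
      c("##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">"))
    sv_groups <- n_base
  } else {
    .write_fixture_vcf(sv_vcf, variants_empty()[0, c("contig", "pos", "id",
                                                     "ref", "alt", "info")])
    sv_groups <- 0L
  }

  # disease-related variants with a clinical-significance mix
  patho_vcf <- file.path(dir, "pathogenic.vcf")
  if (n_pathogenic > 0) {
    ppos <- .fixture_positions(truth, n_pathogenic,
                               used = paste(pos$contig, pos$pos))
    ppos$alt <- alt_of(ppos$ref)
    n_q <- round(n_pathogenic * pathogenic_fraction)
    classes <- c(rep(c("Pathogenic", "Likely_pathogenic"),
                     length.out = n_q),
                 rep(c("Benign", "Uncertain_significance"),
                     length.out = n_pathogenic - n_q))
    ppos$id <- sprintf("clin%04d", seq_len(n_pathogenic))
    ppos$info <- paste0("CLNSIG=", classes)
    ppos <- ppos[order(match(ppos$contig, truth$contigs$name), ppos$pos), ,
                 drop = FALSE]
    .write_fixture_vcf(patho_vcf, ppos,
      "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">")
    n_qualifying <- n_q
  } else {
    .write_fixture_vcf(patho_vcf, variants_empty()[0, c("contig", "pos", "id",
                                                        "ref", "alt", "info")])
    n_qualifying <- 0L
  }

  common_af <- pos$af[pos$group == "common"]
  list(known_vcf = known_vcf, common_vcf = common_vcf, sv_vcf = sv_vcf,
       pathogenic_vcf = patho_vcf,
       truth = list(varNum = n_known,
                    cvNum = sum(common_af >= CVT),
                    ecvNum = sum(common_af[common_af >= CVT]),
                    sv_groups = sv_groups,
                    n_qualifying_pathogenic = n_qualifying,
                    records = pos))
}

#' Generate a complete synthetic dataset with a ready-to-run configuration
#'
#' Convenience wrapper around [fixture_reference()] and
#' [fixture_variant_dbs()]: writes the reference, coding BED, all four
#' variant databases and a configuration file pointing at them.
#'
#' @param dir output directory.
#' @param config_params named list of extra configuration lines (e.g.
#'   `list(OVR = "0.001", gender = "female")`).
#' @param seed integer seed.
#' @inheritParams fixture_reference
#' @inheritParams fixture_variant_dbs
#' @return list with `config` (path), `paths` (all data files) and `truth`.
#' @export
fixture_dataset <- function(dir, genome_length = 1e6, n_contigs = 2,
                            n_fraction = 0.01, coding_fraction = 0.02,
                            n_known = 1000, common_fraction = 0.2,
                            af_common = c(0.30, 0.50), af_rare = c(1e-4, 0.009),
                            pop_tag = "CAF", n_svs = 0,
                            sv_overlap_fraction = 0, n_pathogenic = 0,
                            pathogenic_fraction = 0.5, CVT = 0.01,
                            config_params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- fixture_reference(dir, genome_length = genome_length,
                           n_contigs = n_contigs, n_fraction = n_fraction,
                           coding_fraction = coding_fraction)
  dbs <- fixture_variant_dbs(dir, ref$truth, n_known = n_known,
                             common_fraction = common_fraction,
                             af_common = af_common, af_rare = af_rare,
                             pop_tag = pop_tag, n_svs = n_svs,
                             sv_overlap_fraction = sv_overlap_fraction,
                             n_pathogenic = n_pathogenic,
                             pathogenic_fraction = pathogenic_fraction,
                             CVT = CVT)
  cfg <- file.path(dir, "config.txt")
  lines <- c("# diplosim configuration (synthetic fixture dataset)",
             paste0("reference = ", ref$fasta),
             paste0("coding_bed = ", ref$bed),
             paste0("known_vcf = ", dbs$known_vcf),
             paste0("common_vcf = ", dbs$common_vcf),
             paste0("sv_vcf = ", dbs$sv_vcf),
             paste0("pathogenic_vcf = ", dbs$pathogenic_vcf),
             if (!identical(pop_tag, "CAF")) paste0("background_pop = ", pop_tag),
             vapply(names(config_params), function(k)
               paste0(k, " = ", config_params[[k]]), ""))
  writeLines(lines, cfg)
  list(config = cfg,
       paths = c(reference = ref$fasta, coding_bed = ref$bed,
                 known_vcf = dbs$known_vcf, common_vcf = dbs$common_vcf,
                 sv_vcf = dbs$sv_vcf, pathogenic_vcf = dbs$pathogenic_vcf),
       truth = c(ref$truth[c("GLN", "nGLN", "modLen", "contigs", "n_blocks",
                             "intervals")],
                 dbs$truth, list(seqs = ref$truth$seqs)))
}
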