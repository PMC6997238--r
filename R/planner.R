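# Planning stage.
#
# From the user parameters and the database statistics the planner derives the
# internal calibration parameters, draws candidate genomic positions for novel
# variants, and pre-selects the structural and pathogenic records that will be
# spiked into the simulated genome.

#' Expected overlap rate of novel and known variants
#'
#' Novel variants are drawn uniformly over the genome and some of them will
#' land on positions already occupied by selected known variants, where they
#' are later discarded (known variants take priority). The expected rate of
#' such collisions is `OVR*KVR / (1 - OVR*KVR)`, and the novel draw budget is
#' inflated by `1 + eoR` to compensate.
#'
#' @param OVR overall variation rate.
#' @param KVR known variation rate.
#' @return the expected overlap rate (non-negative scalar).
#' @export
#' @examples
#' compute_eoR(0.001, 0.9)
compute_eoR <- function(OVR, KVR) {
  stopifnot(OVR >= 0, KVR >= 0)
  x <- OVR * KVR
  if (x >= 1) stop("OVR*KVR must be < 1")
  x / (1 - x)
}

#' Practical AF coefficient of common variants
#'
#' Ratio of the requested number of common variants per haploid genome
#' (`GLN*OVR*KVR*CVR`) to the expected number carried by one haploid genome
#' drawn from the background population (`ecvNum`, the sum of common-variant
#' alternate allele frequencies). Common records are then included with
#' per-haplotype probability `paC * AF`, which preserves the relative
#' occurrence probabilities of the variants while hitting the requested
#' count in expectation.
#'
#' @param GLN reference genome length (bp).
#' @param OVR,KVR,CVR overall/known/common variation rates.
#' @param ecvNum sum of qualifying common-variant alt allele frequencies.
#' @return the coefficient `paC` (0 when `CVR` is 0).
#' @export
compute_paC <- function(GLN, OVR, KVR, CVR, ecvNum) {
  if (CVR == 0 || GLN * OVR * KVR * CVR == 0) return(0)
  if (ecvNum <= 0)
    stop("no common variants in database (ecvNum = 0) but CVR > 0")
  GLN * OVR * KVR * CVR / ecvNum
}

#' Practical average AF of non-common known variants
#'
#' Non-common known variants carry no usable AF information, so each is
#' included with the same per-haplotype probability `paAF`, chosen so the
#' expected count per haploid genome is the requested
#' `GLN*OVR*KVR*(1 - CVR)`.
#'
#' @param GLN reference genome length (bp).
#' @param OVR,KVR,CVR overall/known/common variation rates.
#' @param varNum number of records in the known-variant database.
#' @param cvNum number of common records in the common-variant database.
#' @return the probability `paAF` (0 when `CVR` is 1).
#' @export
compute_paAF <- function(GLN, OVR, KVR, CVR, varNum, cvNum) {
  if (CVR == 1 || GLN * OVR * KVR * (1 - CVR) == 0) return(0)
  if (varNum <= cvNum)
    stop("no non-common variants in database (varNum <= cvNum) but CVR < 1")
  GLN * OVR * KVR * (1 - CVR) / (varNum - cvNum)
}

#' Planned number of novel non-coding draws
#'
#' The novel draw budget `GLN*OVR*(1-KVR)` is inflated by the expected
#' known-overlap rate ([compute_eoR()]) and by the fraction of the genome
#' that is invalid for novel placement (N runs and coding regions, where
#' global draws are discarded):
#' `ceil( GLN*OVR*(1-KVR)*(1+eoR) * GLN/(GLN-nGLN-modLen) )`.
#'
#' @param GLN reference genome length (bp).
#' @param nGLN number of N bases in the reference.
#' @param modLen total coding length (bp).
#' @param OVR,KVR overall/known variation rates.
#' @return integer number of planned uniform draws.
#' @export
compute_pnvNum <- function(GLN, nGLN, modLen, OVR, KVR) {
  if (GLN <= nGLN + modLen)
    stop("genome has no valid non-coding, non-N space (GLN <= nGLN + modLen)")
  eoR <- compute_eoR(OVR, KVR)
  ceiling(GLN * OVR * (1 - KVR) * (1 + eoR) * GLN / (GLN - nGLN - modLen))
}

# ---- position planning ------------------------------------------------------

# 1-based start of each contig in the concatenated genome coordinate space.
.contig_starts <- function(gs) {
  len <- as.numeric(gs$contigs$length)
  c(1, head(cumsum(len), -1) + 1)
}

# Membership of 1-based positions in sorted 0-based half-open intervals.
.in_intervals <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  p0 <- pos - 1L
  idx <- findInterval(p0, iv$start)
  idx > 0L & p0 < iv$end[pmax(idx, 1L)]
}

# TRUE for positions falling in an N run of their contig.
positions_in_n <- function(gs, contig, pos) {
  out <- logical(length(pos))
  for (nm in unique(contig)) {
    sel <- contig == nm
    out[sel] <- .in_intervals(pos[sel], gs$n_blocks[[nm]])
  }
  out
}

# TRUE for positions falling in a coding interval of their contig.
positions_in_coding <- function(cm, contig, pos) {
  out <- logical(length(pos))
  for (nm in unique(contig)) {
    sel <- contig == nm
    out[sel] <- .in_intervals(pos[sel], cm$intervals[[nm]])
  }
  out
}

#' Plan candidate non-coding novel positions
#'
#' Draws exactly `pnvNum` positions uniformly over the whole genome, then
#' discards draws that land in N runs or in coding intervals (both are
#' invalid for global novel placement; the draw budget is pre-inflated to
#' compensate, see [compute_pnvNum()]). Retained positions may repeat;
#' duplicates are collapsed later at merge.
#'
#' @param gs `pg_genome_stats` of the reference.
#' @param cm `pg_coding_model` of the coding regions.
#' @param pnvNum number of uniform draws.
#' @return data.frame with columns `contig`, `pos` (1-based).
#' @export
plan_noncoding_positions <- function(gs, cm, pnvNum) {
  stopifnot(pnvNum >= 0)
  if (pnvNum == 0)
    return(data.frame(contig = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  g <- sample.int(gs$GLN, pnvNum, replace = TRUE)
  starts <- .contig_starts(gs)
  idx <- findInterval(g, starts)
  contig <- gs$contigs$name[idx]
  pos <- as.integer(g - starts[idx] + 1)
  keep <- !positions_in_n(gs, contig, pos) & !positions_in_coding(cm, contig, pos)
  data.frame(contig = contig[keep], pos = pos[keep], stringsAsFactors = FALSE)
}

#' Plan novel coding positions
#'
#' Draws positions uniformly over the concatenated coding space and maps them
#' back to genome coordinates. Unlike the global non-coding draw, the coding
#' count is a hard guarantee: duplicate positions (and positions landing on N
#' bases) are re-drawn until exactly `CDN` distinct valid positions are
#' obtained.
#'
#' @param cm `pg_coding_model`.
#' @param CDN requested number of coding positions.
#' @param gs optional `pg_genome_stats`, used to exclude N bases.
#' @return data.frame with columns `contig`, `pos` (1-based), exactly `CDN`
#'   rows, all inside coding intervals.
#' @export
plan_coding_positions <- function(cm, CDN, gs = NULL) {
  stopifnot(CDN >= 0)
  empty <- data.frame(contig = character(), pos = integer(),
                      stringsAsFactors = FALSE)
  if (CDN == 0) return(empty)
  if (cm$modLen == 0)
    stop("CDN > 0 but the coding model is empty (modLen = 0)")
  flat <- do.call(rbind, lapply(names(cm$intervals), function(nm) {
    iv <- cm$intervals[[nm]]
    data.frame(contig = nm, start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  }))
  len <- as.numeric(flat$end - flat$start)
  cstart <- c(1, head(cumsum(len), -1) + 1)
  acc <- empty
  for (iter in seq_len(1000L)) {
    need <- CDN - nrow(acc)
    if (need <= 0L) break
    u <- sample.int(cm$modLen, need, replace = TRUE)
    idx <- findInterval(u, cstart)
    cand <- data.frame(contig = flat$contig[idx],
                       pos = as.integer(flat$start[idx] + (u - cstart[idx]) + 1),
                       stringsAsFactors = FALSE)
    if (!is.null(gs))
      cand <- cand[!positions_in_n(gs, cand$contig, cand$pos), , drop = FALSE]
    acc <- rbind(acc, cand)
    acc <- acc[!duplicated(paste(acc$contig, acc$pos)), , drop = FALSE]
  }
  if (nrow(acc) < CDN)
    stop("could not place ", CDN, " distinct coding positions ",
         "(coding space too small or mostly N)")
  rownames(acc) <- NULL
  acc[seq_len(CDN), , drop = FALSE]
}

# ---- special variant selection ---------------------------------------------

# Reference footprint end of a (structural) VCF record, 1-based inclusive.
.sv_end <- function(rec) {
  end <- suppressWarnings(as.integer(info_tag_value(rec$info, "END")))
  svlen <- suppressWarnings(as.numeric(info_tag_value(rec$info, "SVLEN")))
  fallback <- rec$pos + nchar(rec$ref) - 1L
  out <- ifelse(!is.na(end), end,
                ifelse(!is.na(svlen), rec$pos + abs(svlen), fallback))
  as.integer(pmax(out, rec$pos))
}

#' Select structural variants from the SV database
#'
#' Overlapping SV records are first grouped (connected components of the
#' reference-footprint overlap graph, using INFO `END`, or `POS + |SVLEN|`
#' when `END` is absent). `SVN` groups are then chosen at random and one
#' record drawn from each, so the selected records are pairwise
#' non-overlapping by construction.
#'
#' @param sv_vcf path to the SV database VCF.
#' @param SVN number of SVs to select; must not exceed the number of
#'   non-overlapping groups.
#' @return data.frame of the selected records (VCF columns plus `end`,
#'   the 1-based inclusive footprint end).
#' @export
select_structural_variants <- function(sv_vcf, SVN) {
  stopifnot(SVN >= 0)
  rec <- read_vcf_records(sv_vcf)
  rec$end <- if (nrow(rec)) .sv_end(rec) else integer()
  if (SVN == 0) return(rec[0, , drop = FALSE])
  if (!nrow(rec))
    stop("SVN = ", SVN, " but the SV database has 0 non-overlapping groups")
  # connected components of the overlap graph, per contig
  rec$group <- NA_integer_
  gmax <- 0L
  for (nm in unique(rec$chrom)) {
    sel <- which(rec$chrom == nm)
    ir <- IRanges::IRanges(start = rec$pos[sel], end = rec$end[sel])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    rec$group[sel] <- gmax + comp
    gmax <- gmax + length(red)
  }
  if (SVN > gmax)
    stop("SVN = ", SVN, " exceeds the number of non-overlapping SV groups (",
         gmax, ")")
  groups <- sample.int(gmax, SVN)
  picks <- vapply(groups, function(g) {
    members <- which(rec$group == g)
    if (length(members) == 1L) members else sample(members, 1L)
  }, 0L)
  out <- rec[picks, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select pathogenic variants from the disease-variant database
#'
#' Only records whose clinical-significance tag contains `Pathogenic` or
#' `Likely_pathogenic` are eligible; `PVN` of them are drawn uniformly
#' without replacement.
#'
#' @param path_vcf path to the disease-related variant database VCF.
#' @param PVN number of variants to select.
#' @param clnsig_tag INFO tag carrying clinical significance (default
#'   `CLNSIG`).
#' @return data.frame of the selected records (VCF columns plus `end`).
#' @export
select_pathogenic_variants <- function(path_vcf, PVN, clnsig_tag = "CLNSIG") {
  stopifnot(PVN >= 0)
  rec <- read_vcf_records(path_vcf)
  rec$end <- if (nrow(rec)) as.integer(rec$pos + nchar(rec$ref) - 1L) else integer()
  if (PVN == 0) return(rec[0, , drop = FALSE])
  sig <- info_tag_value(rec$info, clnsig_tag)
  qual <- vapply(strsplit(ifelse(is.na(sig), "", sig), "[,|/]"), function(x)
    any(tolower(trimws(x)) %in% c("pathogenic", "likely_pathogenic")), TRUE)
  eligible <- which(qual)
  if (PVN > length(eligible))
    stop("PVN = ", PVN, " exceeds the number of Pathogenic/Likely_pathogenic ",
         "records (", length(eligible), ")")
  picks <- if (length(eligible) == 1L) eligible else sample(eligible, PVN)
  out <- rec[picks, , drop = FALSE]
  rownames(out) <- NULL
  out
}
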