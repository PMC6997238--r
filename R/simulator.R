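# Simulation stage.
#
# Known variants are Bernoulli-sampled per haplotype (common records at their
# corrected background AF, non-common records at the flat practical average
# AF). Novel variants are instantiated at the planned positions under the
# mutation-law parameters (Ti/Tv, indel rate, power-law lengths, frameshift
# retention). All sources are merged by priority (special > known > novel) and
# written as a phased single-sample VCF.

.variant_cols <- c("contig", "pos", "id", "ref", "alt", "end",
                   "g1", "g2", "source", "info")

variants_empty <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), end = integer(),
             g1 = integer(), g2 = integer(), source = character(),
             info = character(), stringsAsFactors = FALSE)
}

#' Per-contig ploidy for a resolved gender
#'
#' Autosomes (and any non-sex contig, e.g. unplaced scaffolds or chrM) are
#' diploid. Females carry two X and no Y; males one X and one Y. Sex
#' chromosomes are recognized by name (`X`/`chrX`, `Y`/`chrY`,
#' case-insensitive).
#'
#' @param gender `"male"` or `"female"`.
#' @param contig_names character vector of contig names.
#' @return named integer vector of ploidies (0 = contig absent from this
#'   individual), class `pg_ploidy` with a `gender` attribute.
#' @export
ploidy_model <- function(gender, contig_names) {
  stopifnot(gender %in% c("male", "female"))
  lc <- tolower(contig_names)
  pl <- rep(2L, length(contig_names))
  is_x <- lc %in% c("x", "chrx")
  is_y <- lc %in% c("y", "chry")
  if (gender == "male") {
    pl[is_x] <- 1L
    pl[is_y] <- 1L
  } else {
    pl[is_y] <- 0L
  }
  structure(stats::setNames(pl, contig_names), gender = gender,
            class = "pg_ploidy")
}

#' Draw a phased genotype by per-haplotype Bernoulli sampling
#'
#' Each haplotype of a diploid contig is sampled independently with inclusion
#' probability `p`; a hemizygous contig gets a single draw. When no haplotype
#' draws the variant the result is `NULL` (the variant is absent from this
#' individual).
#'
#' @param p per-haplotype inclusion probability in `[0, 1]`.
#' @param ploidy 1 or 2.
#' @return integer vector of 0/1 alleles of length `ploidy`, or `NULL`.
#' @export
#' @examples
#' set.seed(1); draw_genotype(0.5, 2)
draw_genotype <- function(p, ploidy) {
  stopifnot(p >= 0, p <= 1, ploidy %in% c(1L, 2L))
  g <- as.integer(stats::runif(ploidy) < p)
  if (!any(g == 1L)) NULL else g
}

# Vectorized per-haplotype sampling for a block of records.
# Returns a logical matrix keep / integer columns g1, g2 (g2 NA if ploidy 1).
.draw_genotypes <- function(p, ploidy) {
  n <- length(p)
  g1 <- as.integer(stats::runif(n) < p)
  u2 <- stats::runif(n)                      # always drawn: keeps stream aligned
  g2 <- ifelse(ploidy == 2L, as.integer(u2 < p), NA_integer_)
  keep <- g1 == 1L | (!is.na(g2) & g2 == 1L)
  list(g1 = g1, g2 = g2, keep = keep & ploidy > 0L)
}

#' Sample common variants from the common-variant database
#'
#' Streams the database once. Each qualifying common record (background
#' alt-AF sum at least `CVT`) is included per haplotype with probability
#' `min(1, paC * AF)`; sub-threshold records are never selected. For
#' multi-allelic records one alternate allele is chosen proportionally to the
#' per-allele AFs and the summed AF drives inclusion.
#'
#' @param common_vcf path to the common-variant database.
#' @param pop_tag background-population AF INFO tag.
#' @param CVT common-variant AF threshold.
#' @param paC practical AF coefficient from [compute_paC()].
#' @param ploidy `pg_ploidy` ploidy model.
#' @return data.frame of selected variants (`source = "common"`); an `af`
#'   column records the summed background AF of each selected record.
#' @export
sample_common_variants <- function(common_vcf, pop_tag, CVT, paC, ploidy) {
  out <- list()
  mass_raw <- 0
  mass_used <- 0
  n_untagged <- 0L
  vcf_stream(common_vcf, function(chunk) {
    afs <- parse_alt_af(chunk$info, pop_tag)
    present <- !vapply(afs, is.null, TRUE)
    n_untagged <<- n_untagged + sum(!present)
    sums <- vapply(afs, function(a) if (is.null(a)) NA_real_ else sum(a), 0)
    ok <- which(present & !is.na(sums) & sums >= CVT)
    if (!length(ok)) return()
    p_raw <- paC * sums[ok]
    mass_raw <<- mass_raw + sum(p_raw)
    p <- pmin(1, p_raw)
    mass_used <<- mass_used + sum(p)
    pl <- unname(ploidy[chunk$chrom[ok]])
    pl[is.na(pl)] <- 2L
    d <- .draw_genotypes(p, pl)
    sel <- which(d$keep)
    if (!length(sel)) return()
    ii <- ok[sel]
    alt <- vapply(seq_along(sel), function(j) {
      alts <- strsplit(chunk$alt[ii[j]], ",", fixed = TRUE)[[1]]
      if (length(alts) == 1L) return(alts)
      w <- afs[[ii[j]]]
      if (length(w) != length(alts) || all(w <= 0)) w <- rep(1, length(alts))
      alts[sample.int(length(alts), 1L, prob = w)]
    }, "")
    out[[length(out) + 1L]] <<- data.frame(
      contig = chunk$chrom[ii], pos = chunk$pos[ii], id = chunk$id[ii],
      ref = chunk$ref[ii], alt = alt,
      end = chunk$pos[ii] + nchar(chunk$ref[ii]) - 1L,
      g1 = d$g1[sel], g2 = d$g2[sel], source = "common",
      info = NA_character_, af = sums[ii], stringsAsFactors = FALSE)
  })
  if (n_untagged > 0L)
    warning(n_untagged, " common-db record(s) without INFO tag '", pop_tag,
            "' skipped")
  if (mass_raw > 0 && (mass_raw - mass_used) / mass_raw > 0.01)
    warning(sprintf(paste0(
      "%.1f%% of the corrected common-variant inclusion mass was clipped at 1; ",
      "the common-variant count calibration degrades (paC too large for this ",
      "database)"), 100 * (mass_raw - mass_used) / mass_raw))
  if (!length(out)) {
    e <- variants_empty(); e$af <- numeric(); return(e)
  }
  do.call(rbind, out)
}

#' Sample non-common known variants
#'
#' Streams the known-variant database once. Records that would qualify as
#' common (background AF at least `CVT` under `pop_tag`, when the tag is
#' present) are skipped — common variants are drawn from the common database
#' only. Every other record is included per haplotype with the flat
#' probability `paAF`.
#'
#' @param known_vcf path to the known-variant database.
#' @param pop_tag background-population AF INFO tag (used only to recognize
#'   and exclude common records).
#' @param CVT common-variant AF threshold.
#' @param paAF practical average AF from [compute_paAF()]; values above 1 are
#'   clipped with a warning.
#' @param ploidy `pg_ploidy` ploidy model.
#' @return data.frame of selected variants (`source = "known"`).
#' @export
sample_noncommon_variants <- function(known_vcf, pop_tag, CVT, paAF, ploidy) {
  if (paAF > 1) {
    warning("paAF = ", signif(paAF, 4), " exceeds 1 and was clipped; the ",
            "known-variant database is too small for the requested variant count")
    paAF <- 1
  }
  out <- list()
  vcf_stream(known_vcf, function(chunk) {
    afs <- parse_alt_af(chunk$info, pop_tag)
    sums <- vapply(afs, function(a)
      if (is.null(a) || all(is.na(a))) 0 else sum(a), 0)
    ok <- which(sums < CVT)   # non-common only
    if (!length(ok)) return()
    pl <- unname(ploidy[chunk$chrom[ok]])
    pl[is.na(pl)] <- 2L
    d <- .draw_genotypes(rep(paAF, length(ok)), pl)
    sel <- which(d$keep)
    if (!length(sel)) return()
    ii <- ok[sel]
    alt1 <- vapply(strsplit(chunk$alt[ii], ",", fixed = TRUE), `[[`, "", 1L)
    out[[length(out) + 1L]] <<- data.frame(
      contig = chunk$chrom[ii], pos = chunk$pos[ii], id = chunk$id[ii],
      ref = chunk$ref[ii], alt = alt1,
      end = chunk$pos[ii] + nchar(chunk$ref[ii]) - 1L,
      g1 = d$g1[sel], g2 = d$g2[sel], source = "known",
      info = NA_character_, stringsAsFactors = FALSE)
  })
  if (!length(out)) return(variants_empty())
  do.call(rbind, out)
}

# ---- novel variant machinery -----------------------------------------------

.ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
.tv_options <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Choose the alternate base of a novel SNV under a Ti/Tv ratio
#'
#' The transition partner of the reference base is chosen with probability
#' `titv / (titv + 1)`; otherwise one of the two transversion partners is
#' chosen uniformly, so the expected transition/transversion ratio over many
#' sites equals `titv`.
#'
#' @param ref_base character vector over `A`, `C`, `G`, `T`.
#' @param titv transition/transversion ratio (non-negative).
#' @return character vector of alternate bases, same length as `ref_base`.
#' @export
#' @examples
#' set.seed(1)
#' table(choose_alt_snv(rep("A", 1000), titv = 2))
choose_alt_snv <- function(ref_base, titv) {
  stopifnot(titv >= 0, all(ref_base %in% names(.ti_partner)))
  n <- length(ref_base)
  is_ti <- stats::runif(n) < titv / (titv + 1)
  pick2 <- 1L + (stats::runif(n) < 0.5)    # always drawn: keeps stream aligned
  alt <- character(n)
  alt[is_ti] <- .ti_partner[ref_base[is_ti]]
  if (any(!is_ti)) {
    tv <- which(!is_ti)
    m <- rbind(vapply(.tv_options[ref_base[tv]], `[[`, "", 1L),
               vapply(.tv_options[ref_base[tv]], `[[`, "", 2L))
    alt[tv] <- m[cbind(pick2[tv], seq_along(tv))]
  }
  alt
}

# Normalization constant and CDF of the truncated discrete power law
# P(L = k) proportional to k^(-alpha), k = 1..lcap. Cached per (alpha, lcap).
.powerlaw_cdf <- function(alpha, lcap) {
  key <- sprintf("plcdf_%.12g_%d", alpha, lcap)
  cdf <- .diplosim_env[[key]]
  if (is.null(cdf)) {
    w <- seq_len(lcap)^(-alpha)
    cdf <- cumsum(w) / sum(w)
    .diplosim_env[[key]] <- cdf
  }
  cdf
}

#' Sample novel indel lengths from a truncated discrete power law
#'
#' Lengths are drawn from `P(L = k)` proportional to `k^(-PLalpha)` over
#' `k = 1..lcap` by inverse-CDF lookup. Draws exceeding the maximum novel
#' indel length `NIDL` are folded back by the remainder rule: `L <- L mod
#' NIDL`, with a remainder of 0 mapping to `NIDL` (a zero-length indel is
#' meaningless).
#'
#' @param n number of draws.
#' @param PLalpha power-law exponent (> 1).
#' @param NIDL maximum novel indel length (>= 2).
#' @param lcap support cap of the discrete distribution (default 10000; the
#'   remainder rule makes the tail beyond it irrelevant).
#' @return integer vector of `n` lengths in `1..NIDL`.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_indel_length(20, 1.8, 50))
sample_indel_length <- function(n, PLalpha, NIDL, lcap = 10000L) {
  if (PLalpha <= 1)
    stop("PLalpha must be > 1 (the discrete power law is not normalizable)")
  stopifnot(NIDL >= 2)
  if (n == 0L) return(integer())
  cdf <- .powerlaw_cdf(PLalpha, lcap)
  L <- findInterval(stats::runif(n), cdf) + 1L
  over <- L > NIDL
  L[over] <- L[over] %% NIDL
  L[L == 0L] <- as.integer(NIDL)
  L
}

#' Frameshift retention filter for coding indels
#'
#' Non-frameshifting coding indels (length a multiple of 3) are always
#' retained; frameshifting ones survive only with probability `FSR`, echoing
#' the strong purifying selection against frameshifts in real coding
#' sequence.
#'
#' @param len integer vector of indel lengths (nt).
#' @param FSR frameshift retention rate in `[0, 1]`.
#' @return logical vector: retain this indel?
#' @export
retain_coding_indel <- function(len, FSR) {
  stopifnot(FSR >= 0, FSR <= 1, all(len >= 1))
  u <- stats::runif(length(len))
  len %% 3L == 0L | u < FSR
}

#' Maximum-likelihood fit of the truncated power-law exponent
#'
#' Fits `alpha` of `P(L = k)` proportional to `k^(-alpha)`, `k = 1..lcap`, by
#' maximizing the truncated-zeta log-likelihood. Used as a diagnostic to
#' verify that simulated indel lengths follow the configured distribution.
#'
#' @param lengths integer vector of observed lengths.
#' @param lcap support cap used during sampling.
#' @param interval search interval for the exponent.
#' @return the fitted exponent.
#' @export
fit_indel_exponent <- function(lengths, lcap = 10000L, interval = c(1.01, 6)) {
  stopifnot(length(lengths) > 0, all(lengths >= 1), all(lengths <= lcap))
  slog <- sum(log(lengths))
  n <- length(lengths)
  k <- seq_len(lcap)
  nll <- function(a) n * log(sum(k^(-a))) + a * slog
  stats::optimize(nll, interval)$minimum
}

#' Instantiate novel variants at planned positions
#'
#' Each position becomes an indel with probability `NIDR`, otherwise an SNV.
#' SNV alternate bases follow [choose_alt_snv()] with `TiTv` (non-coding) or
#' `TiTvC` (coding). Indels are insertions or deletions with equal
#' probability and a length from [sample_indel_length()]; coding indels whose
#' length is not a multiple of 3 (frameshifting) are retained only with
#' probability `FSR`. Deletions take their bases from the reference with a
#' 1-bp left anchor and are discarded when the footprint crosses a contig end
#' or touches N or ambiguous bases; insertions receive a uniform random base
#' string after the anchor. Every retained novel variant is heterozygous on
#' one haplotype (a single alternate allele on hemizygous contigs).
#'
#' @param positions data.frame with columns `contig`, `pos` (and optionally
#'   `hap` in 1:2, otherwise a fair coin per variant).
#' @param region `"coding"` or `"noncoding"`.
#' @param params a `pg_params_resolved` object.
#' @param reference a `pg_reference` from [load_reference()].
#' @param ploidy `pg_ploidy` ploidy model.
#' @return data.frame of retained novel variants (`source` is
#'   `"novel_coding"` or `"novel_noncoding"`).
#' @export
instantiate_novel <- function(positions, region = c("noncoding", "coding"),
                              params, reference, ploidy) {
  region <- match.arg(region)
  n <- nrow(positions)
  if (n == 0L) return(variants_empty())
  titv <- if (region == "coding") params$TiTvC else params$TiTv
  contig <- positions$contig
  pos <- as.integer(positions$pos)
  clen_map <- vapply(reference$chr, nchar, 0L)
  clen <- unname(clen_map[contig])

  # decision draws in fixed order for seed-stable output
  is_indel <- stats::runif(n) < params$NIDR
  hap <- if (!is.null(positions$hap)) as.integer(positions$hap)
         else 1L + (stats::runif(n) < 0.5)
  pl <- unname(ploidy[contig])
  pl[is.na(pl)] <- 2L

  ref <- alt <- character(n)
  keep <- pl > 0L

  # SNVs
  snv <- which(!is_indel)
  if (length(snv)) {
    base <- toupper(substring(reference$chr[contig[snv]], pos[snv], pos[snv]))
    valid <- base %in% c("A", "C", "G", "T")
    alt_snv <- rep(NA_character_, length(snv))
    if (any(valid)) alt_snv[valid] <- choose_alt_snv(base[valid], titv)
    ref[snv] <- base
    alt[snv] <- alt_snv
    keep[snv] <- keep[snv] & valid
  }

  # indels
  ind <- which(is_indel)
  len <- integer(n)
  if (length(ind)) {
    is_ins <- stats::runif(length(ind)) < 0.5
    L <- sample_indel_length(length(ind), params$PLalpha, params$NIDL)
    len[ind] <- ifelse(is_ins, 0L, L)     # reference-footprint extension
    if (region == "coding")
      keep[ind] <- keep[ind] & retain_coding_indel(L, params$FSR)
    anchor <- toupper(substring(reference$chr[contig[ind]], pos[ind], pos[ind]))
    keep[ind] <- keep[ind] & anchor %in% c("A", "C", "G", "T")
    # deletions: anchor + deleted bases from the reference
    del <- ind[!is_ins]
    if (length(del)) {
      dlen <- L[!is_ins]
      fits <- pos[del] + dlen <= clen[del]
      dref <- rep(NA_character_, length(del))
      dref[fits] <- toupper(substring(reference$chr[contig[del[fits]]],
                                      pos[del[fits]], pos[del[fits]] + dlen[fits]))
      ok <- fits & !is.na(dref) & !grepl("[^ACGT]", dref)
      ref[del] <- dref
      alt[del] <- substring(dref, 1L, 1L)
      keep[del] <- keep[del] & ok
    }
    # insertions: anchor + random bases
    ins <- ind[is_ins]
    if (length(ins)) {
      ilen <- L[is_ins]
      bases <- sample(c("A", "C", "G", "T"), sum(ilen), replace = TRUE)
      splits <- rep.int(seq_along(ins), ilen)
      inserted <- vapply(split(bases, splits), paste, "", collapse = "")
      ref[ins] <- anchor[match(ins, ind)]
      alt[ins] <- paste0(ref[ins], inserted)
      keep[ins] <- keep[ins] & !is.na(ref[ins])
    }
  }

  g1 <- ifelse(pl == 1L, 1L, ifelse(hap == 1L, 1L, 0L))
  g2 <- ifelse(pl == 1L, NA_integer_, ifelse(hap == 2L, 1L, 0L))
  out <- data.frame(
    contig = contig, pos = pos, id = ".", ref = ref, alt = alt,
    end = pos + len,
    g1 = as.integer(g1), g2 = as.integer(g2),
    source = if (region == "coding") "novel_coding" else "novel_noncoding",
    info = NA_character_, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- merging and output -----------------------------------------------------

# Greedy within-tier conflict resolution: earlier reference position wins,
# ties drop the later-processed record. `accepted` is a per-contig list of
# IRanges already claimed by higher tiers.
.merge_tier <- function(vars, accepted) {
  if (!nrow(vars)) return(list(vars = vars, accepted = accepted))
  keep_rows <- list()
  for (nm in unique(vars$contig)) {
    v <- vars[vars$contig == nm, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    acc <- accepted[[nm]]
    if (!is.null(acc) && length(acc)) {
      ir <- IRanges::IRanges(start = v$pos, end = v$end)
      v <- v[!IRanges::overlapsAny(ir, acc), , drop = FALSE]
    }
    if (nrow(v) > 1L) {
      prev_max_end <- c(-Inf, cummax(as.numeric(v$end))[-nrow(v)])
      v <- v[v$pos > prev_max_end, , drop = FALSE]
    }
    if (nrow(v)) {
      new_ir <- IRanges::IRanges(start = v$pos, end = v$end)
      accepted[[nm]] <- if (is.null(acc)) new_ir else c(acc, new_ir)
      keep_rows[[nm]] <- v
    }
  }
  list(vars = if (length(keep_rows)) do.call(rbind, keep_rows) else vars[0, ],
       accepted = accepted)
}

#' Merge variants from all sources by priority
#'
#' Special variants (structural and pathogenic) have the highest priority,
#' then known variants (common and non-common), then novel variants. When two
#' variants have overlapping reference footprints, the lower-priority one is
#' dropped; within the same priority tier the variant at the earlier position
#' wins and exact ties drop the later-processed record. The result is sorted
#' by contig and position and is footprint-disjoint.
#'
#' @param special,known,novel variant data.frames (see [variants_empty()] for
#'   the schema; `novel` is typically coding and non-coding novels combined).
#' @param contig_order optional character vector fixing the output contig
#'   order (defaults to order of first appearance).
#' @return merged, sorted, conflict-free variant data.frame.
#' @export
merge_variants <- function(special, known, novel, contig_order = NULL) {
  tiers <- list(special, known, novel)
  cols <- .variant_cols
  tiers <- lapply(tiers, function(v) {
    if (is.null(v) || !nrow(v)) variants_empty() else v[, cols, drop = FALSE]
  })
  accepted <- list()
  out <- list()
  for (v in tiers) {
    m <- .merge_tier(v, accepted)
    accepted <- m$accepted
    out[[length(out) + 1L]] <- m$vars
  }
  res <- do.call(rbind, out)
  if (!nrow(res)) return(variants_empty())
  lev <- if (is.null(contig_order)) unique(res$contig)
         else intersect(contig_order, unique(res$contig))
  res <- res[order(match(res$contig, lev), res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write simulated variants as a phased single-sample VCF
#'
#' Genotypes are phased with `|`; haplotype 1 is the left allele and
#' corresponds to the `hap1` FASTA written by the generator. Every record
#' carries an `SRC` INFO tag naming its source (`COMMON`, `KNOWN`,
#' `NOVEL_CD`, `NOVEL_NC`, `SV`, `PATHO`); structural and pathogenic records
#' keep their original INFO with `SRC` appended.
#'
#' @param variants merged, sorted variant data.frame from [merge_variants()].
#' @param gs `pg_genome_stats` (for the contig header lines).
#' @param out_path output path (`.vcf` or `.vcf.gz`).
#' @param sample_name sample column name.
#' @param gender resolved gender, recorded in the header so the generator can
#'   rebuild the ploidy model.
#' @return invisible `out_path`.
#' @export
write_variants_vcf <- function(variants, gs, out_path,
                               sample_name = "SIMULATED", gender = NULL) {
  src_map <- c(common = "COMMON", known = "KNOWN", novel_coding = "NOVEL_CD",
               novel_noncoding = "NOVEL_NC", sv = "SV", pathogenic = "PATHO")
  hdr <- vcf_header_lines(gs$contigs, sample_name, gender)
  # declare INFO tags passed through from special-variant records
  passthrough <- unique(unlist(regmatches(
    variants$info[!is.na(variants$info)],
    gregexpr("(?:^|;)([A-Za-z_][A-Za-z0-9_.]*)", variants$info[!is.na(variants$info)]))))
  passthrough <- setdiff(sub("^;", "", passthrough), "SRC")
  if (length(passthrough)) {
    typed <- c(END = "Number=1,Type=Integer", SVLEN = "Number=.,Type=Integer")
    decl <- vapply(sort(passthrough), function(tg)
      sprintf("##INFO=<ID=%s,%s,Description=\"Passed through from source database\">",
              tg, if (tg %in% names(typed)) typed[[tg]] else "Number=.,Type=String"),
      "")
    hdr <- append(hdr, decl, after = length(hdr) - 1L)
  }
  body <- character(0)
  if (nrow(variants)) {
    o <- order(match(variants$contig, gs$contigs$name), variants$pos)
    if (!identical(o, seq_len(nrow(variants))))
      stop("internal error: variants must be sorted before writing")
    src <- src_map[variants$source]
    if (anyNA(src)) stop("internal error: unknown variant source")
    info <- ifelse(is.na(variants$info) | variants$info %in% c("", "."),
                   paste0("SRC=", src),
                   paste0(variants$info, ";SRC=", src))
    gt <- ifelse(is.na(variants$g2), as.character(variants$g1),
                 paste0(variants$g1, "|", variants$g2))
    id <- ifelse(is.na(variants$id) | variants$id == "", ".", variants$id)
    body <- paste(variants$contig, variants$pos, id, variants$ref,
                  variants$alt, ".", ".", info, "GT", gt, sep = "\t")
  }
  con <- if (grepl("\\.gz$", out_path)) gzfile(out_path, "wt")
         else file(out_path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(out_path)
}
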