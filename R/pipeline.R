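# Pipeline orchestration: the three stages behind one master seed.
#
# Each stage derives its own sub-seed from the master seed so that stages are
# individually reproducible and a full run is deterministic end to end.

#' Plan a personal-genome simulation
#'
#' Resolves the user parameters, scans (or loads from `pgstat` caches) the
#' reference genome, coding BED and variant databases, computes the internal
#' calibration parameters, draws candidate novel positions for each
#' haplotype, and pre-selects the structural and pathogenic records.
#'
#' @param config a `pg_params` object or the path of a configuration file
#'   (see [parse_config()]).
#' @param seed integer master seed (default: the `seed` key of the
#'   configuration, if any).
#' @param out optional path of a JSON plan file to write.
#' @param quiet suppress progress messages.
#' @return An object of class `pg_plan`.
#' @export
pg_plan <- function(config, seed = NULL, out = NULL, quiet = FALSE) {
  p <- if (inherits(config, "pg_params")) config else parse_config(config)
  if (is.null(seed)) seed <- p$seed
  say <- function(...) if (!quiet) message("[diplosim] ", ...)

  params <- resolve_parameters(p, derive_seed(seed, "resolve"))
  say("resolved parameters: gender=", params$gender,
      " OVR=", signif(params$OVR, 4), " KVR=", signif(params$KVR, 4),
      " CVR=", signif(params$CVR, 4))

  paths <- params$paths
  if (anyNA(paths[c("reference", "coding_bed", "known_vcf", "common_vcf")]))
    stop("reference, coding_bed, known_vcf and common_vcf paths are required")
  gs <- scan_cached("genome", paths[["reference"]], quiet = quiet)
  cm <- scan_cached("coding", paths[["coding_bed"]], genome = gs, quiet = quiet)
  known <- scan_cached("known", paths[["known_vcf"]], quiet = quiet)
  common <- scan_cached("common", paths[["common_vcf"]],
                        pop_tag = params$background_pop, CVT = params$CVT,
                        quiet = quiet)
  say("database stats: GLN=", gs$GLN, " nGLN=", gs$nGLN, " modLen=", cm$modLen,
      " varNum=", known$varNum, " cvNum=", common$cvNum,
      " ecvNum=", signif(common$ecvNum, 6))

  internal <- list(
    eoR = compute_eoR(params$OVR, params$KVR),
    paC = compute_paC(gs$GLN, params$OVR, params$KVR, params$CVR, common$ecvNum),
    paAF = compute_paAF(gs$GLN, params$OVR, params$KVR, params$CVR,
                        known$varNum, common$cvNum),
    pnvNum = compute_pnvNum(gs$GLN, gs$nGLN, cm$modLen, params$OVR, params$KVR)
  )
  say("internal parameters: paC=", signif(internal$paC, 6),
      " paAF=", signif(internal$paAF, 6), " eoR=", signif(internal$eoR, 6),
      " pnvNum=", internal$pnvNum)

  set_stage_seed(seed, "plan")
  # the per-haploid novel budget is planned independently for each haplotype
  # (novel variants are heterozygous, so each lands on a single haplotype)
  nc1 <- plan_noncoding_positions(gs, cm, internal$pnvNum)
  nc2 <- plan_noncoding_positions(gs, cm, internal$pnvNum)
  noncoding <- rbind(cbind(nc1, hap = if (nrow(nc1)) 1L else integer()),
                     cbind(nc2, hap = if (nrow(nc2)) 2L else integer()))
  coding <- plan_coding_positions(cm, params$CDN, gs = gs)
  svs <- if (params$SVN > 0) {
    if (is.na(paths[["sv_vcf"]])) stop("SVN > 0 but no sv_vcf path configured")
    select_structural_variants(paths[["sv_vcf"]], params$SVN)
  } else NULL
  patho <- if (params$PVN > 0) {
    if (is.na(paths[["pathogenic_vcf"]]))
      stop("PVN > 0 but no pathogenic_vcf path configured")
    select_pathogenic_variants(paths[["pathogenic_vcf"]], params$PVN)
  } else NULL
  say("planned: ", nrow(noncoding), " non-coding draws retained, ",
      nrow(coding), " coding positions, ",
      if (is.null(svs)) 0 else nrow(svs), " SVs, ",
      if (is.null(patho)) 0 else nrow(patho), " pathogenic variants")

  plan <- structure(list(
    params = params, genome = gs, coding_model = cm,
    db_stats = list(varNum = known$varNum, cvNum = common$cvNum,
                    ecvNum = common$ecvNum),
    internal = internal, noncoding = noncoding, coding = coding,
    svs = svs, pathogenic = patho, seed = seed
  ), class = "pg_plan")
  if (!is.null(out)) write_plan(plan, out)
  plan
}

#' @export
print.pg_plan <- function(x, ...) {
  cat("diplosim simulation plan\n")
  cat("  genome: ", nrow(x$genome$contigs), " contig(s), GLN=", x$genome$GLN,
      ", nGLN=", x$genome$nGLN, ", modLen=", x$coding_model$modLen, "\n", sep = "")
  cat("  internal: paC=", signif(x$internal$paC, 5),
      " paAF=", signif(x$internal$paAF, 5),
      " eoR=", signif(x$internal$eoR, 5),
      " pnvNum=", x$internal$pnvNum, "\n", sep = "")
  cat("  planned positions: ", nrow(x$noncoding), " non-coding, ",
      nrow(x$coding), " coding\n", sep = "")
  cat("  special: ", if (is.null(x$svs)) 0 else nrow(x$svs), " SV, ",
      if (is.null(x$pathogenic)) 0 else nrow(x$pathogenic), " pathogenic\n",
      sep = "")
  invisible(x)
}

#' Serialize / load a simulation plan
#'
#' The plan is stored as a single JSON document so the simulate stage can run
#' in a separate process.
#'
#' @param plan a `pg_plan`.
#' @param path JSON file path.
#' @return `write_plan`: invisible `path`; `read_plan`: a `pg_plan`.
#' @export
write_plan <- function(plan, path) {
  params <- unclass(plan$params)
  params$paths <- as.list(params$paths)   # keep names through JSON
  doc <- list(
    params = params,
    genome = list(GLN = plan$genome$GLN, nGLN = plan$genome$nGLN,
                  contigs = plan$genome$contigs,
                  n_blocks = plan$genome$n_blocks),
    coding_model = list(modLen = plan$coding_model$modLen,
                        intervals = plan$coding_model$intervals),
    db_stats = plan$db_stats,
    internal = plan$internal,
    noncoding = plan$noncoding,
    coding = plan$coding,
    svs = plan$svs,
    pathogenic = plan$pathogenic,
    seed = plan$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- doc$params
  params$paths <- unlist(params$paths)
  class(params) <- c("pg_params_resolved", "pg_params")
  fix_df <- function(d, cols) {
    if (is.null(d) || (is.data.frame(d) && !nrow(d)) || !length(d))
      return(NULL)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  gs <- structure(list(
    GLN = doc$genome$GLN, nGLN = doc$genome$nGLN,
    contigs = as.data.frame(doc$genome$contigs),
    n_blocks = lapply(doc$genome$n_blocks, function(b)
      if (!length(b)) data.frame(start = integer(), end = integer())
      else as.data.frame(b))
  ), class = "pg_genome_stats")
  cm <- structure(list(
    intervals = lapply(doc$coding_model$intervals, as.data.frame),
    modLen = doc$coding_model$modLen
  ), class = "pg_coding_model")
  empty_pos <- data.frame(contig = character(), pos = integer(),
                          stringsAsFactors = FALSE)
  noncoding <- fix_df(doc$noncoding)
  if (is.null(noncoding)) noncoding <- cbind(empty_pos, hap = integer())
  coding <- fix_df(doc$coding)
  if (is.null(coding)) coding <- empty_pos
  structure(list(
    params = params, genome = gs, coding_model = cm,
    db_stats = doc$db_stats, internal = doc$internal,
    noncoding = noncoding, coding = coding,
    svs = fix_df(doc$svs), pathogenic = fix_df(doc$pathogenic),
    seed = doc$seed
  ), class = "pg_plan")
}

# Turn pre-selected special records into heterozygous variant rows.
.special_to_variants <- function(rec, source, ploidy) {
  if (is.null(rec) || !nrow(rec)) return(variants_empty())
  pl <- unname(ploidy[rec$chrom])
  pl[is.na(pl)] <- 2L
  hap <- 1L + (stats::runif(nrow(rec)) < 0.5)
  g1 <- ifelse(pl == 1L, 1L, ifelse(hap == 1L, 1L, 0L))
  g2 <- ifelse(pl == 1L, NA_integer_, ifelse(hap == 2L, 1L, 0L))
  alt1 <- vapply(strsplit(rec$alt, ",", fixed = TRUE), `[[`, "", 1L)
  out <- data.frame(
    contig = rec$chrom, pos = rec$pos, id = rec$id, ref = rec$ref,
    alt = alt1, end = as.integer(rec$end),
    g1 = as.integer(g1), g2 = as.integer(g2), source = source,
    info = ifelse(is.na(rec$info) | rec$info == ".", NA_character_, rec$info),
    stringsAsFactors = FALSE)
  out[pl > 0L, , drop = FALSE]
}

# Per-contig IRanges of accepted footprints (for the coding top-up loop).
.footprint_ranges <- function(vars) {
  if (!nrow(vars)) return(list())
  lapply(split(vars[c("pos", "end")], vars$contig), function(d)
    IRanges::IRanges(start = d$pos, end = d$end))
}

#' Simulate the personal-genome variants
#'
#' Runs the sampling stage on a plan: common variants at their corrected
#' background AF, non-common known variants at the practical average AF,
#' novel variants at the planned positions, plus the pre-selected structural
#' and pathogenic records. Sources are merged by priority (special > known >
#' novel) and the coding-novel count is topped up by redrawing until exactly
#' `CDN` coding novels survive the merge. The result is written as a phased
#' single-sample VCF.
#'
#' @param plan a `pg_plan` or the path of a plan JSON file.
#' @param out_vcf output VCF path (`.vcf` or `.vcf.gz`); `NULL` to skip
#'   writing.
#' @param seed integer master seed (default: the plan's seed).
#' @param quiet suppress progress messages.
#' @return invisible list with `variants` (the merged data.frame) and
#'   `counts` (records per source).
#' @export
pg_simulate <- function(plan, out_vcf = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(plan)) plan <- read_plan(plan)
  stopifnot(inherits(plan, "pg_plan"))
  if (is.null(seed)) seed <- plan$seed
  say <- function(...) if (!quiet) message("[diplosim] ", ...)
  params <- plan$params
  gs <- plan$genome
  ploidy <- ploidy_model(params$gender, gs$contigs$name)
  reference <- load_reference(params$paths[["reference"]])

  set_stage_seed(seed, "simulate")
  common <- if (plan$internal$paC > 0)
    sample_common_variants(params$paths[["common_vcf"]], params$background_pop,
                           params$CVT, plan$internal$paC, ploidy)
  else variants_empty()
  common$af <- NULL
  known <- if (plan$internal$paAF > 0)
    sample_noncommon_variants(params$paths[["known_vcf"]], params$background_pop,
                              params$CVT, plan$internal$paAF, ploidy)
  else variants_empty()
  special <- rbind(.special_to_variants(plan$svs, "sv", ploidy),
                   .special_to_variants(plan$pathogenic, "pathogenic", ploidy))
  novel_nc <- instantiate_novel(plan$noncoding, "noncoding", params,
                                reference, ploidy)
  merged <- merge_variants(special, rbind(common, known), novel_nc,
                           contig_order = gs$contigs$name)

  # coding novels: hard count guarantee via redraw-on-conflict
  CDN <- params$CDN
  coding_vars <- variants_empty()
  positions <- plan$coding
  if (CDN > 0) {
    accepted <- .footprint_ranges(merged)
    for (iter in seq_len(1000L)) {
      cand <- instantiate_novel(positions, "coding", params, reference, ploidy)
      res <- .merge_tier(cand, accepted)
      accepted <- res$accepted
      coding_vars <- rbind(coding_vars, res$vars)
      need <- CDN - nrow(coding_vars)
      if (need <= 0L) break
      positions <- plan_coding_positions(plan$coding_model, need, gs = gs)
    }
    if (nrow(coding_vars) < CDN)
      stop("unable to place ", CDN, " coding novel variants after redraws")
  }
  final <- rbind(merged, coding_vars)
  final <- final[order(match(final$contig, gs$contigs$name), final$pos), ,
                 drop = FALSE]
  rownames(final) <- NULL
  counts <- table(factor(final$source,
                         levels = c("common", "known", "novel_coding",
                                    "novel_noncoding", "sv", "pathogenic")))
  say("simulated variants by source: ",
      paste(names(counts), as.integer(counts), sep = "=", collapse = " "))
  if (!is.null(out_vcf)) {
    write_variants_vcf(final, gs, out_vcf, gender = params$gender)
    say("wrote ", out_vcf)
  }
  invisible(list(variants = final, counts = counts))
}

#' Generate the diploid genome sequences
#'
#' Applies the simulated phased variants to the reference, producing one
#' FASTA per haplotype and the two coordinate-map tables. Structural-variant
#' records are ignored at sequence level. For males, the X chromosome is
#' carried on haplotype 1 and the Y on haplotype 2; females carry X on both
#' haplotypes and no Y.
#'
#' @param vcf path of the simulated VCF.
#' @param reference reference FASTA path or a `pg_reference`.
#' @param prefix output path prefix.
#' @param gender `male`/`female`; defaults to the gender recorded in the VCF
#'   header (and to `female` when absent).
#' @param quiet suppress progress messages.
#' @return invisible list with `hap1`, `hap2` (sequence + map) and the
#'   written file paths.
#' @export
pg_generate <- function(vcf, reference, prefix, gender = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[diplosim] ", ...)
  variants <- read_simulated_vcf(vcf)
  if (is.null(gender)) {
    gender <- attr(variants, "gender")
    if (is.na(gender) || !gender %in% c("male", "female")) gender <- "female"
  }
  ref <- if (inherits(reference, "pg_reference")) reference
         else load_reference(reference)
  pl <- ploidy_model(gender, names(ref$dna))
  lc <- tolower(names(ref$dna))
  hap1_contigs <- names(ref$dna)[pl == 2L | (pl == 1L & lc %in% c("x", "chrx"))]
  hap2_contigs <- names(ref$dna)[pl == 2L | (pl == 1L & lc %in% c("y", "chry"))]
  hap1 <- apply_variants(ref, variants, 1L, contigs = hap1_contigs)
  hap2 <- apply_variants(ref, variants, 2L, contigs = hap2_contigs)
  paths <- write_outputs(hap1, hap2, prefix)
  say("wrote ", paste(basename(paths), collapse = ", "))
  invisible(list(hap1 = hap1, hap2 = hap2, paths = paths))
}

#' Run the full pipeline
#'
#' Chains [pg_plan()], [pg_simulate()] and [pg_generate()] under one master
#' seed. Outputs: `<prefix>.plan.json`, `<prefix>.vcf`, `<prefix>.hap1.fa`,
#' `<prefix>.hap2.fa`, `<prefix>.hap1.map.tsv`, `<prefix>.hap2.map.tsv`.
#'
#' @param config configuration file path or `pg_params`.
#' @param prefix output path prefix.
#' @param seed integer master seed.
#' @param quiet suppress progress messages.
#' @return invisible list with the plan, the simulation result and the
#'   output paths.
#' @export
pg_run_all <- function(config, prefix, seed = NULL, quiet = FALSE) {
  plan <- pg_plan(config, seed = seed, out = paste0(prefix, ".plan.json"),
                  quiet = quiet)
  vcf <- paste0(prefix, ".vcf")
  sim <- pg_simulate(plan, out_vcf = vcf, seed = seed, quiet = quiet)
  gen <- pg_generate(vcf, plan$params$paths[["reference"]], prefix,
                     gender = plan$params$gender, quiet = quiet)
  invisible(list(plan = plan, simulation = sim,
                 paths = c(plan = paste0(prefix, ".plan.json"), vcf = vcf,
                           gen$paths)))
}
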