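# User-controlled parameters, their ranges and defaults.
#
# Interval parameters are stored as length-2 numeric vectors c(min, max); a
# degenerate interval (min == max) pins the parameter to a single value.
# Integer-valued parameters are drawn as uniform integers inclusive of both
# bounds when resolved.

.param_table <- list(
  gender  = list(kind = "enum",  choices = c("male", "female", "any"), default = "any"),
  OVR     = list(kind = "ireal", range = c(0, 1),     default = c(0.001, 0.001)),
  KVR     = list(kind = "ireal", range = c(0, 1),     default = c(0.9, 0.9)),
  CVR     = list(kind = "ireal", range = c(0, 1),     default = c(0.8, 0.8)),
  background_pop = list(kind = "string", default = "CAF"),
  CDN     = list(kind = "iint",  range = c(0, 10000), default = c(200, 200)),
  NIDR    = list(kind = "ireal", range = c(0, 1),     default = c(0.1, 0.1)),
  NIDL    = list(kind = "sint",  range = c(2, 200),   default = 50),
  TiTv    = list(kind = "ireal", range = c(1, 5),     default = c(2.0, 2.1)),
  TiTvC   = list(kind = "ireal", range = c(1, 5),     default = c(2.8, 3.0)),
  FSR     = list(kind = "ireal", range = c(0, 1),     default = c(0.2, 0.3)),
  SVN     = list(kind = "iint",  range = c(0, 1000),  default = c(0, 0)),
  PVN     = list(kind = "iint",  range = c(0, 1000),  default = c(0, 0)),
  CVT     = list(kind = "sreal", range = c(0, 1),     default = 0.01),
  PLalpha = list(kind = "sreal", range = c(1 + 1e-9, Inf), default = 1.8)
)

.path_keys <- c("reference", "coding_bed", "known_vcf", "common_vcf",
                "sv_vcf", "pathogenic_vcf")

#' Construct a parameter set
#'
#' Builds a validated set of simulation parameters. Any parameter not supplied
#' takes its documented default. Interval parameters (`OVR`, `KVR`, `CVR`,
#' `CDN`, `NIDR`, `TiTv`, `TiTvC`, `FSR`, `SVN`, `PVN`) may be given either as
#' a single value (pinning the parameter) or as `c(min, max)`.
#'
#' @param ... named parameters; see Details.
#' @param paths named character vector/list with entries `reference`,
#'   `coding_bed`, `known_vcf`, `common_vcf`, `sv_vcf`, `pathogenic_vcf`
#'   (may be omitted for purely in-memory use).
#' @param seed optional integer master seed.
#'
#' @details The parameters and their allowed ranges:
#' \describe{
#'   \item{gender}{`male`, `female` or `any` (default `any`). Determines the
#'     sex-chromosome ploidy of the simulated individual.}
#'   \item{OVR}{overall variation rate, variants per reference base per
#'     haploid genome; in `[0, 1]`, default 0.001.}
#'   \item{KVR}{known variation rate: fraction of all variants taken from the
#'     known-variant database; in `[0, 1]`, default 0.9.}
#'   \item{CVR}{common variation rate: fraction of known variants that are
#'     common; in `[0, 1]`, default 0.8.}
#'   \item{background_pop}{INFO tag carrying the background-population allele
#'     frequency (e.g. `CAF`, `EUR_AF`); default `CAF`.}
#'   \item{CDN}{number of novel coding variants, 0 to 10000, default 200.}
#'   \item{NIDR}{novel indel rate: fraction of novel variants that are indels;
#'     in `[0, 1]`, default 0.1.}
#'   \item{NIDL}{maximum novel indel length in nt, 2 to 200, default 50.}
#'   \item{TiTv, TiTvC}{transition/transversion ratio of novel SNVs outside
#'     and inside coding regions; each in `[1, 5]`, defaults `[2.0, 2.1]` and
#'     `[2.8, 3.0]`.}
#'   \item{FSR}{frameshift retention rate for coding indels whose length is
#'     not a multiple of 3; in `[0, 1]`, default `[0.2, 0.3]`.}
#'   \item{SVN, PVN}{numbers of structural and pathogenic variants to spike
#'     in, 0 to 1000, default 0.}
#'   \item{CVT}{allele-frequency threshold above which a database record
#'     counts as common; default 0.01.}
#'   \item{PLalpha}{exponent of the discrete power-law indel length
#'     distribution; default 1.8.}
#' }
#'
#' @return An object of class `pg_params`.
#' @seealso [parse_config()], [resolve_parameters()]
#' @export
#' @examples
#' p <- parameter_set(OVR = c(0.001, 0.002), gender = "female")
#' p$OVR
parameter_set <- function(..., paths = NULL, seed = NULL) {
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop("all parameters must be named")
  unknown <- setdiff(names(user), names(.param_table))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- lapply(.param_table, `[[`, "default")
  for (k in names(user)) p[[k]] <- .coerce_param(k, user[[k]])
  p$paths <- .coerce_paths(paths, require_all = FALSE)
  p$seed <- if (is.null(seed)) NULL else as.integer(seed)
  structure(p, class = "pg_params")
}

.coerce_param <- function(key, value) {
  def <- .param_table[[key]]
  if (def$kind %in% c("enum", "string")) {
    value <- as.character(value)
    if (length(value) != 1L) stop(key, " must be a single value")
    if (def$kind == "enum" && !value %in% def$choices)
      stop(key, " must be one of: ", paste(def$choices, collapse = ", "))
    return(value)
  }
  value <- suppressWarnings(as.numeric(value))
  if (anyNA(value)) stop(key, ": non-numeric value")
  if (def$kind %in% c("ireal", "iint")) {
    if (length(value) == 1L) value <- c(value, value)
    if (length(value) != 2L) stop(key, " must be one value or an interval min,max")
    if (value[1] > value[2])
      stop(key, ": interval minimum exceeds maximum (", value[1], " > ", value[2], ")")
  } else if (length(value) != 1L) stop(key, " must be a single value")
  rng <- def$range
  if (any(value < rng[1] | value > rng[2]))
    stop(key, " out of range: allowed ", rng[1], " ≤ ", key, " ≤ ",
         if (is.finite(rng[2])) rng[2] else "Inf")
  if (def$kind %in% c("iint", "sint") && any(value != round(value)))
    stop(key, " must be integer-valued")
  value
}

.coerce_paths <- function(paths, require_all = FALSE) {
  out <- stats::setNames(rep(NA_character_, length(.path_keys)), .path_keys)
  if (!is.null(paths)) {
    paths <- as.list(paths)
    unknown <- setdiff(names(paths), .path_keys)
    if (length(unknown))
      stop("unknown database path key(s): ", paste(unknown, collapse = ", "))
    for (k in names(paths)) out[[k]] <- as.character(paths[[k]])
  }
  if (require_all && anyNA(out))
    stop("missing database path(s) in configuration: ",
         paste(.path_keys[is.na(out)], collapse = ", "))
  out
}

#' Parse a configuration file
#'
#' The configuration dialect is flat `key = value` lines; `#` starts a
#' comment; blank lines are ignored; interval parameters are written
#' `min,max`. All six database paths (`reference`, `coding_bed`, `known_vcf`,
#' `common_vcf`, `sv_vcf`, `pathogenic_vcf`) are required. Any simulation
#' parameter left out takes its default (see [parameter_set()]). An optional
#' `seed` key fixes the master seed.
#'
#' @param text character: either a path to a configuration file or the file
#'   content itself (a vector of lines, or one string with embedded newlines).
#' @return A validated `pg_params` object.
#' @export
#' @examples
#' cfg <- c("gender = female", "OVR = 0.001,0.002",
#'          "reference = ref.fa", "coding_bed = cds.bed",
#'          "known_vcf = known.vcf", "common_vcf = common.vcf",
#'          "sv_vcf = sv.vcf", "pathogenic_vcf = clin.vcf")
#' p <- parse_config(cfg)
parse_config <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*=[ \t]*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed configuration line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  if (anyDuplicated(keys))
    stop("duplicate configuration key: ", keys[duplicated(keys)][1])
  known <- c(names(.param_table), .path_keys, "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% names(.param_table)) {
      v <- vals[i]
      if (.param_table[[k]]$kind %in% c("enum", "string")) args[[k]] <- v
      else args[[k]] <- as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
    }
  }
  paths <- as.list(vals[keys %in% .path_keys])
  names(paths) <- keys[keys %in% .path_keys]
  seed <- if ("seed" %in% keys) {
    s <- suppressWarnings(as.integer(vals[keys == "seed"]))
    if (is.na(s)) stop("seed must be an integer")
    s
  } else NULL
  p <- do.call(parameter_set, c(args, list(paths = NULL, seed = seed)))
  p$paths <- .coerce_paths(paths, require_all = TRUE)
  p
}

#' Resolve interval parameters to concrete values
#'
#' Every interval parameter is collapsed to a single value drawn uniformly
#' within its interval (integer parameters: uniform integer inclusive of both
#' bounds); `gender = "any"` is resolved to `male` or `female` by a fair coin.
#' Resolution is deterministic for a fixed seed.
#'
#' @param p a `pg_params` object.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return An object of class `pg_params_resolved`: same fields as `p`, every
#'   interval replaced by one value and `gender` one of `male`/`female`.
#' @export
#' @examples
#' r <- resolve_parameters(parameter_set(), seed = 1)
#' r$TiTv   # a single value in [2.0, 2.1]
resolve_parameters <- function(p, seed = NULL) {
  stopifnot(inherits(p, "pg_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- p
  for (k in names(.param_table)) {
    def <- .param_table[[k]]
    v <- p[[k]]
    r[[k]] <- switch(def$kind,
      enum = if (k == "gender" && identical(v, "any"))
               sample(c("male", "female"), 1L) else v,
      string = v,
      ireal = if (v[1] == v[2]) v[1] else stats::runif(1, v[1], v[2]),
      iint  = if (v[1] == v[2]) as.integer(v[1])
              else sample(seq.int(v[1], v[2]), 1L),
      sint  = as.integer(v),
      sreal = v
    )
  }
  class(r) <- c("pg_params_resolved", "pg_params")
  r
}

#' @export
print.pg_params <- function(x, ...) {
  resolved <- inherits(x, "pg_params_resolved")
  cat(if (resolved) "Resolved simulation parameters\n"
      else "Simulation parameters\n")
  for (k in names(.param_table)) {
    v <- x[[k]]
    lbl <- if (is.numeric(v) && length(v) == 2L && v[1] != v[2])
      paste0("[", v[1], ", ", v[2], "]")
    else paste(unique(v), collapse = ", ")
    cat(sprintf("  %-15s %s\n", k, lbl))
  }
  if (!all(is.na(x$paths))) {
    cat("  databases:\n")
    for (k in .path_keys)
      if (!is.na(x$paths[[k]])) cat(sprintf("    %-13s %s\n", k, x$paths[[k]]))
  }
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
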