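#' @include AllClasses.R
NULL

#' Scoring parameters for the built-in similarity backend
#'
#' Substitution scoring, affine gap costs and Karlin-Altschul statistics used
#' by every alignment operation in the package. A gap of length L costs
#' `gapOpen + L * gapExtend`. The default lambda and K are the standard
#' published values for gapped BLOSUM62 with open 11 / extend 1; `dbSize`
#' (total residue count of the searched database) may be left `NULL` and is
#' then taken from the database actually searched.
#'
#' @param substitutionMatrix integer substitution matrix over the 21-letter
#'   alphabet (20 residues + X); defaults to BLOSUM62.
#' @param gapOpen,gapExtend positive integer gap costs.
#' @param lambda,K Karlin-Altschul scale and constant.
#' @param dbSize optional database residue count.
#' @return a list of class `ScoringParams`.
#' @export
scoringParams <- function(substitutionMatrix = NULL, gapOpen = 11L,
                          gapExtend = 1L, lambda = 0.267, K = 0.041,
                          dbSize = NULL) {
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  stopifnot(lambda > 0, K > 0, gapOpen > 0, gapExtend > 0,
            gapExtend <= gapOpen)
  if (!identical(dim(substitutionMatrix), c(21L, 21L)))
    stop("substitutionMatrix must be 21 x 21 (20 residues + X)")
  storage.mode(substitutionMatrix) <- "integer"
  structure(list(substitutionMatrix = substitutionMatrix,
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend),
                 lambda = lambda, K = K, dbSize = dbSize),
            class = "ScoringParams")
}

#' Karlin-Altschul bit score and E-value
#'
#' `bitScore` converts a raw alignment score into bits,
#' `bit = (lambda * raw - ln K) / ln 2`; `eValue` converts bits into the
#' expected number of chance matches, `E = m * n * 2^-bit`, with `m` the
#' query length and `n` the database residue count. Bit scores are
#' independent of the search-space size; E-values are not.
#'
#' @param raw raw (matrix-unit) alignment score.
#' @param params [scoringParams()].
#' @param bit bit score.
#' @param m query length in residues.
#' @param n database size in residues.
#' @return numeric vector.
#' @export
bitScore <- function(raw, params = scoringParams()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' @rdname bitScore
#' @export
eValue <- function(bit, m, n) m * n * 2^(-bit)

.as_seq_chr <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else stop("sequences must be an AAStringSet or character vector")
  if (any(nchar(out) == 0L)) stop("empty sequence")
  out
}

.hit_df <- function(query, target, raw, params, m, n, tstart, tend) {
  bit <- bitScore(raw, params)
  data.frame(query = query, target = target, raw = raw, bit_score = bit,
             evalue = eValue(bit, m, n), tstart = tstart, tend = tend,
             stringsAsFactors = FALSE)
}

#' Construct a hit table
#'
#' Sorts hits by bit score descending (ties by target id ascending) and
#' validates the Karlin-Altschul invariants.
#'
#' @param hits data.frame with columns query, target, raw, bit_score,
#'   evalue, tstart, tend.
#' @param dbSize database residue count.
#' @param traces optional list of integer column traces parallel to `hits`.
#' @return a [HitTable-class].
#' @export
hitTable <- function(hits, dbSize, traces = list()) {
  o <- order(-hits$bit_score, hits$target)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  if (length(traces)) traces <- traces[o]
  new("HitTable", hits = hits, traces = traces, dbSize = as.numeric(dbSize))
}

#' @describeIn hitTable ranked hits as a data.frame.
#' @param x,object a `HitTable`.
#' @export
hits <- function(x) x@hits

#' @describeIn hitTable database residue count searched.
#' @export
dbSize <- function(x) x@dbSize

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment under affine gaps, reported as a hit with raw
#' score, bit score, E-value (query length x database size search space),
#' aligned ranges and a column trace mapping query positions to target
#' positions. With a symmetric substitution matrix the raw score is
#' symmetric in its arguments; the E-value uses the query length, so the two
#' directions can differ when lengths differ.
#'
#' @param a,b single sequences (character or length-1 `AAStringSet`); `a` is
#'   the query.
#' @param params [scoringParams()]; `dbSize`, when set, is the search-space
#'   size, otherwise the target length is used.
#' @return list with elements query, target, raw, bit_score, evalue,
#'   qstart, qend, tstart, tend, matches, columns, pct_identity, trace.
#' @export
alignLocal <- function(a, b, params = scoringParams()) {
  qa <- .as_seq_chr(a); qb <- .as_seq_chr(b)
  stopifnot(length(qa) == 1L, length(qb) == 1L)
  r <- cpp_local_align(qa, qb, params$substitutionMatrix, .ALPHABET_STR,
                       params$gapOpen, params$gapExtend)
  m <- nchar(qa)
  n <- if (is.null(params$dbSize)) nchar(qb) else params$dbSize
  bit <- bitScore(r$score, params)
  list(query = if (!is.null(names(a))) names(a) else "query",
       target = if (!is.null(names(b))) names(b) else "target",
       raw = r$score, bit_score = bit, evalue = eValue(bit, m, n),
       qstart = r$qstart, qend = r$qend, tstart = r$tstart, tend = r$tend,
       matches = r$matches, columns = r$columns,
       pct_identity = if (r$columns > 0) 100 * r$matches / r$columns else 0,
       trace = r$trace)
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Alignment columns with more than 50% gap characters are excluded; each
#' retained column scores residue `a` as
#' `round(2 * log2(((count_a + 1) / (nrows + 20)) / (1/20)))` -- an integer
#' log-odds in half-bit units against a uniform background with one
#' pseudocount per residue. X scores 0 (neutral) everywhere. The
#' profile-to-MSA column correspondence is kept in `columnMap`.
#'
#' @param msa a [StockholmAlignment-class] with at least 2 rows.
#' @param params [scoringParams()] (reserved for alternative backgrounds).
#' @param sourceNode name of the hierarchy node the seed MSA belongs to.
#' @return a [ProfileModel-class].
#' @export
buildProfile <- function(msa, params = scoringParams(), sourceNode = "") {
  stopifnot(is(msa, "StockholmAlignment"))
  nr <- length(msa@rows)
  if (nr < 2L) stop("insufficient depth: profile needs an MSA with >= 2 rows")
  mat <- do.call(rbind, strsplit(toupper(msa@rows), ""))
  isgap <- mat == "-" | mat == "."
  keep <- which(colMeans(isgap) <= 0.5)
  if (!length(keep)) stop("no match columns: every column is gap-majority")
  bg <- 1 / 20
  scores <- matrix(0L, nrow = length(keep), ncol = length(.ALPHABET),
                   dimnames = list(NULL, .ALPHABET))
  for (ci in seq_along(keep)) {
    col <- mat[, keep[ci]]
    col <- col[!(col %in% c("-", ".", "X"))]
    counts <- table(factor(col, levels = .AA20))
    lo <- log2(((as.numeric(counts) + 1) / (nr + 20)) / bg)
    scores[ci, .AA20] <- as.integer(round(2 * lo))
  }
  new("ProfileModel", scores = scores, columnMap = as.integer(keep),
      sourceNode = sourceNode)
}

#' @describeIn buildProfile number of profile (match) columns.
#' @param profile a `ProfileModel`.
#' @export
profileWidth <- function(profile) nrow(profile@scores)

#' @describeIn buildProfile profile column -> seed MSA column map.
#' @export
profileColumnMap <- function(profile) profile@columnMap

#' Search a sequence database with a profile
#'
#' Scores every database sequence by glocal dynamic programming: global in
#' the profile (skipped profile columns are penalized as deletions) and
#' local in the sequence (free flanks), which matches how a whole-domain
#' model is scored against subsequences of multi-domain proteins. One hit
#' per target, ranked by bit score; the column trace of every hit is kept
#' for downstream residue checks.
#'
#' @param profile a [ProfileModel-class].
#' @param db named `AAStringSet` (or named character vector).
#' @param params [scoringParams()]; `dbSize` defaults to the total residue
#'   count of `db`.
#' @return a [HitTable-class].
#' @export
searchProfile <- function(profile, db, params = scoringParams()) {
  sq <- .as_seq_chr(db)
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    stop("database sequences must have unique names")
  n <- if (is.null(params$dbSize)) sum(nchar(sq)) else params$dbSize
  W <- profileWidth(profile)
  res <- lapply(sq, function(s)
    cpp_profile_search(profile@scores, s, .ALPHABET_STR,
                       params$gapOpen, params$gapExtend))
  raw <- vapply(res, `[[`, numeric(1), "score")
  df <- .hit_df(query = profile@sourceNode, target = names(sq), raw = raw,
                params = params, m = W, n = n,
                tstart = vapply(res, `[[`, numeric(1), "tstart"),
                tend = vapply(res, `[[`, numeric(1), "tend"))
  hitTable(df, dbSize = n, traces = lapply(res, `[[`, "trace"))
}

#' Import a hit table computed by an external search tool
#'
#' Reads HMMER3 `--tblout` tables (`dialect = "hmmer_tblout"`) or BLAST
#' `-outfmt 6` tabular output (`dialect = "blast_tab6"`) into the package's
#' hit-table contract, so gathering-threshold calibration is backend
#' agnostic: the calibration consumes only ranked bit scores. Raw scores are
#' back-computed from the bit scores; rows with malformed numeric fields are
#' rejected with their line numbers.
#'
#' @param path tabular file.
#' @param dialect `"hmmer_tblout"` or `"blast_tab6"`.
#' @param params [scoringParams()] (for the bit/raw conversion only).
#' @param dbSize database residue count to record (default 0 = unknown).
#' @return a [HitTable-class].
#' @export
importHits <- function(path, dialect = c("hmmer_tblout", "blast_tab6"),
                       params = scoringParams(), dbSize = 0) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(query = character(), target = character(),
                      raw = numeric(), bit_score = numeric(),
                      evalue = numeric(), tstart = numeric(), tend = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(hitTable(empty, dbSize))
  fields <- strsplit(lines, "\\s+")
  parse_num <- function(x, what, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop(sprintf("malformed %s at line %d", what, ln[which(is.na(v))[1L]]))
    v
  }
  if (dialect == "hmmer_tblout") {
    short <- vapply(fields, length, integer(1)) < 9L
    if (any(short)) stop(sprintf("malformed line %d: too few fields",
                                 lineno[which(short)[1L]]))
    target <- vapply(fields, `[[`, character(1), 1L)
    query <- vapply(fields, `[[`, character(1), 3L)
    evalue <- parse_num(vapply(fields, `[[`, character(1), 5L), "E-value", lineno)
    bit <- parse_num(vapply(fields, `[[`, character(1), 6L), "bit score", lineno)
    tstart <- rep(NA_real_, length(bit)); tend <- tstart
  } else {
    short <- vapply(fields, length, integer(1)) < 12L
    if (any(short)) stop(sprintf("malformed line %d: too few fields",
                                 lineno[which(short)[1L]]))
    query <- vapply(fields, `[[`, character(1), 1L)
    target <- vapply(fields, `[[`, character(1), 2L)
    tstart <- parse_num(vapply(fields, `[[`, character(1), 9L), "sstart", lineno)
    tend <- parse_num(vapply(fields, `[[`, character(1), 10L), "send", lineno)
    evalue <- parse_num(vapply(fields, `[[`, character(1), 11L), "E-value", lineno)
    bit <- parse_num(vapply(fields, `[[`, character(1), 12L), "bit score", lineno)
  }
  raw <- (bit * log(2) + log(params$K)) / params$lambda
  df <- data.frame(query = query, target = target, raw = raw, bit_score = bit,
                   evalue = evalue, tstart = tstart, tend = tend,
                   stringsAsFactors = FALSE)
  hitTable(df, dbSize)
}

#' Write a hit table as TSV
#'
#' Columns: query, target, bit_score, evalue, tstart, tend.
#'
#' @param x a [HitTable-class].
#' @param path output file.
#' @export
writeHitTable <- function(x, path) {
  stopifnot(is(x, "HitTable"))
  df <- x@hits[, c("query", "target", "bit_score", "evalue", "tstart", "tend")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
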