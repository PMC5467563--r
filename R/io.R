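#' @include backend.R
NULL

# Residue policy: uppercase; ambiguity codes B J Z O U are X-substituted with
# a warning; any other non-alphabet character is an error.
.normalize_residues <- function(x, ids = names(x)) {
  up <- toupper(unname(x))
  if (any(up != unname(x)))
    warning("lowercase residues uppercased")
  amb <- grepl("[BJZOU]", up)
  if (any(amb)) {
    warning(sprintf("ambiguity codes (BJZOU) in %d sequence(s) substituted with X",
                    sum(amb)))
    up <- chartr("BJZOU", "XXXXX", up)
  }
  bad <- grepl(sprintf("[^%s]", .ALPHABET_STR), up)
  if (any(bad))
    stop(sprintf("illegal residue character in sequence '%s'",
                 if (!is.null(ids)) ids[bad][1L] else as.character(which(bad)[1L])))
  names(up) <- ids
  up
}

#' Read / write protein FASTA
#'
#' Ids are the first whitespace-delimited token of each header; the
#' remainder is kept as the `description` metadata column. Residues are
#' uppercased; ambiguity codes B/J/Z/O/U are substituted with X (warning);
#' other non-standard letters are an error. Duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return named `AAStringSet` with a `description` metadata column.
#' @export
readFastaRecords <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("empty FASTA file")
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id '%s'", ids[duplicated(ids)][1L]))
  sq <- .normalize_residues(setNames(as.character(raw), ids))
  out <- Biostrings::AAStringSet(sq)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' @rdname readFastaRecords
#' @param seqs named `AAStringSet` (a `description` metadata column, when
#'   present, is appended to the headers).
#' @export
writeFastaRecords <- function(seqs, path) {
  stopifnot(is(seqs, "XStringSet"))
  if (anyDuplicated(names(seqs))) stop("duplicate id")
  out <- seqs
  mc <- S4Vectors::mcols(seqs)
  if (!is.null(mc) && "description" %in% names(mc)) {
    d <- mc$description
    names(out) <- ifelse(nzchar(d), paste(names(seqs), d), names(seqs))
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Construct an alignment object
#'
#' @param rows named character vector of equal-width gapped rows.
#' @param gc named list of per-column annotation strings (`#=GC` lines).
#' @return a [StockholmAlignment-class].
#' @export
stockholmAlignment <- function(rows, gc = list()) {
  new("StockholmAlignment", rows = rows, gc = gc)
}

#' @describeIn stockholmAlignment alignment width (columns).
#' @param x a `StockholmAlignment`.
#' @export
alignmentWidth <- function(x) if (length(x@rows)) nchar(x@rows[[1L]]) else 0L

#' @describeIn stockholmAlignment named gapped rows.
#' @export
alignmentRows <- function(x) x@rows

#' @describeIn stockholmAlignment per-column annotations.
#' @export
gcAnnotations <- function(x) x@gc

#' Read / write Stockholm 1.0 alignments
#'
#' Single-alignment Stockholm with `#=GC` per-column annotation lines
#' preserved (the functional-residue column mask travels under the reserved
#' tag `FUNC_RES`). Interleaved (multi-block) input is supported; output is
#' written as a single block. Ragged alignments are rejected naming the
#' offending row.
#'
#' @param path Stockholm file.
#' @return a [StockholmAlignment-class].
#' @export
readStockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#\\s*STOCKHOLM", lines[1L]))
    stop("not a Stockholm file (missing '# STOCKHOLM 1.0' header)")
  rows <- list()
  gc <- list()
  for (ln in lines[-1L]) {
    if (grepl("^//", ln)) break
    if (!nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 3L) stop(sprintf("malformed #=GC line: '%s'", ln))
      tag <- f[2L]
      gc[[tag]] <- paste0(if (is.null(gc[[tag]])) "" else gc[[tag]], f[3L])
      next
    }
    if (grepl("^#", ln)) next  # other annotation lines are ignored
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2L) stop(sprintf("malformed sequence line: '%s'", ln))
    rows[[f[1L]]] <- paste0(if (is.null(rows[[f[1L]]])) "" else rows[[f[1L]]],
                            f[2L])
  }
  if (!length(rows)) stop("Stockholm file contains no sequence rows")
  v <- unlist(rows)
  w <- nchar(v)
  if (length(unique(w)) > 1L)
    stop(sprintf("ragged alignment: row '%s' has width %d, expected %d",
                 names(v)[which(w != max(w))[1L]], min(w), max(w)))
  stockholmAlignment(v, gc)
}

#' @rdname readStockholm
#' @param x a [StockholmAlignment-class].
#' @export
writeStockholm <- function(x, path) {
  stopifnot(is(x, "StockholmAlignment"))
  validObject(x)
  pad <- max(nchar(names(x@rows)), nchar(paste0("#=GC ", names(x@gc))), 10L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  for (i in seq_along(x@rows))
    writeLines(sprintf("%-*s %s", pad, names(x@rows)[i], x@rows[[i]]), con)
  for (i in seq_along(x@gc))
    writeLines(sprintf("%-*s %s", pad, paste0("#=GC ", names(x@gc)[i]),
                       x@gc[[i]]), con)
  writeLines("//", con)
  invisible(path)
}

#' Derive functional-residue specifications from a #=GC mask
#'
#' Columns marked in the `FUNC_RES` (or other) `#=GC` annotation -- any
#' character other than `.` or `-` counts as a mark -- become residue
#' specifications whose allowed set is the set of residues observed in that
#' column of the alignment.
#'
#' @param msa a [StockholmAlignment-class].
#' @param tag `#=GC` tag holding the mask (default `"FUNC_RES"`).
#' @param role role text applied to every derived spec.
#' @return data.frame of residue specs (msa_column, allowed, role).
#' @export
residueSpecsFromMask <- function(msa, tag = "FUNC_RES", role = "") {
  stopifnot(is(msa, "StockholmAlignment"))
  mask <- msa@gc[[tag]]
  if (is.null(mask)) stop(sprintf("no #=GC %s annotation", tag))
  marks <- which(!(strsplit(mask, "")[[1]] %in% c(".", "-")))
  if (!length(marks))
    return(data.frame(msa_column = integer(), allowed = character(),
                      role = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(marks, function(col) {
    residues <- unique(substr(msa@rows, col, col))
    residues <- sort(residues[!(residues %in% c("-", "."))])
    data.frame(msa_column = col, allowed = paste(residues, collapse = ""),
               role = role, stringsAsFactors = FALSE)
  }))
}

#' Align a query sequence onto a node's seed alignment
#'
#' The query is searched against the node's profile and appended as the
#' final alignment row, gapped according to its profile column trace:
#' profile match columns show the aligned query residue, deleted columns and
#' non-match columns show gaps. Query residues falling between profile
#' columns (insertions) are not displayed -- existing rows are never
#' modified. Queries with no positive-scoring path are rejected.
#'
#' @param query single named sequence (length-1 `AAStringSet` or named
#'   character).
#' @param node a [HierarchyNode-class] with a profile and seed MSA.
#' @param params [scoringParams()].
#' @return a [StockholmAlignment-class] with the query as last row.
#' @export
alignQueryToMsa <- function(query, node, params = scoringParams()) {
  stopifnot(is(node, "HierarchyNode"))
  if (is.null(node@profile) || is.null(node@seedMsa))
    stop(sprintf("node '%s' has no profile/seed MSA", node@name))
  sq <- .as_seq_chr(query)
  stopifnot(length(sq) == 1L)
  qid <- if (!is.null(names(sq))) names(sq) else "query"
  if (qid %in% names(node@seedMsa@rows)) qid <- paste0(qid, "_query")
  r <- cpp_profile_search(node@profile@scores, unname(sq), .ALPHABET_STR,
                          params$gapOpen, params$gapExtend)
  if (r$score <= 0) stop("query unalignable: no positive-scoring path")
  w <- alignmentWidth(node@seedMsa)
  rowchars <- rep("-", w)
  cm <- node@profile@columnMap
  for (k in seq_along(cm)) {
    if (r$trace[k] > 0)
      rowchars[cm[k]] <- substr(sq, r$trace[k], r$trace[k])
  }
  rows <- c(node@seedMsa@rows, setNames(paste(rowchars, collapse = ""), qid))
  stockholmAlignment(rows, node@seedMsa@gc)
}

#' Plain-text rendering of an alignment with functional columns marked
#'
#' Renders the rows with a final caret line marking functional-residue
#' columns (the text analogue of highlighting conserved residues in an
#' alignment viewer).
#'
#' @param msa a [StockholmAlignment-class].
#' @param columns 1-based columns to mark; defaults to the `FUNC_RES` mask
#'   when present.
#' @return character vector of lines.
#' @export
renderAlignmentText <- function(msa, columns = NULL) {
  stopifnot(is(msa, "StockholmAlignment"))
  if (is.null(columns) && !is.null(msa@gc[["FUNC_RES"]]))
    columns <- which(!(strsplit(msa@gc[["FUNC_RES"]], "")[[1]] %in% c(".", "-")))
  pad <- max(nchar(names(msa@rows)), 1L)
  lines <- sprintf("%-*s %s", pad, names(msa@rows), msa@rows)
  marks <- rep(" ", alignmentWidth(msa))
  if (length(columns)) marks[columns] <- "^"
  c(lines, sprintf("%-*s %s", pad, "", paste(marks, collapse = "")))
}
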