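#' @include backend.R
NULL

#' Configuration for seed-set reduction
#'
#' Curation practice caps seed alignments at roughly 250 sequences: larger
#' alignments are hard to curate by hand, slow to compute with, and biased
#' by over-represented lineages. The reduction first drops fragments, then
#' walks a descending identity ladder, clustering greedily at each rung and
#' keeping representatives, until the representative count fits the cap.
#'
#' @param cap maximum seed count (default 250).
#' @param identityLadder strictly decreasing identity fractions in (0, 1].
#' @param minLengthFraction fragments shorter than this fraction of the
#'   median sequence length are dropped before clustering (default 0.5);
#'   over-short and over-long sequences distort seed MSAs and the profiles
#'   built from them.
#' @return a list of class `SeedConfig`.
#' @export
seedConfig <- function(cap = 250L,
                       identityLadder = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                       minLengthFraction = 0.5) {
  stopifnot(cap >= 1, length(identityLadder) >= 1,
            all(identityLadder > 0), all(identityLadder <= 1),
            all(diff(identityLadder) < 0),
            minLengthFraction >= 0, minLengthFraction <= 1)
  structure(list(cap = as.integer(cap), identityLadder = identityLadder,
                 minLengthFraction = minLengthFraction),
            class = "SeedConfig")
}

#' Pairwise global sequence identity
#'
#' Identity of the optimal global (Needleman-Wunsch) alignment under the
#' backend scoring scheme: identical aligned positions divided by the
#' alignment length (gap columns included). Symmetric in its arguments.
#'
#' @param a,b single sequences (character or length-1 `AAStringSet`).
#' @param params [scoringParams()].
#' @return identity fraction in \[0, 1\].
#' @export
pairwiseIdentity <- function(a, b, params = scoringParams()) {
  qa <- .as_seq_chr(a); qb <- .as_seq_chr(b)
  stopifnot(length(qa) == 1L, length(qb) == 1L)
  cpp_global_align(qa, qb, params$substitutionMatrix, .ALPHABET_STR,
                   params$gapOpen, params$gapExtend)$identity
}

# canonical processing order: length desc, then id asc
.seed_order <- function(seqs) order(-nchar(seqs), names(seqs))

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are processed in canonical order (length descending, id
#' ascending, which makes the result independent of input order). The first
#' sequence seeds cluster 1; each subsequent sequence joins the first
#' existing cluster whose representative it matches at or above the
#' threshold, otherwise it seeds a new cluster. Representatives are the
#' seeding sequences.
#'
#' @param seqs named `AAStringSet` or named character vector.
#' @param identity threshold fraction in (0, 1].
#' @param params [scoringParams()].
#' @return data.frame with columns id, cluster, representative, is_rep, in
#'   canonical processing order.
#' @export
greedyCluster <- function(seqs, identity, params = scoringParams()) {
  sq <- .as_seq_chr(seqs)
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    stop("sequences must have unique names")
  stopifnot(identity > 0, identity <= 1)
  o <- .seed_order(sq)
  sq <- sq[o]
  cl <- cpp_greedy_cluster(unname(sq), identity, params$substitutionMatrix,
                           .ALPHABET_STR, params$gapOpen, params$gapExtend)
  reps <- names(sq)[!duplicated(cl)][order(unique(cl))]
  data.frame(id = names(sq), cluster = cl, representative = reps[cl],
             is_rep = !duplicated(cl), stringsAsFactors = FALSE)
}

#' Reduce a sequence set to a bounded, diversity-sampling seed set
#'
#' Drops fragments below `minLengthFraction` of the median length, then
#' walks the identity ladder from the highest rung down, greedily clustering
#' the whole filtered set at each rung and keeping cluster representatives,
#' stopping at the first rung whose representative count fits the cap. If
#' the ladder is exhausted with more representatives than the cap, the cap
#' longest representatives are kept (ties by id). The result samples the
#' entire input: every filtered sequence is at least final-rung identical to
#' some retained representative (unless hard truncation occurred).
#'
#' @param seqs named `AAStringSet` (or named character vector).
#' @param cfg [seedConfig()].
#' @param params [scoringParams()].
#' @return `AAStringSet` of retained seed sequences, with a `report`
#'   attribute (data.frame: id, representative, rung) mapping every filtered
#'   input sequence to its representative at the final rung.
#' @export
reduceSeedSet <- function(seqs, cfg = seedConfig(), params = scoringParams()) {
  sq <- .as_seq_chr(seqs)
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    stop("sequences must have unique names")
  med <- stats::median(nchar(sq))
  keep <- nchar(sq) >= cfg$minLengthFraction * med
  if (!any(keep)) stop("no full-length sequences after fragment filter")
  sq <- sq[keep]
  report <- NULL
  chosen <- names(sq)
  rung_used <- NA_real_
  if (length(sq) > cfg$cap) {
    for (rung in cfg$identityLadder) {
      cl <- greedyCluster(sq, rung, params)
      reps <- cl$id[cl$is_rep]
      rung_used <- rung
      report <- data.frame(id = cl$id, representative = cl$representative,
                           rung = rung, stringsAsFactors = FALSE)
      if (length(reps) <= cfg$cap) { chosen <- reps; break }
      chosen <- reps
    }
    if (length(chosen) > cfg$cap) {
      # ladder exhausted: keep the cap longest representatives, ties by id
      o <- order(-nchar(sq[chosen]), chosen)
      chosen <- chosen[o][seq_len(cfg$cap)]
      report$representative[!report$representative %in% chosen] <- NA_character_
    }
  } else {
    report <- data.frame(id = names(sq), representative = names(sq),
                         rung = NA_real_, stringsAsFactors = FALSE)
  }
  out <- Biostrings::AAStringSet(sq[chosen])
  attr(out, "report") <- report
  attr(out, "rung") <- rung_used
  out
}
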