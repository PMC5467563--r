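#' @include backend.R
NULL

#' Configuration for gathering-threshold calibration
#'
#' @param dropFraction relative fall between consecutive ranked bit scores
#'   that counts as a "large drop" (default 0.10).
#' @param manualGA optional curator override for the gathering threshold;
#'   when set, the computed GA is replaced and the method recorded as
#'   `manual`.
#' @return a list of class `CalibrationConfig`.
#' @export
calibrationConfig <- function(dropFraction = 0.10, manualGA = NULL) {
  stopifnot(dropFraction > 0, dropFraction < 1)
  structure(list(dropFraction = dropFraction, manualGA = manualGA),
            class = "CalibrationConfig")
}

#' Locate the first large drop in a ranked bit-score list
#'
#' Scanning from the top of a descending score list, returns the smallest
#' index `i` such that `(scores[i] - scores[i+1]) / scores[i] >=
#' dropFraction`, i.e. the rank of the last score before the drop.
#'
#' @param scores descending numeric vector of positive bit scores.
#' @param dropFraction relative drop threshold.
#' @return the index, or `NA_integer_` if no such drop exists.
#' @export
findDrop <- function(scores, dropFraction = 0.10) {
  if (length(scores) == 0L) return(NA_integer_)
  if (any(scores <= 0)) stop("bit scores must be positive")
  if (is.unsorted(rev(scores))) stop("scores must be sorted descending")
  if (length(scores) < 2L) return(NA_integer_)
  rel <- (scores[-length(scores)] - scores[-1L]) / scores[-length(scores)]
  i <- which(rel >= dropFraction - 1e-12)
  if (length(i)) i[1L] else NA_integer_
}

#' Bit score at which the entire seed set is captured
#'
#' The score of the lowest-ranked hit at which every seed id has appeared in
#' the ranking, i.e. the minimum seed bit score. Returns `NA` if any seed is
#' absent from the table.
#'
#' @param table a [HitTable-class] (one hit per target; best-per-target is
#'   taken if duplicates slipped in).
#' @param seedIds non-empty character vector of seed sequence ids.
#' @return bit score, or `NA_real_`.
#' @export
seedCaptureScore <- function(table, seedIds) {
  stopifnot(is(table, "HitTable"))
  if (!length(seedIds)) stop("empty seed set")
  h <- .best_per_target(table@hits)
  idx <- match(seedIds, h$target)
  if (anyNA(idx)) return(NA_real_)
  min(h$bit_score[idx])
}

.best_per_target <- function(h) {
  h <- h[order(-h$bit_score, h$target), , drop = FALSE]
  h[!duplicated(h$target), , drop = FALSE]
}

#' Calibrate trusted, noise and gathering cutoffs for a profile
#'
#' Implements the automatic threshold rule used when a sequence database is
#' ranked against a profile: two candidate trusted cutoffs are computed --
#' the score before the first relative drop of at least `dropFraction`
#' (default 10%) in the ranked bit scores, and the score at which the entire
#' seed set is captured. When both exist the lower is the trusted cutoff
#' (TC). The noise cutoff (NC) is the next strictly lower score in the
#' ranking (equal-score runs count as one rank); when no hit follows the TC,
#' NC equals TC -- in particular, when the only obtainable score is the
#' seed-capture score, TC = NC = that score. The gathering threshold GA is
#' the arithmetic midpoint `(TC + NC) / 2`, deliberately lax: stricter
#' specificity comes from the conserved-residue post-processing, not from
#' the score alone. Calibration uses the best score per target.
#'
#' @param table a [HitTable-class], non-empty.
#' @param seedIds seed sequence ids (the profile's seed alignment members).
#' @param cfg [calibrationConfig()].
#' @return a [Cutoffs-class].
#' @export
computeCutoffs <- function(table, seedIds, cfg = calibrationConfig()) {
  stopifnot(is(table, "HitTable"))
  if (!length(seedIds)) stop("empty seed set")
  h <- .best_per_target(table@hits)
  if (!nrow(h)) stop("empty hit table")
  u <- unique(h$bit_score)  # descending unique score ranks
  u <- u[u > 0]             # non-positive bits are beneath any threshold
  diag <- character()

  candDrop <- NA_real_
  di <- findDrop(u, cfg$dropFraction)
  if (!is.na(di)) candDrop <- u[di]
  candSeed <- seedCaptureScore(table, seedIds)

  if (is.na(candDrop) && is.na(candSeed)) {
    if (!is.null(cfg$manualGA)) {
      return(new("Cutoffs", tc = cfg$manualGA, nc = cfg$manualGA,
                 ga = cfg$manualGA, method = "manual",
                 diagnostics = "no automatic candidate; curator-set GA"))
    }
    stop("calibration failed: curator decision required (no score drop and seed set not captured)")
  }
  if (!is.na(candDrop) && !is.na(candSeed)) {
    tc <- min(candDrop, candSeed)
    method <- "lower_of_both"
    if (candSeed < candDrop && di < length(u) && candSeed < u[di + 1L])
      diag <- c(diag, "seed-capture score lies below the noise score of the first drop; review seed set")
  } else if (!is.na(candDrop)) {
    tc <- candDrop
    method <- "drop"
  } else {
    tc <- candSeed
    method <- "seed_capture"
  }
  lower <- u[u < tc]
  nc <- if (length(lower)) lower[1L] else tc
  if (nc == tc && method == "seed_capture")
    diag <- c(diag, "only the seed-capture score was obtainable; TC = NC = seed score")
  ga <- (tc + nc) / 2
  if (!is.null(cfg$manualGA)) {
    ga <- cfg$manualGA
    method <- "manual"
    diag <- c(diag, "gathering threshold set manually by curator")
  }
  new("Cutoffs", tc = tc, nc = nc, ga = ga, method = method,
      diagnostics = if (length(diag)) paste(diag, collapse = "; ") else "")
}

#' Accessors for calibrated cutoffs
#'
#' @param x a [Cutoffs-class].
#' @return numeric bit score.
#' @export
trustedCutoff <- function(x) x@tc

#' @rdname trustedCutoff
#' @export
noiseCutoff <- function(x) x@nc

#' @rdname trustedCutoff
#' @export
gatheringThreshold <- function(x) x@ga

#' Read/write cutoffs as JSON
#'
#' @param x a [Cutoffs-class].
#' @param path JSON file.
#' @export
writeCutoffsJson <- function(x, path) {
  stopifnot(is(x, "Cutoffs"))
  jsonlite::write_json(list(tc = x@tc, nc = x@nc, ga = x@ga,
                            method = x@method, diagnostics = x@diagnostics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCutoffsJson
#' @export
readCutoffsJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Cutoffs", tc = j$tc, nc = j$nc, ga = j$ga, method = j$method,
      diagnostics = j$diagnostics)
}
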