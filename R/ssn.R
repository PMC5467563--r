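#' @include seed.R
NULL

#' Build a sequence similarity network
#'
#' All-vs-all Smith-Waterman under the backend scoring scheme. For each
#' unordered pair the raw score (symmetric) is converted to a bit score, and
#' the retained E-value is the larger (less significant) of the two
#' directional E-values -- i.e. the one computed with the longer sequence as
#' query -- giving conservative edges. An edge is drawn iff that E-value is
#' at most `maxEvalue`. Every node carries its sequence length; singletons
#' are kept.
#'
#' @param seqs named `AAStringSet` of at least 2 sequences (full-length
#'   sequences: one node per sequence).
#' @param params [scoringParams()]; `dbSize` defaults to the total residue
#'   count of `seqs`.
#' @param maxEvalue edge-inclusion E-value ceiling (default 10).
#' @return a [SimilarityNetwork-class] of kind `full`.
#' @export
buildNetwork <- function(seqs, params = scoringParams(), maxEvalue = 10) {
  sq <- .as_seq_chr(seqs)
  if (length(sq) < 2L) stop("a similarity network needs at least 2 sequences")
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    stop("sequences must have unique names")
  sq <- sq[order(names(sq))]  # canonical order: input-order invariance
  n_db <- if (is.null(params$dbSize)) sum(nchar(sq)) else params$dbSize
  b <- cpp_local_batch(unname(sq), params$substitutionMatrix, .ALPHABET_STR,
                       params$gapOpen, params$gapExtend)
  bit <- bitScore(b$score, params)
  len <- nchar(sq)
  m <- pmax(len[b$i], len[b$j])  # longer query gives the larger E-value
  ev <- eValue(bit, m, n_db)
  keep <- ev <= maxEvalue
  edges <- data.frame(from = names(sq)[b$i][keep], to = names(sq)[b$j][keep],
                      evalue = ev[keep], bit_score = bit[keep],
                      pct_identity = ifelse(b$columns[keep] > 0,
                                            100 * b$matches[keep] / b$columns[keep],
                                            0),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = names(sq), length = unname(len),
                      stringsAsFactors = FALSE)
  new("SimilarityNetwork", nodes = nodes, edges = edges, kind = "full",
      metadata = list(max_evalue = maxEvalue, db_size = n_db,
                      gap_open = params$gapOpen, gap_extend = params$gapExtend))
}

#' @describeIn buildNetwork node table accessor.
#' @param net a `SimilarityNetwork`.
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn buildNetwork edge table accessor.
#' @export
networkEdges <- function(net) net@edges

#' Keep only edges at or below an E-value cutoff
#'
#' Nodes are always retained, so singletons stay visible: the network keeps
#' showing the coverage of the sequence space even at stringent thresholds.
#'
#' @param net a [SimilarityNetwork-class].
#' @param evalueCutoff positive E-value ceiling.
#' @return the thresholded network.
#' @export
applyThreshold <- function(net, evalueCutoff) {
  stopifnot(is(net, "SimilarityNetwork"), evalueCutoff > 0)
  net@edges <- net@edges[net@edges$evalue <= evalueCutoff, , drop = FALSE]
  rownames(net@edges) <- NULL
  net@metadata$threshold <- evalueCutoff
  net
}

#' Connected components of a network
#'
#' @param net a [SimilarityNetwork-class].
#' @return named integer vector: component id per node.
#' @export
networkComponents <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = net@nodes["id"])
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), names(comp))[net@nodes$id]
}

#' Sweep a network across increasingly stringent E-value thresholds
#'
#' The curation move for separating subgroups: at each successively more
#' stringent threshold the number of edges is non-increasing and the number
#' of connected components non-decreasing, until clusters track the
#' functional subdivision of interest.
#'
#' @param net a [SimilarityNetwork-class].
#' @param cutoffs strictly decreasing (permissive to stringent) E-values.
#' @return data.frame of class `SweepReport` with columns cutoff, n_edges,
#'   n_components; per-cutoff component memberships are in the
#'   `memberships` attribute (list of named integer vectors).
#' @export
thresholdSweep <- function(net, cutoffs) {
  stopifnot(is(net, "SimilarityNetwork"))
  if (length(cutoffs) > 1L && any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly decreasing (permissive to stringent)")
  memberships <- list()
  rows <- lapply(seq_along(cutoffs), function(k) {
    thr <- applyThreshold(net, cutoffs[k])
    comp <- networkComponents(thr)
    memberships[[k]] <<- comp
    data.frame(cutoff = cutoffs[k], n_edges = nrow(thr@edges),
               n_components = max(comp))
  })
  out <- do.call(rbind, rows)
  attr(out, "memberships") <- memberships
  class(out) <- c("SweepReport", class(out))
  out
}

#' @describeIn thresholdSweep write the sweep report as TSV.
#' @param x a `SweepReport`.
#' @param path output file.
#' @export
writeSweepReport <- function(x, path) {
  utils::write.table(as.data.frame(unclass(x))[c("cutoff", "n_edges", "n_components")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a network to representative nodes
#'
#' Sequences are clustered greedily at the given identity (see
#' [greedyCluster()]); each cluster becomes one representative node (id =
#' representative sequence id, size = member count). An edge joins two
#' representative nodes iff any member pair is connected in the full
#' network; the edge keeps the best (smallest E-value / largest bit score)
#' member-pair weights. Node attributes other than id/length are summarized
#' per cluster as the sorted unique value list (`<attr>_values`,
#' comma-joined) and the dominant value (`<attr>`, modal, ties broken
#' lexicographically); attributes empty across all members are omitted.
#' At identity 1.0 over all-distinct sequences this is the one-sequence-per
#' node network.
#'
#' @param net the full [SimilarityNetwork-class] over `seqs`.
#' @param seqs the sequences the network was built from.
#' @param identity clustering identity fraction in (0, 1].
#' @param params [scoringParams()].
#' @return a [SimilarityNetwork-class] of kind `representative`.
#' @export
makeRepresentative <- function(net, seqs, identity, params = scoringParams()) {
  stopifnot(is(net, "SimilarityNetwork"), identity > 0, identity <= 1)
  cl <- greedyCluster(seqs, identity, params)
  rep_of <- setNames(cl$representative, cl$id)
  reps <- unique(cl$representative)
  members <- split(cl$id, cl$representative)[reps]
  nodes <- data.frame(id = reps, length = nchar(.as_seq_chr(seqs))[reps],
                      size = lengths(members),
                      members = vapply(members, paste, character(1),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  # summarize painted attributes of the full network
  extra <- setdiff(names(net@nodes), c("id", "length"))
  for (attrname in extra) {
    vals <- setNames(as.character(net@nodes[[attrname]]), net@nodes$id)
    per <- lapply(members, function(ms) {
      v <- vals[ms]
      v[!is.na(v) & nzchar(v)]
    })
    if (!any(lengths(per) > 0L)) next  # empty for all members: omit summary
    nodes[[paste0(attrname, "_values")]] <-
      vapply(per, function(v) paste(sort(unique(v)), collapse = ","),
             character(1))
    nodes[[attrname]] <- vapply(per, function(v) {
      if (!length(v)) return("")
      tab <- sort(table(v), decreasing = TRUE)
      best <- names(tab)[tab == max(tab)]
      sort(best)[1L]
    }, character(1))
  }
  e <- net@edges
  if (nrow(e)) {
    rf <- rep_of[e$from]; rt <- rep_of[e$to]
    keep <- rf != rt
    e <- data.frame(from = pmin(rf[keep], rt[keep]),
                    to = pmax(rf[keep], rt[keep]),
                    evalue = e$evalue[keep], bit_score = e$bit_score[keep],
                    pct_identity = e$pct_identity[keep],
                    stringsAsFactors = FALSE)
    if (nrow(e)) {
      key <- paste(e$from, e$to)
      agg <- lapply(split(seq_len(nrow(e)), key), function(ix) {
        data.frame(from = e$from[ix[1L]], to = e$to[ix[1L]],
                   evalue = min(e$evalue[ix]),
                   bit_score = max(e$bit_score[ix]),
                   pct_identity = max(e$pct_identity[ix]),
                   stringsAsFactors = FALSE)
      })
      e <- do.call(rbind, agg)
      rownames(e) <- NULL
    }
  }
  new("SimilarityNetwork", nodes = nodes, edges = e, kind = "representative",
      metadata = c(net@metadata, list(rep_identity = identity)))
}

#' Paint node attributes from a table
#'
#' Merges an attribute table (keyed by node id, first column or a column
#' named `id`) onto the network's nodes. Rows keyed by unknown ids do not
#' change the network and are reported in `metadata$unmatched`; nodes
#' absent from the table keep empty attributes (NA).
#'
#' @param net a [SimilarityNetwork-class].
#' @param table data.frame of attributes, one row per node id.
#' @return the painted network.
#' @export
paintAttributes <- function(net, table) {
  stopifnot(is(net, "SimilarityNetwork"), is.data.frame(table))
  if (!nrow(table)) return(net)
  keycol <- if ("id" %in% names(table)) "id" else names(table)[1L]
  key <- as.character(table[[keycol]])
  if (anyDuplicated(key))
    stop(sprintf("duplicate key row '%s' in attribute table",
                 key[duplicated(key)][1L]))
  unmatched <- setdiff(key, net@nodes$id)
  idx <- match(net@nodes$id, key)
  for (attrname in setdiff(names(table), keycol))
    net@nodes[[attrname]] <- table[[attrname]][idx]
  net@metadata$unmatched <- unmatched
  net
}

#' Export a network dissemination bundle
#'
#' Packages the network the way curated superfamily downloads are shipped:
#' a `.zip` archive containing `network.xgmml` (Cytoscape-compatible
#' XGMML), an explanatory `README.txt` with the generation parameters and
#' counts, and the node length distribution as both a histogram image
#' (`lengths.png`) and its underlying table (`lengths.tsv`, whose bin
#' counts sum to the node count).
#'
#' @param net a non-empty [SimilarityNetwork-class].
#' @param out path of the `.zip` archive to write.
#' @param label network label recorded in the XGMML and README.
#' @return `out`, invisibly.
#' @export
exportBundle <- function(net, out, label = "ssn") {
  stopifnot(is(net, "SimilarityNetwork"))
  if (!nrow(net@nodes)) stop("cannot export an empty network")
  tmp <- tempfile("bundle")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  xg <- file.path(tmp, "network.xgmml")
  writeXgmml(net, xg, label = label)
  h <- graphics::hist(net@nodes$length, plot = FALSE)
  tsv <- file.path(tmp, "lengths.tsv")
  utils::write.table(data.frame(bin_start = h$breaks[-length(h$breaks)],
                                bin_end = h$breaks[-1L], count = h$counts),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  pngf <- file.path(tmp, "lengths.png")
  grDevices::png(pngf, width = 640, height = 480)
  graphics::hist(net@nodes$length, main = paste(label, "sequence lengths"),
                 xlab = "length (residues)")
  grDevices::dev.off()
  readme <- file.path(tmp, "README.txt")
  meta <- net@metadata
  writeLines(c(
    sprintf("Sequence similarity network bundle: %s", label),
    "",
    "Files:",
    "  network.xgmml  network in XGMML format (Cytoscape-compatible)",
    "  lengths.png    node length distribution histogram",
    "  lengths.tsv    histogram bin table underlying lengths.png",
    "",
    sprintf("Network kind:  %s", net@kind),
    sprintf("Nodes:         %d", nrow(net@nodes)),
    sprintf("Edges:         %d", nrow(net@edges)),
    sprintf("Edge rule:     larger (less significant) of the two directional E-values"),
    if (!is.null(meta$max_evalue))
      sprintf("Build E-value ceiling: %g", meta$max_evalue),
    if (!is.null(meta$threshold))
      sprintf("Applied E-value threshold: %g", meta$threshold),
    if (!is.null(meta$db_size))
      sprintf("Search-space residues (n): %g", meta$db_size),
    if (!is.null(meta$rep_identity))
      sprintf("Representative clustering identity: %g", meta$rep_identity),
    "",
    "Edge attributes carry evalue, bit_score and pct_identity so the network",
    "can be re-thresholded without re-alignment."), readme)
  files <- c("network.xgmml" = xg, "README.txt" = readme,
             "lengths.tsv" = tsv, "lengths.png" = pngf)
  .write_zip(files, out)
  invisible(out)
}
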