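#' @include sfcurate-package.R
NULL

#' Multiple sequence alignment with per-column annotations
#'
#' A single-alignment Stockholm-style MSA: equal-width gapped rows plus
#' optional per-column `#=GC` annotation strings (for example a functional
#' residue mask under the reserved tag `FUNC_RES`). Columns are addressed
#' 1-based.
#'
#' @slot rows named character vector of gapped sequences (gap characters `-`
#'   or `.`), all the same width.
#' @slot gc named list of per-column annotation strings, each of the
#'   alignment width.
#' @export
setClass("StockholmAlignment",
  representation(rows = "character", gc = "list"),
  prototype(rows = character(), gc = list()))

setValidity("StockholmAlignment", function(object) {
  msgs <- character()
  if (length(object@rows)) {
    if (is.null(names(object@rows)) || anyNA(names(object@rows)) ||
        any(names(object@rows) == ""))
      msgs <- c(msgs, "all rows must be named")
    if (anyDuplicated(names(object@rows)))
      msgs <- c(msgs, "duplicate row ids")
    w <- nchar(object@rows)
    if (length(unique(w)) > 1L)
      msgs <- c(msgs, sprintf("ragged alignment: row '%s' has width %d, expected %d",
                              names(object@rows)[which(w != w[1L])[1L]],
                              w[which(w != w[1L])[1L]], w[1L]))
    bad <- vapply(object@gc, function(g) nchar(g) != w[1L], logical(1))
    if (any(bad))
      msgs <- c(msgs, sprintf("#=GC annotation '%s' does not match alignment width",
                              names(object@gc)[bad][1L]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Position-specific scoring profile derived from a seed alignment
#'
#' Integer log-odds scores (half-bit units, uniform background, +1
#' pseudocount per residue) for the match columns of a seed MSA. Columns with
#' more than 50% gaps are excluded; `columnMap` records, for each profile
#' column, the 1-based seed MSA column it came from.
#'
#' @slot scores integer matrix, profile columns x alphabet (20 residues + X).
#' @slot columnMap strictly increasing integer vector of seed MSA columns.
#' @slot sourceNode name of the hierarchy node the seed MSA belongs to.
#' @export
setClass("ProfileModel",
  representation(scores = "matrix", columnMap = "integer", sourceNode = "character"))

setValidity("ProfileModel", function(object) {
  msgs <- character()
  if (nrow(object@scores) < 1L) msgs <- c(msgs, "profile must have width >= 1")
  if (ncol(object@scores) != length(.ALPHABET))
    msgs <- c(msgs, "profile score matrix must cover the 21-letter alphabet")
  if (length(object@columnMap) != nrow(object@scores))
    msgs <- c(msgs, "columnMap length must equal profile width")
  if (is.unsorted(object@columnMap, strictly = TRUE))
    msgs <- c(msgs, "columnMap must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Ranked profile/sequence search results
#'
#' Hits of a database searched against one query (a profile or a sequence),
#' sorted by bit score descending (ties broken by target id ascending), with
#' at most one hit per (query, target) pair. Bit scores and E-values obey the
#' Karlin-Altschul identities `bit = (lambda * raw - ln K) / ln 2` and
#' `evalue = m * n * 2^-bit` where `m` is the query length and `n` the
#' database residue count.
#'
#' @slot hits data.frame with columns query, target, raw, bit_score, evalue,
#'   tstart, tend.
#' @slot traces list (possibly empty) of integer column traces, parallel to
#'   the rows of `hits`; each maps profile/query positions to target residue
#'   indices (0 = unaligned).
#' @slot dbSize numeric, total residues in the searched database.
#' @export
setClass("HitTable",
  representation(hits = "data.frame", traces = "list", dbSize = "numeric"))

setValidity("HitTable", function(object) {
  msgs <- character()
  need <- c("query", "target", "raw", "bit_score", "evalue", "tstart", "tend")
  if (!all(need %in% names(object@hits)))
    msgs <- c(msgs, paste("hits must have columns:", paste(need, collapse = ", ")))
  else {
    h <- object@hits
    if (nrow(h) > 1L) {
      o <- order(-h$bit_score, h$target)
      if (!identical(o, seq_len(nrow(h))))
        msgs <- c(msgs, "hits must be sorted by bit_score desc, target asc")
    }
    if (anyDuplicated(h[c("query", "target")]))
      msgs <- c(msgs, "duplicate (query, target) pair")
  }
  if (length(object@traces) && length(object@traces) != nrow(object@hits))
    msgs <- c(msgs, "traces must be empty or parallel to hits")
  if (length(object@dbSize) != 1L || object@dbSize < 0)
    msgs <- c(msgs, "dbSize must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Calibrated bit-score cutoffs for one profile
#'
#' Trusted cutoff (TC), noise cutoff (NC) and gathering threshold (GA). The
#' GA is the arithmetic midpoint of TC and NC unless a curator supplied a
#' manual override.
#'
#' @slot tc,nc,ga numeric bit scores, `nc <= ga <= tc`.
#' @slot method one of drop, seed_capture, lower_of_both, manual.
#' @slot diagnostics free-text notes for curator review.
#' @export
setClass("Cutoffs",
  representation(tc = "numeric", nc = "numeric", ga = "numeric",
                 method = "character", diagnostics = "character"))

setValidity("Cutoffs", function(object) {
  msgs <- character()
  if (object@nc > object@tc + 1e-9) msgs <- c(msgs, "nc must be <= tc")
  if (!object@method %in% c("drop", "seed_capture", "lower_of_both", "manual"))
    msgs <- c(msgs, "unknown method")
  if (object@method != "manual" &&
      abs(object@ga - (object@tc + object@nc) / 2) > 1e-9)
    msgs <- c(msgs, "ga must be the midpoint of tc and nc")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("ProfileModelOrNULL", c("ProfileModel", "NULL"))
setClassUnion("CutoffsOrNULL", c("Cutoffs", "NULL"))
setClassUnion("StockholmAlignmentOrNULL", c("StockholmAlignment", "NULL"))

#' A node of the superfamily / subgroup / family hierarchy
#'
#' Classification unit carrying its member accessions, seed alignment,
#' profile, calibrated cutoffs and functional residue specifications. The
#' tree is held from the root down; parents are implicit. Subgroups may nest
#' (a subgroup node may parent further subgroup nodes); family nodes are
#' leaves and are treated as isofunctional.
#'
#' Residue specifications are rows of a data.frame with columns
#' `msa_column` (1-based column of this node's seed MSA), `allowed`
#' (string of permitted residue letters) and `role` (free text).
#'
#' @slot level one of superfamily, subgroup, family.
#' @slot name node name, unique within a tree.
#' @slot members character vector of member sequence ids.
#' @slot seedMsa [StockholmAlignment-class] or NULL.
#' @slot profile [ProfileModel-class] or NULL.
#' @slot cutoffs [Cutoffs-class] or NULL.
#' @slot residueSpecs data.frame of functional residue specifications.
#' @slot reactionNote free text describing the conserved chemical capability.
#' @slot children list of child HierarchyNode objects.
#' @export
setClass("HierarchyNode",
  representation(level = "character", name = "character", members = "character",
                 seedMsa = "StockholmAlignmentOrNULL",
                 profile = "ProfileModelOrNULL",
                 cutoffs = "CutoffsOrNULL",
                 residueSpecs = "data.frame",
                 reactionNote = "character",
                 children = "list"),
  prototype(residueSpecs = data.frame(msa_column = integer(),
                                      allowed = character(),
                                      role = character()),
            reactionNote = "", children = list()))

setValidity("HierarchyNode", function(object) {
  msgs <- character()
  if (!object@level %in% c("superfamily", "subgroup", "family"))
    msgs <- c(msgs, "level must be superfamily, subgroup or family")
  if (object@level == "family" && length(object@children))
    msgs <- c(msgs, "family nodes must be leaves")
  if (!all(c("msa_column", "allowed", "role") %in% names(object@residueSpecs)))
    msgs <- c(msgs, "residueSpecs needs columns msa_column, allowed, role")
  if (!all(vapply(object@children, function(x) is(x, "HierarchyNode"), logical(1))))
    msgs <- c(msgs, "children must be HierarchyNode objects")
  if (length(msgs)) msgs else TRUE
})

#' Enzyme functional domain (EFD) of a sequence
#'
#' The portion of a protein responsible for one annotated function: an
#' ordered set of non-overlapping 1-based inclusive ranges, at least one of
#' which is the superfamily domain (SFD) performing the conserved chemistry.
#' A multi-functional protein carries several EFDs whose SFD ranges must not
#' overlap. Range metadata columns: `label` (domain name) and
#' `homology_class` (sf_domain, efd_partner or unrelated).
#'
#' @slot owner id of the owning sequence.
#' @slot ranges [IRanges::IRanges] with mcols label and homology_class.
#' @slot functionLabels free-text function strings.
#' @export
setClass("EnzymeFunctionalDomain",
  representation(owner = "character", ranges = "IRanges",
                 functionLabels = "character"))

setValidity("EnzymeFunctionalDomain", function(object) {
  msgs <- character()
  mc <- S4Vectors::mcols(object@ranges)
  if (is.null(mc) || !all(c("label", "homology_class") %in% names(mc)))
    msgs <- c(msgs, "ranges need mcols label and homology_class")
  else {
    if (!all(mc$homology_class %in% c("sf_domain", "efd_partner", "unrelated")))
      msgs <- c(msgs, "unknown homology_class")
    if (!any(mc$homology_class == "sf_domain"))
      msgs <- c(msgs, "EFD must contain at least one sf_domain range")
  }
  if (length(object@ranges) && any(IRanges::start(object@ranges) < 1L))
    msgs <- c(msgs, "ranges must start at 1 or later")
  if (length(object@ranges) > 1L) {
    o <- order(IRanges::start(object@ranges))
    s <- IRanges::start(object@ranges)[o]
    e <- IRanges::end(object@ranges)[o]
    if (any(s[-1L] <= e[-length(e)]))
      msgs <- c(msgs, "ranges must be pairwise non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of hierarchical annotation transfer for one query
#'
#' @slot query query sequence id.
#' @slot assignedLevel one of none, superfamily, subgroup, family.
#' @slot assignedNode name of the deepest passing node, or NA.
#' @slot perLevel data.frame with one row per evaluated node: node, level,
#'   bit_score, ga, passed_score, passed_residues, passed.
#' @slot residueReport data.frame with one row per evaluated residue spec:
#'   node, msa_column, allowed, observed, passed.
#' @slot evidence hmm_only or hmm_plus_residues.
#' @slot diagnostics free-text notes (for example runner-up family passes).
#' @export
setClass("AnnotationResult",
  representation(query = "character", assignedLevel = "character",
                 assignedNode = "character", perLevel = "data.frame",
                 residueReport = "data.frame", evidence = "character",
                 diagnostics = "character"))

setValidity("AnnotationResult", function(object) {
  msgs <- character()
  if (!object@assignedLevel %in% c("none", "superfamily", "subgroup", "family"))
    msgs <- c(msgs, "bad assignedLevel")
  if (!object@evidence %in% c("hmm_only", "hmm_plus_residues"))
    msgs <- c(msgs, "bad evidence")
  if (object@assignedLevel == "family" && object@evidence != "hmm_plus_residues")
    msgs <- c(msgs, "family-level assignment requires residue evidence")
  if (length(msgs)) msgs else TRUE
})

#' Sequence similarity network
#'
#' Undirected network whose nodes are sequences (kind `full`) or
#' representative clusters (kind `representative`) and whose edges carry the
#' symmetrised pairwise similarity: the retained E-value of an unordered pair
#' is the larger (less significant) of the two directional E-values, so edges
#' are conservative. Edge weights keep evalue, bit score and percent identity
#' so the network can be re-thresholded without re-alignment.
#'
#' @slot nodes data.frame keyed by `id`, always carrying `length`; painted
#'   attributes appear as further columns.
#' @slot edges data.frame with columns from, to, evalue, bit_score,
#'   pct_identity.
#' @slot kind full or representative.
#' @slot metadata list of generation parameters and reports.
#' @export
setClass("SimilarityNetwork",
  representation(nodes = "data.frame", edges = "data.frame", kind = "character",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("SimilarityNetwork", function(object) {
  msgs <- character()
  if (!"id" %in% names(object@nodes)) msgs <- c(msgs, "nodes need an id column")
  else if (anyDuplicated(object@nodes$id)) msgs <- c(msgs, "duplicate node id")
  need <- c("from", "to", "evalue", "bit_score", "pct_identity")
  if (!all(need %in% names(object@edges)))
    msgs <- c(msgs, paste("edges need columns:", paste(need, collapse = ", ")))
  else if (nrow(object@edges)) {
    e <- object@edges
    if (any(e$from == e$to)) msgs <- c(msgs, "self-edges are not allowed")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edge")
    if (!all(c(e$from, e$to) %in% object@nodes$id))
      msgs <- c(msgs, "edge endpoint not in nodes")
  }
  if (!object@kind %in% c("full", "representative"))
    msgs <- c(msgs, "kind must be full or representative")
  if (length(msgs)) msgs else TRUE
})
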