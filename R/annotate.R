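#' @include calibrate.R esfo.R
NULL

#' Check conserved functional residues of a profile hit
#'
#' For each residue specification of the node, the spec's seed-MSA column is
#' located among the profile columns via the profile's column map, the
#' aligned query residue is read through the hit's column trace, and the
#' spec passes iff that residue is in the allowed set. Spec columns the
#' query does not align (deletions) fail. This is the post-processing step
#' that adds specificity beyond the profile score and guards against
#' over-annotation.
#'
#' @param trace integer column trace (profile column -> query residue
#'   index, 0 = deleted), as produced by [searchProfile()] or
#'   [alignLocal()].
#' @param querySeq the query sequence (character or length-1 `AAStringSet`).
#' @param node a [HierarchyNode-class] with profile and residue specs.
#' @return data.frame with one row per spec: node, msa_column, allowed,
#'   observed, passed.
#' @export
checkResidues <- function(trace, querySeq, node) {
  stopifnot(is(node, "HierarchyNode"))
  if (is.null(node@profile)) stop(sprintf("node '%s' has no profile", node@name))
  specs <- node@residueSpecs
  if (!nrow(specs)) stop("node has no residue specifications")
  sq <- .as_seq_chr(querySeq)
  pcol <- match(specs$msa_column, node@profile@columnMap)
  if (anyNA(pcol))
    stop(sprintf("spec/profile mismatch: seed MSA column %s not among profile match columns",
                 paste(specs$msa_column[is.na(pcol)], collapse = ",")))
  obs <- vapply(pcol, function(k) {
    j <- trace[k]
    if (is.na(j) || j == 0L) "-" else substr(sq, j, j)
  }, character(1))
  passed <- mapply(function(o, allowed)
    o != "-" && o %in% strsplit(allowed, "")[[1]],
    obs, specs$allowed)
  data.frame(node = node@name, msa_column = specs$msa_column,
             allowed = specs$allowed, observed = obs,
             passed = unname(passed), stringsAsFactors = FALSE)
}

#' Calibrate profiles and cutoffs across a hierarchy
#'
#' Walks the tree, builds each node's profile from its seed alignment,
#' searches the calibration database with it, and computes the node's
#' trusted / noise / gathering cutoffs using the node's seed alignment rows
#' as the seed set. The database should contain at least all seed
#' sequences; adding unrelated sequences (for example shuffled decoys)
#' gives the noise cutoff a natural anchor below the seed scores.
#'
#' @param root a [HierarchyNode-class]; every node to calibrate needs a
#'   seed MSA.
#' @param db named `AAStringSet` calibration database.
#' @param params [scoringParams()].
#' @param cfg [calibrationConfig()].
#' @return the hierarchy with `profile` and `cutoffs` filled on every node
#'   that has a seed MSA.
#' @export
calibrateHierarchy <- function(root, db, params = scoringParams(),
                               cfg = calibrationConfig()) {
  stopifnot(is(root, "HierarchyNode"))
  node <- root
  if (!is.null(node@seedMsa)) {
    prof <- buildProfile(node@seedMsa, params, sourceNode = node@name)
    if (nrow(node@residueSpecs) &&
        !all(node@residueSpecs$msa_column %in% prof@columnMap))
      stop(sprintf("node '%s': residue spec column dropped from profile (gap-majority)",
                   node@name))
    ht <- searchProfile(prof, db, params)
    node@profile <- prof
    node@cutoffs <- computeCutoffs(ht, names(node@seedMsa@rows), cfg)
  }
  node@children <- lapply(node@children, calibrateHierarchy, db = db,
                          params = params, cfg = cfg)
  node
}

# evaluate one node for one query; returns scores, residue report, pass flags
.eval_node <- function(node, qname, qseq, params) {
  if (is.null(node@profile) || is.null(node@cutoffs))
    stop(sprintf("uncalibrated node '%s'", node@name))
  r <- cpp_profile_search(node@profile@scores, qseq, .ALPHABET_STR,
                          params$gapOpen, params$gapExtend)
  bit <- bitScore(r$score, params)
  ga <- node@cutoffs@ga
  pass_score <- bit >= ga
  has_specs <- nrow(node@residueSpecs) > 0L
  rr <- NULL
  pass_res <- TRUE
  if (has_specs && pass_score) {
    rr <- checkResidues(r$trace, qseq, node)
    pass_res <- all(rr$passed)
  }
  # family-level transfer always requires residue evidence: a family without
  # residue specs can never be assigned (over-annotation guard)
  passed <- pass_score && pass_res && !(node@level == "family" && !has_specs)
  list(node = node@name, level = node@level, bit = bit, ga = ga,
       pass_score = pass_score, pass_res = pass_res, has_specs = has_specs,
       passed = passed, residue_report = rr)
}

#' Assign a query to the deepest supportable hierarchy level
#'
#' Evaluates the superfamily profile first; queries below the superfamily
#' gathering threshold are left unassigned. Otherwise the tree is descended:
#' at each level every child profile is evaluated and every child whose bit
#' score reaches its own gathering threshold (and whose residue
#' specifications, where defined, all pass) is followed. Family-level
#' assignment additionally always requires passing residue checks, so a
#' query can never reach family level on profile score alone; a family
#' failing residues while passing score yields an assignment at its parent
#' level with the residue report attached. When several nodes at the
#' deepest level pass, the highest bit score wins (ties by node name);
#' runners-up are listed in the diagnostics.
#'
#' @param query single named sequence (length-1 named `AAStringSet` or named
#'   character); pass an EFD slice (see [efdSlice()]) when domain ranges are
#'   known.
#' @param root calibrated hierarchy root.
#' @param params [scoringParams()].
#' @return an [AnnotationResult-class].
#' @export
assignAnnotation <- function(query, root, params = scoringParams()) {
  stopifnot(is(root, "HierarchyNode"))
  sq <- .as_seq_chr(query)
  stopifnot(length(sq) == 1L)
  qname <- if (!is.null(names(sq))) names(sq) else "query"
  qseq <- unname(sq)

  evals <- list()
  reports <- list()
  diagnostics <- character()

  ev_root <- .eval_node(root, qname, qseq, params)
  evals[[root@name]] <- ev_root
  if (!is.null(ev_root$residue_report)) reports[[root@name]] <- ev_root$residue_report

  frontier <- if (ev_root$passed) list(root) else list()
  passing <- if (ev_root$passed) list(ev_root) else list()
  while (length(frontier)) {
    next_frontier <- list()
    for (node in frontier) {
      for (ch in node@children) {
        ev <- .eval_node(ch, qname, qseq, params)
        evals[[ch@name]] <- ev
        if (!is.null(ev$residue_report)) reports[[ch@name]] <- ev$residue_report
        if (ev$passed) {
          passing[[length(passing) + 1L]] <- ev
          next_frontier[[length(next_frontier) + 1L]] <- ch
        } else if (ev$pass_score && !ev$pass_res) {
          diagnostics <- c(diagnostics,
            sprintf("%s: profile score passed GA but conserved residues failed",
                    ch@name))
        }
      }
    }
    frontier <- next_frontier
  }

  perLevel <- do.call(rbind, lapply(evals, function(e)
    data.frame(node = e$node, level = e$level, bit_score = e$bit, ga = e$ga,
               passed_score = e$pass_score, passed_residues = e$pass_res,
               passed = e$passed, stringsAsFactors = FALSE)))
  rownames(perLevel) <- NULL
  residueReport <- if (length(reports)) do.call(rbind, unname(reports))
    else data.frame(node = character(), msa_column = integer(),
                    allowed = character(), observed = character(),
                    passed = logical(), stringsAsFactors = FALSE)

  if (!length(passing)) {
    return(new("AnnotationResult", query = qname, assignedLevel = "none",
               assignedNode = NA_character_, perLevel = perLevel,
               residueReport = residueReport, evidence = "hmm_only",
               diagnostics = paste(diagnostics, collapse = "; ")))
  }
  depth <- c(superfamily = 1L, subgroup = 2L, family = 3L)
  dmax <- max(depth[vapply(passing, `[[`, character(1), "level")])
  deepest <- Filter(function(e) depth[[e$level]] == dmax, passing)
  o <- order(-vapply(deepest, `[[`, numeric(1), "bit"),
             vapply(deepest, `[[`, character(1), "node"))
  winner <- deepest[[o[1L]]]
  if (length(deepest) > 1L)
    diagnostics <- c(diagnostics,
      sprintf("also passed at the same level: %s",
              paste(vapply(deepest[o[-1L]], `[[`, character(1), "node"),
                    collapse = ", ")))
  evidence <- if (winner$has_specs) "hmm_plus_residues" else "hmm_only"
  new("AnnotationResult", query = qname, assignedLevel = winner$level,
      assignedNode = winner$node, perLevel = perLevel,
      residueReport = residueReport, evidence = evidence,
      diagnostics = paste(diagnostics, collapse = "; "))
}

#' Annotate a batch of queries and tabulate the transfers
#'
#' One row per query with the assigned superfamily / subgroup / family (the
#' assigned node's root-to-leaf path), per-level bit scores, assigned level
#' and evidence class. Row order is query id ascending; duplicate query ids
#' are rejected.
#'
#' @param db named `AAStringSet` of queries.
#' @param root calibrated hierarchy root.
#' @param params [scoringParams()].
#' @return data.frame with columns id, sf, subgroup, family, sf_bit,
#'   subgroup_bit, family_bit, assigned_level, evidence.
#' @export
batchAnnotate <- function(db, root, params = scoringParams()) {
  sq <- .as_seq_chr(db)
  if (length(sq) && (is.null(names(sq)) || anyDuplicated(names(sq))))
    stop("id collision: query ids must be unique")
  ids <- sort(names(sq))
  rows <- lapply(ids, function(id) {
    res <- assignAnnotation(setNames(sq[id], id), root, params)
    path <- if (!is.na(res@assignedNode)) nodePath(root, res@assignedNode)
            else character()
    lv <- vapply(path, function(nm)
      res@perLevel$level[res@perLevel$node == nm][1L], character(1))
    pick <- function(level) {
      nm <- path[lv == level]
      if (length(nm)) nm[length(nm)] else NA_character_
    }
    bit_of <- function(nm) {
      if (is.na(nm)) return(NA_real_)
      res@perLevel$bit_score[res@perLevel$node == nm][1L]
    }
    sf <- pick("superfamily"); sg <- pick("subgroup"); fam <- pick("family")
    data.frame(id = id, sf = sf, subgroup = sg, family = fam,
               sf_bit = bit_of(sf), subgroup_bit = bit_of(sg),
               family_bit = bit_of(fam), assigned_level = res@assignedLevel,
               evidence = res@evidence, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = character(), sf = character(), subgroup = character(),
                    family = character(), sf_bit = numeric(),
                    subgroup_bit = numeric(), family_bit = numeric(),
                    assigned_level = character(), evidence = character(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @describeIn batchAnnotate write the annotation table as TSV.
#' @param x the data.frame returned by `batchAnnotate`.
#' @param path output file.
#' @export
writeBatchAnnotation <- function(x, path) {
  df <- x
  df[] <- lapply(df, function(col) ifelse(is.na(col), "", as.character(col)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
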