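#' @include AllClasses.R
NULL

#' Construct an enzyme functional domain
#'
#' @param owner id of the owning sequence.
#' @param start,end 1-based inclusive range bounds (parallel vectors).
#' @param label domain names, recycled.
#' @param homologyClass one of sf_domain, efd_partner, unrelated per range.
#' @param functionLabels free-text function strings.
#' @return an [EnzymeFunctionalDomain-class].
#' @export
enzymeFunctionalDomain <- function(owner, start, end, label = "domain",
                                   homologyClass = "sf_domain",
                                   functionLabels = character()) {
  r <- IRanges::IRanges(start = start, end = end)
  S4Vectors::mcols(r) <- S4Vectors::DataFrame(
    label = rep_len(label, length(r)),
    homology_class = rep_len(homologyClass, length(r)))
  new("EnzymeFunctionalDomain", owner = owner, ranges = r,
      functionLabels = functionLabels)
}

#' @describeIn enzymeFunctionalDomain the subset of ranges performing the
#'   conserved superfamily chemistry.
#' @param efd an `EnzymeFunctionalDomain`.
#' @export
sfdRanges <- function(efd) {
  efd@ranges[S4Vectors::mcols(efd@ranges)$homology_class == "sf_domain"]
}

#' Extract the EFD portion of a sequence
#'
#' Classification should operate on enzyme functional domains, not whole
#' chains: transferring annotations from full-length multi-functional
#' proteins propagates the wrong function to single-function relatives.
#' Returns a new record whose sequence is the concatenation of the EFD
#' ranges in order, with the id suffixed by a range descriptor.
#'
#' @param seqs named `AAStringSet` (or named character) containing the owner.
#' @param efd an [EnzymeFunctionalDomain-class].
#' @return a length-1 `AAStringSet`.
#' @export
efdSlice <- function(seqs, efd) {
  stopifnot(is(efd, "EnzymeFunctionalDomain"))
  sq <- .as_seq_chr(seqs)
  if (!efd@owner %in% names(sq))
    stop(sprintf("owner '%s' not found in sequence set", efd@owner))
  s <- sq[[efd@owner]]
  r <- efd@ranges[order(IRanges::start(efd@ranges))]
  if (any(IRanges::start(r) < 1L) || any(IRanges::end(r) > nchar(s)))
    stop("invalid domain range: outside sequence bounds")
  pieces <- substring(s, IRanges::start(r), IRanges::end(r))
  desc <- paste(sprintf("%d-%d", IRanges::start(r), IRanges::end(r)),
                collapse = "_")
  out <- Biostrings::AAStringSet(setNames(paste(pieces, collapse = ""),
                                          paste0(efd@owner, "/", desc)))
  out
}

#' Check that multiple EFDs on one sequence keep disjoint SFD ranges
#'
#' @param efds list of [EnzymeFunctionalDomain-class] objects sharing one
#'   owner.
#' @return TRUE, or a character vector of violations.
#' @export
checkEfdCompatibility <- function(efds) {
  if (length(efds) < 2L) return(TRUE)
  owner <- unique(vapply(efds, function(x) x@owner, character(1)))
  msgs <- character()
  if (length(owner) > 1L) msgs <- c(msgs, "EFDs have different owners")
  sfd <- lapply(efds, sfdRanges)
  for (i in seq_along(sfd)) for (j in seq_len(i - 1L)) {
    if (length(IRanges::findOverlaps(sfd[[i]], sfd[[j]])))
      msgs <- c(msgs, sprintf("SFD ranges of EFDs %d and %d overlap", j, i))
  }
  if (length(msgs)) msgs else TRUE
}

#' Construct a hierarchy node
#'
#' @param level superfamily, subgroup or family.
#' @param name node name.
#' @param members member sequence ids.
#' @param children list of child nodes.
#' @param seedMsa optional [StockholmAlignment-class].
#' @param residueSpecs data.frame with columns msa_column, allowed, role.
#' @param reactionNote free text on the conserved chemical capability.
#' @param profile,cutoffs usually filled by [calibrateHierarchy()].
#' @return a [HierarchyNode-class].
#' @export
hierarchyNode <- function(level, name, members = character(), children = list(),
                          seedMsa = NULL, residueSpecs = NULL,
                          reactionNote = "", profile = NULL, cutoffs = NULL) {
  if (is.null(residueSpecs))
    residueSpecs <- data.frame(msa_column = integer(), allowed = character(),
                               role = character(), stringsAsFactors = FALSE)
  new("HierarchyNode", level = level, name = name,
      members = as.character(members), children = children, seedMsa = seedMsa,
      residueSpecs = residueSpecs, reactionNote = reactionNote,
      profile = profile, cutoffs = cutoffs)
}

#' One functional-residue specification row
#'
#' @param msaColumn 1-based column of the node's seed MSA.
#' @param allowed string of permitted residue letters, e.g. `"HK"`.
#' @param role free text (metal ligand, general acid-base, ...).
#' @return one-row data.frame.
#' @export
functionalResidueSpec <- function(msaColumn, allowed, role = "") {
  stopifnot(nchar(allowed) >= 1,
            all(strsplit(allowed, "")[[1]] %in% .AA20))
  data.frame(msa_column = as.integer(msaColumn), allowed = allowed,
             role = role, stringsAsFactors = FALSE)
}

.walk_nodes <- function(node, f, ...) {
  c(list(f(node, ...)), unlist(lapply(node@children, .walk_nodes, f, ...),
                               recursive = FALSE))
}

#' Flatten a hierarchy into a list of nodes (preorder)
#'
#' @param root a [HierarchyNode-class].
#' @return list of nodes.
#' @export
hierarchyNodes <- function(root) .walk_nodes(root, identity)

#' Find the root-to-node path of a named node
#'
#' @param root a [HierarchyNode-class].
#' @param name node name.
#' @return character vector of node names from root to the node, or NULL.
#' @export
nodePath <- function(root, name) {
  if (root@name == name) return(root@name)
  for (ch in root@children) {
    p <- nodePath(ch, name)
    if (!is.null(p)) return(c(root@name, p))
  }
  NULL
}

# ungapped content of an alignment row
.degap <- function(x) gsub("[-.]", "", x)

# project a column of the parent seed MSA into a child seed MSA through a
# shared row: parent column -> residue index in the shared sequence -> child
# column. Returns NA if no shared row or the residue is deleted.
.project_column <- function(parentMsa, childMsa, column) {
  shared <- intersect(names(parentMsa@rows), names(childMsa@rows))
  if (!length(shared)) return(NA_integer_)
  rid <- shared[1L]
  prow <- strsplit(parentMsa@rows[[rid]], "")[[1]]
  if (column > length(prow)) return(NA_integer_)
  if (prow[column] %in% c("-", ".")) return(NA_integer_)
  respos <- sum(!(prow[seq_len(column)] %in% c("-", ".")))
  crow <- strsplit(childMsa@rows[[rid]], "")[[1]]
  notgap <- which(!(crow %in% c("-", ".")))
  if (respos > length(notgap)) return(NA_integer_)
  notgap[respos]
}

#' Validate a classification hierarchy
#'
#' Checks the structural invariants of a superfamily tree and reports every
#' violation instead of raising: the root must be a superfamily; family
#' nodes are leaves; child member sets are contained in their parents;
#' residue-spec columns fall inside the node's seed MSA; and every
#' higher-level residue spec must be satisfiable in each descendant family's
#' seed MSA (conservation claimed at a level must hold for all its
#' families). Cross-MSA columns are projected through a shared alignment
#' row; families sharing no row with the ancestor MSA are skipped and noted.
#'
#' @param root a [HierarchyNode-class] with level superfamily.
#' @return data.frame of violations (type, node, message); zero rows if the
#'   tree is well formed. Skipped cross-MSA checks are recorded in the
#'   `skipped` attribute.
#' @export
validateHierarchy <- function(root) {
  stopifnot(is(root, "HierarchyNode"))
  viol <- list()
  skipped <- character()
  add <- function(type, node, msg)
    viol[[length(viol) + 1L]] <<- data.frame(type = type, node = node,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  if (root@level != "superfamily")
    add("level", root@name, "root must be a superfamily")
  recurse <- function(node) {
    for (ch in node@children) {
      ok <- switch(node@level,
                   superfamily = ch@level %in% c("subgroup", "family"),
                   subgroup = ch@level %in% c("subgroup", "family"),
                   family = FALSE)
      if (!ok)
        add("level", ch@name,
            sprintf("a %s node cannot parent a %s node", node@level, ch@level))
      missing <- setdiff(ch@members, node@members)
      if (length(missing))
        add("containment", ch@name,
            sprintf("members not in parent '%s': %s", node@name,
                    paste(head(missing, 5L), collapse = ", ")))
      recurse(ch)
    }
    if (nrow(node@residueSpecs) && !is.null(node@seedMsa)) {
      w <- nchar(node@seedMsa@rows[1L])
      bad <- node@residueSpecs$msa_column > w | node@residueSpecs$msa_column < 1L
      if (any(bad))
        add("residue spec out of range", node@name,
            sprintf("msa_column %s outside alignment width %d",
                    paste(node@residueSpecs$msa_column[bad], collapse = ","), w))
    }
  }
  recurse(root)
  # higher-level specs must be satisfiable in each descendant family seed MSA
  check_specs <- function(node) {
    if (nrow(node@residueSpecs) && !is.null(node@seedMsa)) {
      fams <- Filter(function(x) x@level == "family" && !is.null(x@seedMsa),
                     hierarchyNodes(node))
      fams <- Filter(function(x) !identical(x@name, node@name), fams)
      for (fam in fams) {
        for (k in seq_len(nrow(node@residueSpecs))) {
          col <- .project_column(node@seedMsa, fam@seedMsa,
                                 node@residueSpecs$msa_column[k])
          if (is.na(col)) {
            skipped <<- c(skipped,
              sprintf("%s spec column %d vs family %s: no shared row",
                      node@name, node@residueSpecs$msa_column[k], fam@name))
            next
          }
          residues <- unique(substr(fam@seedMsa@rows, col, col))
          residues <- residues[!(residues %in% c("-", "."))]
          allowed <- strsplit(node@residueSpecs$allowed[k], "")[[1]]
          if (!any(residues %in% allowed))
            add("residue spec unsatisfiable", fam@name,
                sprintf("no row of family '%s' satisfies %s spec at column %d (allowed %s)",
                        fam@name, node@name, node@residueSpecs$msa_column[k],
                        node@residueSpecs$allowed[k]))
        }
      }
    }
    lapply(node@children, check_specs)
    invisible(NULL)
  }
  check_specs(root)
  out <- if (length(viol)) do.call(rbind, viol)
         else data.frame(type = character(), node = character(),
                         message = character(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

.node_to_list <- function(node, msaDir, baseDir) {
  msa <- NULL
  if (!is.null(node@seedMsa) && !is.null(msaDir)) {
    file <- file.path(msaDir, paste0(node@name, ".sto"))
    writeStockholm(node@seedMsa, file.path(baseDir, file))
    msa <- file
  }
  list(level = node@level, name = node@name, members = as.list(node@members),
       reaction_note = node@reactionNote,
       residue_specs = if (nrow(node@residueSpecs))
         lapply(seq_len(nrow(node@residueSpecs)), function(i)
           as.list(node@residueSpecs[i, ])) else list(),
       cutoffs = if (!is.null(node@cutoffs))
         list(tc = node@cutoffs@tc, nc = node@cutoffs@nc, ga = node@cutoffs@ga,
              method = node@cutoffs@method,
              diagnostics = node@cutoffs@diagnostics) else NULL,
       msa = msa,
       children = lapply(node@children, .node_to_list, msaDir, baseDir))
}

#' Serialize / load a hierarchy as a JSON document
#'
#' The tree is written as one JSON document; seed alignments are written as
#' Stockholm files next to it (under `msaDir`, relative to the JSON file)
#' and referenced by path. Profiles are not serialized: they are
#' deterministic functions of the seed MSAs and are rebuilt by
#' [calibrateHierarchy()] or [buildProfile()].
#'
#' @param root a [HierarchyNode-class].
#' @param path JSON file path.
#' @param msaDir directory (relative to the JSON file) for Stockholm seed
#'   alignments; NULL skips MSA serialization.
#' @return `path`, invisibly (`writeHierarchyJson`); a [HierarchyNode-class]
#'   (`readHierarchyJson`).
#' @export
writeHierarchyJson <- function(root, path, msaDir = "msa") {
  stopifnot(is(root, "HierarchyNode"))
  baseDir <- dirname(path)
  if (!is.null(msaDir))
    dir.create(file.path(baseDir, msaDir), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.node_to_list(root, msaDir, baseDir), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.node_from_list <- function(x, baseDir) {
  specs <- if (length(x$residue_specs))
    do.call(rbind, lapply(x$residue_specs, function(s)
      data.frame(msa_column = as.integer(s$msa_column), allowed = s$allowed,
                 role = s$role, stringsAsFactors = FALSE)))
  else NULL
  cut <- if (!is.null(x$cutoffs))
    new("Cutoffs", tc = x$cutoffs$tc, nc = x$cutoffs$nc, ga = x$cutoffs$ga,
        method = x$cutoffs$method, diagnostics = x$cutoffs$diagnostics)
  else NULL
  msa <- if (!is.null(x$msa)) readStockholm(file.path(baseDir, x$msa)) else NULL
  hierarchyNode(level = x$level, name = x$name,
                members = unlist(x$members, use.names = FALSE),
                children = lapply(x$children, .node_from_list, baseDir),
                seedMsa = msa, residueSpecs = specs,
                reactionNote = if (is.null(x$reaction_note)) "" else x$reaction_note,
                cutoffs = cut)
}

#' @rdname writeHierarchyJson
#' @export
readHierarchyJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  .node_from_list(x, dirname(path))
}

#' Write the per-sequence annotation table
#'
#' Fixed column order: id, sf, subgroup, family, evidence_level, species,
#' ec, notes. Missing columns are filled with empty strings.
#'
#' @param df data.frame keyed by sequence id.
#' @param path output TSV.
#' @export
writeAnnotationTsv <- function(df, path) {
  cols <- c("id", "sf", "subgroup", "family", "evidence_level", "species",
            "ec", "notes")
  for (col in setdiff(cols, names(df))) df[[col]] <- ""
  df <- df[cols]
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
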