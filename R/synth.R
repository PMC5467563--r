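#' @include esfo.R io.R
NULL

#' Configuration for the synthetic superfamily generator
#'
#' Describes a functionally diverse superfamily evolved from a common
#' ancestor: subgroup ancestors diverge from the root ancestor, family
#' ancestors from their subgroup ancestor, and members from their family
#' ancestor, by i.i.d. per-site substitution at the given rates. Conserved
#' functional residues are planted at disjoint positions for every level
#' (superfamily positions identical in all sequences; subgroup and family
#' positions identical within their lineage) and are never mutated within
#' their lineage. A fraction of members carries an extra, unrelated domain
#' appended after the superfamily domain, giving multi-domain
#' architectures; ground truth records the EFD/SFD ranges.
#'
#' @param seed RNG seed; the whole generation is reproducible from it.
#' @param ancestorLength superfamily-domain length in residues (default 280).
#' @param nSubgroups,familiesPerSubgroup,membersPerFamily tree shape
#'   (defaults 3, 2, 40).
#' @param subgroupDivergence,familyDivergence,withinFamilyDivergence
#'   per-site substitution probabilities (defaults 0.45, 0.25, 0.08); must
#'   increase with hierarchy height.
#' @param sfResidues,subgroupResidues,familyResidues planted conserved
#'   position counts per level (defaults 4, 3, 3).
#' @param extraDomainProb probability that a member carries an appended
#'   unrelated domain (default 0.3).
#' @param extraDomainLength integer range (min, max) of extra-domain
#'   lengths (default 60--120).
#' @param mutantFraction fraction of held-out queries duplicated as
#'   catalytic-residue knockouts (default 0.2).
#' @param queriesPerFamily held-out queries generated per family (default 20).
#' @param unplacedPerSubgroup sequences per subgroup classified only at
#'   subgroup level -- true subgroup members (superfamily- and
#'   subgroup-conserved residues intact) belonging to no family (default
#'   12). Real superfamilies always contain such partially classified
#'   sequences, and they give the ranked profile search its natural score
#'   continuum below the seed set.
#' @param unplacedDivergence per-site divergence of unplaced subgroup
#'   members from their subgroup ancestor (default 0.35, i.e. beyond the
#'   family level).
#' @param unplacedSf sequences classified only at superfamily level
#'   (superfamily-conserved residues intact, no subgroup; default 12).
#' @param unplacedSfDivergence their per-site divergence from the root
#'   ancestor (default 0.55, beyond the subgroup level).
#' @param indelRate optional per-site deletion probability (default 0 =
#'   substitution-only); deletions never hit planted positions.
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(seed = 1L, ancestorLength = 280L, nSubgroups = 3L,
                        familiesPerSubgroup = 2L, membersPerFamily = 40L,
                        subgroupDivergence = 0.45, familyDivergence = 0.25,
                        withinFamilyDivergence = 0.08, sfResidues = 4L,
                        subgroupResidues = 3L, familyResidues = 3L,
                        extraDomainProb = 0.3,
                        extraDomainLength = c(60L, 120L),
                        mutantFraction = 0.2, queriesPerFamily = 20L,
                        unplacedPerSubgroup = 12L, unplacedDivergence = 0.35,
                        unplacedSf = 12L, unplacedSfDivergence = 0.55,
                        indelRate = 0) {
  stopifnot(subgroupDivergence >= 0, subgroupDivergence < 1,
            familyDivergence >= 0, familyDivergence < 1,
            withinFamilyDivergence >= 0, withinFamilyDivergence < 1,
            withinFamilyDivergence < familyDivergence,
            familyDivergence < subgroupDivergence,
            mutantFraction >= 0, mutantFraction <= 1,
            unplacedDivergence > familyDivergence,
            unplacedSfDivergence > subgroupDivergence,
            unplacedSfDivergence < 1, indelRate >= 0, indelRate < 1)
  structure(list(seed = as.integer(seed),
                 ancestorLength = as.integer(ancestorLength),
                 nSubgroups = as.integer(nSubgroups),
                 familiesPerSubgroup = as.integer(familiesPerSubgroup),
                 membersPerFamily = as.integer(membersPerFamily),
                 subgroupDivergence = subgroupDivergence,
                 familyDivergence = familyDivergence,
                 withinFamilyDivergence = withinFamilyDivergence,
                 sfResidues = as.integer(sfResidues),
                 subgroupResidues = as.integer(subgroupResidues),
                 familyResidues = as.integer(familyResidues),
                 extraDomainProb = extraDomainProb,
                 extraDomainLength = as.integer(extraDomainLength),
                 mutantFraction = mutantFraction,
                 queriesPerFamily = as.integer(queriesPerFamily),
                 unplacedPerSubgroup = as.integer(unplacedPerSubgroup),
                 unplacedDivergence = unplacedDivergence,
                 unplacedSf = as.integer(unplacedSf),
                 unplacedSfDivergence = unplacedSfDivergence,
                 indelRate = indelRate),
            class = "SynthConfig")
}

.rand_seq <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

# substitute each non-frozen site with probability p (to a different residue)
.mutate <- function(chars, p, frozen) {
  free <- setdiff(seq_along(chars), frozen)
  hit <- free[runif(length(free)) < p]
  for (i in hit) chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  chars
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic superfamily with known ground truth
#'
#' Returns full-length member sequences, a populated classification
#' hierarchy (per-node seed MSAs over the superfamily-domain columns,
#' planted residue specifications, `FUNC_RES` column masks) and a ground
#' truth table. Deterministic given the configuration.
#'
#' @param cfg a [synthConfig()].
#' @return list of class `SynthSuperfamily` with elements `sequences`
#'   (named `AAStringSet`, full length), `hierarchy`
#'   ([HierarchyNode-class]), `truth` (data.frame: id, sf, subgroup,
#'   family, length, sfd_start, sfd_end, has_extra, extra_start,
#'   extra_end), `positions` (planted positions per node) and `config`.
#' @export
generateSuperfamily <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  .with_seed(cfg$seed, {
    L <- cfg$ancestorLength
    npos <- cfg$sfResidues + cfg$nSubgroups * cfg$subgroupResidues +
      cfg$nSubgroups * cfg$familiesPerSubgroup * cfg$familyResidues
    if (npos > L)
      stop("infeasible: more planted positions than ancestor length")
    pool <- sample(L, npos)
    take <- function(n) {
      out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; sort(out)
    }
    sf_pos <- take(cfg$sfResidues)
    anc <- strsplit(.rand_seq(L), "")[[1]]

    positions <- list(superfamily = sf_pos)
    ancestors <- list()
    seqs <- character()
    msarows <- character()   # gapped SFD rows (ancestor coordinates)
    truth <- list()
    sg_nodes <- list()

    for (s in seq_len(cfg$nSubgroups)) {
      sgname <- sprintf("sg%d", s)
      sg_pos <- take(cfg$subgroupResidues)
      sg_anc <- .mutate(anc, cfg$subgroupDivergence, frozen = sf_pos)
      # subgroup conserved residues are whatever the subgroup ancestor carries
      positions[[sgname]] <- sg_pos
      fam_nodes <- list()
      for (f in seq_len(cfg$familiesPerSubgroup)) {
        famname <- sprintf("%s_fam%d", sgname, f)
        fam_pos <- take(cfg$familyResidues)
        fam_anc <- .mutate(sg_anc, cfg$familyDivergence,
                           frozen = c(sf_pos, sg_pos))
        positions[[famname]] <- fam_pos
        frozen <- c(sf_pos, sg_pos, fam_pos)
        ids <- sprintf("%s_m%03d", famname, seq_len(cfg$membersPerFamily))
        for (id in ids) {
          mem <- .mutate(fam_anc, cfg$withinFamilyDivergence, frozen)
          delmask <- rep(FALSE, L)
          if (cfg$indelRate > 0) {
            delmask <- runif(L) < cfg$indelRate
            delmask[frozen] <- FALSE
          }
          row <- mem; row[delmask] <- "-"
          sfd <- paste(mem[!delmask], collapse = "")
          extra <- ""
          if (runif(1) < cfg$extraDomainProb)
            extra <- .rand_seq(sample(seq(cfg$extraDomainLength[1L],
                                          cfg$extraDomainLength[2L]), 1L))
          seqs[[id]] <- paste0(sfd, extra)
          msarows[[id]] <- paste(row, collapse = "")
          truth[[id]] <- data.frame(
            id = id, sf = "synthSF", subgroup = sgname, family = famname,
            length = nchar(seqs[[id]]), sfd_start = 1L, sfd_end = nchar(sfd),
            has_extra = nzchar(extra),
            extra_start = if (nzchar(extra)) nchar(sfd) + 1L else NA_integer_,
            extra_end = if (nzchar(extra)) nchar(seqs[[id]]) else NA_integer_,
            stringsAsFactors = FALSE)
        }
        fam_nodes[[famname]] <- list(name = famname, members = ids,
                                     pos = fam_pos, anc = fam_anc)
        ancestors[[famname]] <- fam_anc
      }
      # subgroup members placed in no family (beyond family-level divergence)
      uids <- if (cfg$unplacedPerSubgroup > 0)
        sprintf("%s_u%02d", sgname, seq_len(cfg$unplacedPerSubgroup))
      else character()
      for (id in uids) {
        mem <- .mutate(sg_anc, cfg$unplacedDivergence, frozen = c(sf_pos, sg_pos))
        extra <- if (runif(1) < cfg$extraDomainProb)
          .rand_seq(sample(seq(cfg$extraDomainLength[1L],
                               cfg$extraDomainLength[2L]), 1L)) else ""
        sfd <- paste(mem, collapse = "")
        seqs[[id]] <- paste0(sfd, extra)
        truth[[id]] <- data.frame(
          id = id, sf = "synthSF", subgroup = sgname, family = NA_character_,
          length = nchar(seqs[[id]]), sfd_start = 1L, sfd_end = nchar(sfd),
          has_extra = nzchar(extra),
          extra_start = if (nzchar(extra)) nchar(sfd) + 1L else NA_integer_,
          extra_end = if (nzchar(extra)) nchar(seqs[[id]]) else NA_integer_,
          stringsAsFactors = FALSE)
      }
      sg_nodes[[sgname]] <- list(name = sgname, pos = sg_pos, anc = sg_anc,
                                 fams = fam_nodes, unplaced = uids)
    }
    # superfamily members placed in no subgroup (beyond subgroup divergence)
    sf_uids <- if (cfg$unplacedSf > 0)
      sprintf("synthSF_u%02d", seq_len(cfg$unplacedSf))
    else character()
    for (id in sf_uids) {
      mem <- .mutate(anc, cfg$unplacedSfDivergence, frozen = sf_pos)
      extra <- if (runif(1) < cfg$extraDomainProb)
        .rand_seq(sample(seq(cfg$extraDomainLength[1L],
                             cfg$extraDomainLength[2L]), 1L)) else ""
      sfd <- paste(mem, collapse = "")
      seqs[[id]] <- paste0(sfd, extra)
      truth[[id]] <- data.frame(
        id = id, sf = "synthSF", subgroup = NA_character_,
        family = NA_character_, length = nchar(seqs[[id]]), sfd_start = 1L,
        sfd_end = nchar(sfd), has_extra = nzchar(extra),
        extra_start = if (nzchar(extra)) nchar(sfd) + 1L else NA_integer_,
        extra_end = if (nzchar(extra)) nchar(seqs[[id]]) else NA_integer_,
        stringsAsFactors = FALSE)
    }

    func_mask <- function(cols) {
      m <- rep(".", L); m[cols] <- "x"; paste(m, collapse = "")
    }
    spec_df <- function(cols, residues, role) {
      do.call(rbind, mapply(function(col, res)
        functionalResidueSpec(col, res, role), cols, residues,
        SIMPLIFY = FALSE))
    }
    make_family_node <- function(fn, sgname) {
      rows <- msarows[fn$members]
      cols <- sort(fn$pos)
      hierarchyNode("family", fn$name, members = fn$members,
                    seedMsa = stockholmAlignment(rows,
                      gc = list(FUNC_RES = func_mask(cols))),
                    residueSpecs = spec_df(cols, fn$anc[cols],
                                           "family-conserved catalytic residue"),
                    reactionNote = sprintf("isofunctional family %s", fn$name))
    }
    make_sg_node <- function(sg) {
      seedids <- unlist(lapply(sg$fams, `[[`, "members"), use.names = FALSE)
      cols <- sort(sg$pos)
      # unplaced sequences are members of the node but not curated seeds
      hierarchyNode("subgroup", sg$name, members = c(seedids, sg$unplaced),
                    children = unname(lapply(sg$fams, make_family_node, sg$name)),
                    seedMsa = stockholmAlignment(msarows[seedids],
                      gc = list(FUNC_RES = func_mask(cols))),
                    residueSpecs = spec_df(cols, sg$anc[cols],
                                           "subgroup-conserved residue"),
                    reactionNote = sprintf("subgroup %s shared chemistry", sg$name))
    }
    allmembers <- names(seqs)
    seedids_sf <- unlist(lapply(sg_nodes, function(sg)
      unlist(lapply(sg$fams, `[[`, "members"), use.names = FALSE)),
      use.names = FALSE)
    root <- hierarchyNode("superfamily", "synthSF", members = allmembers,
                          children = unname(lapply(sg_nodes, make_sg_node)),
                          seedMsa = stockholmAlignment(msarows[seedids_sf],
                            gc = list(FUNC_RES = func_mask(sort(sf_pos)))),
                          residueSpecs = spec_df(sort(sf_pos),
                                                 anc[sort(sf_pos)],
                                                 "superfamily-conserved residue"),
                          reactionNote = "conserved partial reaction of the superfamily")
    structure(list(sequences = Biostrings::AAStringSet(unlist(seqs)),
                   hierarchy = root,
                   truth = do.call(rbind, unname(truth)),
                   positions = positions, ancestors = ancestors,
                   config = cfg),
              class = "SynthSuperfamily")
  })
}

#' Generate labelled held-out queries for a synthetic superfamily
#'
#' Fresh members are drawn per family by the same generative process as the
#' superfamily members (so they were never seen by seed alignments or
#' calibration), plus `mutantFraction` additional copies in which the first
#' family-level planted residue is substituted with a disallowed residue --
#' catalytic knockouts that must not be annotated at family level.
#'
#' @param sf a `SynthSuperfamily` from [generateSuperfamily()].
#' @return list with `sequences` (named `AAStringSet`) and `labels`
#'   (data.frame: id, sf, subgroup, family, is_mutant, template).
#' @export
generateQueries <- function(sf) {
  stopifnot(inherits(sf, "SynthSuperfamily"))
  cfg <- sf$config
  .with_seed(cfg$seed + 1000003L, {
    seqs <- character()
    labels <- list()
    for (sgnode in sf$hierarchy@children) {
      for (fam in sgnode@children) {
        famname <- fam@name
        fam_pos <- sf$positions[[famname]]
        sg_pos <- sf$positions[[sgnode@name]]
        sf_pos <- sf$positions$superfamily
        frozen <- c(sf_pos, sg_pos, fam_pos)
        fam_anc <- sf$ancestors[[famname]]
        nq <- cfg$queriesPerFamily
        ids <- sprintf("%s_q%02d", famname, seq_len(nq))
        delmasks <- list()
        for (id in ids) {
          mem <- .mutate(fam_anc, cfg$withinFamilyDivergence, frozen)
          delmask <- rep(FALSE, length(mem))
          if (cfg$indelRate > 0) {
            delmask <- runif(length(mem)) < cfg$indelRate
            delmask[frozen] <- FALSE
          }
          delmasks[[id]] <- delmask
          sfd <- paste(mem[!delmask], collapse = "")
          extra <- if (runif(1) < cfg$extraDomainProb)
            .rand_seq(sample(seq(cfg$extraDomainLength[1L],
                                 cfg$extraDomainLength[2L]), 1L)) else ""
          seqs[[id]] <- paste0(sfd, extra)
          labels[[id]] <- data.frame(id = id, sf = "synthSF",
                                     subgroup = sgnode@name, family = famname,
                                     is_mutant = FALSE, template = NA_character_,
                                     stringsAsFactors = FALSE)
        }
        nmut <- round(cfg$mutantFraction * nq)
        if (nmut > 0) for (k in seq_len(nmut)) {
          tmpl <- ids[k]
          mid <- sprintf("%s_mut%02d", famname, k)
          chars <- strsplit(seqs[[tmpl]], "")[[1]]
          col <- sort(fam_pos)[1L]
          allowed <- strsplit(fam@residueSpecs$allowed[
            fam@residueSpecs$msa_column == col][1L], "")[[1]]
          # planted positions are never deleted; the column's position in the
          # query is the count of surviving sites up to it
          pos <- col - sum(delmasks[[tmpl]][seq_len(col - 1L)])
          repl <- setdiff(c("G", "A", "S"), c(allowed, chars[pos]))[1L]
          chars[pos] <- repl
          seqs[[mid]] <- paste(chars, collapse = "")
          labels[[mid]] <- data.frame(id = mid, sf = "synthSF",
                                      subgroup = sgnode@name, family = famname,
                                      is_mutant = TRUE, template = tmpl,
                                      stringsAsFactors = FALSE)
        }
      }
    }
    list(sequences = Biostrings::AAStringSet(unlist(seqs)),
         labels = do.call(rbind, unname(labels)))
  })
}

#' Shuffle sequences residue-wise (decoys)
#'
#' Returns length- and composition-preserving shuffles, useful as decoys in
#' calibration databases and as negatives in annotation tests.
#'
#' @param seqs named `AAStringSet` or named character.
#' @param seed RNG seed.
#' @return named `AAStringSet` (ids suffixed `_shuf`).
#' @export
shuffleResidues <- function(seqs, seed = 1L) {
  sq <- .as_seq_chr(seqs)
  .with_seed(seed, {
    out <- vapply(sq, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
    names(out) <- paste0(names(sq), "_shuf")
    Biostrings::AAStringSet(out)
  })
}

#' Write a synthetic superfamily to disk
#'
#' FASTA of the full-length members, the hierarchy as JSON with per-node
#' Stockholm seed alignments, and the ground truth as TSV.
#'
#' @param sf a `SynthSuperfamily`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSuperfamily <- function(sf, dir) {
  stopifnot(inherits(sf, "SynthSuperfamily"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaRecords(sf$sequences, file.path(dir, "members.fasta"))
  writeHierarchyJson(sf$hierarchy, file.path(dir, "hierarchy.json"))
  utils::write.table(sf$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
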