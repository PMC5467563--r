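test_that("generation is byte-reproducible from the seed", {
  cfg <- synthConfig(seed = 3, membersPerFamily = 4L, queriesPerFamily = 3L,
                     unplacedPerSubgroup = 2L, unplacedSf = 2L)
  a <- generateSuperfamily(cfg)
  b <- generateSuperfamily(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth, b$truth)
  expect_identical(a$positions, b$positions)
  qa <- generateQueries(a); qb <- generateQueries(b)
  expect_identical(as.character(qa$sequences), as.character(qb$sequences))
  expect_identical(qa$labels, qb$labels)
  c2 <- generateSuperfamily(synthConfig(seed = 4, membersPerFamily = 4L))
  expect_false(identical(as.character(a$sequences)[1],
                         as.character(c2$sequences)[1]))
})

test_that("superfamily-level planted residues are identical in every member", {
  sf <- small_superfamily()
  pos <- sf$positions$superfamily
  rows <- sf$hierarchy@seedMsa@rows
  for (p in pos) {
    col <- unique(substr(rows, p, p))
    expect_length(col, 1L)
  }
  # subgroup plantings are constant within, but not across, subgroups
  sg_nodes <- sf$hierarchy@children
  for (sg in sg_nodes) {
    for (p in sf$positions[[sg@name]]) {
      expect_length(unique(substr(sg@seedMsa@rows, p, p)), 1L)
    }
  }
})

test_that("planted position sets are pairwise disjoint", {
  sf <- small_superfamily()
  all_pos <- unlist(sf$positions, use.names = FALSE)
  expect_equal(anyDuplicated(all_pos), 0L)
})

test_that("pairwise identity ordering reflects the divergence hierarchy", {
  sf <- small_superfamily()
  tr <- sf$truth[!is.na(sf$truth$family) & !sf$truth$has_extra, ]
  pick <- function(fam, n) head(tr$id[tr$family == fam], n)
  fams <- unique(tr$family)
  within <- pairwiseIdentity(sf$sequences[[pick(fams[1], 2)[1]]],
                             sf$sequences[[pick(fams[1], 2)[2]]])
  cross_fam <- pairwiseIdentity(sf$sequences[[pick(fams[1], 1)]],
                                sf$sequences[[pick(fams[2], 1)]])
  cross_sg <- pairwiseIdentity(sf$sequences[[pick(fams[1], 1)]],
                               sf$sequences[[pick(fams[3], 1)]])
  expect_gt(within, cross_fam)
  expect_gt(cross_fam, cross_sg)
})

test_that("ground truth records EFD/SFD ranges consistent with the sequences", {
  sf <- small_superfamily()
  tr <- sf$truth
  expect_equal(tr$length, unname(nchar(as.character(sf$sequences[tr$id]))))
  expect_true(all(tr$sfd_end[tr$has_extra] < tr$length[tr$has_extra]))
  expect_true(all(tr$sfd_end[!tr$has_extra] == tr$length[!tr$has_extra]))
  with_extra <- tr[tr$has_extra, ][1, ]
  efd <- enzymeFunctionalDomain(with_extra$id, with_extra$sfd_start,
                                with_extra$sfd_end)
  sl <- efdSlice(sf$sequences, efd)
  expect_equal(Biostrings::width(sl), with_extra$sfd_end)
})

test_that("held-out queries respect their labels", {
  sf <- small_superfamily()
  q <- generateQueries(sf)
  expect_equal(nrow(q$labels), length(q$sequences))
  expect_setequal(q$labels$id, names(q$sequences))
  cfg <- sf$config
  n_fam <- cfg$nSubgroups * cfg$familiesPerSubgroup
  expect_equal(sum(!q$labels$is_mutant), n_fam * cfg$queriesPerFamily)
  expect_equal(sum(q$labels$is_mutant),
               n_fam * round(cfg$mutantFraction * cfg$queriesPerFamily))
  # intact queries retain every planted residue of their lineage
  intact <- q$labels[!q$labels$is_mutant, ][1, ]
  fam_node <- NULL
  for (sg in sf$hierarchy@children) for (f in sg@children)
    if (f@name == intact$family) fam_node <- f
  seqchars <- strsplit(as.character(q$sequences[[intact$id]]), "")[[1]]
  for (k in seq_len(nrow(fam_node@residueSpecs))) {
    col <- fam_node@residueSpecs$msa_column[k]
    expect_true(seqchars[col] %in%
                  strsplit(fam_node@residueSpecs$allowed[k], "")[[1]])
  }
})

test_that("the optional deletion mode gaps alignments but never planted columns", {
  cfg <- synthConfig(seed = 5, membersPerFamily = 6L, indelRate = 0.02,
                     unplacedPerSubgroup = 2L, unplacedSf = 2L,
                     queriesPerFamily = 3L)
  sf <- generateSuperfamily(cfg)
  rows <- sf$hierarchy@seedMsa@rows
  expect_true(any(grepl("-", rows)))
  for (p in sf$positions$superfamily)
    expect_false(any(substr(rows, p, p) == "-"))
  expect_equal(nrow(validateHierarchy(sf$hierarchy)), 0L)
  # profiles can still be built and searched over gapped seed alignments
  cal <- calibrateHierarchy(sf$hierarchy, sf$sequences)
  expect_true(all(vapply(hierarchyNodes(cal),
                         function(n) !is.null(n@cutoffs), logical(1))))
})

test_that("a written superfamily bundle reloads consistently", {
  sf <- small_superfamily()
  dir <- withr::local_tempdir()
  writeSuperfamily(sf, dir)
  seqs <- readFastaRecords(file.path(dir, "members.fasta"))
  expect_equal(as.character(seqs), as.character(sf$sequences))
  h <- readHierarchyJson(file.path(dir, "hierarchy.json"))
  expect_equal(nrow(validateHierarchy(h)), 0L)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), nrow(sf$truth))
})
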