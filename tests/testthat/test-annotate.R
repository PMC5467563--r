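test_that("a verbatim family seed member annotates to its family with residue evidence", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  fam <- cal@children[[1]]@children[[1]]
  seed_id <- fam@members[1]
  res <- assignAnnotation(sf$sequences[seed_id], cal)
  expect_s4_class(res, "AnnotationResult")
  expect_equal(res@assignedLevel, "family")
  expect_equal(res@assignedNode, fam@name)
  expect_equal(res@evidence, "hmm_plus_residues")
  expect_true(all(res@residueReport$passed[res@residueReport$node == fam@name]))
})

test_that("a planted catalytic mutant is held at subgroup level with a failing residue report", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  q <- generateQueries(sf)
  mutants <- q$labels[q$labels$is_mutant, ]
  expect_gt(nrow(mutants), 0)
  for (k in seq_len(min(4, nrow(mutants)))) {
    lab <- mutants[k, ]
    res <- assignAnnotation(q$sequences[lab$id], cal)
    expect_true(res@assignedLevel %in% c("subgroup", "superfamily"))
    rr <- res@residueReport[res@residueReport$node == lab$family, ]
    expect_true(any(!rr$passed))
    # the mutated copy differs from its template at exactly one position
    tpl <- strsplit(as.character(q$sequences[[lab$template]]), "")[[1]]
    mut <- strsplit(as.character(q$sequences[[lab$id]]), "")[[1]]
    expect_equal(sum(tpl != mut), 1L)
  }
})

test_that("shuffled sequences are left unannotated", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  dec <- shuffleResidues(sf$sequences[1:5], seed = 17)
  for (id in names(dec)) {
    res <- assignAnnotation(dec[id], cal)
    expect_equal(res@assignedLevel, "none")
  }
})

test_that("family assignment implies the subgroup and superfamily gates passed", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  q <- generateQueries(sf)
  intact <- q$labels$id[!q$labels$is_mutant]
  for (id in intact[seq(1, length(intact), by = 7)]) {
    res <- assignAnnotation(q$sequences[id], cal)
    if (res@assignedLevel == "family") {
      pl <- res@perLevel
      path <- nodePath(cal, res@assignedNode)
      anc <- pl[pl$node %in% path, ]
      expect_true(all(anc$bit_score >= anc$ga))
    }
  }
})

test_that("batch annotation tabulates queries deterministically and guards duplicates", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  empty <- batchAnnotate(Biostrings::AAStringSet(), cal)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("id", "sf", "subgroup", "family", "evidence") %in% names(empty)))

  two <- sf$sequences[c(2, 1)]
  tab <- batchAnnotate(two, cal)
  expect_equal(tab$id, sort(names(two)))  # id-ascending row order
  expect_false(any(tab$assigned_level == "family" & tab$evidence == "hmm_only"))

  dup <- setNames(sf$sequences[c(1, 1)], c("same", "same"))
  expect_error(batchAnnotate(dup, cal), "id collision")
})

test_that("residue checks read the aligned query through the column trace", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  fam <- cal@children[[1]]@children[[1]]
  qid <- fam@members[1]
  qseq <- as.character(sf$sequences[[qid]])
  r <- sfcurate:::cpp_profile_search(fam@profile@scores, qseq,
                                     "ACDEFGHIKLMNPQRSTVWYX", 11L, 1L)
  rep0 <- checkResidues(r$trace, qseq, fam)
  expect_true(all(rep0$passed))
  expect_equal(nrow(rep0), nrow(fam@residueSpecs))

  # a deletion spanning the spec column fails that spec
  trace_del <- r$trace
  pcol <- match(fam@residueSpecs$msa_column[1], profileColumnMap(fam@profile))
  trace_del[pcol] <- 0L
  rep1 <- checkResidues(trace_del, qseq, fam)
  expect_false(rep1$passed[1])
  expect_equal(rep1$observed[1], "-")

  # spec columns absent from the profile are a contract violation
  fam_bad <- fam
  fam_bad@residueSpecs$msa_column[1] <- 9999L
  expect_error(checkResidues(r$trace, qseq, fam_bad), "spec/profile mismatch")
})

test_that("annotation on uncalibrated hierarchies is refused", {
  sf <- small_superfamily()
  expect_error(assignAnnotation(sf$sequences[1], sf$hierarchy),
               "uncalibrated")
})

test_that("query-to-MSA alignment appends the query without touching seed rows", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  fam <- cal@children[[1]]@children[[1]]
  seed_id <- fam@members[1]
  before <- fam@seedMsa@rows
  aln <- alignQueryToMsa(sf$sequences[seed_id], fam)
  expect_equal(aln@rows[seq_along(before)], before)  # immutability
  appended <- aln@rows[[length(aln@rows)]]
  # a seed queried against its own profile reproduces its row on match columns
  own <- before[[seed_id]]
  cm <- profileColumnMap(fam@profile)
  expect_equal(substring(appended, cm, cm), substring(own, cm, cm))
  # rendering marks the functional-residue columns
  txt <- renderAlignmentText(aln)
  expect_match(txt[length(txt)], "\\^")
})
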