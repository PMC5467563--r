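test_that("efdSlice concatenates ranges, preserves full-length, rejects out-of-bounds", {
  set.seed(11)
  seqs <- Biostrings::AAStringSet(setNames(random_aa(300), "P1"))

  full <- enzymeFunctionalDomain("P1", 1, 300)
  expect_equal(as.character(efdSlice(seqs, full)[[1]]), as.character(seqs[[1]]))

  efd <- enzymeFunctionalDomain("P1", start = c(10, 100), end = c(50, 150),
                                label = c("core", "cap"),
                                homologyClass = c("sf_domain", "efd_partner"))
  sl <- efdSlice(seqs, efd)
  expect_equal(Biostrings::width(sl), 41 + 51)
  expect_equal(names(sl), "P1/10-50_100-150")
  expect_equal(as.character(sl[[1]]),
               paste0(substr(seqs[[1]], 10, 50), substr(seqs[[1]], 100, 150)))

  bad <- enzymeFunctionalDomain("P1", 250, 310)
  expect_error(efdSlice(seqs, bad), "invalid domain range")
})

test_that("efdSlice length equals the sum of range widths for random EFDs", {
  set.seed(21)
  seqs <- Biostrings::AAStringSet(setNames(random_aa(200), "Q1"))
  for (k in 1:20) {
    nr <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 191, by = 10), nr))
    ends <- starts + sample(0:8, nr, replace = TRUE)
    efd <- enzymeFunctionalDomain("Q1", starts, ends)
    expect_equal(Biostrings::width(efdSlice(seqs, efd)),
                 sum(ends - starts + 1))
  }
})

test_that("EFD validity enforces SFD presence and non-overlap; SFDs of co-resident EFDs must not overlap", {
  expect_error(enzymeFunctionalDomain("P1", c(1, 5), c(10, 20)),
               "non-overlapping")
  expect_error(enzymeFunctionalDomain("P1", 1, 10, homologyClass = "efd_partner"),
               "sf_domain")
  a <- enzymeFunctionalDomain("P1", 1, 100)
  b <- enzymeFunctionalDomain("P1", 150, 250)
  expect_true(isTRUE(checkEfdCompatibility(list(a, b))))
  c2 <- enzymeFunctionalDomain("P1", 90, 180)
  expect_match(checkEfdCompatibility(list(a, c2))[1], "overlap")
})

test_that("validateHierarchy reports containment, level and residue-spec violations", {
  msa_sf <- stockholmAlignment(c(s1 = "ACDEFGHIKLMN", s2 = "ACDEFGHIKLMN",
                                 s3 = "ACDEYGHIKLMN"))
  msa_fam <- stockholmAlignment(c(s1 = "ACDEFGHIKLMN", s2 = "ACDEFGHIKLMN"))
  fam <- hierarchyNode("family", "famA", members = c("s1", "s2"),
                       seedMsa = msa_fam,
                       residueSpecs = functionalResidueSpec(5, "FY"))
  sg <- hierarchyNode("subgroup", "sgA", members = c("s1", "s2", "s3"),
                      children = list(fam), seedMsa = msa_sf)
  root <- hierarchyNode("superfamily", "SF", members = c("s1", "s2", "s3"),
                        children = list(sg), seedMsa = msa_sf)
  expect_equal(nrow(validateHierarchy(root)), 0L)

  # member of the family absent from its subgroup
  fam_bad <- hierarchyNode("family", "famA", members = c("s1", "s9"),
                           seedMsa = msa_fam)
  root_bad <- hierarchyNode("superfamily", "SF", members = c("s1", "s2", "s3"),
    children = list(hierarchyNode("subgroup", "sgA", members = c("s1", "s2"),
                                  children = list(fam_bad))))
  rep <- validateHierarchy(root_bad)
  expect_true("containment" %in% rep$type)

  # root must be a superfamily
  rep2 <- validateHierarchy(hierarchyNode("subgroup", "sgX"))
  expect_true("level" %in% rep2$type)

  # superfamily spec unsatisfiable in a family seed MSA: column 5 is F/F in
  # the family, but the spec allows only W
  root_spec <- hierarchyNode("superfamily", "SF", members = c("s1", "s2", "s3"),
    children = list(hierarchyNode("subgroup", "sgA", members = c("s1", "s2"),
                                  children = list(fam))),
    seedMsa = msa_sf, residueSpecs = functionalResidueSpec(5, "W"))
  rep3 <- validateHierarchy(root_spec)
  expect_true("residue spec unsatisfiable" %in% rep3$type)
})

test_that("synthetic hierarchies validate cleanly and serialize through JSON", {
  sf <- small_superfamily()
  expect_equal(nrow(validateHierarchy(sf$hierarchy)), 0L)

  dir <- withr::local_tempdir()
  path <- file.path(dir, "sf.json")
  writeHierarchyJson(sf$hierarchy, path)
  back <- readHierarchyJson(path)
  expect_equal(back@name, sf$hierarchy@name)
  expect_equal(length(hierarchyNodes(back)), length(hierarchyNodes(sf$hierarchy)))
  expect_equal(sort(back@members), sort(sf$hierarchy@members))
  fam0 <- hierarchyNodes(sf$hierarchy)[[3]]
  fam1 <- hierarchyNodes(back)[[3]]
  expect_equal(fam1@residueSpecs, fam0@residueSpecs)
  expect_equal(fam1@seedMsa@rows, fam0@seedMsa@rows)
  expect_equal(nrow(validateHierarchy(back)), 0L)
})

test_that("annotation TSV export uses the fixed column order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  writeAnnotationTsv(data.frame(id = c("a", "b"), family = "famX",
                                species = "E. coli"), path)
  got <- read.delim(path)
  expect_identical(names(got), c("id", "sf", "subgroup", "family",
                                 "evidence_level", "species", "ec", "notes"))
  expect_equal(got$family, c("famX", "famX"))
})
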