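test_that("local alignment matches the brute-force DP oracle and is symmetric", {
  p <- scoringParams()
  # classic short pair
  h <- alignLocal("HEAGAWGHEE", "PAWHEAE", p)
  expect_equal(h$raw, oracle_local_score("HEAGAWGHEE", "PAWHEAE", p))
  set.seed(81)
  for (k in 1:40) {
    a <- random_aa(sample(5:30, 1))
    b <- random_aa(sample(5:30, 1))
    expect_equal(alignLocal(a, b, p)$raw, oracle_local_score(a, b, p))
    expect_equal(alignLocal(a, b, p)$raw, alignLocal(b, a, p)$raw)
  }
})

test_that("self-alignment raw score is the sum of diagonal matrix entries", {
  p <- scoringParams()
  set.seed(91)
  s <- random_aa(50)
  h <- alignLocal(s, s, p)
  ch <- strsplit(s, "")[[1]]
  expect_equal(h$raw, sum(diag(p$substitutionMatrix)[
    match(ch, rownames(p$substitutionMatrix))]))
  expect_equal(h$pct_identity, 100)
  expect_equal(h$trace, seq_len(50))
})

test_that("bit-score and E-value identities hold exactly for emitted hits", {
  p <- scoringParams()
  set.seed(101)
  db <- setNames(vapply(1:5, function(i) random_aa(60), character(1)),
                 paste0("t", 1:5))
  msa <- stockholmAlignment(setNames(c(db[[1]], db[[1]]), c("r1", "r2")))
  ht <- searchProfile(buildProfile(msa, p, "q"), db, p)
  h <- hits(ht)
  expect_equal(h$bit_score, (p$lambda * h$raw - log(p$K)) / log(2),
               tolerance = 1e-9)
  expect_equal(h$evalue,
               profileWidth(buildProfile(msa, p, "q")) * dbSize(ht) *
                 2^(-h$bit_score),
               tolerance = 1e-9)
  # E-value decreases strictly with bit score for fixed m, n
  expect_true(all(diff(h$evalue[order(h$bit_score)]) <= 0))
})

test_that("profile construction follows the pseudocount log-odds formula", {
  p <- scoringParams()
  msa <- stockholmAlignment(c(r1 = "AC--A", r2 = "AC--G", r3 = "AD---"))
  prof <- buildProfile(msa, p, "toy")
  # columns 3 and 4 are gap-majority and excluded; column 5 (1/3 gaps) stays
  expect_equal(profileColumnMap(prof), c(1L, 2L, 5L))
  hand <- function(count, n = 3) as.integer(round(2 * log2(((count + 1) / (n + 20)) / (1 / 20))))
  expect_equal(unname(prof@scores[1, "A"]), hand(3))
  expect_equal(unname(prof@scores[1, "C"]), hand(0))
  expect_equal(unname(prof@scores[2, "C"]), hand(2))
  expect_equal(unname(prof@scores[2, "D"]), hand(1))
  expect_equal(unname(prof@scores[3, "A"]), hand(1))
  # a column of identical residues scores that residue maximally
  msa2 <- stockholmAlignment(setNames(rep("W", 10), paste0("r", 1:10)))
  prof2 <- buildProfile(msa2, p, "toy2")
  expect_equal(names(which.max(prof2@scores[1, ])), "W")
  expect_error(buildProfile(stockholmAlignment(c(only = "ACD")), p),
               "insufficient depth")
})

test_that("profile search ranks seeds above shuffles and ignores database order", {
  sf <- small_superfamily()
  cal <- small_calibrated()
  fam <- cal@children[[1]]@children[[1]]
  seeds <- sf$sequences[fam@members]
  decoys <- shuffleResidues(seeds, seed = 5)
  db <- c(seeds, decoys)
  ht <- searchProfile(fam@profile, db)
  h <- hits(ht)
  expect_true(all(h$bit_score[h$target %in% names(seeds)] > 0))
  expect_gt(mean(h$bit_score[h$target %in% names(seeds)]),
            mean(h$bit_score[h$target %in% names(decoys)]))
  # permutation of the database leaves the ranked table unchanged
  ht2 <- searchProfile(fam@profile, rev(db))
  expect_equal(hits(ht2), hits(ht))
})

test_that("external hit tables import with dialect mapping and line-level errors", {
  dir <- withr::local_tempdir()
  p <- scoringParams()

  empty <- file.path(dir, "empty.tbl")
  writeLines("# comment only", empty)
  expect_equal(nrow(hits(importHits(empty, "hmmer_tblout"))), 0L)

  tbl <- file.path(dir, "three.tbl")
  writeLines(c(
    "# target name af a query name  af b   E-value  score  bias  x y z",
    "seqA - prof1 - 1e-50 180.5 0.1 0 0 0 0 0",
    "seqB - prof1 - 1e-30 120.0 0.0 0 0 0 0 0",
    "seqC - prof1 - 1e-10  60.25 0.2 0 0 0 0 0"), tbl)
  ht <- importHits(tbl, "hmmer_tblout")
  expect_equal(hits(ht)$target, c("seqA", "seqB", "seqC"))
  expect_equal(hits(ht)$bit_score, c(180.5, 120.0, 60.25))
  expect_true(all(diff(hits(ht)$bit_score) < 0))

  bad <- file.path(dir, "bad.tbl")
  writeLines(c(
    "seqA - prof1 - 1e-50 180.5 0.1 0 0 0 0 0",
    "seqB - prof1 - 1e-30 notanumber 0.0 0 0 0 0 0"), bad)
  expect_error(importHits(bad, "hmmer_tblout"), "line 2")

  b6 <- file.path(dir, "hits.b6")
  writeLines(c(
    "q1\tseqA\t97.5\t100\t2\t0\t1\t100\t5\t104\t1e-40\t150.1",
    "q1\tseqB\t80.0\t100\t20\t1\t1\t100\t3\t101\t1e-20\t99.9"), b6)
  hb <- importHits(b6, "blast_tab6")
  expect_equal(hits(hb)$target, c("seqA", "seqB"))
  expect_equal(hits(hb)$tstart, c(5, 3))
  expect_equal(hits(hb)$evalue, c(1e-40, 1e-20))
})

test_that("hit tables reject duplicate pairs and enforce rank order", {
  df <- data.frame(query = "q", target = c("a", "a"), raw = c(10, 9),
                   bit_score = c(10, 9), evalue = c(1e-3, 1e-2),
                   tstart = NA_real_, tend = NA_real_)
  expect_error(hitTable(df, 100), "duplicate")
})
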