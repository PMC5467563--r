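test_that("the drop scan finds the first >=10% fall and handles edge cases", {
  expect_equal(findDrop(c(100, 95, 80, 78)), 2L)      # 95 -> 80 is 15.8%
  expect_true(is.na(findDrop(c(130, 125, 120, 118, 117))))
  expect_true(is.na(findDrop(150)))
  expect_error(findDrop(c(80, 100)), "descending")
  expect_error(findDrop(c(100, -5)), "positive")
  expect_equal(findDrop(c(100, 89.9)), 1L)
  expect_true(is.na(findDrop(c(100, 91))))
})

test_that("seed capture returns the lowest seed score, or nothing when a seed is absent", {
  ht <- make_hit_table(c("a", "b", "c", "d"), c(200, 190, 100, 90))
  expect_equal(seedCaptureScore(ht, c("a", "b")), 190)
  expect_equal(seedCaptureScore(ht, c("a", "b", "c", "d")), 90)
  expect_true(is.na(seedCaptureScore(ht, c("a", "zz"))))
  expect_error(seedCaptureScore(ht, character()), "empty seed set")
})

test_that("cutoff computation reproduces the worked examples of the threshold rules", {
  # drop and seed capture coincide at 190: TC=190, NC=100, GA=145
  ht <- make_hit_table(c("a", "b", "c", "d"), c(200, 190, 100, 90))
  co <- computeCutoffs(ht, seedIds = c("a", "b"))
  expect_equal(trustedCutoff(co), 190)
  expect_equal(noiseCutoff(co), 100)
  expect_equal(gatheringThreshold(co), 145)

  # a single score capturing the whole seed set: TC = NC = GA = that score
  ht1 <- make_hit_table("a", 150)
  co1 <- computeCutoffs(ht1, "a")
  expect_equal(c(trustedCutoff(co1), noiseCutoff(co1), gatheringThreshold(co1)),
               c(150, 150, 150))
  expect_equal(co1@method, "seed_capture")

  # no >=10% drop anywhere; seeds captured at 120: TC=120, NC=118, GA=119
  ht2 <- make_hit_table(c("a", "b", "c", "d", "e"),
                        c(130, 125, 120, 118, 117))
  co2 <- computeCutoffs(ht2, c("a", "b", "c"))
  expect_equal(trustedCutoff(co2), 120)
  expect_equal(noiseCutoff(co2), 118)
  expect_equal(gatheringThreshold(co2), 119)
  expect_equal(co2@method, "seed_capture")

  # neither candidate computable
  ht3 <- make_hit_table(c("a", "b"), c(100, 99))
  expect_error(computeCutoffs(ht3, c("a", "zz")), "curator decision required")

  # curator override
  com <- computeCutoffs(ht, c("a", "b"),
                        calibrationConfig(manualGA = 160))
  expect_equal(gatheringThreshold(com), 160)
  expect_equal(com@method, "manual")
})

test_that("cutoffs agree with an independent rule transcription on random instances", {
  set.seed(111)
  p <- scoringParams()
  for (k in 1:300) {
    n <- sample(1:40, 1)
    bits <- sort(round(runif(n, 1, 500), 2), decreasing = TRUE)
    if (sample(c(TRUE, FALSE), 1)) bits <- unique(bits)
    targets <- sprintf("t%02d", seq_along(bits))
    seeds <- sample(targets, sample(seq_len(n), 1))
    if (runif(1) < 0.1) seeds <- c(seeds, "absent")
    ht <- make_hit_table(targets, bits)
    want <- oracle_cutoffs(targets, bits, seeds)
    if (is.null(want)) {
      expect_error(computeCutoffs(ht, seeds))
    } else {
      got <- computeCutoffs(ht, seeds)
      expect_equal(trustedCutoff(got), want$tc)
      expect_equal(noiseCutoff(got), want$nc)
      expect_equal(gatheringThreshold(got), want$ga)
      # invariants: NC <= GA <= TC, GA exactly the midpoint
      expect_lte(noiseCutoff(got), gatheringThreshold(got))
      expect_lte(gatheringThreshold(got), trustedCutoff(got))
      expect_identical(gatheringThreshold(got),
                       (trustedCutoff(got) + noiseCutoff(got)) / 2)
    }
  }
})

test_that("a new top hit that introduces no fresh drop leaves the cutoffs unchanged", {
  set.seed(121)
  for (k in 1:50) {
    n <- sample(3:30, 1)
    bits <- sort(round(runif(n, 10, 400), 1), decreasing = TRUE)
    targets <- sprintf("t%02d", seq_along(bits))
    seeds <- sample(targets, sample(2:n, 1))
    ht <- make_hit_table(targets, bits)
    got <- tryCatch(computeCutoffs(ht, seeds), error = function(e) NULL)
    if (is.null(got)) next
    # 5% above the previous top: cannot create a >=10% drop by itself
    extra <- make_hit_table(c(targets, "top"), c(bits, bits[1] * 1.05))
    got2 <- computeCutoffs(extra, seeds)
    expect_equal(trustedCutoff(got2), trustedCutoff(got))
    expect_equal(noiseCutoff(got2), noiseCutoff(got))
    expect_equal(gatheringThreshold(got2), gatheringThreshold(got))
  }
})

test_that("cutoffs survive a JSON round trip", {
  dir <- withr::local_tempdir()
  co <- computeCutoffs(make_hit_table(c("a", "b", "c"), c(100, 80, 70)), "a")
  path <- file.path(dir, "cutoffs.json")
  writeCutoffsJson(co, path)
  back <- readCutoffsJson(path)
  expect_equal(trustedCutoff(back), trustedCutoff(co))
  expect_equal(noiseCutoff(back), noiseCutoff(co))
  expect_equal(gatheringThreshold(back), gatheringThreshold(co))
  expect_equal(back@method, co@method)
})
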