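test_that("network construction draws symmetric conservative edges", {
  set.seed(131)
  s <- random_aa(80)
  pairden <- Biostrings::AAStringSet(setNames(c(s, s), c("a", "b")))
  net <- buildNetwork(pairden, maxEvalue = 10)
  expect_equal(nrow(networkEdges(net)), 1L)
  expect_equal(networkNodes(net)$length, c(80L, 80L))

  # unrelated random sequences at a stringent ceiling: no edges, nodes kept
  rnd <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) random_aa(80), character(1)), paste0("r", 1:6)))
  net0 <- buildNetwork(rnd, maxEvalue = 1e-12)
  expect_equal(nrow(networkEdges(net0)), 0L)
  expect_equal(nrow(networkNodes(net0)), 6L)

  # input order does not matter
  seqs <- c(pairden, rnd)
  n1 <- buildNetwork(seqs, maxEvalue = 10)
  n2 <- buildNetwork(rev(seqs), maxEvalue = 10)
  expect_equal(networkNodes(n1), networkNodes(n2))
  expect_equal(networkEdges(n1), networkEdges(n2))

  expect_error(buildNetwork(pairden[1]), "at least 2")
})

test_that("the retained E-value of a pair is the larger directional one", {
  set.seed(141)
  a <- random_aa(60)
  b <- paste0(a, random_aa(120))  # same core, much longer
  net <- buildNetwork(Biostrings::AAStringSet(c(short = a, long = b)),
                      maxEvalue = 10)
  e <- networkEdges(net)
  p <- scoringParams()
  h <- alignLocal(a, b, scoringParams(dbSize = net@metadata$db_size))
  expect_equal(e$evalue, max(60, 180) * net@metadata$db_size * 2^(-h$bit_score),
               tolerance = 1e-9)
})

test_that("thresholding keeps nodes, filters edges, and sweeps monotonically", {
  net <- default_network()
  e <- networkEdges(net)
  # permissive cutoff above every edge: no-op
  same <- applyThreshold(net, max(e$evalue) * 10)
  expect_equal(nrow(networkEdges(same)), nrow(e))
  # below every edge: empty edge set, full node set
  none <- applyThreshold(net, min(e$evalue) / 10)
  expect_equal(nrow(networkEdges(none)), 0L)
  expect_equal(nrow(networkNodes(none)), nrow(networkNodes(net)))

  cuts <- 10^seq(-6, -90, by = -12)
  sw <- thresholdSweep(net, cuts)
  expect_true(all(diff(sw$n_edges) <= 0))
  expect_true(all(diff(sw$n_components) >= 0))
  expect_error(thresholdSweep(net, rev(cuts)), "decreasing")
})

test_that("swept components at the best cutoff recover the planted subgroups", {
  sf <- default_superfamily()
  net <- default_network()
  cuts <- 10^seq(-6, -90, by = -6)
  sw <- thresholdSweep(net, cuts)
  truth <- setNames(sf$truth$subgroup, sf$truth$id)
  ari <- vapply(attr(sw, "memberships"), function(m)
    mclust::adjustedRandIndex(m, truth[names(m)]), numeric(1))
  expect_gte(max(ari), 0.9)
})

test_that("representative networks partition the sequences and summarize attributes", {
  set.seed(151)
  seqs <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) random_aa(70), character(1)), paste0("n", 1:6)))
  net <- buildNetwork(seqs, maxEvalue = 10)

  # identity 1.0 over all-distinct sequences: one node per sequence
  rep1 <- makeRepresentative(net, seqs, identity = 1.0)
  expect_equal(nrow(networkNodes(rep1)), 6L)
  expect_equal(sort(networkNodes(rep1)$id), sort(names(seqs)))

  # a cluster of five with EC values {x3, x2}: dominant is the majority value
  base <- random_aa(70)
  clus <- Biostrings::AAStringSet(setNames(rep(base, 5), paste0("c", 1:5)))
  cnet <- buildNetwork(clus, maxEvalue = 10)
  cnet <- paintAttributes(cnet, data.frame(
    id = paste0("c", 1:5), ec = c("1.1.1.1", "1.1.1.1", "1.1.1.1",
                                  "1.1.1.2", "1.1.1.2")))
  crep <- makeRepresentative(cnet, clus, identity = 0.9)
  expect_equal(nrow(networkNodes(crep)), 1L)
  expect_equal(networkNodes(crep)$size, 5L)
  expect_equal(networkNodes(crep)$ec, "1.1.1.1")
  expect_equal(networkNodes(crep)$ec_values, "1.1.1.1,1.1.1.2")
  # partition property: members cover the input exactly once
  members <- unlist(strsplit(networkNodes(crep)$members, ","))
  expect_setequal(members, names(clus))

  # attributes empty for every member are omitted from the summary
  cnet2 <- paintAttributes(buildNetwork(clus, maxEvalue = 10),
                           data.frame(id = paste0("c", 1:5), note = ""))
  crep2 <- makeRepresentative(cnet2, clus, identity = 0.9)
  expect_false("note" %in% names(networkNodes(crep2)))
})

test_that("attribute painting merges by id and reports unmatched rows", {
  set.seed(161)
  seqs <- Biostrings::AAStringSet(setNames(
    vapply(1:3, function(i) random_aa(50), character(1)), c("a", "b", "c")))
  net <- buildNetwork(seqs, maxEvalue = 10)
  same <- paintAttributes(net, data.frame())
  expect_equal(networkNodes(same), networkNodes(net))

  painted <- paintAttributes(net, data.frame(id = c("a", "b", "zz"),
                                             ec = c("1.1.1.1", "2.2.2.2", "9.9.9.9")))
  expect_equal(networkNodes(painted)$ec,
               c("1.1.1.1", "2.2.2.2", NA))
  expect_equal(painted@metadata$unmatched, "zz")
  expect_equal(networkEdges(painted), networkEdges(net))

  expect_error(paintAttributes(net, data.frame(id = c("a", "a"), ec = "x")),
               "duplicate key")
})

test_that("XGMML round trips reproduce nodes, edges and attributes exactly", {
  set.seed(171)
  seqs <- Biostrings::AAStringSet(setNames(
    c(rep(random_aa(60), 2), random_aa(60)), c("a", "b", "c")))
  net <- buildNetwork(seqs, maxEvalue = 10)
  net <- paintAttributes(net, data.frame(id = c("a", "b", "c"),
                                         ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2")))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "net.xgmml")
  writeXgmml(net, path)
  back <- readXgmml(path)
  expect_setequal(networkNodes(back)$id, networkNodes(net)$id)
  nb <- networkNodes(back)[order(networkNodes(back)$id), ]
  nn <- networkNodes(net)[order(networkNodes(net)$id), ]
  expect_equal(nb$length, nn$length)
  expect_equal(nb$ec, nn$ec)
  eb <- networkEdges(back); en <- networkEdges(net)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(eb), key(en))
  o1 <- order(key(eb)); o2 <- order(key(en))
  expect_identical(eb$evalue[o1], en$evalue[o2])
  expect_identical(eb$bit_score[o1], en$bit_score[o2])

  # an edgeless network still writes valid XGMML
  net0 <- applyThreshold(net, 1e-300)
  writeXgmml(net0, path)
  back0 <- readXgmml(path)
  expect_equal(nrow(networkEdges(back0)), 0L)
  expect_equal(nrow(networkNodes(back0)), 3L)
})

test_that("the dissemination bundle carries the network, README and length histogram", {
  set.seed(181)
  seqs <- Biostrings::AAStringSet(setNames(
    vapply(1:8, function(i) random_aa(sample(50:90, 1)), character(1)),
    paste0("s", 1:8)))
  net <- buildNetwork(seqs, maxEvalue = 10)
  dir <- withr::local_tempdir()
  zipf <- file.path(dir, "bundle.zip")
  exportBundle(net, zipf, label = "demo")
  listing <- utils::unzip(zipf, list = TRUE)
  expect_setequal(listing$Name, c("network.xgmml", "README.txt",
                                  "lengths.tsv", "lengths.png"))
  utils::unzip(zipf, exdir = dir)
  # histogram bin counts sum to the node count
  bins <- read.delim(file.path(dir, "lengths.tsv"))
  expect_equal(sum(bins$count), nrow(networkNodes(net)))
  # the zipped XGMML parses back to the same network
  back <- readXgmml(file.path(dir, "network.xgmml"))
  expect_setequal(networkNodes(back)$id, networkNodes(net)$id)
  expect_match(readLines(file.path(dir, "README.txt")), "XGMML", all = FALSE)
})
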