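# Independent brute-force oracles, written against the package's documented
# conventions (gap of length L costs open + L * ext) but sharing no code with
# the implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# full-matrix global alignment score (three-state affine)
oracle_global_score <- function(a, b, p = scoringParams()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  S <- p$substitutionMatrix; go <- p$gapOpen; ge <- p$gapExtend
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge, Y[i, j - 1] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# full-matrix local (Smith-Waterman) score
oracle_local_score <- function(a, b, p = scoringParams()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  S <- p$substitutionMatrix; go <- p$gapOpen; ge <- p$gapExtend
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- X
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc)
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    best <- max(best, M[i, j])
  }
  best
}

# direct transcription of the threshold rules, scanning the ranked list:
# two candidates (score before the first >=10% consecutive drop; score at
# which every seed has appeared), TC = the lower available one, NC = next
# strictly lower ranked score (TC if none), GA = midpoint. Returns NULL when
# neither candidate exists.
oracle_cutoffs <- function(targets, bits, seeds, drop = 0.10) {
  o <- order(-bits, targets)
  targets <- targets[o]; bits <- bits[o]
  keep <- !duplicated(targets)
  targets <- targets[keep]; bits <- bits[keep]
  ranks <- unique(bits[bits > 0])
  cand_drop <- NA_real_
  if (length(ranks) >= 2) {
    for (i in 1:(length(ranks) - 1)) {
      if ((ranks[i] - ranks[i + 1]) / ranks[i] >= drop - 1e-12) {
        cand_drop <- ranks[i]
        break
      }
    }
  }
  cand_seed <- if (all(seeds %in% targets))
    min(bits[targets %in% seeds]) else NA_real_
  cands <- c(cand_drop, cand_seed)
  cands <- cands[!is.na(cands)]
  if (!length(cands)) return(NULL)
  tc <- min(cands)
  below <- ranks[ranks < tc]
  nc <- if (length(below)) max(below) else tc
  list(tc = tc, nc = nc, ga = (tc + nc) / 2)
}

# assemble a HitTable directly from target/bit vectors (raw back-computed so
# the Karlin-Altschul identities hold)
make_hit_table <- function(targets, bits, dbSize = 1e6, query = "q",
                           m = 100, p = scoringParams()) {
  raw <- (bits * log(2) + log(p$K)) / p$lambda
  hitTable(data.frame(query = query, target = targets, raw = raw,
                      bit_score = bits, evalue = eValue(bits, m, dbSize),
                      tstart = NA_real_, tend = NA_real_,
                      stringsAsFactors = FALSE), dbSize)
}
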