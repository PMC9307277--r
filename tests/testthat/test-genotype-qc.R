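# Independent enumeration oracle for the Hardy-Weinberg exact test:
# probability of each heterozygote count from the hypergeometric-style
# closed form, normalised by direct summation.
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nAB %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAB, hets)] + 1e-12])
}

test_that("HWE exact test matches full enumeration", {
  expect_equal(hweExactTest(10, 0, 0), 1)        # monomorphic
  expect_equal(hweExactTest(0, 0, 0), 1)
  for (cnt in list(c(0, 50, 0), c(25, 50, 25), c(5, 10, 30), c(2, 40, 2))) {
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 hweOracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_gt(hweExactTest(25, 50, 25), 0.5)
  expect_error(hweExactTest(-1, 0, 0), "non-negative")
})

test_that("qc filter removes low call rate, low MAF, HWE outliers", {
  set.seed(21)
  n <- 100
  calls <- sapply(1:10, function(j) rbinom(n, 2, 0.5))
  calls[, 2] <- rbinom(n, 2, 0.02)               # MAF ~0.02 < 0.05
  calls[, 3] <- rep(c(0L, 2L), n / 2)            # extreme HWE violation
  calls[1, sample(10, 3)] <- NA                  # ind 1: call rate 0.7 < 0.9
  g <- gmFromCalls(calls)
  out <- qcFilter(g)
  expect_equal(nIndividuals(out$genotypes), n - 1)
  kept <- markerMap(out$genotypes)$marker_id
  expect_false(markerMap(g)$marker_id[2] %in% kept)
  expect_false(markerMap(g)$marker_id[3] %in% kept)
  expect_true(markerMap(g)$marker_id[1] %in% kept)
  # marker with MAF exactly 0.04 is removed ("< 5%")
  calls2 <- cbind(rbinom(50, 2, 0.5), c(rep(1L, 4), rep(0L, 46)))
  out2 <- qcFilter(gmFromCalls(calls2))
  expect_equal(nMarkers(out2$genotypes), 1)
  # report is consistent
  rep1 <- out$report
  expect_equal(unname(rep1$input["markers"]),
               unname(sum(rep1$removed_markers) + rep1$retained["markers"]))
})

test_that("qc filter is idempotent and orients dosage to the minor allele", {
  set.seed(22)
  calls <- sapply(1:12, function(j) rbinom(80, 2, runif(1, 0.1, 0.9)))
  g <- gmFromCalls(calls)
  once <- qcFilter(g)
  twice <- qcFilter(once$genotypes)
  expect_identical(genotypeCalls(once$genotypes),
                   genotypeCalls(twice$genotypes))
  expect_equal(twice$report$removed_individuals, 0)
  expect_true(all(colMeans(genotypeCalls(once$genotypes)) <= 1 + 1e-12))
})

test_that("ld r2: identity, perfect negative, null magnitude", {
  calls <- cbind(c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L), c(0L, 0L, 2L, 2L))
  g <- gmFromCalls(calls)
  expect_equal(ldR2(g, 1, 1), 1)
  expect_equal(ldR2(g, 1, 2), 1)                 # perfect negative, squared
  const <- gmFromCalls(cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 0L)))
  expect_true(is.na(ldR2(const, 1, 2)))
  # E[r2] ~ 1/(n-1) for independent markers
  set.seed(23)
  n <- 1000
  cal <- sapply(1:400, function(j) rbinom(n, 2, 0.4))
  gi <- gmFromCalls(cal)
  r2s <- sapply(seq(1, 399, by = 2), function(j) ldR2(gi, j, j + 1))
  se <- sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * se)
})

test_that("ld pruning: duplicates collapse, independent markers survive", {
  set.seed(24)
  base <- rbinom(60, 2, 0.5)
  calls <- cbind(base, base, rbinom(60, 2, 0.5), rbinom(60, 2, 0.3))
  g <- gmFromCalls(calls)
  kept <- ldPrune(g)
  expect_equal(length(kept), 3)
  expect_true(sum(markerMap(g)$marker_id[1:2] %in% kept) == 1)
  # independent markers all retained
  set.seed(25)
  gi <- gmFromCalls(sapply(1:8, function(j) rbinom(50, 2, 0.5)))
  expect_equal(length(ldPrune(gi)), 8)
})

test_that("ld pruning resolves a constructed 10-marker block correctly", {
  # two duplicate groups (r2 = 1 within group) among otherwise independent
  # markers: the survivor set is derivable by hand -- one member per group
  # (ties in MAF resolved to the earlier position) plus all singletons
  set.seed(26)
  n <- 120
  base1 <- rbinom(n, 2, 0.5)
  base2 <- rbinom(n, 2, 0.3)
  calls <- cbind(base1, rbinom(n, 2, 0.4), base1,        # group1: 1, 3
                 base2, base2, base2,                     # group2: 4, 5, 6
                 rbinom(n, 2, 0.5), rbinom(n, 2, 0.25),
                 rbinom(n, 2, 0.45), rbinom(n, 2, 0.35))
  g <- gmFromCalls(calls)
  ids <- markerMap(g)$marker_id
  kept <- ldPrune(g, window = 5, step = 1, r2Max = 0.9)
  expect_setequal(kept, ids[c(1, 2, 4, 7, 8, 9, 10)])
  # no surviving within-window pair exceeds the threshold, on LD-rich data
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2L - x[i]; x }
  rich <- cbind(base1, flip(base1, 2), flip(base1, 3), rbinom(n, 2, 0.4),
                base1, flip(base1, 25), rbinom(n, 2, 0.3),
                flip(base1, 1), rbinom(n, 2, 0.5), flip(base1, 30))
  gr <- gmFromCalls(rich)
  keptR <- ldPrune(gr)
  idx <- match(keptR, markerMap(gr)$marker_id)
  for (s in seq_along(idx)) {
    win <- idx[s:min(s + 4, length(idx))]
    for (a in win) for (b in win) if (a < b) {
      r <- ldR2(gr, a, b)
      expect_true(is.na(r) || r <= 0.9)
    }
  }
  # and pruning is insensitive to individual order
  perm <- sample(n)
  gp <- GenotypeMatrix(genotypeCalls(gr)[perm, ], markerMap(gr))
  expect_setequal(ldPrune(gr), ldPrune(gp))
})

test_that("AIM detection follows the frequency-difference rules", {
  set.seed(27)
  p <- 6
  freqM <- c(1.0, 0.9, 0.6, 0.5, 1.0, 0.8)
  freqD <- c(0.0, 0.2, 0.4, 0.5, 0.85, 0.9)
  mkPanel <- function(fr, n) gmFromCalls(sapply(fr, function(f)
    rbinom(n, 2, f)))
  # deterministic panels: use expected dosages scaled to calls
  callsM <- sapply(freqM, function(f) rbinom(30, 2, f))
  callsD <- sapply(freqD, function(f) rbinom(30, 2, f))
  callsM[, 1] <- 2L; callsD[, 1] <- 0L            # fixed difference
  callsM[, 3] <- rbinom(30, 2, 0.6); callsD[, 3] <- rbinom(30, 2, 0.45)
  gM <- gmFromCalls(callsM); gD <- gmFromCalls(callsD)
  aims <- findAims(gM, gD)
  expect_true(markerMap(gM)$marker_id[1] %in% aims$marker_id)
  expect_true(aims$fixed_difference[aims$marker_id ==
                                      markerMap(gM)$marker_id[1]])
  # freq difference 0.15 at marker 3: not an AIM
  expect_false(markerMap(gM)$marker_id[3] %in% aims$marker_id)
  # 9 calls in one panel: excluded regardless of frequencies
  callsM9 <- callsM; callsM9[10:30, 1] <- NA
  aims9 <- findAims(gmFromCalls(callsM9), gD)
  expect_false(markerMap(gM)$marker_id[1] %in% aims9$marker_id)
  # marker-map mismatch errors
  gBad <- gmFromCalls(callsD[, 1:5])
  expect_error(findAims(gM, gBad), "marker map")
})

test_that("hybrid index: boundaries and pedigree expectation", {
  aims <- data.frame(marker_id = sprintf("chr1_m%04d", 1:5),
                     musculus_allele = rep("B", 5),
                     stringsAsFactors = FALSE)
  pureM <- gmFromCalls(matrix(2L, 3, 5))
  expect_equal(unname(hybridIndex(pureM, aims)), rep(1, 3))
  het <- gmFromCalls(matrix(1L, 3, 5))
  expect_equal(unname(hybridIndex(het, aims)), rep(0.5, 3))
  pureD <- gmFromCalls(matrix(0L, 2, 5))
  expect_equal(unname(hybridIndex(pureD, aims)), rep(0, 2))
  # simulated G2 cohort: mean hybrid index near the pedigree expectation
  co <- smallCohort()
  f <- co$founders
  aims2 <- data.frame(marker_id = f$map$marker_id[f$diagnostic],
                      musculus_allele = "M", stringsAsFactors = FALSE)
  hi <- hybridIndex(co$genotypes, aims2)
  expected <- mean(f$subspeciesWeights)          # balanced 4-stock cross
  expect_lt(abs(mean(hi) - expected), 0.05)
})
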