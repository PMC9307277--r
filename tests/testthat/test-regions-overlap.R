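test_that("region expansion matches a brute-force r2 scan", {
  # constructed LD block: markers at 1, 2 and 3 Mb are exact copies, the
  # rest independent
  set.seed(91)
  n <- 80
  base <- rbinom(n, 2, 0.5)
  calls <- cbind(rbinom(n, 2, 0.4), base, rbinom(n, 2, 0.3), base,
                 rbinom(n, 2, 0.45), base, rbinom(n, 2, 0.35))
  map <- data.frame(marker_id = sprintf("m%d", 1:7), chromosome = 1,
                    position_bp = c(5e5, 1e6, 15e5, 2e6, 25e5, 3e6, 35e5),
                    genetic_pos_cM = 1:7)
  g <- GenotypeMatrix(calls, map)
  r <- expandRegion("m4", g)
  expect_equal(r$start_bp, 1e6)
  expect_equal(r$end_bp, 3e6)
  # brute-force check over all same-chromosome markers
  brute <- sapply(1:7, function(k) {
    rr <- ldR2(g, 4, k); !is.na(rr) && rr > 0.9
  })
  expect_equal(range(map$position_bp[brute]), c(r$start_bp, r$end_bp))
  # marker with no LD partner: 1-bp interval at its own position
  r3 <- expandRegion("m3", g)
  expect_equal(c(r3$start_bp, r3$end_bp), c(15e5, 15e5))
  expect_error(expandRegion("nope", g), "not in full")
})

test_that("region merging: 9 Mb merges, 10 Mb does not, order-insensitive", {
  iv <- data.frame(chrom = c("1", "1", "1", "2"),
                   start_bp = c(1e6, 12e6, 40e6, 1e6),
                   end_bp = c(3e6, 14e6, 41e6, 2e6),
                   marker = c("a", "b", "c", "d"),
                   taxon = c("t1", "t1", "t2", "t3"),
                   stringsAsFactors = FALSE)
  # gap between (1-3 Mb) and (12-14 Mb) = 12e6 - 3e6 - 1 < 10 Mb -> merged
  m <- mergeRegions(iv)
  expect_equal(nrow(m), 3)
  first <- m[m$chrom == "1" & m$start_bp == 1e6, ]
  expect_equal(first$end_bp, 14e6)
  expect_equal(first$markers, "a,b")
  # gap of exactly 10 Mb is not merged (strict <)
  ivx <- data.frame(chrom = "1", start_bp = c(1e6, 2e7),
                    end_bp = c(1e7, 2.1e7))
  gap <- ivx$start_bp[2] - ivx$end_bp[1] - 1
  expect_equal(gap, 1e7 - 1)                 # 9999999 strictly between
  expect_equal(nrow(mergeRegions(ivx)), 1)   # gap < 10 Mb: merged
  ivy <- data.frame(chrom = "1", start_bp = c(1e6, 1e7 + 1e7 + 1),
                    end_bp = c(1e7, 3e7))
  expect_equal(ivy$start_bp[2] - ivy$end_bp[1] - 1, 1e7)  # exactly 10 Mb
  expect_equal(nrow(mergeRegions(ivy)), 2)
  # overlapping intervals collapse to min start / max end; idempotent;
  # order-insensitive
  ivo <- data.frame(chrom = "3", start_bp = c(5e6, 1e6), end_bp = c(9e6, 6e6))
  mo <- mergeRegions(ivo)
  expect_equal(c(mo$start_bp, mo$end_bp), c(1e6, 9e6))
  m2 <- mergeRegions(iv[sample(nrow(iv)), ])
  expect_equal(m[order(m$chrom, m$start_bp), c("chrom", "start_bp", "end_bp")],
               m2[order(m2$chrom, m2$start_bp),
                  c("chrom", "start_bp", "end_bp")])
  mm <- mergeRegions(m[, c("chrom", "start_bp", "end_bp")])
  expect_equal(mm[, 1:3], m[, 1:3])
  expect_true(all(m$end_bp - m$start_bp + 1 >= 1))
})

test_that("gene assignment and nearest up/downstream genes", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    chrom = "1",
                    start_bp = c(1e6, 5e6, 9e6, 20e6),
                    end_bp = c(2e6, 6e6, 10e6, 21e6),
                    strand = "+", stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "1", start_bp = 4e6, end_bp = 11e6)
  out <- assignGenes(regions, ann)
  expect_equal(out$genes, "gB,gC")
  # empty annotation: empty lists, no error
  empty <- assignGenes(regions, ann[0, ])
  expect_equal(empty$genes, "")
  # SNP inside gB: gB plus the nearest gene on the other side
  ng <- nearestGenes("1", 5.8e6, ann)
  expect_true("gB" %in% ng)
  expect_equal(length(ng), 2)
  expect_true("gC" %in% ng)                  # 9e6 - 5.8e6 < 5.8e6 - 2e6
  # SNP between genes: one upstream and one downstream
  ng2 <- nearestGenes("1", 7e6, ann)
  expect_setequal(ng2, c("gB", "gC"))
  # contig mismatch errors
  expect_error(assignGenes(data.frame(chrom = "9", start_bp = 1,
                                      end_bp = 10), ann), "contig")
})

test_that("interval-overlap permutation matches geometric expectation", {
  genome <- c("1" = 1e8)
  setA <- data.frame(chrom = "1", start_bp = 4e7, end_bp = 4e7 + 1e6 - 1)
  setB <- data.frame(chrom = "1", start_bp = 6e7, end_bp = 6e7 + 1e6 - 1)
  out <- overlapPermutation(setA, setB, genome, nPerm = 4000, seed = 92)
  expect_equal(out$observed, 0)
  # closed-form collision probability for a uniformly placed 1 Mb interval
  pHit <- (2e6 - 1) / (1e8 - 1e6 + 1)
  se <- sqrt(pHit * (1 - pHit) / 4000)
  expect_lt(abs(out$permutedMean - pHit), 3 * se)
  expect_gte(out$p, 1 / 4001)
  # set_b covering the whole chromosome: every permutation overlaps; p = 1
  setBfull <- data.frame(chrom = "1", start_bp = 1, end_bp = 1e8)
  outF <- overlapPermutation(setA, setBfull, genome, nPerm = 200, seed = 93)
  expect_equal(outF$observed, 1)
  expect_equal(outF$permutedMean, 1)
  expect_equal(outF$p, 1)
  # empty set_a
  out0 <- overlapPermutation(setA[0, ], setB, genome, nPerm = 100)
  expect_equal(out0$observed, 0)
  expect_equal(out0$p, 1)
  # interval longer than chromosome errors
  expect_error(overlapPermutation(
    data.frame(chrom = "1", start_bp = 1, end_bp = 2e8), setB, genome),
    "longer than")
  # oversized regions can be filtered before testing
  big <- data.frame(chrom = "1", start_bp = 1, end_bp = 2e7)
  outBig <- overlapPermutation(big, setB, genome, nPerm = 100,
                               maxRegionBp = 1e7)
  expect_equal(outBig$observed, 0)
  expect_equal(outBig$p, 1)
})

test_that("gene-set enrichment: hypergeometric mean and edge cases", {
  universe <- sprintf("g%04d", 1:1000)
  geneSet <- universe[1:100]
  hits <- universe[seq(10, 500, by = 10)]    # 50 genes
  out <- genesetEnrichment(hits, geneSet, universe, nPerm = 4000, seed = 94)
  # permuted mean ~ hypergeometric mean 50 * 100/1000 = 5
  hypSd <- sqrt(50 * 0.1 * 0.9 * (1000 - 50) / (1000 - 1))
  expect_lt(abs(out$permutedMean - 5), 3 * hypSd / sqrt(4000))
  expect_gte(out$pPermutation, 1 / 4001)
  # gene_set = universe: overlap = |hit|, p = 1
  all1 <- genesetEnrichment(hits, universe, universe, nPerm = 200)
  expect_equal(all1$observed, length(hits))
  expect_equal(all1$pPermutation, 1)
  # disjoint by construction
  disj <- genesetEnrichment(universe[501:550], universe[1:100], universe,
                            nPerm = 200)
  expect_equal(disj$observed, 0)
  expect_error(genesetEnrichment(hits, geneSet, character()), "empty")
})
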