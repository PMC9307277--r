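test_that("dominance classification bins and orientation", {
  expect_equal(classifyDominance(1, 0)$class, "additive")
  expect_equal(classifyDominance(1, 0)$ratio, 0)
  expect_equal(classifyDominance(1, -1)$class, "recessive")
  expect_equal(classifyDominance(0.4, 0.6)$ratio, 1.5)
  expect_equal(classifyDominance(0.4, 0.6)$class, "overdominant")
  expect_equal(classifyDominance(1, -1.3)$class, "underdominant")
  expect_equal(classifyDominance(1, -0.5)$class, "partially recessive")
  expect_equal(classifyDominance(1, 0.5)$class, "partially dominant")
  expect_equal(classifyDominance(1, 1)$class, "dominant")
  # boundary values fall in the closed bins
  expect_equal(classifyDominance(1, 0.25)$class, "additive")
  expect_equal(classifyDominance(1, 0.75)$class, "dominant")
  expect_equal(classifyDominance(1, 1.25)$class, "dominant")
  expect_equal(classifyDominance(1, -0.75)$class, "recessive")
  # negative a re-oriented: ratio uses |a|, d unchanged
  expect_equal(classifyDominance(-1, 1)$ratio, 1)
  expect_equal(classifyDominance(-1, 1)$class, "dominant")
  # degenerate cases
  expect_equal(classifyDominance(0, 0)$class, "additive")
  expect_warning(z <- classifyDominance(0, 2), "sign of d")
  expect_equal(z$class, "overdominant")
})

test_that("dominance classification is scale invariant", {
  set.seed(81)
  for (i in 1:50) {
    a <- rnorm(1); d <- rnorm(1); c0 <- exp(rnorm(1))
    if (a == 0) next
    expect_identical(classifyDominance(a, d)$class,
                     classifyDominance(c0 * a, c0 * d)$class)
  }
})

test_that("transgressive test: midpoint none, separated low, calibration", {
  set.seed(82)
  n <- 50
  geno <- rep(0:2, each = n)
  # heterozygote midway: none
  yMid <- c(rnorm(n, 0), rnorm(n, 1), rnorm(n, 2))
  expect_equal(transgressiveTest(yMid, geno), "none")
  # heterozygote far below both homozygotes: low
  yLow <- c(rnorm(n, 0), rnorm(n, -5), rnorm(n, 0.5))
  expect_equal(transgressiveTest(yLow, geno), "low")
  yHigh <- c(rnorm(n, 0), rnorm(n, 5), rnorm(n, 0.5))
  expect_equal(transgressiveTest(yHigh, geno), "high")
  # missing genotype class: none with a warning
  expect_warning(res <- transgressiveTest(rnorm(2 * n), rep(c(0, 2), n)),
                 "fewer than")
  expect_equal(res, "none")
  # null calibration: low+high rate bounded near alpha^2 under H0
  hits <- replicate(400, {
    y0 <- rnorm(3 * n)
    transgressiveTest(y0, geno) != "none"
  })
  expect_lte(mean(hits), 0.05^2 + 0.02)
})

test_that("allele origin: AIM lookup and constructed truth", {
  aims <- data.frame(marker_id = c("m1", "m2"),
                     musculus_allele = c("M", "D"),
                     stringsAsFactors = FALSE)
  expect_equal(alleleOrigin("m1", aims, "M"), "musculus")
  expect_equal(alleleOrigin("m1", aims, "D"), "domesticus")
  expect_equal(alleleOrigin("m9", aims, "M"), "uninformative")
  # simulated cohort where the domesticus allele raises the trait: the
  # scan-estimated high allele must always resolve to domesticus
  co <- smallCohort()
  g <- co$genotypes
  f <- co$founders
  loco <- grmLocoAll(g)
  diagIdx <- which(f$diagnostic &
                     apply(genotypeCalls(g), 2, function(x) {
                       tab <- table(factor(x, levels = 0:2))
                       all(tab >= 30)
                     }))[1:3]
  aims2 <- data.frame(marker_id = markerMap(g)$marker_id[diagIdx],
                      musculus_allele = "M", stringsAsFactors = FALSE)
  for (k in seq_along(diagIdx)) {
    j <- diagIdx[k]
    mId <- markerMap(g)$marker_id[j]
    # dosage counts the M allele; a = -2 means M lowers, D raises
    cs <- data.frame(marker_id = mId, taxon = 1, a = -2, d = 0)
    model <- traitModel(nTaxa = 2, causalSnps = cs, sigma2G = 0.05,
                        sigma2M = 0.02, sigma2S = 0.02, sigma2E = 0.2)
    tr <- simulateTraits(g, co$pedigree, co$grm, model, seed = 90 + k)
    sc <- scanTrait(tr$latent[, 1], g, co$pedigree, loco, markers = mId)
    enc <- encodeGenotypes(g, j)
    highAllele <- if (sc$a > 0) enc$majorAllele else enc$minorAllele
    expect_equal(alleleOrigin(mId, aims2, highAllele), "domesticus")
  }
})

test_that("PVE: null marker ~0, recovery, nested modes", {
  co <- smallCohort()
  g <- co$genotypes
  ped <- co$pedigree
  segregating <- which(apply(genotypeCalls(g), 2,
                             function(x) all(0:2 %in% x)))
  j <- segregating[3]
  mId <- markerMap(g)$marker_id[j]
  set.seed(83)
  # null trait: PVE of a random marker is tiny
  y0 <- rnorm(nrow(ped))
  expect_lt(pve(y0, g, mId, ped, co$grm, mode = "all-additive"), 0.02)
  # constructed effect ~25% of variance
  enc <- encodeGenotypes(g, j)
  xa <- rep(0, nrow(ped)); xa[enc$used] <- enc$Xa
  reps <- sapply(1:20, function(i) {
    # effect variance 1/3 against residual variance 1 -> true PVE = 25%
    y <- xa / sd(xa) * sqrt(1 / 3) + rnorm(nrow(ped))
    pve(y, g, mId, ped, co$grm, mode = "peak-additive+dominance")
  })
  expect_lt(abs(mean(reps) - 0.25), 0.07)
  # additive+dominance explains at least as much as additive alone
  y <- xa / sd(xa) + rnorm(nrow(ped))
  ms <- markerMap(g)$marker_id[segregating[3:5]]
  pveAd <- pve(y, g, ms, ped, co$grm, mode = "all-additive+dominance")
  pveA <- pve(y, g, ms, ped, co$grm, mode = "all-additive")
  expect_gte(pveAd, pveA - 0.02)
  expect_true(pveAd >= 0 && pveAd <= 1)
  # collinear marker set (one marker duplicated under a second id):
  # dropped with a warning, no crash
  dupCalls <- genotypeCalls(g)[, c(j, segregating[4], j)]
  gDup <- gmFromCalls(dupCalls)
  dupIds <- markerMap(gDup)$marker_id
  expect_warning(
    pveDup <- pve(y, gDup, dupIds, ped, co$grm, mode = "all-additive"),
    "collinear")
  expect_true(pveDup >= 0 && pveDup <= 1)
})

test_that("estimated d over |a| recovers the simulated architecture class", {
  co <- smallCohort()
  g <- co$genotypes
  loco <- grmLocoAll(g)
  segregating <- which(apply(genotypeCalls(g), 2, function(x) {
    tab <- table(factor(x, levels = 0:2)); all(tab >= 30)
  }))
  cases <- data.frame(a = c(1, 1, 1), d = c(0, 1, -1),
                      class = c("additive", "dominant", "recessive"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    j <- segregating[i]
    mId <- markerMap(g)$marker_id[j]
    cs <- data.frame(marker_id = mId, taxon = 1, a = cases$a[i],
                     d = cases$d[i])
    model <- traitModel(nTaxa = 2, causalSnps = cs, sigma2G = 0.1,
                        sigma2M = 0.02, sigma2S = 0.02, sigma2E = 0.2)
    tr <- simulateTraits(g, co$pedigree, co$grm, model, seed = 84 + i)
    sc <- scanTrait(tr$latent[, 1], g, co$pedigree, loco, markers = mId)
    est <- classifyDominance(sc$a, sc$d)
    expect_equal(est$class, cases$class[i])
  }
})
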