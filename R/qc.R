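## Genotype quality control, LD pruning, ancestry-informative markers and
## hybrid index.

## Minor allele frequency per marker from dosages (of the counted allele);
## returns frequency of the rarer allele.
.maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: conditional on the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability is less than or equal to that of the observed
#' count (standard, not mid-, p).
#'
#' @param nAA,nAB,nBB observed genotype counts.
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n == 0) return(1)
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) return(1)          # monomorphic
  ## heterozygote counts compatible with the allele counts
  hets <- seq(nAB %% 2, min(nA, nB), by = 2)
  ## log P(nAB = h | nA, n) = log[ n! / (nAA! nAB! nBB!) * 2^h ] + const
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (nB - h) / 2
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= pObs + 1e-12]))
}

#' Genotype quality control filter
#'
#' Removes, in fixed order, (1) individuals with call rate below
#' `indCallRate`, then (2) markers that are non-biallelic, missing in more
#' than `snpMissing` of individuals, with minor allele frequency below
#' `maf`, or with Hardy-Weinberg exact p below `hweP`.  Dosage orientation
#' (counted = minor allele) is recomputed after filtering.
#'
#' @param g a [GenotypeMatrix-class].
#' @param indCallRate minimum individual call rate (default 0.90).
#' @param snpMissing maximum per-marker missingness (default 0.10).
#' @param maf minimum minor allele frequency (default 0.05; markers with MAF
#'   strictly below are removed).
#' @param hweP Hardy-Weinberg exact-test threshold (default 1e-10).
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `report` (a `QCReport` list of removal counts and thresholds).
#' @export
qcFilter <- function(g, indCallRate = 0.90, snpMissing = 0.10, maf = 0.05,
                     hweP = 1e-10) {
  stopifnot(indCallRate >= 0, indCallRate <= 1, snpMissing >= 0,
            snpMissing <= 1, maf >= 0, maf <= 1, hweP >= 0, hweP <= 1)
  calls <- genotypeCalls(g)
  n0 <- nrow(calls); p0 <- ncol(calls)
  ## individuals first
  cr <- rowMeans(!is.na(calls))
  keepInd <- cr >= indCallRate
  g1 <- subsetGenotypes(g, individuals = which(keepInd))
  calls <- genotypeCalls(g1)
  ## markers
  nonBiallelic <- g1@alleles$allele1 == g1@alleles$allele2 |
    grepl(",", g1@alleles$allele1) | grepl(",", g1@alleles$allele2)
  miss <- colMeans(is.na(calls))
  mafv <- .maf(calls)
  mafv[is.nan(mafv)] <- 0
  hwe <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]
    hweExactTest(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                 sum(x == 0, na.rm = TRUE))
  }, 0)
  dropMiss <- miss > snpMissing
  dropMaf <- mafv < maf
  dropHwe <- hwe < hweP
  keepMar <- !(nonBiallelic | dropMiss | dropMaf | dropHwe)
  if (!any(keepMar))
    warning("no markers survive QC")
  out <- subsetGenotypes(g1, markers = which(keepMar))
  ## re-orient dosages to count the within-cohort minor allele
  out <- .orientMinor(out)
  report <- structure(list(
    input = c(individuals = n0, markers = p0),
    removed_individuals = sum(!keepInd),
    removed_markers = c(non_biallelic = sum(nonBiallelic),
                        missingness = sum(dropMiss & !nonBiallelic),
                        maf = sum(dropMaf & !dropMiss & !nonBiallelic),
                        hwe = sum(dropHwe & !dropMaf & !dropMiss &
                                    !nonBiallelic)),
    retained = c(individuals = nIndividuals(out), markers = nMarkers(out)),
    thresholds = c(ind_call_rate = indCallRate, snp_missing = snpMissing,
                   maf = maf, hwe_p = hweP)), class = "QCReport")
  list(genotypes = out, report = report)
}

## Flip dosages so the counted allele is the within-cohort minor allele.
.orientMinor <- function(g) {
  calls <- genotypeCalls(g)
  if (ncol(calls) == 0) return(g)
  f <- colMeans(calls, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    cnt <- g@counted
    al <- g@alleles
    other <- ifelse(cnt[flip] == al$allele1[flip], al$allele2[flip],
                    al$allele1[flip])
    cnt[flip] <- other
    g@counted <- cnt
    g@calls <- calls
  }
  g
}

#' Squared LD between two markers
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' individuals.
#'
#' @param g a [GenotypeMatrix-class].
#' @param i,j marker indices or ids.
#' @return r-squared in `[0, 1]`, or `NA` if either marker has zero variance
#'   among the jointly observed individuals.
#' @export
ldR2 <- function(g, i, j) {
  calls <- genotypeCalls(g)
  if (is.character(i)) i <- match(i, markerMap(g)$marker_id)
  if (is.character(j)) j <- match(j, markerMap(g)$marker_id)
  x <- calls[, i]; y <- calls[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` markers (advanced by `step`), while any
#' retained pair has r-squared above `r2Max`, the member of the worst pair
#' with the lower minor allele frequency is dropped (tie: the later
#' position).  The returned marker set has no within-window pair exceeding
#' `r2Max`.
#'
#' @param g a [GenotypeMatrix-class], markers sorted by chromosome and
#'   position.
#' @param window window size in markers (default 5).
#' @param step step size in markers (default 1).
#' @param r2Max r-squared threshold (default 0.9; strictly greater is
#'   pruned).
#' @return character vector of retained marker ids.
#' @export
ldPrune <- function(g, window = 5, step = 1, r2Max = 0.9) {
  calls <- genotypeCalls(g)
  map <- markerMap(g)
  mafv <- .maf(calls)
  keep <- rep(TRUE, ncol(calls))
  for (cc in unique(map$chromosome)) {
    act <- which(map$chromosome == cc)      # windows slide over RETAINED markers
    repeat {                                # passes until a fixed point:
      removedAny <- FALSE                   # removals can shift markers into
      s <- 1                                # windows already visited
      while (s <= length(act)) {
        repeat {
          win <- act[s:min(s + window - 1, length(act))]
          if (length(win) < 2) break
          r2 <- outer(seq_along(win), seq_along(win),
                      Vectorize(function(a, b) {
            if (a >= b) return(0)
            r <- ldR2(g, win[a], win[b])
            if (is.na(r)) 0 else r
          }))
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[worst[1], worst[2]] <= r2Max) break
          pair <- win[c(worst[1], worst[2])]
          m <- mafv[pair]
          drop <- if (m[1] < m[2]) pair[1]
                  else if (m[2] < m[1]) pair[2]
                  else pair[which.max(map$position_bp[pair])]
          keep[drop] <- FALSE
          act <- act[act != drop]
          removedAny <- TRUE
        }
        s <- s + step
      }
      if (!removedAny) break
    }
  }
  map$marker_id[keep]
}

#' Find ancestry-informative markers (AIMs)
#'
#' A marker is ancestry informative if both subspecies reference panels have
#' at least `minCalls` genotype calls, the major allele differs between
#' panels, and the absolute allele-frequency difference exceeds
#' `minFreqDiff`.
#'
#' @param refMusculus,refDomesticus reference-panel
#'   [GenotypeMatrix-class]es sharing the same marker map.
#' @param minCalls minimum calls per subspecies (default 10).
#' @param minFreqDiff minimum allele-frequency difference (default 0.3,
#'   strictly greater qualifies).
#' @return `data.frame` with `marker_id`, `musculus_allele` (the allele label
#'   tagging musculus ancestry), `freq_musculus`, `freq_domesticus`,
#'   `fixed_difference`.
#' @export
findAims <- function(refMusculus, refDomesticus, minCalls = 10,
                     minFreqDiff = 0.3) {
  mapM <- markerMap(refMusculus); mapD <- markerMap(refDomesticus)
  if (!identical(mapM$marker_id, mapD$marker_id))
    stop("reference panels must share the same marker map")
  cm <- genotypeCalls(refMusculus); cd <- genotypeCalls(refDomesticus)
  ## frequencies of the counted allele, aligned to refMusculus orientation
  same <- countedAllele(refMusculus) == countedAllele(refDomesticus)
  nM <- colSums(!is.na(cm)); nD <- colSums(!is.na(cd))
  fM <- colMeans(cm, na.rm = TRUE) / 2
  fD0 <- colMeans(cd, na.rm = TRUE) / 2
  fD <- ifelse(same, fD0, 1 - fD0)
  enough <- nM >= minCalls & nD >= minCalls
  majorDiffers <- (fM > 0.5) != (fD > 0.5)
  bigDiff <- abs(fM - fD) > minFreqDiff
  aim <- enough & majorDiffers & bigDiff & !is.na(fM) & !is.na(fD)
  al <- alleleLabels(refMusculus)
  counted <- countedAllele(refMusculus)
  other <- ifelse(counted == al$allele1, al$allele2, al$allele1)
  musAllele <- ifelse(fM > fD, counted, other)
  data.frame(marker_id = mapM$marker_id[aim],
             musculus_allele = musAllele[aim],
             freq_musculus = unname(fM[aim]),
             freq_domesticus = unname(fD[aim]),
             fixed_difference = unname(abs(fM - fD)[aim] >= 1 - 1e-12),
             stringsAsFactors = FALSE)
}

#' Per-individual hybrid index
#'
#' Fraction of non-missing AIM allele copies that are the musculus allele
#' (the percentage of musculus ancestry).
#'
#' @param g a [GenotypeMatrix-class].
#' @param aims AIM table from [findAims()].
#' @return numeric vector in `[0, 1]` per individual; `NA` (with a warning)
#'   for individuals with no AIM calls.
#' @export
hybridIndex <- function(g, aims) {
  map <- markerMap(g)
  idx <- match(aims$marker_id, map$marker_id)
  ok <- !is.na(idx)
  idx <- idx[ok]
  if (!length(idx)) stop("no AIMs present in the genotype matrix")
  calls <- genotypeCalls(g)[, idx, drop = FALSE]
  ## dosage counts `counted` allele; convert to musculus-allele dosage
  counted <- countedAllele(g)[idx]
  flip <- counted != aims$musculus_allele[ok]
  calls[, flip] <- 2L - calls[, flip]
  nCalls <- rowSums(!is.na(calls))
  hi <- rowSums(calls, na.rm = TRUE) / (2 * nCalls)
  if (any(nCalls == 0)) {
    warning(sum(nCalls == 0), " individual(s) with zero AIM calls")
    hi[nCalls == 0] <- NA_real_
  }
  hi
}
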