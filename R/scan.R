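## Per-SNP additive + dominance mixed-model scan, genomic control, and
## multiple-testing thresholds.

#' Additive/dominance encoding of one marker
#'
#' Genotypes are coded `Xa` in \{1, 0, -1\} for the major-allele homozygote,
#' heterozygote and minor-allele homozygote (A = major allele within the
#' mapping cohort), and `Xd` in \{0, 1\} for homozygotes and heterozygotes.
#' Individuals missing at the marker are excluded.
#'
#' @param g a [GenotypeMatrix-class].
#' @param marker marker id or column index.
#' @return list with `Xa`, `Xd`, `used` (row indices of non-missing
#'   individuals), `majorAllele`, `minorAllele`.
#' @export
encodeGenotypes <- function(g, marker) {
  map <- markerMap(g)
  j <- if (is.character(marker)) match(marker, map$marker_id) else marker
  if (is.na(j)) stop("marker not found: ", marker)
  dos <- genotypeCalls(g)[, j]
  used <- which(!is.na(dos))
  dos <- dos[used]
  if (length(unique(dos)) < 2) stop("marker is monomorphic: ", marker)
  f <- mean(dos) / 2                 # frequency of the counted allele
  counted <- countedAllele(g)[j]
  al <- alleleLabels(g)[j, ]
  other <- if (counted == al$allele1) al$allele2 else al$allele1
  if (f <= 0.5) {                    # counted allele is minor: BB = dosage 2
    xa <- 1 - dos
    major <- other; minor <- counted
  } else {
    xa <- dos - 1
    major <- counted; minor <- other
  }
  list(Xa = as.numeric(xa), Xd = as.numeric(dos == 1), used = used,
       majorAllele = unname(major), minorAllele = unname(minor))
}

## Null-model machinery for the approximate (per-chromosome) scan: fit the
## null LMM once, freeze its covariance, and whiten.  With V fixed, the ML
## log-likelihood difference between nested fixed designs is half the drop
## in the whitened residual sum of squares.
.scanNull <- function(y, pedigree, locoGrm, criterion = "ML") {
  terms <- list(randomTerm("mating_pair", groups = pedigree$mating_pair),
                randomTerm("kinship", kernel = locoGrm))
  fit <- remlFit(y, randomTerms = terms, criterion = criterion)
  s2 <- varianceComponents(fit)
  n <- length(y)
  V <- s2["mating_pair"] * terms[[1]]$K + s2["kinship"] * terms[[2]]$K +
    diag(max(s2["residual"], 1e-10 * var(y)), n)
  L <- chol(V)
  list(fit = fit,
       whiten = function(M) backsolve(L, M, transpose = TRUE))
}

.rssOf <- function(Xw, yw) sum(qr.resid(qr(Xw), yw)^2)

#' Mixed-model association scan of one trait
#'
#' Per marker, fits `y = mu + a Xa + d Xd + u_pair + u_kinship + e` with the
#' leave-one-chromosome-out centred GRM for the marker's chromosome, against
#' the null `y = mu + u_pair + u_kinship + e`.  `p_total` is the 2-df
#' likelihood-ratio test of (a, d); `p_additive` and `p_dominance` are 1-df
#' drop-one tests.  Mode "approximate" estimates the variance components
#' once per chromosome under the null and reuses them for every marker
#' (whitened least squares); mode "exact" refits the variance components by
#' ML for every marker and model.
#'
#' @param y trait vector.
#' @param g a [GenotypeMatrix-class].
#' @param pedigree pedigree `data.frame` with `mating_pair`.
#' @param locoGrms named list of LOCO [GRM-class]es (names = chromosome
#'   labels), as from [grmLocoAll()].
#' @param mode "approximate" (default) or "exact".
#' @param markers optional subset of marker ids to test.
#' @return `data.frame` with one row per tested marker: `marker`, `chrom`,
#'   `pos`, `n`, `a`, `d`, `p_total`, `p_additive`, `p_dominance`.
#' @export
scanTrait <- function(y, g, pedigree, locoGrms,
                      mode = c("approximate", "exact"), markers = NULL) {
  mode <- match.arg(mode)
  map <- markerMap(g)
  if (is.null(markers)) markers <- map$marker_id
  idx <- match(markers, map$marker_id)
  chroms <- unique(map$chromosome[idx])
  out <- vector("list", length(idx))
  pos <- 0
  for (cc in chroms) {
    if (!as.character(cc) %in% names(locoGrms))
      stop("no LOCO GRM for chromosome ", cc)
    onC <- idx[map$chromosome[idx] == cc]
    if (mode == "approximate") {
      nullM <- .scanNull(y, pedigree, locoGrms[[as.character(cc)]])
      n <- length(y)
      yw <- nullM$whiten(matrix(y))
      ones <- nullM$whiten(matrix(1, n, 1))
      rss0 <- .rssOf(ones, yw)
    }
    for (j in onC) {
      dosJ <- genotypeCalls(g)[, j]
      if (length(unique(dosJ[!is.na(dosJ)])) < 2) next  # monomorphic: skip
      enc <- encodeGenotypes(g, j)
      ## dominance is estimable only when all three genotype classes occur
      hasD <- length(unique(enc$Xa[enc$Xd == 0])) == 2 && any(enc$Xd == 1)
      dfT <- if (hasD) 2 else 1
      if (mode == "approximate") {
        ## mean-impute the encoding for excluded individuals so the frozen
        ## whitening stays valid
        xa <- rep(mean(enc$Xa), n); xa[enc$used] <- enc$Xa
        xd <- rep(mean(enc$Xd), n); xd[enc$used] <- enc$Xd
        Xaw <- nullM$whiten(matrix(xa))
        Xdw <- nullM$whiten(matrix(xd))
        full <- if (hasD) cbind(ones, Xaw, Xdw) else cbind(ones, Xaw)
        rssF <- .rssOf(full, yw)
        statT <- max(0, rss0 - rssF)
        statA <- if (hasD)
          max(0, .rssOf(cbind(ones, Xdw), yw) - rssF) else statT
        statD <- if (hasD)
          max(0, .rssOf(cbind(ones, Xaw), yw) - rssF) else NA_real_
        cf <- qr.coef(qr(full), yw)
        aHat <- cf[2]; dHat <- if (hasD) cf[3] else NA_real_
      } else {
        use <- enc$used
        ped <- pedigree[use, , drop = FALSE]
        Ksub <- grmMatrix(locoGrms[[as.character(cc)]])[use, use]
        terms <- list(randomTerm("mating_pair", groups = ped$mating_pair),
                      randomTerm("kinship", kernel = Ksub))
        ys <- y[use]
        Xf <- if (hasD) cbind(`(Intercept)` = 1, Xa = enc$Xa, Xd = enc$Xd)
        else cbind(`(Intercept)` = 1, Xa = enc$Xa)
        fF <- remlFit(ys, Xf, terms, criterion = "ML")
        f0 <- remlFit(ys, Xf[, 1, drop = FALSE], terms, criterion = "ML")
        statT <- max(0, 2 * (mlLogLik(fF) - mlLogLik(f0)))
        if (hasD) {
          fA <- remlFit(ys, Xf[, c(1, 3)], terms, criterion = "ML")
          fD <- remlFit(ys, Xf[, c(1, 2)], terms, criterion = "ML")
          statA <- max(0, 2 * (mlLogLik(fF) - mlLogLik(fA)))
          statD <- max(0, 2 * (mlLogLik(fF) - mlLogLik(fD)))
          dHat <- fixedEffects(fF)["Xd"]
        } else {
          statA <- statT; statD <- NA_real_; dHat <- NA_real_
        }
        aHat <- fixedEffects(fF)["Xa"]
      }
      pos <- pos + 1
      out[[pos]] <- data.frame(
        marker = map$marker_id[j], chrom = map$chromosome[j],
        pos = map$position_bp[j], n = length(enc$used),
        a = unname(aHat), d = unname(dHat),
        p_total = pchisq(statT, dfT, lower.tail = FALSE),
        p_additive = pchisq(statA, 1, lower.tail = FALSE),
        p_dominance = pchisq(statD, 1, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(pos)])
}

#' Genomic control
#'
#' Converts p-values to 1-df chi-square statistics, computes the inflation
#' factor `lambda = median(chi2) / 0.4549...` and, when `lambda` exceeds
#' 1.05, divides the statistics by `lambda` and converts back to p-values;
#' otherwise the p-values are returned unchanged.
#'
#' @param p vector of p-values in (0, 1].
#' @param trigger inflation threshold above which control is applied
#'   (default 1.05).
#' @return list with `lambda` and `adjusted` (p-value vector).
#' @export
genomicControl <- function(p, trigger = 1.05) {
  if (!length(p)) stop("empty p-value vector")
  chi2 <- qchisq(p, 1, lower.tail = FALSE)
  lambda <- median(chi2) / qchisq(0.5, 1)
  adjusted <- if (lambda > trigger)
    pchisq(chi2 / lambda, 1, lower.tail = FALSE)
  else p
  list(lambda = lambda, adjusted = adjusted)
}

#' Effective number of independent traits
#'
#' From the eigenvalues of the trait correlation matrix (pairwise-complete
#' observations): `Meff = 1 + (M - 1) (1 - Var(lambda) / M)` with the sample
#' variance (denominator M - 1), clipped to `[1, M]`.  Constant trait
#' columns are excluded with a warning.
#'
#' @param traits samples x traits numeric matrix.
#' @return `Meff`, a real in `[1, M]`.
#' @export
effectiveTests <- function(traits) {
  traits <- as.matrix(traits)
  if (ncol(traits) < 2) stop("need at least 2 traits")
  sds <- apply(traits, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("excluding ", sum(sds == 0 | is.na(sds)), " constant trait(s)")
    traits <- traits[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  M <- ncol(traits)
  cc <- suppressWarnings(cor(traits, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0; diag(cc) <- 1
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  meff <- 1 + (M - 1) * (1 - var(ev) / M)
  min(max(meff, 1), M)
}

#' Genome-wide and study-wide significance thresholds
#'
#' Genome-wide: Bonferroni across markers, `alpha / n_markers`.  Study-wide:
#' the genome-wide threshold divided by the effective number of traits.
#'
#' @param nMarkers number of markers scanned.
#' @param meff effective number of traits (default 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return named vector with `genome_wide` and `study_wide`.
#' @export
significanceThresholds <- function(nMarkers, meff = 1, alpha = 0.05) {
  stopifnot(nMarkers >= 1, meff >= 1)
  gw <- alpha / nMarkers
  c(genome_wide = gw, study_wide = gw / meff)
}

#' Scan several traits and flag significant associations
#'
#' Runs [scanTrait()] per trait, applies per-trait genomic control to the
#' 2-df total p-values, computes the effective number of traits and both
#' thresholds, and flags genome-wide / study-wide significant records.
#'
#' @param traits samples x traits matrix.
#' @param g a [GenotypeMatrix-class].
#' @param pedigree pedigree `data.frame`.
#' @param locoGrms list of LOCO GRMs from [grmLocoAll()].
#' @param mode scan mode, "approximate" or "exact".
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `records` (one `data.frame`, all traits, with
#'   `p_adjusted` and significance flags), `lambda` (per trait), `meff`,
#'   `thresholds`.
#' @export
runScan <- function(traits, g, pedigree, locoGrms, mode = "approximate",
                    alpha = 0.05) {
  meff <- if (ncol(traits) > 1) effectiveTests(traits) else 1
  thr <- significanceThresholds(nMarkers(g), meff, alpha)
  lambdas <- numeric(ncol(traits))
  recs <- vector("list", ncol(traits))
  for (j in seq_len(ncol(traits))) {
    r <- scanTrait(traits[, j], g, pedigree, locoGrms, mode)
    gc <- genomicControl(r$p_total)
    lambdas[j] <- gc$lambda
    r$p_adjusted <- gc$adjusted
    r$trait <- colnames(traits)[j]
    r$genome_wide <- r$p_adjusted < thr["genome_wide"]
    r$study_wide <- r$p_adjusted < thr["study_wide"]
    recs[[j]] <- r
  }
  names(lambdas) <- colnames(traits)
  list(records = do.call(rbind, recs), lambda = lambdas, meff = meff,
       thresholds = thr)
}
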