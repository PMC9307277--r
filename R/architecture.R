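## Dominance classification on the d/|a| scale, transgressive-heterozygote
## detection, allele-origin assignment and percent variance explained.

#' Classify dominance from additive and dominance effects
#'
#' The ratio is `d / |a|`, oriented so that +1 means complete dominance of
#' the allele associated with higher abundance: effects are re-signed so the
#' higher-abundance homozygote defines +a (re-labelling the alleles flips
#' the sign of `a` but leaves `d` unchanged).  Classes: underdominant
#' (< -1.25), recessive ([-1.25, -0.75]), partially recessive
#' ((-0.75, -0.25)), additive ([-0.25, 0.25]), partially dominant
#' ((0.25, 0.75)), dominant ([0.75, 1.25]), overdominant (> 1.25).
#'
#' @param a additive effect (half the distance between homozygote means).
#' @param d dominance deviation (heterozygote mean minus homozygote
#'   midpoint).
#' @return list with `ratio` (d / |a|) and `class`.
#' @export
classifyDominance <- function(a, d) {
  if (a == 0 && d == 0) return(list(ratio = 0, class = "additive"))
  if (a == 0) {
    warning("a = 0: ratio undefined, class from the sign of d")
    return(list(ratio = sign(d) * Inf,
                class = if (d > 0) "overdominant" else "underdominant"))
  }
  ratio <- d / abs(a)
  cls <- if (ratio < -1.25) "underdominant"
  else if (ratio <= -0.75) "recessive"
  else if (ratio < -0.25) "partially recessive"
  else if (ratio <= 0.25) "additive"
  else if (ratio < 0.75) "partially dominant"
  else if (ratio <= 1.25) "dominant"
  else "overdominant"
  list(ratio = ratio, class = cls)
}

#' Transgressive-heterozygote test at one marker
#'
#' Welch two-sample tests of the heterozygote mean against each homozygote
#' mean: "low" when both tests reject at `alpha` and the heterozygote mean
#' lies below both homozygote means; "high" symmetrically; otherwise "none".
#'
#' @param y trait vector.
#' @param genotypes dosage vector (0/1/2) aligned with `y`.
#' @param alpha per-test significance level (default 0.05).
#' @param minPerClass minimum individuals per genotype class (default 3).
#' @return "low", "high" or "none".
#' @export
transgressiveTest <- function(y, genotypes, alpha = 0.05, minPerClass = 3) {
  ok <- !is.na(y) & !is.na(genotypes)
  y <- y[ok]; genotypes <- genotypes[ok]
  groups <- split(y, factor(genotypes, levels = c(0, 1, 2)))
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < minPerClass)) {
    warning("genotype class with fewer than ", minPerClass, " individuals")
    return("none")
  }
  het <- groups[["1"]]; hom0 <- groups[["0"]]; hom2 <- groups[["2"]]
  p0 <- t.test(het, hom0)$p.value
  p2 <- t.test(het, hom2)$p.value
  mh <- mean(het)
  if (p0 < alpha && p2 < alpha) {
    if (mh < mean(hom0) && mh < mean(hom2)) return("low")
    if (mh > mean(hom0) && mh > mean(hom2)) return("high")
  }
  "none"
}

#' Subspecies origin of the high-abundance allele
#'
#' For an ancestry-informative marker, reports whether the allele associated
#' with higher abundance is the musculus or the domesticus allele; for any
#' other marker the origin is "uninformative".
#'
#' @param marker marker id.
#' @param aims AIM table from [findAims()].
#' @param highAllele allele label associated with higher abundance (e.g. the
#'   major allele when the additive estimate is positive).
#' @return "musculus", "domesticus" or "uninformative".
#' @export
alleleOrigin <- function(marker, aims, highAllele) {
  i <- match(marker, aims$marker_id)
  if (is.na(i)) return("uninformative")
  if (identical(highAllele, aims$musculus_allele[i])) "musculus"
  else "domesticus"
}

#' Percent variance explained by significant markers
#'
#' Fits the mixed model with the requested marker fixed effects (plus
#' intercept; random effects: mating pair and kinship) and returns the
#' marginal R-squared: the variance of the fixed-effect predictions over
#' the sum of that variance, the random-component variances and the
#' residual variance.
#'
#' @param y trait vector.
#' @param g a [GenotypeMatrix-class].
#' @param markers marker ids (already significant for this trait).
#' @param pedigree pedigree `data.frame` with `mating_pair`.
#' @param grm kinship [GRM-class] (full-genome centred GRM).
#' @param mode "peak-additive+dominance" (additive + dominance of the given
#'   markers), "all-additive" (additive terms only) or
#'   "all-additive+dominance".
#' @return PVE, a real in `[0, 1]`.
#' @export
pve <- function(y, g, markers, pedigree, grm,
                mode = c("peak-additive+dominance", "all-additive",
                         "all-additive+dominance")) {
  mode <- match.arg(mode)
  map <- markerMap(g)
  ord <- order(map$chromosome[match(markers, map$marker_id)],
               map$position_bp[match(markers, map$marker_id)])
  markers <- markers[ord]
  cols <- list(`(Intercept)` = rep(1, length(y)))
  for (m in markers) {
    enc <- encodeGenotypes(g, m)
    xa <- rep(mean(enc$Xa), length(y)); xa[enc$used] <- enc$Xa
    xd <- rep(mean(enc$Xd), length(y)); xd[enc$used] <- enc$Xd
    cols[[paste0(m, "_a")]] <- xa
    if (mode != "all-additive") cols[[paste0(m, "_d")]] <- xd
  }
  X <- do.call(cbind, cols)
  ## drop collinear columns deterministically (markers are position-ordered)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear marker column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  terms <- list(randomTerm("mating_pair", groups = pedigree$mating_pair),
                randomTerm("kinship", kernel = grm))
  fit <- remlFit(y, X, terms)
  pred <- drop(X %*% fixedEffects(fit))
  vf <- var(pred)
  vf / (vf + sum(varianceComponents(fit)))
}
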