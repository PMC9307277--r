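# Shared in-code fixtures.  A small cohort (4 chromosomes, 320 G2s) is
# built once per test run; tests needing other shapes build their own.

smallMap <- function(nMarkers = 40, nChrom = 2)
  defaultMarkerMap(nMarkers, nChrom)

# genotype matrix straight from a dosage matrix with an evenly spaced map
gmFromCalls <- function(calls, nChrom = 1) {
  map <- defaultMarkerMap(ncol(calls), nChrom)
  GenotypeMatrix(calls, map)
}

cohortCache <- new.env()

# standard simulated cohort: 400 markers / 4 chromosomes, 8 x 40 G2s
smallCohort <- function() {
  if (is.null(cohortCache$c)) {
    mm <- defaultMarkerMap(400, 4)
    f <- simulateFounders(mm, seed = 11)
    cr <- simulateCross(f, makeCrossDesign(f, 40), seed = 12)
    cohortCache$c <- c(cr, list(founders = f, grm = grmCentred(cr$genotypes)))
  }
  cohortCache$c
}

# independent dense REML evaluator used as an oracle against the package's
# fit: direct log-det + quadratic-form formula, no shared code path
denseRemlLogLik <- function(sigma2, y, X, Ks) {
  n <- length(y); p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Ks)) V <- V + sigma2[k] * Ks[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}
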