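## Narrow-sense and chip heritability per trait, with significance by
## simulation-based restricted likelihood ratio tests, and the
## cospeciation-rate comparison.

.h2Terms <- function(grm, pedigree) {
  if (any(is.na(pedigree$mating_pair)) || any(is.na(pedigree$subcross)))
    stop("missing pedigree labels for sample(s): ",
         paste(pedigree$individual[is.na(pedigree$mating_pair) |
                                     is.na(pedigree$subcross)],
               collapse = ", "))
  list(randomTerm("genetic", kernel = grm),
       randomTerm("mating_pair",
                  groups = interaction(pedigree$subcross,
                                       pedigree$mating_pair, drop = TRUE)),
       randomTerm("subcross", groups = pedigree$subcross))
}

.h2FromFit <- function(fit) {
  s2 <- varianceComponents(fit)
  tot <- sum(s2)
  if (tot <= 0) return(0)
  unname(s2["genetic"] / tot)
}

#' Narrow-sense heritability of one trait
#'
#' Fits a linear mixed model with random effects: centred-GRM kernel,
#' mating pair nested within sub-cross, sub-cross, and residual.  The
#' narrow-sense heritability is `sigma2_g / (sigma2_g + sigma2_m + sigma2_s
#' + sigma2_e)`.  Significance of the genetic component is assessed with a
#' simulation-based restricted likelihood ratio test ([rlrtTest()]); a
#' genetic component pinned at zero is reported as h2 = 0 with p = 1.
#'
#' @param y trait vector (one column of the trait matrix).
#' @param grm a centred [GRM-class].
#' @param pedigree pedigree `data.frame` with `individual`, `mating_pair`,
#'   `subcross`.
#' @param nSim RLRT bootstrap samples (0 skips the test, p = NA).
#' @param seed seed for the RLRT bootstrap.
#' @return A `HeritabilityRecord` list: `h2`, `p`, `components`, `fit`.
#' @export
estimateH2 <- function(y, grm, pedigree, nSim = 0, seed = 1) {
  terms <- .h2Terms(grm, pedigree)
  fit <- remlFit(y, randomTerms = terms)
  h2 <- .h2FromFit(fit)
  p <- NA_real_
  if (varianceComponents(fit)["genetic"] <= 0) {
    h2 <- 0
    if (nSim > 0) p <- 1
  } else if (nSim > 0) {
    rl <- rlrtTest(y, testedTerm = terms[[1]], nuisanceTerms = terms[-1],
                   nSim = nSim, seed = seed)
    p <- rl$p
  }
  structure(list(h2 = h2, p = p,
                 components = varianceComponents(fit), fit = fit),
            class = "HeritabilityRecord")
}

#' Chip heritability of one trait
#'
#' As [estimateH2()] but with the standardised GRM kernel; the chip
#' heritability is the fraction of phenotypic variance explained by
#' genotyped SNPs.
#'
#' @inheritParams estimateH2
#' @param grm a standardised [GRM-class].
#' @return A `HeritabilityRecord` list with `h2` holding the chip estimate.
#' @export
estimateChipH2 <- function(y, grm, pedigree, nSim = 0, seed = 1) {
  estimateH2(y, grm, pedigree, nSim = nSim, seed = seed)
}

#' Heritability of every trait in a matrix
#'
#' @param traits samples x traits matrix (as from [transformTraits()]).
#' @param grmCentred,grmStandardised centred and standardised
#'   [GRM-class]es; either may be NULL to skip that estimate.
#' @param pedigree pedigree `data.frame`.
#' @param nSim RLRT bootstrap samples per trait (0 skips the tests).
#' @param seed base seed.
#' @return `data.frame` with one row per trait: `trait`, `h2`, `p_h2`,
#'   `chip_h2`, `p_chip` and the narrow-sense variance components.
#' @export
heritabilityTable <- function(traits, grmCentred, grmStandardised = NULL,
                              pedigree, nSim = 0, seed = 1) {
  out <- lapply(seq_len(ncol(traits)), function(j) {
    y <- traits[, j]
    hr <- estimateH2(y, grmCentred, pedigree, nSim = nSim, seed = seed + j)
    ch <- if (!is.null(grmStandardised))
      estimateChipH2(y, grmStandardised, pedigree, nSim = nSim,
                     seed = seed + j)
    else list(h2 = NA_real_, p = NA_real_)
    data.frame(trait = colnames(traits)[j], h2 = hr$h2, p_h2 = hr$p,
               chip_h2 = ch$h2, p_chip = ch$p,
               sigma2_g = hr$components["genetic"],
               sigma2_m = hr$components["mating_pair"],
               sigma2_s = hr$components["subcross"],
               sigma2_e = hr$components["residual"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Heritability versus cospeciation rate
#'
#' Spearman correlation between per-genus heritability estimates and
#' externally supplied cospeciation rates (shared genera matched on exact
#' genus strings), plus an ordinary least-squares regression of h2 on
#' cospeciation rate and median relative abundance with per-coefficient
#' t-tests and the overall F-test.
#'
#' @param h2Table `data.frame` with columns `genus` and `h2`.
#' @param cospec `data.frame` with columns `genus` and `rate`.
#' @param abundance `data.frame` with columns `genus` and
#'   `median_abundance`; optional (regression skipped when absent).
#' @param minShared minimum shared genera required (default 5).
#' @return list with `rho`, `p_spearman`, `n_shared`, and (when abundance is
#'   given) `regression` (coefficient table) and `f_test`.
#' @export
cospeciationAnalysis <- function(h2Table, cospec, abundance = NULL,
                                 minShared = 5) {
  shared <- intersect(h2Table$genus, cospec$genus)
  if (length(shared) == 0) stop("no shared genera between tables")
  if (length(shared) < minShared)
    stop("fewer than ", minShared, " shared genera")
  h2 <- h2Table$h2[match(shared, h2Table$genus)]
  rate <- cospec$rate[match(shared, cospec$genus)]
  ct <- suppressWarnings(cor.test(h2, rate, method = "spearman"))
  out <- list(rho = unname(ct$estimate), p_spearman = ct$p.value,
              n_shared = length(shared))
  if (!is.null(abundance)) {
    ab <- abundance$median_abundance[match(shared, abundance$genus)]
    fit <- lm(h2 ~ rate + ab)
    sm <- summary(fit)
    out$regression <- sm$coefficients
    out$f_test <- c(F = unname(sm$fstatistic[1]),
                    df1 = unname(sm$fstatistic[2]),
                    df2 = unname(sm$fstatistic[3]),
                    p = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                                  sm$fstatistic[3], lower.tail = FALSE)),
                    r_squared = sm$r.squared)
  }
  out
}

#' @importFrom stats pf
NULL
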