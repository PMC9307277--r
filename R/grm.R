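## Genomic relatedness matrices: centred, standardised, leave-one-
## chromosome-out.  Missing dosages are mean-imputed per marker before
## centring.

.imputedDosage <- function(g) {
  x <- genotypeCalls(g)
  storage.mode(x) <- "double"
  mns <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mns[idx[, 2]]
  x
}

.grmCore <- function(g, flavour, excluded = NA_character_) {
  x <- .imputedDosage(g)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  v <- colMeans(xc^2)                      # biased (1/n) sample variance
  poly <- v > 0
  if (!any(poly)) stop("all markers are monomorphic")
  if (flavour == "standardised") {
    if (any(!poly))
      warning(sum(!poly), " zero-variance marker(s) excluded from the sum")
    xc <- sweep(xc[, poly, drop = FALSE], 2, sqrt(v[poly]), "/")
  }
  p <- if (flavour == "standardised") sum(poly) else ncol(xc)
  K <- tcrossprod(xc) / p
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(genotypeCalls(g)), rownames(genotypeCalls(g)))
  new("GRM", matrix = K, flavour = flavour, excludedChromosome = excluded,
      nMarkersUsed = as.integer(p))
}

#' Centred genomic relatedness matrix
#'
#' `K = (1/p) sum_i (x_i - xbar_i 1)(x_i - xbar_i 1)^T` over marker dosage
#' columns, after per-marker mean imputation of missing dosages.
#'
#' @param g a [GenotypeMatrix-class] with at least one polymorphic marker.
#' @return A [GRM-class] of flavour "centred".
#' @export
grmCentred <- function(g) .grmCore(g, "centred")

#' Standardised genomic relatedness matrix
#'
#' As [grmCentred()] but each marker term is divided by its biased (1/n)
#' sample variance; zero-variance markers are excluded from the sum and `p`
#' adjusted, so that the trace equals n exactly.
#'
#' @param g a [GenotypeMatrix-class].
#' @return A [GRM-class] of flavour "standardised".
#' @export
grmStandardised <- function(g) .grmCore(g, "standardised")

#' Leave-one-chromosome-out GRM
#'
#' The GRM computed from all markers not on the excluded chromosome; used
#' when scanning that chromosome to avoid proximal contamination.
#'
#' @param g a [GenotypeMatrix-class].
#' @param chromosome chromosome label to exclude.
#' @param flavour "centred" (default) or "standardised".
#' @return A [GRM-class] with `excludedChromosome` recorded.
#' @export
grmLoco <- function(g, chromosome, flavour = c("centred", "standardised")) {
  flavour <- match.arg(flavour)
  keep <- which(markerMap(g)$chromosome != chromosome)
  if (!length(keep))
    stop("no markers remain after excluding chromosome ", chromosome)
  .grmCore(subsetGenotypes(g, markers = keep), flavour,
           excluded = as.character(chromosome))
}

#' All leave-one-chromosome-out GRMs
#'
#' @param g a [GenotypeMatrix-class].
#' @param flavour GRM flavour (default "centred").
#' @return named list of [GRM-class] objects, one per chromosome present.
#' @export
grmLocoAll <- function(g, flavour = "centred") {
  chroms <- unique(markerMap(g)$chromosome)
  out <- lapply(chroms, function(cc) grmLoco(g, cc, flavour))
  names(out) <- as.character(chroms)
  out
}
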