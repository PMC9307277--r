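#' @import methods
#' @importFrom stats as.dist cor cor.test chisq.test dist ecdf fisher.test lm
#'   median optimize pchisq pnorm pt qchisq quantile rbinom rmultinom rnorm
#'   rpois runif sd setNames t.test var optim rbeta
#' @importFrom utils head read.table write.table tail
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix: individuals x markers dosage matrix plus marker map
## ---------------------------------------------------------------------------

#' GenotypeMatrix: biallelic genotype calls with a marker map
#'
#' Rows are individuals, columns are markers.  Calls count copies of the
#' `counted` allele at each marker (0, 1, 2 or `NA` for missing).  The marker
#' map carries chromosome, physical position (bp, 1-based) and genetic
#' position (cM) for every marker, ordered by chromosome then position.
#'
#' @slot calls integer matrix, individuals x markers, values in \{0, 1, 2, NA\}.
#' @slot map `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp`, `genetic_pos_cM`; one row per column of `calls`.
#' @slot alleles `data.frame` with columns `allele1`, `allele2` giving the
#'   two allele labels per marker.
#' @slot counted character vector, per marker, the allele whose copies the
#'   dosage counts (orientation record; after QC this is the cohort minor
#'   allele).
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", map = "data.frame",
                 alleles = "data.frame", counted = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  v <- object@calls
  if (!all(is.na(v) | v %in% c(0L, 1L, 2L)))
    msg <- c(msg, "calls must be 0, 1, 2 or NA")
  if (ncol(v) != nrow(object@map))
    msg <- c(msg, "marker map rows must match call columns")
  need <- c("marker_id", "chromosome", "position_bp", "genetic_pos_cM")
  if (!all(need %in% names(object@map)))
    msg <- c(msg, paste("map needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@map$marker_id))
      msg <- c(msg, "duplicate marker ids")
    sp <- split(object@map$position_bp, object@map$chromosome)
    if (!all(vapply(sp, function(p) all(diff(p) > 0), TRUE)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    sg <- split(object@map$genetic_pos_cM, object@map$chromosome)
    if (!all(vapply(sg, function(p) all(diff(p) >= 0), TRUE)))
      msg <- c(msg, "genetic positions must be non-decreasing within chromosome")
  }
  if (length(object@counted) && length(object@counted) != ncol(v))
    msg <- c(msg, "counted allele vector must have one entry per marker")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls individuals x markers matrix of dosages (0/1/2/NA).
#' @param map marker map `data.frame` (`marker_id`, `chromosome`,
#'   `position_bp`, `genetic_pos_cM`).
#' @param alleles optional `data.frame` with `allele1`, `allele2` labels;
#'   defaults to "A"/"B".
#' @param counted optional per-marker label of the counted allele; defaults
#'   to `allele2`.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, map, alleles = NULL, counted = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls))) colnames(calls) <- map$marker_id
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ind%04d", seq_len(nrow(calls)))
  map$marker_id <- as.character(map$marker_id)
  if (is.null(alleles))
    alleles <- data.frame(allele1 = rep("A", nrow(map)),
                          allele2 = rep("B", nrow(map)),
                          stringsAsFactors = FALSE)
  if (is.null(counted)) counted <- alleles$allele2
  new("GenotypeMatrix", calls = calls, map = map, alleles = alleles,
      counted = as.character(counted))
}

#' @describeIn GenotypeMatrix-class number of individuals
#' @param x,object a `GenotypeMatrix`
#' @export
nIndividuals <- function(x) nrow(x@calls)

#' @describeIn GenotypeMatrix-class number of markers
#' @export
nMarkers <- function(x) ncol(x@calls)

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn GenotypeMatrix-class marker map accessor
#' @export
markerMap <- function(x) x@map

#' @describeIn GenotypeMatrix-class counted-allele orientation accessor
#' @export
countedAllele <- function(x) x@counted

#' @describeIn GenotypeMatrix-class allele label accessor
#' @export
alleleLabels <- function(x) x@alleles

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "markers on",
      length(unique(object@map$chromosome)), "chromosome(s)\n")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
})

## Subset individuals/markers keeping the map in step (internal).
subsetGenotypes <- function(g, individuals = NULL, markers = NULL) {
  calls <- g@calls; map <- g@map; al <- g@alleles; cnt <- g@counted
  if (!is.null(individuals)) calls <- calls[individuals, , drop = FALSE]
  if (!is.null(markers)) {
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    al <- al[markers, , drop = FALSE]
    cnt <- cnt[markers]
  }
  rownames(map) <- NULL
  new("GenotypeMatrix", calls = calls, map = map, alleles = al, counted = cnt)
}

## ---------------------------------------------------------------------------
## GRM
## ---------------------------------------------------------------------------

#' GRM: genomic relatedness matrix
#'
#' An n x n symmetric relatedness matrix with its flavour ("centred" or
#' "standardised"), the number of markers used, and, for leave-one-
#' chromosome-out matrices, the excluded chromosome.
#'
#' @slot matrix n x n symmetric numeric matrix.
#' @slot flavour "centred" or "standardised".
#' @slot excludedChromosome character, `NA` unless LOCO.
#' @slot nMarkersUsed integer, markers entering the sum.
#' @export
setClass("GRM",
  representation(matrix = "matrix", flavour = "character",
                 excludedChromosome = "character", nMarkersUsed = "integer"))

setValidity("GRM", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, "matrix must be symmetric")
  if (!object@flavour %in% c("centred", "standardised"))
    msg <- c(msg, "flavour must be 'centred' or 'standardised'")
  if (length(msg)) msg else TRUE
})

#' @describeIn GRM-class the relatedness matrix itself
#' @param x,object a `GRM`
#' @export
grmMatrix <- function(x) x@matrix

#' @describeIn GRM-class GRM flavour accessor
#' @export
grmFlavour <- function(x) x@flavour

#' @describeIn GRM-class excluded chromosome (NA unless LOCO)
#' @export
excludedChromosome <- function(x) x@excludedChromosome

setMethod("show", "GRM", function(object) {
  cat("GRM (", object@flavour, "): ", nrow(object@matrix), " x ",
      ncol(object@matrix), ", ", object@nMarkersUsed, " markers",
      sep = "")
  if (!is.na(object@excludedChromosome))
    cat(", excluding chromosome", object@excludedChromosome)
  cat("\n")
})

## ---------------------------------------------------------------------------
## AbundanceTable
## ---------------------------------------------------------------------------

#' AbundanceTable: taxon-by-sample count table
#'
#' Non-negative integer counts for taxa (rows) by samples (columns), with
#' per-taxon metadata (taxonomic rank, lineage) and the profiling level the
#' table came from (DNA = 16S gene copies, RNA = 16S transcripts).
#'
#' @slot counts taxa x samples integer matrix, non-negative.
#' @slot taxonData `data.frame` with at least `rank` (one of ASV, genus,
#'   family, order, class, phylum) and `lineage`.
#' @slot level "DNA" or "RNA".
#' @export
setClass("AbundanceTable",
  representation(counts = "matrix", taxonData = "data.frame",
                 level = "character"))

abundanceRanks <- c("ASV", "genus", "family", "order", "class", "phylum")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  cnt <- object@counts
  if (any(cnt < 0, na.rm = TRUE) || any(cnt != round(cnt), na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative integers")
  if (nrow(cnt) != nrow(object@taxonData))
    msg <- c(msg, "taxonData rows must match count rows")
  if (!all(object@taxonData$rank %in% abundanceRanks))
    msg <- c(msg, paste("taxon rank must be one of:",
                        paste(abundanceRanks, collapse = ", ")))
  if (!object@level %in% c("DNA", "RNA"))
    msg <- c(msg, "level must be 'DNA' or 'RNA'")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts taxa x samples matrix of non-negative integer counts.
#' @param taxonData optional `data.frame` with `rank` and `lineage`;
#'   defaults to rank "genus".
#' @param level profiling level, "DNA" or "RNA".
#' @return An [AbundanceTable-class] object.
#' @export
AbundanceTable <- function(counts, taxonData = NULL, level = "DNA") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%04d", seq_len(ncol(counts)))
  if (is.null(taxonData))
    taxonData <- data.frame(rank = rep("genus", nrow(counts)),
                            lineage = rownames(counts),
                            stringsAsFactors = FALSE)
  new("AbundanceTable", counts = counts, taxonData = taxonData, level = level)
}

#' @describeIn AbundanceTable-class count matrix accessor
#' @param x,object an `AbundanceTable`
#' @export
abundanceCounts <- function(x) x@counts

#' @describeIn AbundanceTable-class taxon metadata accessor
#' @export
taxonData <- function(x) x@taxonData

#' @describeIn AbundanceTable-class profiling level accessor
#' @export
abundanceLevel <- function(x) x@level

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable (", object@level, "): ", nrow(object@counts),
      " taxa x ", ncol(object@counts), " samples\n", sep = "")
  cat("  ranks:", paste(names(table(object@taxonData$rank)), collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## LMMFit
## ---------------------------------------------------------------------------

#' LMMFit: fitted linear mixed model
#'
#' Variance components (one per random term plus "residual"), generalised
#' least squares fixed effects with standard errors, and the restricted and
#' ordinary log-likelihoods at the optimum.
#'
#' @slot sigma2 named numeric vector of variance components; last element is
#'   "residual".
#' @slot beta named numeric vector of fixed-effect estimates.
#' @slot betaSE standard errors for `beta`.
#' @slot remlLogLik restricted log-likelihood at the reported components.
#' @slot mlLogLik ordinary (ML) log-likelihood at the reported components.
#' @slot criterion "REML" or "ML" (which criterion was maximised).
#' @slot converged logical convergence flag.
#' @slot iterations optimiser iteration count.
#' @slot boundary logical vector: component pinned at (numerically) zero.
#' @export
setClass("LMMFit",
  representation(sigma2 = "numeric", beta = "numeric", betaSE = "numeric",
                 remlLogLik = "numeric", mlLogLik = "numeric",
                 criterion = "character", converged = "logical",
                 iterations = "integer", boundary = "logical"))

setValidity("LMMFit", function(object) {
  msg <- character()
  if (any(object@sigma2 < 0)) msg <- c(msg, "variance components must be >= 0")
  if (!is.finite(object@remlLogLik))
    msg <- c(msg, "restricted log-likelihood must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn LMMFit-class variance component accessor
#' @param x,object an `LMMFit`
#' @export
varianceComponents <- function(x) x@sigma2

#' @describeIn LMMFit-class fixed effect accessor
#' @export
fixedEffects <- function(x) x@beta

#' @describeIn LMMFit-class restricted log-likelihood accessor
#' @export
remlLogLik <- function(x) x@remlLogLik

#' @describeIn LMMFit-class ordinary (ML) log-likelihood accessor
#' @export
mlLogLik <- function(x) x@mlLogLik

setMethod("show", "LMMFit", function(object) {
  cat("LMMFit (", object@criterion, "):",
      if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "evaluations\n")
  cat("  restricted logLik:", format(object@remlLogLik), "\n")
  comps <- format(signif(object@sigma2, 4))
  cat("  components:", paste(names(object@sigma2), comps, sep = "=",
                             collapse = ", "), "\n")
  cat("  fixed:", paste(names(object@beta), format(signif(object@beta, 4)),
                        sep = "=", collapse = ", "), "\n")
})
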