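## Significant-region construction from LD, region merging, gene
## assignment, and permutation-based overlap / gene-set enrichment tests.
## Coordinates are 1-based inclusive throughout; BED input is converted
## from 0-based half-open at the boundary.

#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Expand a significant SNP to its LD region
#'
#' The interval spans from the most distant upstream to the most distant
#' downstream marker on the same chromosome with r-squared above `r2Min` to
#' the index SNP, in the full (pre-LD-filtered) genotype set.  A marker with
#' no LD partners yields a 1-bp interval at its own position.
#'
#' @param sigMarker index marker id.
#' @param fullGenotypes full pre-pruning [GenotypeMatrix-class].
#' @param r2Min r-squared threshold (default 0.9, strictly greater
#'   qualifies).
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `marker`.
#' @export
expandRegion <- function(sigMarker, fullGenotypes, r2Min = 0.9) {
  map <- markerMap(fullGenotypes)
  j <- match(sigMarker, map$marker_id)
  if (is.na(j)) stop("marker not in full genotype set: ", sigMarker)
  onC <- which(map$chromosome == map$chromosome[j])
  r2 <- vapply(onC, function(k)
    if (k == j) 1 else {
      r <- ldR2(fullGenotypes, j, k)
      if (is.na(r)) 0 else r
    }, 0)
  partners <- onC[r2 > r2Min]
  if (!length(partners)) partners <- j
  data.frame(chrom = map$chromosome[j],
             start_bp = min(map$position_bp[partners]),
             end_bp = max(map$position_bp[partners]),
             marker = sigMarker, stringsAsFactors = FALSE)
}

#' Merge significant intervals into regions
#'
#' Same-chromosome intervals whose gap (bases strictly between them) is
#' less than `maxGapBp` are merged transitively; member markers and taxa
#' are unioned.
#'
#' @param intervals `data.frame` with `chrom`, `start_bp`, `end_bp` and
#'   optionally `marker` and `taxon` columns.
#' @param maxGapBp merge distance in bp (default 10 Mb; a gap of exactly
#'   `maxGapBp` is not merged).
#' @return `data.frame` of regions: `chrom`, `start_bp`, `end_bp`,
#'   `n_members`, `markers`, `taxa` (comma-separated).
#' @export
mergeRegions <- function(intervals, maxGapBp = 1e7) {
  if (nrow(intervals) == 0)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_members = integer(),
                      markers = character(), taxa = character()))
  gr <- GRanges(as.character(intervals$chrom),
                IRanges(intervals$start_bp, intervals$end_bp))
  red <- reduce(gr, min.gapwidth = maxGapBp, with.revmap = TRUE)
  rev <- mcols(red)$revmap
  getCol <- function(col, i) {
    if (!col %in% names(intervals)) return("")
    paste(sort(unique(intervals[[col]][rev[[i]]])), collapse = ",")
  }
  data.frame(chrom = as.character(seqnames(red)),
             start_bp = start(red), end_bp = end(red),
             n_members = lengths(rev),
             markers = vapply(seq_along(red), function(i)
               getCol("marker", i), ""),
             taxa = vapply(seq_along(red), function(i)
               getCol("taxon", i), ""),
             stringsAsFactors = FALSE)
}

#' Read a BED annotation into 1-based inclusive gene coordinates
#'
#' @param path BED file (chrom, start, end, name, ...); 0-based half-open
#'   coordinates converted on read.
#' @return `data.frame` with `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`.
#' @export
readBedAnnotation <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  data.frame(gene_id = if (ncol(bed) >= 4) bed[[4]]
             else sprintf("feature%d", seq_len(nrow(bed))),
             chrom = as.character(bed[[1]]),
             start_bp = bed[[2]] + 1L, end_bp = bed[[3]],
             strand = if (ncol(bed) >= 6) bed[[6]] else "*",
             stringsAsFactors = FALSE)
}

#' Attach overlapping genes to regions
#'
#' @param regions region `data.frame` from [mergeRegions()].
#' @param annotation gene `data.frame` as from [readBedAnnotation()].
#' @return `regions` with a `genes` column (comma-separated ids of genes
#'   overlapping each region).
#' @export
assignGenes <- function(regions, annotation) {
  if (nrow(annotation) == 0 || nrow(regions) == 0) {
    regions$genes <- rep("", nrow(regions))
    return(regions)
  }
  unmatched <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(unmatched) && nrow(annotation) > 0 &&
      !any(regions$chrom %in% annotation$chrom))
    stop("contig names not found in annotation: ",
         paste(unmatched, collapse = ", "))
  rg <- GRanges(as.character(regions$chrom),
                IRanges(regions$start_bp, regions$end_bp))
  ag <- GRanges(as.character(annotation$chrom),
                IRanges(annotation$start_bp, annotation$end_bp))
  hits <- findOverlaps(rg, ag)
  genes <- rep("", nrow(regions))
  for (i in unique(queryHits(hits))) {
    ids <- annotation$gene_id[subjectHits(hits)[queryHits(hits) == i]]
    genes[i] <- paste(sort(unique(ids)), collapse = ",")
  }
  regions$genes <- genes
  regions
}

#' Nearest genes up- and downstream of a SNP
#'
#' Returns up to two genes: the nearest gene upstream and the nearest gene
#' downstream of the SNP position; a gene containing the SNP counts once.
#'
#' @param chrom,positionBp SNP coordinates.
#' @param annotation gene `data.frame` as from [readBedAnnotation()].
#' @return character vector of 0-2 gene ids.
#' @export
nearestGenes <- function(chrom, positionBp, annotation) {
  ann <- annotation[annotation$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(ann) == 0) return(character())
  inside <- ann$start_bp <= positionBp & ann$end_bp >= positionBp
  if (any(inside)) {
    dist <- pmin(abs(ann$start_bp - positionBp), abs(ann$end_bp - positionBp))
    within <- ann$gene_id[inside][which.min(dist[inside])]
    ## plus the next nearest on the side the contained gene does not cover
    up <- ann[!inside & ann$end_bp < positionBp, , drop = FALSE]
    down <- ann[!inside & ann$start_bp > positionBp, , drop = FALSE]
    other <- character()
    if (nrow(up) && nrow(down)) {
      du <- positionBp - max(up$end_bp); dd <- min(down$start_bp) - positionBp
      other <- if (du <= dd) up$gene_id[which.max(up$end_bp)]
      else down$gene_id[which.min(down$start_bp)]
    } else if (nrow(up)) other <- up$gene_id[which.max(up$end_bp)]
    else if (nrow(down)) other <- down$gene_id[which.min(down$start_bp)]
    return(unique(c(within, other)))
  }
  up <- ann[ann$end_bp < positionBp, , drop = FALSE]
  down <- ann[ann$start_bp > positionBp, , drop = FALSE]
  out <- character()
  if (nrow(up)) out <- c(out, up$gene_id[which.max(up$end_bp)])
  if (nrow(down)) out <- c(out, down$gene_id[which.min(down$start_bp)])
  out
}

#' Permutation test for interval-set overlap
#'
#' The observed statistic is the number of overlapping interval pairs
#' between `setA` and `setB`.  The null is built by placing each `setA`
#' interval uniformly at random within its own chromosome (length
#' preserved); `p = (1 + #[perm >= observed]) / (nPerm + 1)` (enrichment).
#'
#' @param setA,setB interval `data.frame`s with `chrom`, `start_bp`,
#'   `end_bp`.
#' @param genome named vector of chromosome lengths (bp).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param maxRegionBp optionally drop intervals longer than this from both
#'   sets before testing (e.g. 10 Mb for cross-study comparisons); NULL
#'   keeps all.
#' @return list with `observed`, `permutedMean`, `p`.
#' @export
overlapPermutation <- function(setA, setB, genome, nPerm = 10000, seed = 1,
                               maxRegionBp = NULL) {
  if (!is.null(maxRegionBp)) {
    setA <- setA[setA$end_bp - setA$start_bp + 1 <= maxRegionBp, ,
                 drop = FALSE]
    setB <- setB[setB$end_bp - setB$start_bp + 1 <= maxRegionBp, ,
                 drop = FALSE]
  }
  if (nrow(setA) == 0)
    return(list(observed = 0, permutedMean = 0, p = 1))
  lens <- setA$end_bp - setA$start_bp + 1
  chromLen <- genome[as.character(setA$chrom)]
  if (any(is.na(chromLen)) || any(lens > chromLen))
    stop("interval longer than its chromosome (or chromosome missing)")
  countPairs <- function(a) {
    ga <- GRanges(as.character(a$chrom), IRanges(a$start_bp, a$end_bp))
    gb <- GRanges(as.character(setB$chrom),
                  IRanges(setB$start_bp, setB$end_bp))
    length(findOverlaps(ga, gb))
  }
  observed <- countPairs(setA)
  set.seed(seed)
  perms <- vapply(seq_len(nPerm), function(i) {
    st <- floor(runif(nrow(setA), 1, chromLen - lens + 2))
    countPairs(data.frame(chrom = setA$chrom, start_bp = st,
                          end_bp = st + lens - 1))
  }, 0L)
  list(observed = observed, permutedMean = mean(perms),
       p = (1 + sum(perms >= observed)) / (nPerm + 1))
}

#' Gene-set enrichment by permutation and Fisher's exact test
#'
#' Observed statistic: `|hit ∩ set|`.  Permutations draw `|hit|` genes
#' uniformly without replacement from the universe.  A Fisher exact p from
#' the 2x2 table is reported alongside.
#'
#' @param hitGenes genes of interest (subset of `universe`).
#' @param geneSet annotated set (subset of `universe`).
#' @param universe all candidate genes.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed`, `permutedMean`, `pPermutation`, `pFisher`.
#' @export
genesetEnrichment <- function(hitGenes, geneSet, universe, nPerm = 10000,
                              seed = 1) {
  if (!length(universe)) stop("empty gene universe")
  hitGenes <- intersect(hitGenes, universe)
  geneSet <- intersect(geneSet, universe)
  observed <- length(intersect(hitGenes, geneSet))
  set.seed(seed)
  inSet <- universe %in% geneSet
  perms <- vapply(seq_len(nPerm), function(i)
    sum(inSet[sample.int(length(universe), length(hitGenes))]), 0L)
  tab <- matrix(c(observed, length(hitGenes) - observed,
                  length(geneSet) - observed,
                  length(universe) - length(hitGenes) - length(geneSet) +
                    observed), 2, 2)
  list(observed = observed, permutedMean = mean(perms),
       pPermutation = (1 + sum(perms >= observed)) / (nPerm + 1),
       pFisher = fisher.test(tab, alternative = "greater")$p.value)
}
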