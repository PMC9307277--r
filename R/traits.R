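## Turning taxon count tables into mapping-ready traits: rarefaction, core
## microbiome, diversity indices, inverse-logistic transform.

#' Rarefy samples to a common depth
#'
#' Samples with fewer total reads than `depth` are dropped with a warning;
#' the rest are subsampled without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]).
#'
#' @param t an [AbundanceTable-class].
#' @param depth target depth (default 10000).
#' @param seed integer seed for the subsampling.
#' @return A rarefied [AbundanceTable-class].
#' @export
rarefyCounts <- function(t, depth = 10000, seed = 1) {
  stopifnot(depth >= 1)
  cnt <- abundanceCounts(t)
  tot <- colSums(cnt)
  keep <- tot >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped")
  cnt <- cnt[, keep, drop = FALSE]
  set.seed(seed)
  rar <- t(vegan::rrarefy(base::t(cnt), depth))
  storage.mode(rar) <- "integer"
  new("AbundanceTable", counts = rar, taxonData = taxonData(t),
      level = abundanceLevel(t))
}

#' Core-microbiome taxon selection
#'
#' A taxon is core when its prevalence exceeds 25 percent of samples and the
#' median of its non-zero relative abundances exceeds 0.2 percent for ASV- and
#' genus-level taxa, or 0.5 percent for family, order, class and phylum.
#' Relative abundances are counts over the per-sample total of the (rarefied)
#' table.
#'
#' @param t a rarefied [AbundanceTable-class].
#' @param minPrevalence prevalence threshold (default 0.25, strictly greater
#'   qualifies).
#' @return character vector of core taxon ids (row names).
#' @export
coreTaxa <- function(t, minPrevalence = 0.25) {
  cnt <- abundanceCounts(t)
  ranks <- taxonData(t)$rank
  if (!all(ranks %in% abundanceRanks)) stop("unknown taxon rank")
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  prevalence <- rowMeans(cnt > 0)
  medNZ <- apply(rel, 1, function(x) if (any(x > 0)) median(x[x > 0]) else 0)
  thr <- ifelse(ranks %in% c("ASV", "genus"), 0.002, 0.005)
  rownames(cnt)[prevalence > minPrevalence & medNZ > thr]
}

#' Inverse-logistic trait transform
#'
#' Applies `exp(x) / (1 + exp(x))` to each relative abundance, producing the
#' mapping traits; optionally appends per-sample Shannon and Chao1 columns
#' (untransformed).
#'
#' @param t a rarefied [AbundanceTable-class].
#' @param core core taxon ids from [coreTaxa()].
#' @param includeDiversity append Shannon and Chao1 trait columns (default
#'   TRUE).
#' @return samples x traits numeric matrix with a `traitData` attribute
#'   (`data.frame`: taxon, rank, level).
#' @export
transformTraits <- function(t, core, includeDiversity = TRUE) {
  cnt <- abundanceCounts(t)
  if (!all(core %in% rownames(cnt))) stop("core taxa missing from table")
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  y <- base::t(rel[core, , drop = FALSE])
  vals <- exp(y) / (1 + exp(y))
  meta <- data.frame(taxon = core,
                     rank = taxonData(t)$rank[match(core, rownames(cnt))],
                     level = abundanceLevel(t), stringsAsFactors = FALSE)
  if (includeDiversity) {
    ad <- alphaDiversity(t)
    vals <- cbind(vals, shannon = ad$shannon, chao1 = ad$chao1)
    meta <- rbind(meta, data.frame(taxon = c("shannon", "chao1"),
                                   rank = c("ASV", "ASV"),
                                   level = abundanceLevel(t)))
  }
  attr(vals, "traitData") <- meta
  vals
}

#' Per-sample alpha diversity (Shannon and Chao1)
#'
#' Shannon = -sum p log p over non-zero taxa (natural log); Chao1 = observed
#' richness + F1 (F1 - 1) / (2 (F2 + 1)) with F1 and F2 the singleton and
#' doubleton counts.
#'
#' @param t a rarefied [AbundanceTable-class].
#' @return `data.frame` with `sample`, `shannon`, `chao1`.
#' @export
alphaDiversity <- function(t) {
  cnt <- abundanceCounts(t)
  if (any(colSums(cnt) == 0)) stop("empty sample(s) in abundance table")
  shannon <- apply(cnt, 2, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  chao1 <- apply(cnt, 2, function(x) {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
  data.frame(sample = colnames(cnt), shannon = unname(shannon),
             chao1 = unname(chao1), stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(u, v) = 1 - 2 sum min(u, v) / (sum u + sum v)`, computed with
#' [vegan::vegdist()]; symmetric with a zero diagonal.
#'
#' @param t an [AbundanceTable-class] with equal-depth samples.
#' @return sample x sample dissimilarity matrix in `[0, 1]`.
#' @export
brayCurtis <- function(t) {
  cnt <- abundanceCounts(t)
  as.matrix(vegan::vegdist(base::t(cnt), method = "bray"))
}
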