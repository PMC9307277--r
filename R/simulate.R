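## Forward simulator for a hybrid-zone intercross: 8 partially inbred founder
## lines from two house-mouse subspecies, G1 line crosses, and 8 G2
## sub-crosses of 40 males each, plus compositional abundance traits with
## additive, dominance, maternal, subcross, polygenic and residual variance.

#' Build an evenly spaced autosomal marker map
#'
#' Markers are placed uniformly along each chromosome; in the absence of a
#' genetic map, 1 cM = 1 Mb.
#'
#' @param nMarkers total marker count, split evenly across chromosomes.
#' @param nChromosomes number of autosomes (default 19, the mouse karyotype).
#' @param chromosomeLengthBp physical length per chromosome in bp.
#' @return `data.frame` with `marker_id`, `chromosome`, `position_bp`,
#'   `genetic_pos_cM`.
#' @export
defaultMarkerMap <- function(nMarkers, nChromosomes = 19,
                             chromosomeLengthBp = 1e8) {
  per <- rep(nMarkers %/% nChromosomes, nChromosomes)
  extra <- nMarkers %% nChromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  maps <- lapply(seq_len(nChromosomes), function(cc) {
    pos <- round(seq(1, chromosomeLengthBp, length.out = per[cc]))
    pos <- pos + seq_along(pos) - 1L          # guard against rounding ties
    data.frame(marker_id = sprintf("chr%d_m%04d", cc, seq_len(per[cc])),
               chromosome = cc, position_bp = pos,
               genetic_pos_cM = pos / 1e6, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate partially inbred founder lines from a two-subspecies hybrid zone
#'
#' A stated fraction of markers is made subspecies-diagnostic (the
#' musculus-tagged allele at frequency 1 in the musculus pool and 0 in the
#' domesticus pool).  Each line's chromosomes are mosaics of the two
#' subspecies backgrounds: at every diagnostic marker the line carries the
#' musculus allele with probability equal to its subspecies weight
#' (expected musculus ancestry).  Non-diagnostic markers segregate at shared
#' frequencies; residual within-line heterozygosity is controlled by the
#' inbreeding coefficient.
#'
#' @param markerMap map as from [defaultMarkerMap()].
#' @param nLines number of founder lines (default 8: two per breeding stock).
#' @param subspeciesWeights expected musculus ancestry per line, in `[0,1]`;
#'   default four predominantly domesticus lines (0.2) and four predominantly
#'   musculus lines (0.8).
#' @param diagnosticFraction fraction of markers made subspecies-diagnostic
#'   (default 0.14, the fixed-difference fraction observed on the array used
#'   for this cross type).
#' @param inbreeding founder inbreeding coefficient (default 0.9; the lines
#'   emulated had coefficients above 82 percent).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A `FounderSet` list: `haplotypes` (line x 2 x marker array of 0/1
#'   alleles, 1 = musculus-tagged), `lineId`, `stock`, `subspeciesWeights`,
#'   `diagnostic` (logical per marker), `inbreeding`, `map`.
#' @export
simulateFounders <- function(markerMap, nLines = 8,
                             subspeciesWeights = rep(c(0.2, 0.8), each = 4),
                             diagnosticFraction = 0.14, inbreeding = 0.9,
                             seed = 1) {
  if (nrow(markerMap) == 0) stop("marker map is empty")
  if (length(subspeciesWeights) != nLines)
    stop("subspeciesWeights must have length nLines")
  if (diagnosticFraction < 0 || diagnosticFraction > 1)
    stop("diagnosticFraction must be in [0, 1]")
  set.seed(seed)
  p <- nrow(markerMap)
  nDiag <- round(diagnosticFraction * p)
  diagnostic <- rep(FALSE, p)
  diagnostic[sample.int(p, nDiag)] <- TRUE
  ## shared (non-informative) allele-1 frequency at non-diagnostic markers
  baseFreq <- runif(p, 0.1, 0.9)
  haps <- array(0L, dim = c(nLines, 2, p))
  for (l in seq_len(nLines)) {
    w <- subspeciesWeights[l]
    ancestry <- rbinom(p, 1, w)           # per-marker subspecies background
    ## diagnostic markers: allele fixed by background on both chromosomes
    h1 <- integer(p); h2 <- integer(p)
    h1[diagnostic] <- ancestry[diagnostic]
    h2[diagnostic] <- ancestry[diagnostic]
    ## non-diagnostic markers: IBD with probability = inbreeding
    nd <- !diagnostic
    ibd <- runif(sum(nd)) < inbreeding
    a1 <- rbinom(sum(nd), 1, baseFreq[nd])
    a2 <- ifelse(ibd, a1, rbinom(sum(nd), 1, baseFreq[nd]))
    h1[nd] <- a1; h2[nd] <- a2
    haps[l, 1, ] <- h1; haps[l, 2, ] <- h2
  }
  stock <- rep(sprintf("stock%d", seq_len(ceiling(nLines / 2))),
               each = 2, length.out = nLines)
  structure(list(haplotypes = haps,
                 lineId = sprintf("L%d", seq_len(nLines)),
                 stock = stock,
                 subspeciesWeights = subspeciesWeights,
                 diagnostic = diagnostic, inbreeding = inbreeding,
                 map = markerMap),
            class = "FounderSet")
}

## One meiosis under Haldane's model: crossover count per chromosome is
## Poisson(length in Morgans), positions uniform on the genetic map, no
## interference.  hapPair: 2 x p matrix; returns a length-p gamete.
.gamete <- function(hapPair, map) {
  out <- integer(ncol(hapPair))
  for (cc in unique(map$chromosome)) {
    idx <- which(map$chromosome == cc)
    g <- map$genetic_pos_cM[idx]
    span <- max(g) - min(g)
    ncx <- rpois(1, span / 100)
    strand <- sample.int(2, 1)
    if (ncx == 0) {
      out[idx] <- hapPair[strand, idx]
    } else {
      cx <- sort(runif(ncx, min(g), max(g)))
      seg <- findInterval(g, cx)            # 0..ncx segments
      pick <- ((strand - 1) + seg) %% 2 + 1
      out[idx] <- hapPair[cbind(pick, idx)]
    }
  }
  out
}

#' Default cross design: 8 G1 line crosses and 8 G2 sub-crosses
#'
#' G1 crosses pair each predominantly domesticus line with a predominantly
#' musculus line so every line appears once as dam and once as sire; G2
#' sub-crosses pair G1s such that every G2 individual has one grandparent
#' from each of the four breeding stocks.
#'
#' @param founders a `FounderSet` with 8 lines (two per stock).
#' @param offspringPerSubcross G2 males per sub-cross (default 40).
#' @param pairsPerSubcross distinct G1 mating pairs per sub-cross (default 5).
#' @return A `CrossDesign` list with `g1Pairings` and `g2Subcrosses`.
#' @export
makeCrossDesign <- function(founders, offspringPerSubcross = 40,
                            pairsPerSubcross = 5) {
  ids <- founders$lineId
  if (length(ids) != 8) stop("default design needs exactly 8 founder lines")
  ## lines 1:4 = stocks 1-2 (domesticus side), 5:8 = stocks 3-4 (musculus side)
  g1 <- data.frame(
    cross = sprintf("c%d", 1:8),
    dam_line  = ids[c(1, 5, 2, 6, 3, 7, 4, 8)],
    sire_line = ids[c(5, 2, 6, 1, 7, 4, 8, 3)],
    stringsAsFactors = FALSE)
  ## subcross k mates a G1 from the stock1/3 ring with one from the 2/4 ring
  g2 <- data.frame(
    subcross = sprintf("S%d", 1:8),
    dam_cross  = sprintf("c%d", c(1, 2, 3, 4, 5, 6, 7, 8)),
    sire_cross = sprintf("c%d", c(5, 6, 7, 8, 1, 2, 3, 4)),
    n_offspring = offspringPerSubcross,
    n_pairs = pairsPerSubcross,
    stringsAsFactors = FALSE)
  structure(list(g1Pairings = g1, g2Subcrosses = g2), class = "CrossDesign")
}

#' Simulate the G0 -> G1 -> G2 intercross
#'
#' Meiosis follows Haldane's model (Poisson crossovers on the genetic map, no
#' interference).  Each sub-cross draws its offspring from several distinct
#' G1 mating pairs; the pedigree records the sub-cross and mating-pair label
#' of every G2 individual.
#'
#' @param founders a `FounderSet` from [simulateFounders()].
#' @param design a `CrossDesign` from [makeCrossDesign()], or one with the
#'   same structure.
#' @param seed integer seed.
#' @return list with `genotypes` (a [GenotypeMatrix-class], dosages counting
#'   the musculus-tagged allele) and `pedigree` (`data.frame`: `individual`,
#'   `subcross`, `mating_pair`, `dam`, `sire`).
#' @export
simulateCross <- function(founders, design, seed = 1) {
  map <- founders$map
  set.seed(seed)
  g1 <- design$g1Pairings
  bad <- setdiff(unique(c(g1$dam_line, g1$sire_line)), founders$lineId)
  if (length(bad))
    stop("G1 pairing references unknown line(s): ", paste(bad, collapse = ", "))
  lineHap <- function(id) founders$haplotypes[match(id, founders$lineId), , ]
  makeG1 <- function(crossId) {
    row <- g1[g1$cross == crossId, ]
    rbind(.gamete(lineHap(row$dam_line), map),
          .gamete(lineHap(row$sire_line), map))
  }
  g2 <- design$g2Subcrosses
  nTotal <- sum(g2$n_offspring)
  p <- nrow(map)
  calls <- matrix(0L, nTotal, p)
  ped <- vector("list", nrow(g2))
  k <- 0
  for (s in seq_len(nrow(g2))) {
    row <- g2[s, ]
    nPairs <- max(1, min(row$n_pairs, row$n_offspring))
    perPair <- diff(round(seq(0, row$n_offspring, length.out = nPairs + 1)))
    recs <- vector("list", nPairs)
    for (pr in seq_len(nPairs)) {
      dam <- makeG1(row$dam_cross)
      sire <- makeG1(row$sire_cross)
      pairId <- sprintf("%s_p%d", row$subcross, pr)
      ids <- character(perPair[pr])
      for (o in seq_len(perPair[pr])) {
        k <- k + 1
        calls[k, ] <- .gamete(dam, map) + .gamete(sire, map)
        ids[o] <- sprintf("G2_%04d", k)
      }
      recs[[pr]] <- data.frame(individual = ids, subcross = row$subcross,
                               mating_pair = pairId,
                               dam = sprintf("%s_dam%d", row$dam_cross, pr),
                               sire = sprintf("%s_sire%d", row$sire_cross, pr),
                               stringsAsFactors = FALSE)
    }
    ped[[s]] <- do.call(rbind, recs)
  }
  ped <- do.call(rbind, ped)
  rownames(calls) <- ped$individual
  al <- data.frame(allele1 = rep("D", p), allele2 = rep("M", p),
                   stringsAsFactors = FALSE)
  g <- GenotypeMatrix(calls, map, alleles = al, counted = al$allele2)
  list(genotypes = g, pedigree = ped)
}

#' Specify the generative model for abundance traits
#'
#' @param nTaxa number of taxa in the community.
#' @param causalSnps `data.frame` with columns `marker_id`, `taxon` (row
#'   index), `a` (additive effect, half the latent distance between
#'   homozygotes), `d` (dominance deviation); may be empty.
#' @param sigma2G,sigma2M,sigma2S,sigma2E polygenic, mating-pair, subcross
#'   and residual variance on the latent scale (all >= 0).
#' @param baselineLog baseline log-abundances per taxon (defaults to a
#'   realistic long-tailed community profile).
#' @param depth sequencing depth per sample (default 10000, the rarefaction
#'   depth used downstream).
#' @return A `TraitModel` list.
#' @export
traitModel <- function(nTaxa, causalSnps = NULL, sigma2G = 0.5, sigma2M = 0.1,
                       sigma2S = 0.05, sigma2E = 0.35, baselineLog = NULL,
                       depth = 10000) {
  if (any(c(sigma2G, sigma2M, sigma2S, sigma2E) < 0))
    stop("variance components must be non-negative")
  if (is.null(causalSnps))
    causalSnps <- data.frame(marker_id = character(), taxon = integer(),
                             a = numeric(), d = numeric(),
                             stringsAsFactors = FALSE)
  if (is.null(baselineLog))
    baselineLog <- sort(log(seq_len(nTaxa)^-1.2), decreasing = TRUE) + 2
  structure(list(nTaxa = nTaxa, causalSnps = causalSnps, sigma2G = sigma2G,
                 sigma2M = sigma2M, sigma2S = sigma2S, sigma2E = sigma2E,
                 baselineLog = baselineLog, depth = as.integer(depth)),
            class = "TraitModel")
}

## Draw one MVN(0, s2 * K) vector via eigendecomposition; errors if K has a
## materially negative eigenvalue.
.mvnKernel <- function(eigK, s2) {
  d <- pmax(eigK$values, 0)
  drop(eigK$vectors %*% (sqrt(s2 * d) * rnorm(length(d))))
}

#' Simulate abundance traits on a simulated cohort
#'
#' Latent trait per taxon = baseline + sum over causal SNPs of `a * Xa + d *
#' Xd` (Xa in \{1,0,-1\} for the counted-allele homozygote, heterozygote and
#' other homozygote; Xd = 1 for heterozygotes) + mating-pair effect +
#' subcross effect + polygenic effect MVN(0, sigma2G * GRM) + residual.  The
#' latent matrix is mapped through a per-sample softmax to a composition and
#' counts are drawn multinomially at the sequencing depth.
#'
#' @param genotypes [GenotypeMatrix-class] of the cohort.
#' @param pedigree pedigree `data.frame` with `mating_pair` and `subcross`.
#' @param grm [GRM-class] used for the polygenic term.
#' @param model a `TraitModel` from [traitModel()].
#' @param seed integer seed.
#' @param level profiling level label for the output table.
#' @return list with `abundance` (an [AbundanceTable-class]), `latent`
#'   (samples x taxa matrix) and `truth` (a `TruthRecord` list: per-taxon
#'   latent-scale `h2`, the causal-SNP table with `d_over_abs_a`, and the
#'   per-individual polygenic values).
#' @export
simulateTraits <- function(genotypes, pedigree, grm, model, seed = 1,
                           level = "DNA") {
  K <- grmMatrix(grm)
  n <- nIndividuals(genotypes)
  if (nrow(K) != n) stop("GRM dimension does not match genotypes")
  eigK <- eigen(K, symmetric = TRUE)
  if (min(eigK$values) < -1e-8)
    stop(sprintf("GRM is not positive semidefinite (eigenvalue %g)",
                 min(eigK$values)))
  cs <- model$causalSnps
  if (nrow(cs) && !all(cs$marker_id %in% markerMap(genotypes)$marker_id))
    stop("causal SNP ids not present in the marker map")
  set.seed(seed)
  nTaxa <- model$nTaxa
  pairF <- factor(pedigree$mating_pair)
  subF <- factor(pedigree$subcross)
  latent <- matrix(rep(model$baselineLog, each = n), n, nTaxa)
  polygenic <- matrix(0, n, nTaxa)
  for (t in seq_len(nTaxa)) {
    gpart <- .mvnKernel(eigK, model$sigma2G)
    polygenic[, t] <- gpart
    latent[, t] <- latent[, t] + gpart +
      rnorm(nlevels(pairF), 0, sqrt(model$sigma2M))[pairF] +
      rnorm(nlevels(subF), 0, sqrt(model$sigma2S))[subF] +
      rnorm(n, 0, sqrt(model$sigma2E))
  }
  if (nrow(cs)) {
    calls <- genotypeCalls(genotypes)
    for (r in seq_len(nrow(cs))) {
      dos <- calls[, match(cs$marker_id[r], markerMap(genotypes)$marker_id)]
      xa <- dos - 1          # counted-allele homozygote = +1
      xd <- as.numeric(dos == 1)
      latent[, cs$taxon[r]] <- latent[, cs$taxon[r]] +
        cs$a[r] * xa + cs$d[r] * xd
    }
  }
  ## per-sample softmax -> composition -> multinomial counts
  counts <- matrix(0L, nTaxa, n)
  for (i in seq_len(n)) {
    z <- latent[i, ] - max(latent[i, ])
    pr <- exp(z) / sum(exp(z))
    counts[, i] <- rmultinom(1, model$depth, pr)
  }
  rownames(counts) <- sprintf("taxon%03d", seq_len(nTaxa))
  colnames(counts) <- rownames(genotypeCalls(genotypes))
  tot <- model$sigma2G + model$sigma2M + model$sigma2S + model$sigma2E
  h2 <- if (tot > 0) model$sigma2G / tot else 0
  truth <- list(h2 = rep(h2, nTaxa),
                causal = if (nrow(cs))
                  transform(cs, d_over_abs_a = ifelse(cs$a == 0, NA,
                                                      cs$d / abs(cs$a)))
                else cs,
                polygenic = polygenic)
  rownames(latent) <- rownames(genotypeCalls(genotypes))
  list(abundance = AbundanceTable(counts, level = level),
       latent = latent, truth = truth)
}

#' One-call simulation of a complete study cohort
#'
#' Convenience wrapper: founders, cross, centred GRM and traits from one
#' seed, at the default study conditions (8 lines, 8 sub-crosses x 40 males
#' = 320 G2 individuals).
#'
#' @param markerMap marker map (default 2000 markers on 19 autosomes).
#' @param model a `TraitModel` (default 20 taxa, no causal SNPs).
#' @param seed integer seed; split into per-stage substreams.
#' @param offspringPerSubcross G2 males per sub-cross.
#' @return list with `founders`, `genotypes`, `pedigree`, `grm`, `abundance`,
#'   `latent`, `truth`.
#' @export
simulateStudy <- function(markerMap = defaultMarkerMap(2000), model = NULL,
                          seed = 1, offspringPerSubcross = 40) {
  if (is.null(model)) model <- traitModel(nTaxa = 20)
  s <- stageSeeds(seed, 3)
  founders <- simulateFounders(markerMap, seed = s[1])
  cross <- simulateCross(founders,
                         makeCrossDesign(founders, offspringPerSubcross),
                         seed = s[2])
  grm <- grmCentred(cross$genotypes)
  tr <- simulateTraits(cross$genotypes, cross$pedigree, grm, model,
                       seed = s[3])
  c(list(founders = founders, grm = grm), cross, tr)
}

## Deterministic substream seeds below 2^31 from one master seed.
stageSeeds <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + 12345 * seq_len(k)) %% (2^31 - 1)
}
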