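## Text-format IO: PLINK-style .ped/.map, minimal VCF (GT only), pedigree
## and abundance TSVs, GRM TSV + side-car JSON, truth JSON.

#' Write genotypes as PLINK-style .ped/.map text
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`).
#' @export
writePlink <- function(g, prefix) {
  map <- markerMap(g)
  write.table(data.frame(map$chromosome, map$marker_id,
                         map$genetic_pos_cM, map$position_bp),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  calls <- genotypeCalls(g)
  al <- alleleLabels(g)
  counted <- countedAllele(g)
  other <- ifelse(counted == al$allele1, al$allele2, al$allele1)
  lines <- vapply(seq_len(nrow(calls)), function(i) {
    d <- calls[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, counted, other))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, counted, other))
    paste(c("FAM", rownames(calls)[i], "0", "0", "1", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK-style .ped/.map text genotypes
#'
#' Alleles are re-coded as dosages of the per-marker second-seen allele;
#' `0` is missing.  Markers with more than two alleles are kept but flagged
#' non-biallelic via identical allele labels, so [qcFilter()] removes them.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return A [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  names(map) <- c("chromosome", "marker_id", "genetic_pos_cM", "position_bp")
  map <- map[, c("marker_id", "chromosome", "position_bp", "genetic_pos_cM")]
  ped <- strsplit(readLines(paste0(prefix, ".ped")), " +")
  ids <- vapply(ped, `[`, "", 2)
  gtxt <- lapply(ped, function(x) x[-(1:6)])
  p <- nrow(map)
  n <- length(ped)
  calls <- matrix(NA_integer_, n, p, dimnames = list(ids, map$marker_id))
  a1lab <- character(p); a2lab <- character(p)
  for (j in seq_len(p)) {
    pair <- vapply(gtxt, function(x) x[c(2 * j - 1, 2 * j)],
                   character(2))
    obs <- setdiff(unique(as.vector(pair)), "0")
    if (length(obs) > 2) {               # non-biallelic: flag and skip
      a1lab[j] <- a2lab[j] <- paste(sort(obs), collapse = ",")
      next
    }
    a1 <- if (length(obs) >= 1) obs[1] else "A"
    a2 <- if (length(obs) >= 2) obs[2] else a1
    a1lab[j] <- a1; a2lab[j] <- if (length(obs) >= 2) a2 else paste0(a1, "'")
    miss <- pair[1, ] == "0" | pair[2, ] == "0"
    dos <- colSums(pair == a2)
    dos[miss] <- NA_integer_
    calls[, j] <- dos
  }
  GenotypeMatrix(calls, map,
                 alleles = data.frame(allele1 = a1lab, allele2 = a2lab,
                                      stringsAsFactors = FALSE),
                 counted = a2lab)
}

#' Read genotypes from a minimal VCF (GT field only)
#'
#' @param path uncompressed VCF file; only the GT subfield is used.
#' @return A [GenotypeMatrix-class] counting ALT-allele copies.
#' @export
readVcfGenotypes <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  rows <- strsplit(body[-1], "\t")
  samples <- header[-(1:9)]
  rec <- function(i, f) vapply(rows, `[`, "", i)
  chrom <- rec(1); pos <- as.integer(rec(2)); id <- rec(3)
  ref <- rec(4); alt <- rec(5)
  gt <- t(vapply(rows, function(r) {
    g <- sub(":.*", "", r[-(1:9)])
    ifelse(g %in% c("./.", ".", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(x) sum(x == "1"), 0L))
  }, integer(length(samples))))
  if (length(samples) == 1) gt <- matrix(gt, ncol = 1)
  calls <- t(gt)
  dimnames(calls) <- list(samples, id)
  map <- data.frame(marker_id = id, chromosome = chrom, position_bp = pos,
                    genetic_pos_cM = pos / 1e6, stringsAsFactors = FALSE)
  GenotypeMatrix(calls, map,
                 alleles = data.frame(allele1 = ref, allele2 = alt,
                                      stringsAsFactors = FALSE),
                 counted = alt)
}

#' Write / read an abundance table as TSV
#'
#' Rows are taxa, columns samples, with `taxon`, `rank` and `lineage`
#' leading columns.
#'
#' @param t an [AbundanceTable-class].
#' @param path output TSV path.
#' @export
writeAbundanceTsv <- function(t, path) {
  df <- data.frame(taxon = rownames(abundanceCounts(t)),
                   rank = taxonData(t)$rank, lineage = taxonData(t)$lineage,
                   abundanceCounts(t), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundanceTsv
#' @param level profiling level label for the table read back.
#' @export
readAbundanceTsv <- function(path, level = "DNA") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(cnt) <- df$taxon
  AbundanceTable(cnt, data.frame(rank = df$rank, lineage = df$lineage,
                                 stringsAsFactors = FALSE), level = level)
}

#' Write a pedigree table as TSV
#'
#' @param pedigree pedigree `data.frame` (`individual`, `subcross`,
#'   `mating_pair`, `dam`, `sire`).
#' @param path output TSV path.
#' @export
writePedigreeTsv <- function(pedigree, path) {
  write.table(pedigree, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePedigreeTsv
#' @export
readPedigreeTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Persist a GRM as TSV plus a side-car JSON
#'
#' @param grm a [GRM-class].
#' @param prefix path prefix (writes `<prefix>.tsv` and `<prefix>.json`).
#' @export
writeGrm <- function(grm, prefix) {
  m <- grmMatrix(grm)
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(flavour = grmFlavour(grm),
                            n_markers = grm@nMarkersUsed,
                            excluded_chromosome = excludedChromosome(grm)),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(prefix)
}

#' @rdname writeGrm
#' @param path path prefix used by [writeGrm()].
#' @export
readGrm <- function(path) {
  df <- read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new("GRM", matrix = (m + t(m)) / 2, flavour = meta$flavour,
      excludedChromosome = if (is.null(meta$excluded_chromosome))
        NA_character_ else as.character(meta$excluded_chromosome),
      nMarkersUsed = as.integer(meta$n_markers))
}
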