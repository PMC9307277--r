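## End-to-end pipeline orchestration: simulate (optional) -> QC -> GRM ->
## traits -> heritability -> association scan -> architecture -> regions,
## with a YAML run configuration and a manifest for reproducibility.

#' Default run configuration
#'
#' All thresholds default to the values used throughout the package:
#' QC (call rate 0.90, missingness 0.10, MAF 0.05, HWE 1e-10), LD pruning
#' (window 5, step 1, r2 0.9), rarefaction depth 10000, core-microbiome
#' prevalence 0.25, scan alpha 0.05, region merge gap 10 Mb.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir output directory.
#' @return A `RunConfig` list.
#' @export
defaultRunConfig <- function(seed = 1, outDir = "hybridmap_run") {
  list(
    seed = seed, out_dir = outDir,
    paths = list(genotypes = NULL, traits = NULL, pedigree = NULL,
                 annotation = NULL, cospeciation = NULL),
    simulate = list(enabled = TRUE, n_markers = 2000, n_chromosomes = 19,
                    offspring_per_subcross = 20, n_taxa = 20,
                    depth = 10000),
    qc = list(ind_call_rate = 0.90, snp_missing = 0.10, maf = 0.05,
              hwe_p = 1e-10),
    ld = list(window = 5, step = 1, r2_max = 0.9),
    traits = list(rarefaction_depth = 10000, min_prevalence = 0.25),
    heritability = list(n_sim = 0),
    scan = list(mode = "approximate", alpha = 0.05),
    regions = list(r2_min = 0.9, max_gap_bp = 1e7))
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  utils::modifyList(base, cfg)
}

#' @rdname readRunConfig
#' @param config a `RunConfig` list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full mapping pipeline
#'
#' Executes simulate (optional) -> genotype QC -> LD pruning -> GRMs ->
#' trait preparation -> heritability -> association scan -> dominance
#' architecture -> significant regions, writing TSV artifacts and a
#' manifest to the output directory.  Re-running with the same
#' configuration and seed reproduces all outputs bit-identically.
#'
#' @param config a `RunConfig` list (see [defaultRunConfig()]) or the path
#'   to a YAML config.
#' @return the output directory path, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  seeds <- stageSeeds(config$seed, 6)
  log <- function(...) message("[hybridmap] ", ...)

  ## --- inputs: simulate or load ---------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    log("simulating cohort")
    mm <- defaultMarkerMap(config$simulate$n_markers,
                           config$simulate$n_chromosomes)
    founders <- simulateFounders(mm, seed = seeds[1])
    cross <- simulateCross(
      founders, makeCrossDesign(founders,
                                config$simulate$offspring_per_subcross),
      seed = seeds[2])
    g <- cross$genotypes
    pedigree <- cross$pedigree
    model <- traitModel(nTaxa = config$simulate$n_taxa,
                        depth = config$simulate$depth)
    sim <- simulateTraits(g, pedigree, grmCentred(g), model,
                          seed = seeds[3])
    abundance <- sim$abundance
    writePlink(g, out("genotypes"))
    writePedigreeTsv(pedigree, out("pedigree.tsv"))
    writeAbundanceTsv(abundance, out("abundance.tsv"))
    jsonlite::write_json(list(h2 = sim$truth$h2, causal = sim$truth$causal),
                         out("truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    for (f in c("genotypes", "traits", "pedigree"))
      if (is.null(config$paths[[f]]))
        stop("config paths$", f, " is required when simulate is disabled")
    if (!is.null(config$paths$pedigree) &&
        !file.exists(config$paths$pedigree))
      stop("pedigree file not found: ", config$paths$pedigree)
    g <- readPlink(config$paths$genotypes)
    pedigree <- readPedigreeTsv(config$paths$pedigree)
    abundance <- readAbundanceTsv(config$paths$traits)
  }

  ## --- genotype QC + LD pruning ---------------------------------------
  log("genotype QC")
  qc <- qcFilter(g, config$qc$ind_call_rate, config$qc$snp_missing,
                 config$qc$maf, config$qc$hwe_p)
  gq <- qc$genotypes
  keep <- ldPrune(gq, config$ld$window, config$ld$step, config$ld$r2_max)
  gm <- subsetGenotypes(gq, markers = match(keep, markerMap(gq)$marker_id))
  pedigree <- pedigree[match(rownames(genotypeCalls(gm)),
                             pedigree$individual), ]
  writeLines(keep, out("retained_markers.txt"))
  write.table(data.frame(filter = c("individuals_removed",
                                    names(qc$report$removed_markers)),
                         removed = c(qc$report$removed_individuals,
                                     unname(qc$report$removed_markers))),
              out("qc_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## --- GRMs ------------------------------------------------------------
  log("relatedness matrices")
  grmC <- grmCentred(gm)
  grmS <- grmStandardised(gm)
  loco <- grmLocoAll(gm)
  writeGrm(grmC, out("grm_centred"))
  writeGrm(grmS, out("grm_standardised"))

  ## --- traits ----------------------------------------------------------
  log("trait preparation")
  rar <- rarefyCounts(abundance, config$traits$rarefaction_depth,
                      seed = seeds[4])
  core <- coreTaxa(rar, config$traits$min_prevalence)
  if (!length(core)) stop("no core taxa at the configured thresholds")
  traits <- transformTraits(rar, core)
  keepSamp <- intersect(rownames(traits), pedigree$individual)
  traits <- traits[keepSamp, , drop = FALSE]
  idx <- match(keepSamp, pedigree$individual)
  pedigree <- pedigree[idx, ]
  sel <- match(keepSamp, rownames(grmMatrix(grmC)))
  subGrm <- function(gr) new("GRM", matrix = grmMatrix(gr)[sel, sel],
                             flavour = grmFlavour(gr),
                             excludedChromosome = excludedChromosome(gr),
                             nMarkersUsed = gr@nMarkersUsed)
  grmC <- subGrm(grmC); grmS <- subGrm(grmS)
  loco <- lapply(loco, subGrm)
  gm <- subsetGenotypes(gm, individuals = sel)

  ## --- heritability ----------------------------------------------------
  log("heritability")
  herit <- heritabilityTable(traits, grmC, grmS, pedigree,
                             nSim = config$heritability$n_sim,
                             seed = seeds[5])
  write.table(herit, out("heritability.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## --- association scan ------------------------------------------------
  log("association scan")
  scan <- runScan(traits, gm, pedigree, loco, mode = config$scan$mode,
                  alpha = config$scan$alpha)
  write.table(scan$records, out("associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(lambda_gc = as.list(scan$lambda),
                            meff = scan$meff,
                            thresholds = as.list(scan$thresholds)),
                       out("scan_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  ## --- architecture + regions ------------------------------------------
  sig <- scan$records[scan$records$study_wide, , drop = FALSE]
  if (nrow(sig)) {
    log("architecture and regions for ", nrow(sig), " significant records")
    arch <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      cd <- classifyDominance(sig$a[i], sig$d[i])
      data.frame(trait = sig$trait[i], marker = sig$marker[i],
                 d_over_abs_a = cd$ratio, class = cd$class,
                 stringsAsFactors = FALSE)
    }))
    write.table(arch, out("dominance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    iv <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      r <- expandRegion(sig$marker[i], gq, config$regions$r2_min)
      r$taxon <- sig$trait[i]
      r
    }))
    regions <- mergeRegions(iv, config$regions$max_gap_bp)
    if (!is.null(config$paths$annotation))
      regions <- assignGenes(regions,
                             readBedAnnotation(config$paths$annotation))
    write.table(regions, out("regions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    log("no study-wide significant records")
  }

  ## --- manifest ---------------------------------------------------------
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridmap")),
    seed = config$seed,
    config = config,
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(config$out_dir)
}
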