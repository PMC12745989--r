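#' Configuration for a full pipeline run
#'
#' Bundles the design configuration, simulation parameters, stage toggles
#' and analysis settings behind \code{\link{runPipeline}}.
#'
#' @param design a \code{\link{designConfig}}.
#' @param sim a \code{\link{simulationParams}}.
#' @param kVoxels reliable voxels kept per unilateral region.
#' @param folds,repeats cross-validation specification.
#' @param mappingPairs data.frame (source, target) of region pairs to map;
#'   default the low-to-high-level pair highlighted throughout the analyses
#'   (lingual to middle occipital).
#' @param trainQuality quality condition the mapping models are trained on.
#' @param roiSets region sets for decoding; default each single region plus
#'   the all-region joint set.
#' @param mappingAlpha significance threshold for mapping comparisons.
#' @param decodingQ FDR threshold for decoding comparisons.
#' @param stages character subset of c("simulate", "extract", "rsa", "map",
#'   "decode").
#' @param seed master seed for the whole run.
#' @return validated configuration list (class \code{"RunConfig"}).
#' @export
runConfig <- function(design = designConfig(), sim = simulationParams(),
                      kVoxels = 100L, folds = 4L, repeats = 10L,
                      mappingPairs = data.frame(source = "lingual",
                                                target = "middle_occipital",
                                                stringsAsFactors = FALSE),
                      trainQuality = "low",
                      roiSets = NULL, mappingAlpha = 0.05, decodingQ = 0.1,
                      stages = c("simulate", "extract", "rsa", "map",
                                 "decode"),
                      seed = 1L) {
  stopifnot(inherits(design, "DesignConfig"),
            inherits(sim, "SimulationParams"),
            mappingAlpha > 0, mappingAlpha < 1, decodingQ > 0, decodingQ < 1)
  if (is.null(roiSets)) {
    roiSets <- c(lapply(sim$roiNames, identity), list(sim$roiNames))
  }
  cfg <- list(design = design, sim = sim, kVoxels = as.integer(kVoxels),
              folds = as.integer(folds), repeats = as.integer(repeats),
              mappingPairs = mappingPairs, trainQuality = trainQuality,
              roiSets = roiSets, mappingAlpha = mappingAlpha,
              decodingQ = decodingQ, stages = stages, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

.writeTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, extract, rsa, map and decode stages as toggled, writes
#' every result table as a tab-delimited file into \code{outDir} together
#' with a machine-readable provenance record (configuration, seed, package
#' version, configuration hash), and returns the result objects invisibly.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created if needed).
#' @param verbose print stage progress.
#' @return (invisibly) list with the stage outputs.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("vqmvpa_"),
                        verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[vqmvpa] ", ...)
  out <- list(outDir = outDir)
  stage <- function(name) name %in% config$stages

  # provenance: serialize the configuration and hash it
  cfg_json <- jsonlite::toJSON(list(
    design = unclass(config$design),
    sim = lapply(unclass(config$sim), function(x)
      if (is.matrix(x)) as.data.frame(x) else x),
    kVoxels = config$kVoxels, folds = config$folds,
    repeats = config$repeats, mappingPairs = config$mappingPairs,
    trainQuality = config$trainQuality, roiSets = config$roiSets,
    mappingAlpha = config$mappingAlpha, decodingQ = config$decodingQ,
    stages = config$stages, seed = config$seed),
    auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(outDir, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  design <- NULL; dataset <- NULL; repSet <- NULL

  if (stage("simulate")) {
    say("simulate: generating design and betas")
    design <- generateDesign(config$design)
    dataset <- simulateBetas(design, config$sim)
    .writeTable(trialTable(design), file.path(outDir, "design.tsv"))
    out$design <- design; out$dataset <- dataset
  }
  if (stage("extract")) {
    if (is.null(dataset)) stop("extract stage requires the simulate stage")
    say("extract: voxel reliability selection and patterns")
    sel <- selectAllReliableVoxels(dataset, k = config$kVoxels)
    repSet <- buildRepresentations(dataset, sel)
    out$representations <- repSet
  }
  if (stage("rsa")) {
    if (is.null(repSet)) stop("rsa stage requires the extract stage")
    say("rsa: information content and group statistics")
    ict <- infoContentTable(repSet)
    .writeTable(ict, file.path(outDir, "info_content.tsv"))
    stats_rows <- do.call(rbind, lapply(names(repSet@averaged[[1]]),
                                        function(roi) {
      cq <- compareAcrossQuality(ict, roi)
      data.frame(roi = roi, F = cq$anova$F, df1 = cq$anova$df1,
                 df2 = cq$anova$df2, p = cq$anova$p,
                 stringsAsFactors = FALSE)
    }))
    .writeTable(stats_rows, file.path(outDir, "rsa_anova.tsv"))
    out$infoContent <- ict; out$rsaAnova <- stats_rows
  }
  if (stage("map")) {
    if (is.null(repSet)) stop("map stage requires the extract stage")
    say("map: inter-region mapping with noise ceilings")
    map_tab <- do.call(rbind, lapply(seq_len(nrow(config$mappingPairs)),
                                     function(i) {
      qualityGeneralization(repSet,
                            source = config$mappingPairs$source[i],
                            target = config$mappingPairs$target[i],
                            trainQuality = config$trainQuality,
                            folds = config$folds, repeats = config$repeats,
                            seed = childSeed(config$seed, 200L + i))
    }))
    .writeTable(aggregateMapping(map_tab), file.path(outDir, "mapping.tsv"))
    nc <- noiseCeilingTable(repSet)
    .writeTable(nc, file.path(outDir, "noise_ceiling.tsv"))
    out$mapping <- map_tab; out$noiseCeiling <- nc
  }
  if (stage("decode")) {
    if (is.null(repSet)) stop("decode stage requires the extract stage")
    say("decode: quality decoding over region sets")
    dec <- decodingTable(repSet, config$roiSets, folds = config$folds,
                         repeats = config$repeats,
                         seed = childSeed(config$seed, 300L))
    .writeTable(dec$table, file.path(outDir, "decoding.tsv"))
    rb <- randomBaseline(qualityTargets(repSet), repeats = 100L,
                         seed = childSeed(config$seed, 301L))
    .writeTable(data.frame(metric = c("srcc", "plcc"),
                           mean = c(rb$meanSrcc, rb$meanPlcc),
                           sd = c(rb$sdSrcc, rb$sdPlcc)),
                file.path(outDir, "random_baseline.tsv"))
    out$decoding <- dec; out$randomBaseline <- rb
  }

  prov <- list(package = "vqmvpa",
               version = as.character(packageVersion("vqmvpa")),
               seed = config$seed, config_hash = cfg_hash,
               stages = config$stages,
               r_version = as.character(getRversion()))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
             file.path(outDir, "provenance.json"))
  say("done: results in ", outDir)
  invisible(out)
}
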