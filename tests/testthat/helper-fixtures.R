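# Shared desk-scale fixtures, built once per test run and memoised.
# The small study: 2 runs, 4 images per category x quality cell per task
# (72 unique images per task), 30 voxels per unilateral region of which 20
# are reliable, 10 voxels selected per hemisphere (20-dimensional patterns).

.fixture_env <- new.env(parent = emptyenv())

smallDesignConfig <- function(nParticipants = 3L, seed = 101L) {
  designConfig(nParticipants = nParticipants, nRuns = 2L,
               imagesPerCell = 4L, seed = seed)
}

smallParams <- function(seed = 202L, ...) {
  simulationParams(voxelsPerUnilateralRoi = 30L, nReliableVoxels = 20L,
                   seed = seed, ...)
}

# dataset + representations reused by the representation/rsa/mapping tests
smallStudy <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  design <- generateDesign(smallDesignConfig())
  dataset <- simulateBetas(design, smallParams())
  selections <- selectAllReliableVoxels(dataset, k = 10L)
  repSet <- buildRepresentations(dataset, selections)
  .fixture_env$study <- list(design = design, dataset = dataset,
                             selections = selections, repSet = repSet)
  .fixture_env$study
}

# a hand-built RepresentationSet with known pattern matrices (no simulator),
# for null-model and degenerate-input tests
syntheticRepSet <- function(patterns1, patterns2, categories, qualities,
                            roi = "calcarine", participant = "sub01") {
  n <- nrow(patterns1)
  z <- function(m) t(apply(m, 1, vqmvpa::zscore))
  avg <- z((patterns1 + patterns2) / 2)
  info <- data.frame(image_id = sprintf("img%03d", seq_len(n)),
                     category = categories, quality = qualities,
                     task = "QA", stringsAsFactors = FALSE)
  per <- list(); av <- list()
  per[[participant]] <- setNames(list(list(rep1 = z(patterns1),
                                           rep2 = z(patterns2))), roi)
  av[[participant]] <- setNames(list(avg), roi)
  new("RepresentationSet", averaged = av, perRepetition = per,
      imageInfo = info, k = as.integer(ncol(patterns1) / 2),
      hemisphereOrder = c("L", "R"))
}

# ordered task sequence of a trial table, for repetition-lag scans
taskSequence <- function(trials, task, participant = trials$participant[1]) {
  tr <- trials[trials$task == task & trials$participant == participant, ]
  tr <- tr[order(tr$run, tr$block, tr$trial), ]
  tr$image_id
}

minRepetitionGap <- function(sequence) {
  pos <- split(seq_along(sequence), sequence)
  min(vapply(pos, function(p) if (length(p) < 2) Inf else min(diff(p)),
             numeric(1)))
}
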