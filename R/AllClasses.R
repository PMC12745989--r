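#' Canonical region and condition vocabularies
#'
#' Seven bilateral visual regions of interest, ordered along the ventral
#' processing hierarchy; the first four are treated as low-level (early)
#' visual cortex and the last three as high-level.
#'
#' @return character vector of region names.
#' @export
visualRoiNames <- function() {
  c("calcarine", "cuneus", "lingual", "superior_occipital",
    "middle_occipital", "inferior_occipital", "fusiform")
}

#' @rdname visualRoiNames
#' @export
lowLevelRoiNames <- function() visualRoiNames()[1:4]

#' @rdname visualRoiNames
#' @export
highLevelRoiNames <- function() visualRoiNames()[5:7]

#' @rdname visualRoiNames
#' @export
categoryLevels <- function() c("face", "object", "scene")

#' @rdname visualRoiNames
#' @export
qualityLevels <- function() c("low", "neutral", "high")

.TRIAL_COLUMNS <- c("participant", "run", "block", "task", "trial",
                    "image_id", "category", "quality", "repetition",
                    "onset_s", "duration_s", "isi_s")

#' StimulusDesign: the experimental trial table
#'
#' One row per trial: who saw which image, of what content category and
#' perceived quality, in which task block, and when. Produced by
#' \code{\link{generateDesign}}.
#'
#' @slot trials data.frame with columns participant, run, block, task, trial,
#'   image_id, category, quality, repetition, onset_s, duration_s, isi_s.
#' @slot config the validated design configuration used to build the table.
#' @export
setClass("StimulusDesign",
         representation(trials = "data.frame", config = "list"))

setValidity("StimulusDesign", function(object) {
  tr <- object@trials
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(tr))
  if (length(missing_cols))
    return(paste("missing trial columns:", paste(missing_cols, collapse = ", ")))
  if (!all(tr$task %in% c("QA", "CC"))) return("task must be QA or CC")
  if (!all(tr$category %in% categoryLevels())) return("unknown category label")
  if (!all(tr$quality %in% qualityLevels())) return("unknown quality label")
  if (!all(tr$repetition %in% c(1L, 2L))) return("repetition must be 1 or 2")
  TRUE
})

#' @describeIn StimulusDesign accessor for the trial table.
#' @param x a StimulusDesign.
#' @export
trialTable <- function(x) {
  stopifnot(is(x, "StimulusDesign"))
  x@trials
}

#' @describeIn StimulusDesign accessor for the design configuration.
#' @export
designConfigOf <- function(x) {
  stopifnot(is(x, "StimulusDesign"))
  x@config
}

setMethod("show", "StimulusDesign", function(object) {
  tr <- object@trials
  cat("StimulusDesign:", length(unique(tr$participant)), "participant(s),",
      max(tr$run), "run(s),", nrow(tr), "trials\n")
  cat("  tasks:", paste(unique(tr$task), collapse = "/"),
      " unique images:", length(unique(tr$image_id)), "\n")
})

#' BetaDataset: trial-level voxel beta patterns
#'
#' Simulated (or imported) single-trial beta weights, one trial x voxel
#' matrix per participant and unilateral region (region keys look like
#' \code{"calcarine_L"}). Rows align 1:1 with that participant's rows of the
#' design trial table.
#'
#' @slot betas nested list: \code{betas[[participant]][[roi_hemi]]} is a
#'   numeric matrix, trials x voxels.
#' @slot design the \code{StimulusDesign} the trial axis aligns with.
#' @slot params the simulation parameter list used (empty for imported data).
#' @slot reliableVoxels nested list of the planted reliable-voxel indices per
#'   participant and unilateral region (ground truth for recovery checks;
#'   empty for imported data).
#' @export
setClass("BetaDataset",
         representation(betas = "list", design = "StimulusDesign",
                        params = "list", reliableVoxels = "list"))

setValidity("BetaDataset", function(object) {
  tr <- object@betas
  des <- object@design@trials
  for (p in names(tr)) {
    n_tr <- sum(des$participant == p)
    for (key in names(tr[[p]])) {
      m <- tr[[p]][[key]]
      if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("betas[[%s]][[%s]] is not a numeric matrix", p, key))
      if (nrow(m) != n_tr)
        return(sprintf("trial axis of %s/%s (%d) does not match design (%d)",
                       p, key, nrow(m), n_tr))
      if (!all(is.finite(m)))
        return(sprintf("non-finite betas in %s/%s", p, key))
    }
  }
  TRUE
})

#' @describeIn BetaDataset participants present in the dataset.
#' @param x a BetaDataset.
#' @export
participants <- function(x) names(x@betas)

#' @describeIn BetaDataset one trial x voxel beta matrix.
#' @param participant participant id.
#' @param roi bilateral region name.
#' @param hemisphere "L" or "R".
#' @export
betaMatrix <- function(x, participant, roi, hemisphere) {
  stopifnot(is(x, "BetaDataset"))
  x@betas[[participant]][[paste(roi, hemisphere, sep = "_")]]
}

setMethod("show", "BetaDataset", function(object) {
  ps <- names(object@betas)
  keys <- if (length(ps)) names(object@betas[[1]]) else character()
  dims <- if (length(keys)) dim(object@betas[[1]][[1]]) else c(0, 0)
  cat("BetaDataset:", length(ps), "participant(s),", length(keys),
      "unilateral region(s),", dims[1], "trials x", dims[2], "voxels\n")
})

#' RepresentationSet: per-image region response patterns
#'
#' For each participant and bilateral region, the image x dimension pattern
#' matrices built by \code{\link{buildRepresentations}}: left- and
#' right-hemisphere reliable voxels concatenated (left first), kept per
#' presentation and averaged across the two presentations, each pattern
#' z-scored across its entries.
#'
#' @slot averaged list: \code{averaged[[participant]][[roi]]} is an image x
#'   (2k) matrix of repetition-averaged, z-scored patterns.
#' @slot perRepetition list: \code{perRepetition[[participant]][[roi]]} is a
#'   list of two image x (2k) matrices (\code{rep1}, \code{rep2}).
#' @slot imageInfo data.frame (image_id, category, quality, task) giving the
#'   row order shared by every pattern matrix.
#' @slot k voxels selected per unilateral region.
#' @slot hemisphereOrder concatenation order, fixed "L","R".
#' @export
setClass("RepresentationSet",
         representation(averaged = "list", perRepetition = "list",
                        imageInfo = "data.frame", k = "integer",
                        hemisphereOrder = "character"))

setValidity("RepresentationSet", function(object) {
  n_img <- nrow(object@imageInfo)
  for (p in names(object@averaged)) {
    for (r in names(object@averaged[[p]])) {
      m <- object@averaged[[p]][[r]]
      if (nrow(m) != n_img) return("averaged pattern rows != image index")
      if (ncol(m) != 2L * object@k) return("pattern length != 2k")
    }
  }
  TRUE
})

#' @describeIn RepresentationSet image index table (id, category, quality, task).
#' @param x a RepresentationSet.
#' @export
imageInfo <- function(x) {
  stopifnot(is(x, "RepresentationSet"))
  x@imageInfo
}

#' @describeIn RepresentationSet repetition-averaged pattern matrix.
#' @param participant participant id.
#' @param roi bilateral region name.
#' @export
averagedPatterns <- function(x, participant, roi) {
  stopifnot(is(x, "RepresentationSet"))
  x@averaged[[participant]][[roi]]
}

#' @describeIn RepresentationSet per-presentation pattern matrices
#'   (list with elements rep1 and rep2).
#' @export
repetitionPatterns <- function(x, participant, roi) {
  stopifnot(is(x, "RepresentationSet"))
  x@perRepetition[[participant]][[roi]]
}

setMethod("show", "RepresentationSet", function(object) {
  ps <- names(object@averaged)
  rois <- if (length(ps)) names(object@averaged[[1]]) else character()
  cat("RepresentationSet:", length(ps), "participant(s),", length(rois),
      "region(s),", nrow(object@imageInfo), "images,",
      2L * object@k, "dimensions per pattern\n")
})

#' RDM: representational dissimilarity matrix
#'
#' Square symmetric matrix of pairwise pattern dissimilarities over images,
#' with the item labels needed to restrict or compare it.
#'
#' @slot values n x n numeric dissimilarity matrix.
#' @slot items data.frame with at least column \code{id}; \code{category}
#'   and \code{quality} when known.
#' @slot metric "pearson_distance" or "euclidean".
#' @export
setClass("RDM",
         representation(values = "matrix", items = "data.frame",
                        metric = "character"))

setValidity("RDM", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("RDM must be square")
  if (nrow(v) != nrow(object@items)) return("item index does not match matrix")
  if (max(abs(v - t(v))) > 1e-10) return("RDM must be symmetric")
  if (max(abs(diag(v))) > 1e-10) return("RDM diagonal must be zero")
  if (object@metric == "pearson_distance" &&
      (min(v) < -1e-10 || max(v) > 2 + 1e-10))
    return("pearson-distance entries must lie in [0, 2]")
  if (object@metric == "euclidean" && min(v) < -1e-10)
    return("euclidean entries must be non-negative")
  TRUE
})

#' @describeIn RDM the dissimilarity matrix.
#' @param x an RDM.
#' @export
rdmValues <- function(x) {
  stopifnot(is(x, "RDM"))
  x@values
}

#' @describeIn RDM the item index.
#' @export
rdmItems <- function(x) {
  stopifnot(is(x, "RDM"))
  x@items
}

setMethod("show", "RDM", function(object) {
  cat("RDM (", object@metric, "): ", nrow(object@values), " x ",
      ncol(object@values), " items\n", sep = "")
})

#' @describeIn RDM restrict an RDM to a subset of items.
#' @param keep logical or integer index over items.
#' @export
subsetRDM <- function(x, keep) {
  stopifnot(is(x, "RDM"))
  new("RDM", values = x@values[keep, keep, drop = FALSE],
      items = x@items[keep, , drop = FALSE], metric = x@metric)
}
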