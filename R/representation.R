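#' Split-half condition profiles for one unilateral region
#'
#' For every voxel, the mean beta of each of the 18 conditions (2 tasks x 3
#' content categories x 3 quality levels), computed separately in the
#' odd-run half and the even-run half (runs are split by parity and trials
#' averaged within each half).
#'
#' @param dataset a \code{\linkS4class{BetaDataset}}.
#' @param participant participant id.
#' @param roi bilateral region name.
#' @param hemisphere "L" or "R".
#' @return array of dimension (2 halves x 18 conditions x voxels), halves
#'   named "odd"/"even".
#' @export
conditionProfiles <- function(dataset, participant, roi, hemisphere) {
  stopifnot(is(dataset, "BetaDataset"))
  mat <- betaMatrix(dataset, participant, roi, hemisphere)
  if (is.null(mat)) stop("no betas for that participant/region/hemisphere")
  tr <- dataset@design@trials
  tr <- tr[tr$participant == participant, , drop = FALSE]
  if (length(unique(tr$run)) < 2L)
    stop("cannot split a single run into odd and even halves")
  cond <- interaction(tr$task, tr$category, tr$quality, drop = FALSE,
                      sep = ":")
  cond_levels <- levels(cond)
  half <- ifelse(tr$run %% 2L == 1L, "odd", "even")
  out <- array(NA_real_, dim = c(2L, length(cond_levels), ncol(mat)),
               dimnames = list(c("odd", "even"), cond_levels, NULL))
  for (h in c("odd", "even")) {
    for (cl in cond_levels) {
      rows <- which(half == h & cond == cl)
      if (!length(rows))
        stop(sprintf("condition '%s' has no trials in the %s-run half",
                     cl, h))
      out[h, cl, ] <- colMeans(mat[rows, , drop = FALSE])
    }
  }
  out
}

#' Split-half voxel reliability
#'
#' Pearson correlation, per voxel, between its 18-condition profile in the
#' odd-run half and in the even-run half. Voxels whose profile is constant in
#' either half get the undefined flag \code{NA} (they rank below all defined
#' values at selection time).
#'
#' @param profiles array from \code{\link{conditionProfiles}}.
#' @return numeric vector of per-voxel reliabilities in [-1, 1], NA where
#'   undefined.
#' @export
computeVoxelReliability <- function(profiles) {
  stopifnot(is.array(profiles), dim(profiles)[1] == 2L)
  nv <- dim(profiles)[3]
  vapply(seq_len(nv), function(v)
    safeCor(profiles["odd", , v], profiles["even", , v]), numeric(1))
}

#' Select the most reliable voxels
#'
#' The \code{k} voxels with the highest split-half reliability; ties at the
#' cutoff are broken toward the lower voxel index, and undefined (NA)
#' reliabilities rank below every defined value. Returned in canonical
#' (ascending index) order.
#'
#' @param reliability numeric vector from \code{\link{computeVoxelReliability}}.
#' @param k number of voxels to select (default 100).
#' @return integer vector of \code{k} voxel indices, sorted ascending.
#' @export
selectReliableVoxels <- function(reliability, k = 100L) {
  k <- as.integer(k)
  defined <- sum(!is.na(reliability))
  if (defined < k)
    stop(sprintf("only %d voxels have defined reliability; %d requested",
                 defined, k))
  key <- ifelse(is.na(reliability), -Inf, reliability)
  ord <- order(-key, seq_along(key))
  sort(ord[seq_len(k)])
}

#' Reliability-based voxel selections for a whole dataset
#'
#' Convenience wrapper running \code{\link{conditionProfiles}},
#' \code{\link{computeVoxelReliability}} and
#' \code{\link{selectReliableVoxels}} over every participant and unilateral
#' region of a dataset.
#'
#' @param dataset a \code{\linkS4class{BetaDataset}}.
#' @param k voxels to keep per unilateral region.
#' @param rois bilateral region names (default: all present).
#' @return nested list \code{[[participant]][[roi_hemi]]} of voxel indices.
#' @export
selectAllReliableVoxels <- function(dataset, k = 100L, rois = NULL) {
  stopifnot(is(dataset, "BetaDataset"))
  ids <- participants(dataset)
  keys <- names(dataset@betas[[1]])
  if (!is.null(rois))
    keys <- keys[sub("_[LR]$", "", keys) %in% rois]
  sel <- list()
  for (p in ids) {
    sel[[p]] <- list()
    for (key in keys) {
      roi <- sub("_[LR]$", "", key)
      hemi <- sub("^.*_", "", key)
      prof <- conditionProfiles(dataset, p, roi, hemi)
      sel[[p]][[key]] <- selectReliableVoxels(computeVoxelReliability(prof), k)
    }
  }
  sel
}

#' Build per-image region representation vectors
#'
#' For every participant, bilateral region and image: the selected
#' left-hemisphere voxel betas concatenated with the selected right-hemisphere
#' betas (left first, each in canonical voxel order), giving a vector of
#' length 2k (200 with the default k = 100). Per-presentation vectors keep
#' the two presentations separate; the averaged vector is the mean of the two
#' raw presentations, taken before normalization. Every stored pattern is
#' z-scored across its entries.
#'
#' @param dataset a \code{\linkS4class{BetaDataset}}.
#' @param selections nested list from \code{\link{selectAllReliableVoxels}}.
#' @return a \code{\linkS4class{RepresentationSet}}.
#' @export
buildRepresentations <- function(dataset,
                                 selections = selectAllReliableVoxels(dataset)) {
  stopifnot(is(dataset, "BetaDataset"))
  tr <- dataset@design@trials
  imgs <- unique(tr[, c("image_id", "category", "quality", "task")])
  rownames(imgs) <- NULL
  ids <- names(selections)
  keys <- names(selections[[1]])
  rois <- unique(sub("_[LR]$", "", keys))
  for (roi in rois)
    if (!all(paste(roi, c("L", "R"), sep = "_") %in% keys))
      stop(sprintf("selections must cover both hemispheres of %s", roi))
  k <- length(selections[[1]][[1]])

  averaged <- list(); per_rep <- list()
  for (p in ids) {
    tr_p <- tr[tr$participant == p, , drop = FALSE]
    rep_trial <- lapply(1:2, function(r)
      match(imgs$image_id,
            ifelse(tr_p$repetition == r, tr_p$image_id, NA_character_)))
    for (r in 1:2)
      if (anyNA(rep_trial[[r]]))
        stop(sprintf("image %s lacks presentation %d for %s",
                     imgs$image_id[which(is.na(rep_trial[[r]]))[1]], r, p))
    averaged[[p]] <- list(); per_rep[[p]] <- list()
    for (roi in rois) {
      left <- betaMatrix(dataset, p, roi, "L")
      right <- betaMatrix(dataset, p, roi, "R")
      sel_l <- selections[[p]][[paste0(roi, "_L")]]
      sel_r <- selections[[p]][[paste0(roi, "_R")]]
      raw <- lapply(1:2, function(r)
        cbind(left[rep_trial[[r]], sel_l, drop = FALSE],
              right[rep_trial[[r]], sel_r, drop = FALSE]))
      avg_raw <- (raw[[1]] + raw[[2]]) / 2
      znorm <- function(m) t(apply(m, 1L, zscore))
      per_rep[[p]][[roi]] <- list(rep1 = znorm(raw[[1]]),
                                  rep2 = znorm(raw[[2]]))
      averaged[[p]][[roi]] <- znorm(avg_raw)
    }
  }
  new("RepresentationSet", averaged = averaged, perRepetition = per_rep,
      imageInfo = imgs, k = as.integer(k), hemisphereOrder = c("L", "R"))
}
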