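#' Parameters of the synthetic beta-pattern generator
#'
#' Controls the generative model behind \code{\link{simulateBetas}}. Each
#' image carries a 5-dimensional latent code per region: a 3-dimensional
#' semantic part (one-hot category direction, scaled by
#' \code{semanticEffect} and a region- and quality-specific gain) and a
#' 2-dimensional quality part (low (0,1), neutral (1,1), high (1,0), scaled
#' by \code{qualityEffect}). In low-level regions the semantic gain increases
#' with image quality (degraded images carry weaker semantic structure); in
#' high-level regions it is constant across quality, and the semantic
#' direction is passed through a mixing transform that is quality-specific
#' when \code{qualityDependentMixing} is TRUE (one shared transform
#' otherwise).
#'
#' Reliable voxels load linearly on the latent code; the remaining voxels
#' carry pure noise. Image-level latent noise and image-level voxel noise are
#' shared by the two presentations of an image (they are reproducible
#' signal), while repetition noise is drawn independently per presentation.
#'
#' @param roiNames bilateral region names (7).
#' @param voxelsPerUnilateralRoi voxels simulated per unilateral region.
#' @param nReliableVoxels voxels per unilateral region that carry signal.
#' @param semanticEffect amplitude of the semantic latent component.
#' @param gains region x quality matrix of semantic gains in [0, 1]
#'   (rows = \code{roiNames}, columns = low/neutral/high). Defaults to
#'   \code{lowLevelGains} for low-level regions and the constant
#'   \code{highLevelGain} for high-level regions.
#' @param lowLevelGains named vector (low, neutral, high) used to fill the
#'   low-level rows of \code{gains}.
#' @param highLevelGain constant gain for high-level regions.
#' @param qualityEffect amplitude of the (weak, distributed) quality latent
#'   component present in every region.
#' @param qualityDependentMixing if TRUE the low-to-high-level semantic
#'   mixing transform differs across quality levels.
#' @param latentNoiseSd sd of image-level latent noise (shared across the two
#'   presentations).
#' @param noiseSd sd of image-level voxel noise (shared across presentations).
#' @param repetitionNoiseSd sd of presentation-specific voxel noise.
#' @param seed integer seed controlling every random draw.
#' @return a validated parameter list (class \code{"SimulationParams"}).
#' @export
simulationParams <- function(roiNames = visualRoiNames(),
                             voxelsPerUnilateralRoi = 150L,
                             nReliableVoxels = 100L,
                             semanticEffect = 1.5,
                             gains = NULL,
                             lowLevelGains = c(low = 0.2, neutral = 0.5,
                                               high = 0.9),
                             highLevelGain = 0.9,
                             qualityEffect = 0.4,
                             qualityDependentMixing = FALSE,
                             latentNoiseSd = 0.4,
                             noiseSd = 0.8,
                             repetitionNoiseSd = 0.8,
                             seed = 1L) {
  if (is.null(gains)) {
    gains <- matrix(NA_real_, length(roiNames), 3,
                    dimnames = list(roiNames, qualityLevels()))
    for (r in roiNames) {
      gains[r, ] <- if (r %in% lowLevelRoiNames())
        lowLevelGains[qualityLevels()] else rep(highLevelGain, 3)
    }
  }
  gains <- as.matrix(gains)
  if (!identical(dim(gains), c(length(roiNames), 3L)))
    stop("gains must be a (regions x 3 qualities) matrix")
  dimnames(gains) <- list(roiNames, qualityLevels())
  if (any(gains < 0 | gains > 1)) stop("semantic gains must lie in [0, 1]")
  if (nReliableVoxels > voxelsPerUnilateralRoi)
    stop("nReliableVoxels cannot exceed voxelsPerUnilateralRoi")
  p <- list(roiNames = roiNames,
            voxelsPerUnilateralRoi = as.integer(voxelsPerUnilateralRoi),
            nReliableVoxels = as.integer(nReliableVoxels),
            semanticEffect = semanticEffect, gains = gains,
            qualityEffect = qualityEffect,
            qualityDependentMixing = isTRUE(qualityDependentMixing),
            latentNoiseSd = latentNoiseSd, noiseSd = noiseSd,
            repetitionNoiseSd = repetitionNoiseSd, seed = as.integer(seed))
  class(p) <- "SimulationParams"
  p
}

.qualityEmbedding <- function(quality) {
  emb <- rbind(low = c(0, 1), neutral = c(1, 1), high = c(1, 0))
  emb[quality, , drop = FALSE]
}

.categoryOneHot <- function(category) {
  diag(3)[match(category, categoryLevels()), , drop = FALSE]
}

# random 3x3 orthogonal matrix (QR of a Gaussian matrix, sign-fixed)
.randomRotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))))
}

#' Simulate trial-level voxel betas with planted structure
#'
#' Generates a \code{\linkS4class{BetaDataset}} over the trials of
#' \code{design} according to the generative model described in
#' \code{\link{simulationParams}}: per image and region a latent code
#' (semantic + quality parts plus image-level latent noise) is mapped to the
#' reliable voxels of each hemisphere by a Gaussian loading matrix;
#' unreliable voxels receive pure noise; the two presentations of an image
#' share the latent draw and the image-level voxel noise but receive
#' independent repetition noise. The whole dataset is a deterministic
#' function of (design, params).
#'
#' @param design a \code{\linkS4class{StimulusDesign}}.
#' @param params a \code{\link{simulationParams}} list.
#' @return a \code{\linkS4class{BetaDataset}}.
#' @export
simulateBetas <- function(design, params = simulationParams()) {
  stopifnot(is(design, "StimulusDesign"), inherits(params, "SimulationParams"))
  tr <- design@trials
  ids <- unique(tr$participant)
  rois <- params$roiNames
  nv <- params$voxelsPerUnilateralRoi
  nr <- params$nReliableVoxels
  imgs <- unique(tr[, c("image_id", "category", "quality")])
  n_img <- nrow(imgs)

  withSeed(params$seed, {
    # population-level structure: semantic mixing transforms per quality
    shared_mix <- .randomRotation()
    mixing <- if (params$qualityDependentMixing) {
      ms <- lapply(qualityLevels(), function(q) .randomRotation())
      names(ms) <- qualityLevels()
      ms
    } else {
      setNames(rep(list(shared_mix), 3), qualityLevels())
    }

    onehot <- .categoryOneHot(imgs$category)        # n_img x 3
    qemb <- .qualityEmbedding(imgs$quality)         # n_img x 2

    betas <- list()
    truth <- list()
    for (p in ids) {
      rows_p <- which(tr$participant == p)
      tr_p <- tr[rows_p, , drop = FALSE]
      img_of_trial <- match(tr_p$image_id, imgs$image_id)
      betas[[p]] <- list()
      truth[[p]] <- list()
      for (roi in rois) {
        g <- params$gains[roi, ]
        gain_img <- g[imgs$quality]
        sem_dir <- onehot
        if (roi %in% highLevelRoiNames()) {
          # high-level semantic direction is a (possibly quality-specific)
          # mix of the category code
          sem_dir <- t(vapply(seq_len(n_img), function(i)
            as.numeric(mixing[[imgs$quality[i]]] %*% onehot[i, ]),
            numeric(3)))
        }
        z_sem <- params$semanticEffect * gain_img * sem_dir
        z_qual <- params$qualityEffect * qemb
        latent <- cbind(z_sem, z_qual) +
          matrix(rnorm(n_img * 5, sd = params$latentNoiseSd), n_img, 5)
        for (hemi in c("L", "R")) {
          rel_idx <- sort(sample.int(nv, nr))
          load <- matrix(rnorm(nr * 5), nr, 5)
          signal_img <- latent %*% t(load)              # n_img x nr
          img_noise <- matrix(rnorm(n_img * nv, sd = params$noiseSd),
                              n_img, nv)
          base <- matrix(0, n_img, nv)
          base[, rel_idx] <- signal_img
          base <- base + img_noise
          mat <- base[img_of_trial, , drop = FALSE] +
            matrix(rnorm(length(rows_p) * nv,
                         sd = params$repetitionNoiseSd),
                   length(rows_p), nv)
          key <- paste(roi, hemi, sep = "_")
          betas[[p]][[key]] <- mat
          truth[[p]][[key]] <- rel_idx
        }
      }
    }
    new("BetaDataset", betas = betas, design = design,
        params = unclass(params), reliableVoxels = truth)
  })
}
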