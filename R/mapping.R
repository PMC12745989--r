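#' Prediction score: linear correlation of actual and predicted vectors
#'
#' Pearson correlation rho = Cov(y, yhat) / sqrt(Var(y) Var(yhat)) between an
#' actual and a predicted pattern vector. Constant vectors make the score
#' undefined (NA).
#'
#' @param actual,predicted numeric vectors of equal length >= 2.
#' @return rho in [-1, 1], or NA when undefined.
#' @export
predictionScore <- function(actual, predicted) {
  safeCor(actual, predicted)
}

#' Fit a per-dimension kernel-regression mapping between two regions
#'
#' One epsilon-insensitive support-vector regressor with a radial basis
#' function kernel per target dimension (C = 1, epsilon = 0.1 by default,
#' matching the configuration used for all mapping and decoding models),
#' trained on inputs standardized with means and standard deviations
#' estimated on the training set only.
#'
#' @param trainX images x d_in matrix of source-region patterns.
#' @param trainY images x d_out matrix of target-region patterns.
#' @param C regularization parameter.
#' @param epsilon epsilon-insensitivity width.
#' @param gamma RBF kernel width; default 1/d_in.
#' @return a \code{MappingModel} (list with the fitted regressors and the
#'   input scaler).
#' @export
fitMapping <- function(trainX, trainY, C = 1, epsilon = 0.1, gamma = NULL) {
  trainX <- as.matrix(trainX); trainY <- as.matrix(trainY)
  stopifnot(nrow(trainX) == nrow(trainY), nrow(trainX) >= 2L)
  if (sd(as.numeric(trainX)) == 0)
    stop("training input matrix is entirely constant")
  ctr <- colMeans(trainX)
  scl <- apply(trainX, 2L, sd)
  scl[scl == 0] <- 1  # constant feature columns carry no information
  Xs <- sweep(sweep(trainX, 2L, ctr), 2L, scl, "/")
  gamma <- gamma %||% (1 / ncol(trainX))
  models <- lapply(seq_len(ncol(trainY)), function(j)
    .svrFit(Xs, trainY[, j], C, epsilon, gamma))
  structure(list(models = models, center = ctr, scale = scl, gamma = gamma,
                 C = C, epsilon = epsilon, d_out = ncol(trainY)),
            class = "MappingModel")
}

# epsilon-SVR fit; when every residual of the mean fits inside the epsilon
# tube libsvm returns an empty model, which is exactly the constant function
.svrFit <- function(Xs, y, C, epsilon, gamma) {
  if (max(y) - min(y) <= 2 * epsilon)
    return(list(constant = mean(range(y))))
  e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
             cost = C, epsilon = epsilon, gamma = gamma, scale = FALSE,
             fitted = FALSE)
}

.svrPredict <- function(model, Xs) {
  if (!is.null(model$constant))
    return(rep(model$constant, nrow(Xs)))
  as.numeric(stats::predict(model, Xs))
}

#' Predict target-region patterns from source-region patterns
#'
#' @param model a \code{MappingModel} from \code{\link{fitMapping}}.
#' @param newX images x d_in matrix of source patterns.
#' @return images x d_out matrix of predicted target patterns.
#' @export
predictMapping <- function(model, newX) {
  stopifnot(inherits(model, "MappingModel"))
  newX <- as.matrix(newX)
  Xs <- sweep(sweep(newX, 2L, model$center), 2L, model$scale, "/")
  preds <- vapply(model$models, function(m)
    .svrPredict(m, Xs), numeric(nrow(Xs)))
  matrix(preds, nrow = nrow(Xs), ncol = model$d_out)
}

.repRows <- function(repSet, participant, roi, imageIds) {
  reps <- repetitionPatterns(repSet, participant, roi)
  if (is.null(reps)) stop("no patterns for that participant/region")
  idx <- match(imageIds, imageInfo(repSet)$image_id)
  if (anyNA(idx)) stop("unknown image id")
  list(rep1 = reps$rep1[idx, , drop = FALSE],
       rep2 = reps$rep2[idx, , drop = FALSE])
}

#' Fit a cross-repetition mapping between two regions
#'
#' Trains the mapping on both cross-repetition directions stacked: source
#' presentation 1 paired with target presentation 2, and source presentation
#' 2 with target presentation 1, so that shared trial-specific noise cannot
#' inflate the learned mapping.
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param participant participant id.
#' @param source,target bilateral region names.
#' @param trainImages image ids to train on.
#' @param ... passed to \code{\link{fitMapping}}.
#' @return a \code{MappingModel}.
#' @export
fitCrossMapping <- function(repSet, participant, source, target, trainImages,
                            ...) {
  a <- .repRows(repSet, participant, source, trainImages)
  b <- .repRows(repSet, participant, target, trainImages)
  fitMapping(rbind(a$rep1, a$rep2), rbind(b$rep2, b$rep1), ...)
}

#' Score a mapping by cross-prediction over repetitions
#'
#' Predicts target presentation-2 patterns from source presentation-1
#' patterns and vice versa, scores every test image's predicted vs actual
#' pattern vector with \code{\link{predictionScore}}, and returns the mean
#' over both directions and all test images (flagged-undefined images are
#' dropped).
#'
#' @param model a \code{MappingModel}.
#' @inheritParams fitCrossMapping
#' @param testImages image ids to score.
#' @return mean rho over test images and directions.
#' @export
crossPredictScore <- function(model, repSet, participant, source, target,
                              testImages) {
  a <- .repRows(repSet, participant, source, testImages)
  b <- .repRows(repSet, participant, target, testImages)
  pred2 <- predictMapping(model, a$rep1)   # predict target rep2 from src rep1
  pred1 <- predictMapping(model, a$rep2)   # and target rep1 from src rep2
  scores <- c(vapply(seq_along(testImages), function(i)
    predictionScore(b$rep2[i, ], pred2[i, ]), numeric(1)),
    vapply(seq_along(testImages), function(i)
      predictionScore(b$rep1[i, ], pred1[i, ]), numeric(1)))
  mean(scores, na.rm = TRUE)
}

#' Fit and score a cross-repetition mapping in one step
#'
#' @inheritParams fitCrossMapping
#' @param testImages image ids held out for scoring.
#' @return mean cross-prediction rho over the test images.
#' @export
crossPredict <- function(repSet, participant, source, target, trainImages,
                         testImages, ...) {
  model <- fitCrossMapping(repSet, participant, source, target, trainImages,
                           ...)
  crossPredictScore(model, repSet, participant, source, target, testImages)
}

#' Repetition-based noise ceiling
#'
#' Per image, the Pearson correlation between the two presentation patterns;
#' averaged over images this bounds any mapping's achievable cross-prediction
#' performance for that participant and region. Images with a constant
#' pattern are flagged, excluded, and counted.
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param participant participant id.
#' @param roi bilateral region name.
#' @return list with \code{perImage} (rho per image), \code{mean} (the
#'   participant/region ceiling), and \code{nExcluded}.
#' @export
noiseCeiling <- function(repSet, participant, roi) {
  reps <- repetitionPatterns(repSet, participant, roi)
  if (is.null(reps)) stop("no patterns for that participant/region")
  n <- nrow(reps$rep1)
  rho <- vapply(seq_len(n), function(i)
    safeCor(reps$rep1[i, ], reps$rep2[i, ]), numeric(1))
  list(perImage = rho, mean = mean(rho, na.rm = TRUE),
       nExcluded = sum(is.na(rho)))
}

#' Noise-ceiling table over participants and regions
#'
#' Participant-level ceilings plus group rows (the mean over participants per
#' region).
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param rois regions (default: all).
#' @return data.frame (participant, roi, rho); group rows have participant
#'   \code{"group"}.
#' @export
noiseCeilingTable <- function(repSet, rois = NULL) {
  ids <- names(repSet@averaged)
  rois <- rois %||% names(repSet@averaged[[1]])
  per <- do.call(rbind, lapply(ids, function(p)
    data.frame(participant = p, roi = rois,
               rho = vapply(rois, function(r)
                 noiseCeiling(repSet, p, r)$mean, numeric(1)),
               stringsAsFactors = FALSE)))
  grp <- do.call(rbind, lapply(rois, function(r)
    data.frame(participant = "group", roi = r,
               rho = mean(per$rho[per$roi == r]), stringsAsFactors = FALSE)))
  rbind(per, grp)
}

.assignFolds <- function(info, folds, stratifyBy = "category") {
  # per quality: equal-size folds, stratified so no fold loses a category
  fold <- integer(nrow(info))
  for (q in unique(info$quality)) {
    rows_q <- which(info$quality == q)
    if (length(rows_q) %% folds != 0L)
      stop(sprintf("%d images of quality '%s' cannot split into %d equal folds",
                   length(rows_q), q, folds))
    if (!is.null(stratifyBy)) {
      for (cc in unique(info[[stratifyBy]][rows_q])) {
        rows_qc <- rows_q[info[[stratifyBy]][rows_q] == cc]
        fold[rows_qc] <- sample(rep(seq_len(folds),
                                    length.out = length(rows_qc)))
      }
    } else {
      fold[rows_q] <- sample(rep(seq_len(folds),
                                 length.out = length(rows_q)))
    }
  }
  fold
}

#' Quality-conditional generalization of an inter-region mapping
#'
#' Repeated cross-validation of a mapping trained on one quality condition
#' and tested on held-out folds of all three. Per repeat, each quality's
#' images are divided into equal folds (stratified by content category by
#' default so no fold loses a category); for each fold index, the model is
#' trained on the remaining folds of the training quality and scored by
#' cross-repetition prediction on the held-out fold of each test quality
#' (the same fold number across qualities).
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param source,target bilateral region names.
#' @param trainQuality quality condition used for training.
#' @param folds number of folds (default 4).
#' @param repeats number of independent fold divisions (default 10).
#' @param seed master seed; each (participant, repeat) cell draws its own
#'   child seed.
#' @param participantIds participants to analyse (default: all).
#' @param stratify stratify folds by category (default TRUE); FALSE gives
#'   pure-random folds.
#' @param ... passed to \code{\link{fitMapping}}.
#' @return data.frame (participant, source, target, train_quality,
#'   test_quality, fold, rep, rho).
#' @export
qualityGeneralization <- function(repSet, source, target,
                                  trainQuality = "low", folds = 4L,
                                  repeats = 10L, seed = 1L,
                                  participantIds = NULL, stratify = TRUE,
                                  ...) {
  stopifnot(is(repSet, "RepresentationSet"),
            trainQuality %in% qualityLevels())
  info <- imageInfo(repSet)
  ids <- participantIds %||% names(repSet@averaged)
  rows <- list()
  for (pi in seq_along(ids)) {
    p <- ids[pi]
    for (rep_i in seq_len(repeats)) {
      fold <- withSeed(childSeed(seed, pi * 1000L + rep_i),
                       .assignFolds(info, folds,
                                    if (stratify) "category" else NULL))
      for (f in seq_len(folds)) {
        train_imgs <- info$image_id[info$quality == trainQuality & fold != f]
        model <- fitCrossMapping(repSet, p, source, target, train_imgs, ...)
        for (q in qualityLevels()) {
          test_imgs <- info$image_id[info$quality == q & fold == f]
          rho <- crossPredictScore(model, repSet, p, source, target,
                                   test_imgs)
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p, source = source, target = target,
            train_quality = trainQuality, test_quality = q, fold = f,
            rep = rep_i, rho = rho, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-participant mean mapping performance by test quality
#'
#' @param table data.frame from \code{\link{qualityGeneralization}}.
#' @return data.frame (participant, source, target, train_quality,
#'   test_quality, rho) averaged over folds and repeats.
#' @export
aggregateMapping <- function(table) {
  agg <- stats::aggregate(rho ~ participant + source + target +
                            train_quality + test_quality,
                          data = table, FUN = mean)
  agg[order(agg$participant, agg$test_quality), , drop = FALSE]
}

#' Does mapping performance depend on test quality?
#'
#' Welch's ANOVA of per-participant mean cross-prediction performance across
#' the three test-quality conditions, with Games-Howell pairwise follow-up;
#' pairs at p < 0.05 are flagged.
#'
#' @param table data.frame from \code{\link{qualityGeneralization}}.
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{anova}, \code{posthoc} (with a
#'   \code{significant} column) and the aggregated per-participant means.
#' @export
mappingSignificance <- function(table, alpha = 0.05) {
  agg <- aggregateMapping(table)
  if (length(unique(agg$participant)) < 2L)
    stop("need at least two participants")
  an <- welchAnova(agg$rho, agg$test_quality)
  ph <- gamesHowell(agg$rho, agg$test_quality)
  ph$significant <- ph$p < alpha
  list(anova = an, posthoc = ph, means = agg)
}
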