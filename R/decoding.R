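#' Spearman rank correlation coefficient (SRCC)
#'
#' Rank agreement between predicted and actual quality scores. On untied
#' data this equals the classical 1 - 6 sum(d_i^2) / (n (n^2 - 1)); with
#' ties (the integer quality targets are heavily tied) mid-ranks are used
#' and the statistic is the Pearson correlation of the rank vectors.
#'
#' @param predicted,actual numeric vectors of equal length >= 2.
#' @return SRCC in [-1, 1], or NA when an input is constant.
#' @export
srcc <- function(predicted, actual) {
  safeCor(predicted, actual, method = "spearman")
}

#' Pearson linear correlation coefficient (PLCC)
#'
#' Linear agreement between predicted and actual quality scores.
#'
#' @param predicted,actual numeric vectors of equal length >= 2.
#' @return PLCC in [-1, 1], or NA when an input is constant.
#' @export
plcc <- function(predicted, actual) {
  safeCor(predicted, actual, method = "pearson")
}

#' Integer quality targets for a representation set
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @return integer vector per image: 1 = low, 2 = neutral, 3 = high.
#' @export
qualityTargets <- function(repSet) {
  match(imageInfo(repSet)$quality, qualityLevels())
}

#' Decode perceived quality from one or more regions
#'
#' Support-vector regression (RBF kernel, C = 1, epsilon = 0.1) of the
#' integer quality targets (1/2/3) on the concatenated repetition-averaged
#' pattern vectors of a region set, evaluated by repeated cross-validation:
#' per repeat the images are divided into equal folds (stratified by quality
#' and category), the model is trained out-of-fold and its continuous
#' out-of-fold predictions are scored with SRCC and PLCC; the reported
#' values are means over repeats.
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param roiSet character vector of 1..7 region names to concatenate.
#' @param participant participant id.
#' @param folds number of folds (default 4).
#' @param repeats number of repeated fold divisions (default 10).
#' @param seed master seed; each repeat draws a child seed.
#' @param C,epsilon support-vector regression hyperparameters.
#' @return list with \code{srcc}, \code{plcc} (means over repeats),
#'   \code{perRepeat} data.frame, and \code{predictions} (per-image
#'   out-of-fold predictions averaged over repeats).
#' @export
decodeQuality <- function(repSet, roiSet, participant, folds = 4L,
                          repeats = 10L, seed = 1L, C = 1, epsilon = 0.1) {
  stopifnot(is(repSet, "RepresentationSet"), length(roiSet) >= 1L)
  info <- imageInfo(repSet)
  X <- do.call(cbind, lapply(roiSet, function(r) {
    m <- averagedPatterns(repSet, participant, r)
    if (is.null(m)) stop("no patterns for region ", r)
    if (nrow(m) != nrow(info)) stop("mismatched image sets across regions")
    m
  }))
  y <- match(info$quality, qualityLevels())
  strat <- interaction(info$quality, info$category, drop = TRUE)
  n <- nrow(X)
  pred_mat <- matrix(NA_real_, repeats, n)
  per_rep <- data.frame(rep = seq_len(repeats), srcc = NA_real_,
                        plcc = NA_real_)
  for (rep_i in seq_len(repeats)) {
    fold <- withSeed(childSeed(seed, rep_i), {
      f <- integer(n)
      for (s in levels(strat)) {
        rows <- which(strat == s)
        f[rows] <- sample(rep(seq_len(folds), length.out = length(rows)))
      }
      f
    })
    preds <- numeric(n)
    ctrscl <- NULL
    for (f in seq_len(folds)) {
      tr_rows <- which(fold != f); te_rows <- which(fold == f)
      ctr <- colMeans(X[tr_rows, , drop = FALSE])
      scl <- apply(X[tr_rows, , drop = FALSE], 2L, sd)
      scl[scl == 0] <- 1
      Xs_tr <- sweep(sweep(X[tr_rows, , drop = FALSE], 2L, ctr), 2L, scl, "/")
      Xs_te <- sweep(sweep(X[te_rows, , drop = FALSE], 2L, ctr), 2L, scl, "/")
      fit <- .svrFit(Xs_tr, y[tr_rows], C, epsilon, gamma = 1 / ncol(X))
      preds[te_rows] <- .svrPredict(fit, Xs_te)
    }
    pred_mat[rep_i, ] <- preds
    per_rep$srcc[rep_i] <- srcc(preds, y)
    per_rep$plcc[rep_i] <- plcc(preds, y)
  }
  list(srcc = mean(per_rep$srcc), plcc = mean(per_rep$plcc),
       perRepeat = per_rep, predictions = colMeans(pred_mat))
}

#' Random-score decoding baseline
#'
#' Correlates uniformly random continuous scores (optionally random integer
#' levels) against the quality targets; its mean is the chance level and its
#' spread the chance variability of SRCC/PLCC at this image count.
#'
#' @param targets integer quality targets.
#' @param repeats number of random draws.
#' @param seed integer seed.
#' @param integerScores draw random integer levels instead of continuous
#'   uniform scores.
#' @return list with per-draw \code{srcc}/\code{plcc} vectors and their
#'   means and standard deviations.
#' @export
randomBaseline <- function(targets, repeats = 100L, seed = 1L,
                           integerScores = FALSE) {
  n <- length(targets)
  withSeed(seed, {
    s <- numeric(repeats); p <- numeric(repeats)
    for (i in seq_len(repeats)) {
      r <- if (integerScores) sample(1:3, n, replace = TRUE) else runif(n)
      s[i] <- srcc(r, targets); p[i] <- plcc(r, targets)
    }
    list(srcc = s, plcc = p,
         meanSrcc = mean(s, na.rm = TRUE), sdSrcc = sd(s),
         meanPlcc = mean(p, na.rm = TRUE), sdPlcc = sd(p))
  })
}

#' Group-level prediction
#'
#' Averages the per-image predicted scores over participants and scores the
#' averaged prediction against the targets (group rows are computed from
#' averaged predictions, not averaged correlations).
#'
#' @param predictionMatrix participants x images matrix of predicted scores
#'   (identical image ordering across participants).
#' @param targets integer quality targets per image.
#' @return list with \code{srcc} and \code{plcc} of the group prediction.
#' @export
groupPrediction <- function(predictionMatrix, targets) {
  predictionMatrix <- as.matrix(predictionMatrix)
  if (ncol(predictionMatrix) != length(targets))
    stop("prediction matrix and targets cover different image sets")
  g <- colMeans(predictionMatrix)
  list(srcc = srcc(g, targets), plcc = plcc(g, targets))
}

#' Decoding results over region sets and participants
#'
#' Runs \code{\link{decodeQuality}} for every requested region set and
#' participant, and adds group rows computed from participant-averaged
#' predictions.
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param roiSets list of character vectors of region names.
#' @param folds,repeats,seed,C,epsilon passed to \code{\link{decodeQuality}}.
#' @return list with \code{table} (participant- and group-level SRCC/PLCC
#'   per set) and \code{predictions} (per set, the participants x images
#'   prediction matrix).
#' @export
decodingTable <- function(repSet, roiSets, folds = 4L, repeats = 10L,
                          seed = 1L, C = 1, epsilon = 0.1) {
  ids <- names(repSet@averaged)
  targets <- qualityTargets(repSet)
  rows <- list(); preds <- list()
  for (si in seq_along(roiSets)) {
    set <- roiSets[[si]]
    set_name <- paste(set, collapse = "+")
    pm <- matrix(NA_real_, length(ids), length(targets),
                 dimnames = list(ids, NULL))
    for (pi in seq_along(ids)) {
      res <- decodeQuality(repSet, set, ids[pi], folds = folds,
                           repeats = repeats,
                           seed = childSeed(seed, si * 10000L + pi),
                           C = C, epsilon = epsilon)
      pm[pi, ] <- res$predictions
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids[pi], roi_set = set_name, srcc = res$srcc,
        plcc = res$plcc, stringsAsFactors = FALSE)
    }
    gp <- groupPrediction(pm, targets)
    rows[[length(rows) + 1L]] <- data.frame(
      participant = "group", roi_set = set_name, srcc = gp$srcc,
      plcc = gp$plcc, stringsAsFactors = FALSE)
    preds[[set_name]] <- pm
  }
  list(table = do.call(rbind, rows), predictions = preds)
}

#' Compare each region set to the all-region joint model
#'
#' Two-sample t test (Welch by default) of each set's participant-level
#' performance against the joint model's, Benjamini-Hochberg corrected at
#' q = 0.1; sets whose mean performance is not significantly different from
#' the joint model are flagged.
#'
#' @param table participant-level rows of a \code{\link{decodingTable}}
#'   result (columns participant, roi_set, and the chosen metric).
#' @param jointSet name of the joint all-region set in \code{roi_set}.
#' @param metric "srcc" (default) or "plcc".
#' @param q false-discovery-rate threshold.
#' @param pooledVariance use the pooled-variance t test instead of Welch.
#' @return data.frame (roi_set, mean_diff, p, p_adj,
#'   not_different_from_joint).
#' @export
compareToJoint <- function(table, jointSet = paste(visualRoiNames(),
                                                   collapse = "+"),
                           metric = c("srcc", "plcc"), q = 0.1,
                           pooledVariance = FALSE) {
  metric <- match.arg(metric)
  tab <- table[table$participant != "group", , drop = FALSE]
  joint <- tab[[metric]][tab$roi_set == jointSet]
  if (length(joint) < 2L) stop("need at least two participants")
  sets <- setdiff(unique(tab$roi_set), jointSet)
  res <- do.call(rbind, lapply(sets, function(s) {
    x <- tab[[metric]][tab$roi_set == s]
    tt <- t.test(x, joint, var.equal = pooledVariance)
    data.frame(roi_set = s, mean_diff = mean(x) - mean(joint),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$not_different_from_joint <- res$p_adj >= q
  res
}
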