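#' Compute a representational dissimilarity matrix
#'
#' Pairwise dissimilarity between the rows of a pattern matrix. The default
#' metric is the correlation distance 1 - Pearson r (entries in [0, 2]);
#' Euclidean distance is available as an alternative.
#'
#' @param patterns item x dimension numeric matrix (>= 2 items, >= 2 dims).
#' @param items optional data.frame of item labels (id, category, quality);
#'   defaults to row names or index.
#' @param metric "pearson_distance" (default) or "euclidean".
#' @return an \code{\linkS4class{RDM}}.
#' @export
computeRDM <- function(patterns, items = NULL,
                       metric = c("pearson_distance", "euclidean")) {
  metric <- match.arg(metric)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L || ncol(patterns) < 2L)
    stop("need at least 2 items and 2 dimensions")
  sds <- apply(patterns, 1L, sd)
  if (metric == "pearson_distance" && any(sds == 0))
    stop(sprintf("constant pattern for item %d cannot enter a correlation-distance RDM",
                 which(sds == 0)[1]))
  v <- if (metric == "pearson_distance") {
    d <- 1 - cor(t(patterns))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
  } else {
    as.matrix(dist(patterns))
  }
  if (is.null(items)) {
    ids <- rownames(patterns) %||% as.character(seq_len(nrow(patterns)))
    items <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  dimnames(v) <- NULL
  new("RDM", values = v, items = items, metric = metric)
}

#' Ideal semantic model RDM
#'
#' Content categories are encoded as orthogonal one-hot vectors (1,0,0),
#' (0,1,0), (0,0,1); the model dissimilarity is their correlation distance:
#' 0 for same-category pairs and exactly 1.5 for different-category pairs
#' (the Pearson correlation of two distinct length-3 one-hot vectors is
#' -1/2).
#'
#' @param categories character vector of "face"/"object"/"scene" per item.
#' @param ids optional item ids.
#' @return an \code{\linkS4class{RDM}} with entries in \{0, 1.5\}.
#' @export
idealSemanticRDM <- function(categories, ids = NULL) {
  if (!all(categories %in% categoryLevels()))
    stop("unknown category label: ",
         paste(setdiff(categories, categoryLevels()), collapse = ", "))
  n <- length(categories)
  v <- 1.5 * (outer(categories, categories, "!="))
  mode(v) <- "numeric"
  diag(v) <- 0
  items <- data.frame(id = ids %||% as.character(seq_len(n)),
                      category = categories, stringsAsFactors = FALSE)
  new("RDM", values = v, items = items, metric = "pearson_distance")
}

#' Ideal quality model RDM
#'
#' Quality levels are embedded as low = (0,1), neutral = (1,1),
#' high = (1,0), so that neutral is equidistant (distance 1) from low and
#' high while low and high are sqrt(2) apart; the model dissimilarity is the
#' Euclidean distance between embeddings.
#'
#' @param qualities character vector of "low"/"neutral"/"high" per item.
#' @param ids optional item ids.
#' @return an \code{\linkS4class{RDM}} with entries in \{0, 1, sqrt(2)\}.
#' @export
idealQualityRDM <- function(qualities, ids = NULL) {
  if (!all(qualities %in% qualityLevels()))
    stop("unknown quality label: ",
         paste(setdiff(qualities, qualityLevels()), collapse = ", "))
  emb <- .qualityEmbedding(qualities)
  v <- as.matrix(dist(emb))
  dimnames(v) <- NULL
  items <- data.frame(id = ids %||% as.character(seq_along(qualities)),
                      quality = qualities, stringsAsFactors = FALSE)
  new("RDM", values = v, items = items, metric = "euclidean")
}

#' Information content of a region RDM with respect to a model RDM
#'
#' Pearson (optionally Spearman) correlation between the strictly-upper
#' triangles of a measured RDM and an ideal model RDM over the same items in
#' the same order; a scalar measure of how strongly the region's patterns
#' encode the model's labels. Optionally restricted to the items of one
#' quality condition (the sub-RDM of those items). A constant triangle makes
#' the correlation undefined and returns NA with a \code{reason} attribute.
#'
#' @param roiRdm measured \code{\linkS4class{RDM}}.
#' @param idealRdm model \code{\linkS4class{RDM}} over the same items.
#' @param quality optional quality level to restrict to.
#' @param method "pearson" (default) or "spearman".
#' @return correlation in [-1, 1], or flagged NA when undefined.
#' @export
informationContent <- function(roiRdm, idealRdm, quality = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(roiRdm, "RDM"), is(idealRdm, "RDM"))
  if (nrow(roiRdm@values) != nrow(idealRdm@values))
    stop("RDMs cover different numbers of items")
  if (!identical(roiRdm@items$id, idealRdm@items$id))
    stop("RDM item orderings differ")
  if (!is.null(quality)) {
    keep <- which(roiRdm@items$quality == quality)
    if (length(keep) < 3L) stop("too few items in that quality condition")
    roiRdm <- subsetRDM(roiRdm, keep)
    idealRdm <- subsetRDM(idealRdm, keep)
  }
  a <- upperTriVec(roiRdm@values)
  b <- upperTriVec(idealRdm@values)
  if (sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant RDM triangle"
    return(out)
  }
  cor(a, b, method = method)
}

#' Entrywise group average of participant RDMs
#'
#' @param rdms list of \code{\linkS4class{RDM}}s over identical item sets in
#'   identical order.
#' @return the entrywise-mean \code{\linkS4class{RDM}}.
#' @export
groupAverageRDM <- function(rdms) {
  stopifnot(length(rdms) >= 1L, all(vapply(rdms, is, TRUE, "RDM")))
  ref <- rdms[[1]]
  for (r in rdms[-1])
    if (!identical(r@items$id, ref@items$id))
      stop("participant RDMs have mismatched item indices")
  v <- Reduce(`+`, lapply(rdms, rdmValues)) / length(rdms)
  new("RDM", values = v, items = ref@items, metric = ref@metric)
}

#' Information-content table over participants, regions and conditions
#'
#' Per participant and region: the semantic information content within each
#' quality condition (sub-RDM restriction) and over all items, and the
#' quality information content over all items.
#'
#' @param repSet a \code{\linkS4class{RepresentationSet}}.
#' @param rois regions to include (default: all in the set).
#' @param method correlation method passed to \code{\link{informationContent}}.
#' @return data.frame (participant, roi, quality, label_type, r).
#' @export
infoContentTable <- function(repSet, rois = NULL, method = "pearson") {
  stopifnot(is(repSet, "RepresentationSet"))
  ids <- names(repSet@averaged)
  rois <- rois %||% names(repSet@averaged[[1]])
  info <- imageInfo(repSet)
  item_tab <- data.frame(id = info$image_id, category = info$category,
                         quality = info$quality, stringsAsFactors = FALSE)
  sem <- idealSemanticRDM(info$category, ids = info$image_id)
  sem@items$quality <- info$quality
  qual <- idealQualityRDM(info$quality, ids = info$image_id)
  qual@items$quality <- info$quality
  rows <- list()
  for (p in ids) {
    for (roi in rois) {
      rdm <- computeRDM(averagedPatterns(repSet, p, roi), items = item_tab)
      for (q in c(qualityLevels(), "all")) {
        qq <- if (q == "all") NULL else q
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, roi = roi, quality = q, label_type = "semantic",
          r = as.numeric(informationContent(rdm, sem, quality = qq,
                                            method = method)),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, roi = roi, quality = "all", label_type = "quality",
        r = as.numeric(informationContent(rdm, qual, method = method)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F test for equal group means under unequal variances
#' (Welch-Satterthwaite denominator degrees of freedom).
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list with F, df1, df2 and p.
#' @export
welchAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  ns <- tapply(values, groups, length)
  vs <- tapply(values, groups, stats::var)
  if (any(ns < 2L)) stop("every group needs at least two observations")
  if (any(vs == 0) && any(ns[vs == 0] < 2L))
    stop("zero-variance group with fewer than two observations")
  ht <- oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = unname(ht$p.value))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise comparisons after a heteroscedastic ANOVA: Welch t statistics per
#' pair with Welch-Satterthwaite degrees of freedom, referred to the
#' studentized-range distribution with the total number of groups.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return data.frame (group1, group2, diff, se, t, df, p).
#' @export
gamesHowell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L)) stop("every group needs at least two observations")
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, stats::var)
  combs <- utils::combn(levels(groups), 2)
  out <- apply(combs, 2L, function(pair) {
    i <- pair[1]; j <- pair[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    tstat <- (ms[i] - ms[j]) / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                     (vs[j] / ns[j])^2 / (ns[j] - 1))
    # the studentized-range algorithm is undefined below 2 denominator df
    p <- if (is.finite(df) && df >= 2)
      ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    else NA_real_
    c(diff = unname(ms[i] - ms[j]), se = unname(sqrt(se2)),
      t = unname(tstat), df = unname(df), p = unname(p))
  })
  data.frame(group1 = combs[1, ], group2 = combs[2, ], t(out),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare information content across quality conditions within a region
#'
#' Welch's ANOVA of per-participant semantic information content across the
#' three quality conditions, with Games-Howell pairwise follow-up.
#'
#' @param table data.frame from \code{\link{infoContentTable}}.
#' @param roi region to test.
#' @param label_type which information content to test (default "semantic").
#' @return list with elements \code{anova} (\code{\link{welchAnova}} result)
#'   and \code{posthoc} (\code{\link{gamesHowell}} table).
#' @export
compareAcrossQuality <- function(table, roi, label_type = "semantic") {
  sub <- table[table$roi == roi & table$label_type == label_type &
                 table$quality %in% qualityLevels(), , drop = FALSE]
  if (!nrow(sub)) stop("no rows for that region/label type")
  list(anova = welchAnova(sub$r, sub$quality),
       posthoc = gamesHowell(sub$r, sub$quality))
}
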