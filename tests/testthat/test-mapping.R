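test_that("prediction score equals the covariance-ratio formula", {
  expect_equal(predictionScore(1:5, 1:5), 1)
  expect_equal(predictionScore(1:5, -(1:5)), -1)
  y <- c(1, 2, 3, 4); yh <- c(1, 2, 3, 5)
  # hand oracle: Cov / sqrt(Var * Var)
  oracle <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(predictionScore(y, yh), oracle, tolerance = 1e-12)
  expect_equal(predictionScore(y, yh), 0.9827076, tolerance = 1e-6)
  expect_true(is.na(predictionScore(rep(1, 4), 1:4)))
})

test_that("mapping fits recover an identity transform and respect scaling", {
  set.seed(11)
  X <- matrix(rnorm(120 * 12), 120, 12)
  m <- fitMapping(X[1:100, ], X[1:100, ])
  pred <- predictMapping(m, X[101:120, ])
  rho <- mean(vapply(1:20, function(i)
    predictionScore(X[100 + i, ], pred[i, ]), numeric(1)))
  expect_gt(rho, 0.85)  # identity map learned well above chance

  # duplicated training rows leave the fit unchanged within solver tolerance
  m2 <- fitMapping(rbind(X[1:100, ], X[1:50, ]),
                   rbind(X[1:100, ], X[1:50, ]))
  pred2 <- predictMapping(m2, X[101:120, ])
  expect_lt(mean(abs(pred2 - pred)), 0.15)

  # tiny training sets still produce a finite fitted model
  m3 <- fitMapping(X[1:2, ], matrix(rnorm(24), 2, 12))
  pred3 <- predictMapping(m3, X[3:40, ])
  expect_true(all(is.finite(pred3)))
  expect_error(fitMapping(matrix(1, 10, 5), matrix(rnorm(50), 10, 5)),
               "constant")
})

test_that("cross-prediction is symmetric in repetition labels and null-calibrated", {
  set.seed(21)
  n <- 24; d <- 16
  cats <- rep(categoryLevels(), length.out = n)
  quals <- rep(qualityLevels(), each = n / 3)
  base <- matrix(rnorm(n * d), n, d)
  rs <- syntheticRepSet(base + matrix(rnorm(n * d, sd = 0.3), n, d),
                        base + matrix(rnorm(n * d, sd = 0.3), n, d),
                        cats, quals)
  ids <- imageInfo(rs)$image_id
  # single region predicted from itself: well above chance, below the
  # repetition-reliability ceiling
  rho <- crossPredict(rs, "sub01", "calcarine", "calcarine",
                      trainImages = ids[1:16], testImages = ids[17:24])
  ceiling <- noiseCeiling(rs, "sub01", "calcarine")$mean
  expect_gt(rho, 0.25)
  expect_lte(rho, ceiling + 0.05)

  # swapping repetition labels leaves the averaged score unchanged
  rs_sw <- rs
  rs_sw@perRepetition$sub01$calcarine <-
    rev(rs@perRepetition$sub01$calcarine)
  names(rs_sw@perRepetition$sub01$calcarine) <- c("rep1", "rep2")
  m <- fitCrossMapping(rs, "sub01", "calcarine", "calcarine", ids[1:16])
  m_sw <- fitCrossMapping(rs_sw, "sub01", "calcarine", "calcarine", ids[1:16])
  s <- crossPredictScore(m, rs, "sub01", "calcarine", "calcarine", ids[17:24])
  s_sw <- crossPredictScore(m_sw, rs_sw, "sub01", "calcarine", "calcarine",
                            ids[17:24])
  # identical up to solver tolerance (training rows are reordered)
  expect_equal(s, s_sw, tolerance = 1e-4)

  # pure-noise source: mean rho near zero over seeds
  null_scores <- vapply(1:50, function(seed) {
    set.seed(seed + 300)
    src1 <- matrix(rnorm(n * d), n, d); src2 <- matrix(rnorm(n * d), n, d)
    tgt <- matrix(rnorm(n * d), n, d)
    rs0 <- syntheticRepSet(src1, src2, cats, quals)
    rs0@perRepetition$sub01$fusiform <-
      list(rep1 = t(apply(tgt, 1, zscore)), rep2 = t(apply(tgt, 1, zscore)))
    rs0@averaged$sub01$fusiform <- t(apply(tgt, 1, zscore))
    crossPredict(rs0, "sub01", "calcarine", "fusiform",
                 trainImages = ids[1:16], testImages = ids[17:24])
  }, numeric(1))
  expect_lt(abs(mean(null_scores)), 0.05)
})

test_that("noise ceiling matches its per-image definition", {
  set.seed(5)
  n <- 10; d <- 20
  r1 <- matrix(rnorm(n * d), n, d)
  rs <- syntheticRepSet(r1, r1, rep("face", n), rep("low", n))
  expect_equal(noiseCeiling(rs, "sub01", "calcarine")$mean, 1,
               tolerance = 1e-12)

  # independent repetitions: ceiling near zero over seeds
  means <- vapply(1:50, function(seed) {
    set.seed(seed)
    rs0 <- syntheticRepSet(matrix(rnorm(n * d), n, d),
                           matrix(rnorm(n * d), n, d),
                           rep("face", n), rep("low", n))
    noiseCeiling(rs0, "sub01", "calcarine")$mean
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)

  # group ceiling is the arithmetic mean of participant ceilings
  st <- smallStudy()
  tab <- noiseCeilingTable(st$repSet, rois = "lingual")
  per <- tab$rho[tab$participant != "group"]
  expect_equal(tab$rho[tab$participant == "group"], mean(per),
               tolerance = 1e-12)
})

test_that("fold assignment partitions images exactly, stratified by category", {
  st <- smallStudy()
  qg <- qualityGeneralization(st$repSet, "lingual", "middle_occipital",
                              trainQuality = "low", folds = 4, repeats = 2,
                              seed = 77, participantIds = "sub01")
  # every (repeat, test quality) combination covers all four folds
  expect_identical(nrow(qg), 2L * 4L * 3L)
  expect_true(all(table(qg$rep, qg$test_quality) == 4))
  expect_true(all(qg$rho >= -1 & qg$rho <= 1))

  # infeasible fold count errors
  expect_error(qualityGeneralization(st$repSet, "lingual",
                                     "middle_occipital", folds = 5,
                                     repeats = 1, seed = 1,
                                     participantIds = "sub01"),
               "folds")

  # determinism from (dataset, seed)
  qg2 <- qualityGeneralization(st$repSet, "lingual", "middle_occipital",
                               trainQuality = "low", folds = 4, repeats = 2,
                               seed = 77, participantIds = "sub01")
  expect_identical(qg, qg2)
})

test_that("mapping significance reuses the Welch/Games-Howell machinery", {
  set.seed(13)
  tab <- expand.grid(participant = sprintf("sub%02d", 1:8),
                     source = "a", target = "b", train_quality = "low",
                     test_quality = qualityLevels(), fold = 1:2, rep = 1,
                     stringsAsFactors = FALSE)
  tab$rho <- rnorm(nrow(tab), mean = ifelse(tab$test_quality == "low",
                                            0.6, 0.2), sd = 0.05)
  ms <- mappingSignificance(tab)
  agg <- aggregateMapping(tab)
  direct <- welchAnova(agg$rho, agg$test_quality)
  expect_equal(ms$anova$F, direct$F, tolerance = 1e-12)
  expect_true(ms$anova$p < 0.05)
  expect_true(any(ms$posthoc$significant))
  expect_error(mappingSignificance(tab[tab$participant == "sub01", ]),
               "two participants")
})
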