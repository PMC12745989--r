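test_that("SRCC matches the rank-difference formula on untied data", {
  expect_equal(srcc(c(1, 3, 2, 4), c(1, 2, 3, 4)), 1 - 6 * 2 / (4 * 15))
  expect_equal(srcc(c(1, 3, 2, 4), c(1, 2, 3, 4)), 0.8)
  expect_equal(srcc(1:6, 1:6), 1)
  expect_equal(srcc(6:1, 1:6), -1)
  # general untied case agrees with the printed formula
  set.seed(2)
  for (i in 1:10) {
    a <- sample(20); b <- sample(20)
    d <- rank(a) - rank(b)
    expect_equal(srcc(a, b), 1 - 6 * sum(d^2) / (20 * (20^2 - 1)),
                 tolerance = 1e-12)
  }
  # ties: mid-rank Pearson-on-ranks
  a <- c(1, 1, 2, 3); b <- c(2, 1, 2, 3)
  expect_equal(srcc(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_true(is.na(srcc(rep(1, 5), 1:5)))
})

test_that("PLCC matches the hand-computed Pearson oracle", {
  x <- c(1, 2, 3); y <- c(2, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(plcc(x, y), oracle, tolerance = 1e-12)
  expect_equal(plcc(x, y), sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(plcc(3 * (1:8) + 2, 1:8), 1)
  expect_equal(plcc(-2 * (1:8) + 1, 1:8), -1)
  expect_true(is.na(plcc(rep(2, 4), 1:4)))
  # monotone increasing linear transform: SRCC and PLCC both 1
  expect_equal(srcc(2 * (1:9) + 5, 1:9), 1)
})

test_that("decoding covers every image once per repeat and concatenates features", {
  st <- smallStudy()
  res <- decodeQuality(st$repSet, c("calcarine", "lingual"), "sub01",
                       folds = 4, repeats = 2, seed = 5)
  n <- nrow(imageInfo(st$repSet))
  expect_length(res$predictions, n)
  expect_true(all(is.finite(res$predictions)))
  expect_identical(nrow(res$perRepeat), 2L)
  expect_true(all(abs(res$perRepeat$srcc) <= 1))
  # determinism
  res2 <- decodeQuality(st$repSet, c("calcarine", "lingual"), "sub01",
                        folds = 4, repeats = 2, seed = 5)
  expect_identical(res$predictions, res2$predictions)
  # a planted quality code is decodable well above chance
  expect_gt(res$srcc, 0.3)
})

test_that("permuted targets decode at chance", {
  # decoding against randomly permuted quality labels has zero expected SRCC
  st <- smallStudy()
  res <- decodeQuality(st$repSet, "calcarine", "sub01", folds = 4,
                       repeats = 1, seed = 6)
  y <- qualityTargets(st$repSet)
  set.seed(8)
  null_srcc <- replicate(200, srcc(res$predictions, sample(y)))
  expect_lt(abs(mean(null_srcc)), 0.05)
})

test_that("the random baseline is centred on zero and shrinks with n", {
  targets <- rep(1:3, each = 32)
  rb <- randomBaseline(targets, repeats = 200, seed = 3)
  expect_lt(abs(rb$meanSrcc), 0.05)
  expect_lt(abs(rb$meanPlcc), 0.05)
  rb_small <- randomBaseline(rep(1:3, each = 8), repeats = 200, seed = 3)
  expect_lt(rb$sdSrcc, rb_small$sdSrcc)  # sd shrinks with image count
  # seeded determinism and the integer-score option
  expect_identical(randomBaseline(targets, 10, seed = 4)$srcc,
                   randomBaseline(targets, 10, seed = 4)$srcc)
  rb_int <- randomBaseline(targets, repeats = 50, seed = 5,
                           integerScores = TRUE)
  expect_lt(abs(rb_int$meanSrcc), 0.1)
})

test_that("group prediction averages predictions, not correlations", {
  targets <- rep(1:3, each = 10)
  set.seed(9)
  # identical participants: group equals individual
  p1 <- targets + rnorm(30, sd = 0.5)
  gp <- groupPrediction(rbind(p1, p1), targets)
  expect_equal(gp$srcc, srcc(p1, targets), tolerance = 1e-12)
  # single participant: identity
  expect_equal(groupPrediction(matrix(p1, 1), targets)$plcc,
               plcc(p1, targets), tolerance = 1e-12)
  expect_error(groupPrediction(matrix(p1, 1), targets[1:10]), "image sets")

  # independent zero-mean noise: group beats the mean individual
  wins <- 0L
  for (seed in 1:50) {
    set.seed(seed + 100)
    preds <- t(replicate(6, targets + rnorm(30, sd = 1.2)))
    grp <- groupPrediction(preds, targets)$srcc
    ind <- mean(apply(preds, 1, srcc, actual = targets))
    if (grp >= ind) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("comparison to the joint model applies Welch t and BH correctly", {
  set.seed(17)
  joint_name <- paste(visualRoiNames(), collapse = "+")
  mk <- function(set, mu) data.frame(participant = sprintf("sub%02d", 1:14),
                                     roi_set = set,
                                     srcc = rnorm(14, mu, 0.08),
                                     plcc = rnorm(14, mu, 0.08),
                                     stringsAsFactors = FALSE)
  tab <- rbind(mk(joint_name, 0.60), mk("calcarine", 0.25),
               mk("lingual", 0.59))
  res <- compareToJoint(tab)
  expect_false(res$not_different_from_joint[res$roi_set == "calcarine"])
  expect_true(res$not_different_from_joint[res$roi_set == "lingual"])
  # BH oracle: brute-force step-up on the same p-values
  p <- res$p
  m <- length(p); o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  expect_equal(res$p_adj, adj, tolerance = 1e-12)

  # BH monotonicity: adding a more extreme p never de-flags a significant set
  tab2 <- rbind(tab, mk("cuneus", 0.05))
  res2 <- compareToJoint(tab2)
  sig1 <- res$roi_set[!res$not_different_from_joint]
  sig2 <- res2$roi_set[!res2$not_different_from_joint]
  expect_true(all(sig1 %in% sig2))
  expect_error(compareToJoint(tab[tab$participant == "sub01", ]),
               "two participants")
})

test_that("power: a one-SD planted deficit is detected after FDR at n = 14", {
  joint_name <- paste(visualRoiNames(), collapse = "+")
  detected <- vapply(1:200, function(seed) {
    set.seed(seed)
    tab <- rbind(data.frame(participant = sprintf("sub%02d", 1:14),
                            roi_set = joint_name,
                            srcc = rnorm(14, 0.6, 0.1), plcc = 0,
                            stringsAsFactors = FALSE),
                 data.frame(participant = sprintf("sub%02d", 1:14),
                            roi_set = "calcarine",
                            srcc = rnorm(14, 0.48, 0.1), plcc = 0,
                            stringsAsFactors = FALSE))
    !compareToJoint(tab)$not_different_from_joint
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})
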