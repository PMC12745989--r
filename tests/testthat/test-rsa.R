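test_that("correlation-distance RDMs match the hand-computed Pearson oracle", {
  p <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 2, 1))
  rdm <- computeRDM(p)
  v <- rdmValues(rdm)
  # independent oracle: raw-sum Pearson formula
  pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  expect_equal(v[1, 2], 1 - pearson(p[1, ], p[2, ]), tolerance = 1e-12)
  expect_equal(v[1, 2], 1 - 0.9819805, tolerance = 1e-6)
  expect_equal(v[1, 3], 2, tolerance = 1e-12)   # exact negation
  expect_equal(diag(v), rep(0, 3))
  expect_equal(v, t(v))
  expect_equal(rdmValues(computeRDM(rbind(p[1, ], p[1, ])))[1, 2], 0,
               tolerance = 1e-12)
  expect_error(computeRDM(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})

test_that("ideal model RDMs take their closed-form values exactly", {
  cats <- c("face", "face", "object", "scene")
  sem <- rdmValues(idealSemanticRDM(cats))
  expect_identical(sem[1, 2], 0)
  expect_identical(sem[1, 3], 1.5)
  expect_true(all(sem %in% c(0, 1.5)))
  # the encoding route agrees: 1 - cor of one-hot category vectors
  onehot <- diag(3)[match(cats, categoryLevels()), ]
  expect_equal(sem, 1 - cor(t(onehot)), tolerance = 1e-12)

  quals <- c("low", "neutral", "high", "low")
  qv <- rdmValues(idealQualityRDM(quals))
  expect_equal(qv[1, 2], 1)         # low <-> neutral
  expect_equal(qv[2, 3], 1)         # neutral <-> high
  expect_equal(qv[1, 3], sqrt(2))   # low <-> high
  expect_identical(qv[1, 4], 0)
  # neutral equidistant from low and high
  expect_equal(qv[1, 2], qv[2, 3])
  expect_error(idealSemanticRDM(c("face", "dog")), "unknown")
  expect_error(idealQualityRDM(c("low", "ugly")), "unknown")
})

test_that("information content correlates upper triangles and flags degenerates", {
  cats <- rep(categoryLevels(), each = 3)
  ideal <- idealSemanticRDM(cats)
  expect_equal(informationContent(ideal, ideal), 1, tolerance = 1e-12)
  rev_rdm <- new("RDM", values = {
    v <- 2 - rdmValues(ideal); diag(v) <- 0; v
  }, items = rdmItems(ideal), metric = "pearson_distance")
  expect_equal(informationContent(rev_rdm, ideal), -1, tolerance = 1e-12)
  const <- idealSemanticRDM(rep("face", 5))
  out <- informationContent(const, const)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "constant")
})

test_that("information content is invariant to common item reordering", {
  st <- smallStudy()
  info <- imageInfo(st$repSet)
  items <- data.frame(id = info$image_id, category = info$category,
                      quality = info$quality, stringsAsFactors = FALSE)
  pat <- averagedPatterns(st$repSet, "sub01", "cuneus")
  rdm <- computeRDM(pat, items = items)
  sem <- idealSemanticRDM(info$category, ids = info$image_id)
  r0 <- informationContent(rdm, sem)
  set.seed(3)
  perm <- sample(nrow(info))
  rdm_p <- computeRDM(pat[perm, ], items = items[perm, ])
  sem_p <- idealSemanticRDM(info$category[perm], ids = info$image_id[perm])
  expect_equal(informationContent(rdm_p, sem_p), r0, tolerance = 1e-12)
  # spearman variant is defined and bounded
  rs <- informationContent(rdm, sem, method = "spearman")
  expect_true(abs(rs) <= 1)
})

test_that("group averaging suppresses independent noise", {
  cats <- rep(categoryLevels(), each = 4)
  sem <- idealSemanticRDM(cats)
  n <- length(cats)
  onehot <- diag(3)[match(cats, categoryLevels()), ]
  wins <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    rdms <- lapply(1:6, function(i) {
      pat <- onehot %*% matrix(rnorm(3 * 10), 3, 10) +
        matrix(rnorm(n * 10, sd = 1.5), n, 10)
      computeRDM(pat)
    })
    grp <- informationContent(groupAverageRDM(rdms), sem)
    ind <- mean(vapply(rdms, informationContent, numeric(1), idealRdm = sem))
    if (grp >= ind) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90% of replicates

  # identities
  expect_equal(rdmValues(groupAverageRDM(list(sem))), rdmValues(sem))
  flip <- new("RDM", values = {
    v <- 2 - rdmValues(sem); diag(v) <- 0; v
  }, items = rdmItems(sem), metric = "pearson_distance")
  avg <- rdmValues(groupAverageRDM(list(sem, flip)))
  expect_true(sd(upperTri <- avg[upper.tri(avg)]) < 1e-12)
  bad <- new("RDM", values = rdmValues(sem)[1:6, 1:6],
             items = rdmItems(sem)[1:6, ], metric = "pearson_distance")
  expect_error(groupAverageRDM(list(sem, bad)), "mismatched")
})

test_that("Welch ANOVA matches the textbook-formula oracle", {
  g1 <- c(1, 2, 3, 4); g2 <- c(1, 2, 3, 4); g3 <- c(11, 12, 13, 14)
  res <- welchAnova(c(g1, g2, g3), rep(c("a", "b", "c"), each = 4))

  # independent hand evaluation of Welch's formulas
  groups <- list(g1, g2, g3)
  ns <- sapply(groups, length); ms <- sapply(groups, mean)
  vs <- sapply(groups, var)
  w <- ns / vs
  mw <- sum(w * ms) / sum(w)
  k <- 3
  num <- sum(w * (ms - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (ns - 1)) / (k^2 - 1)
  F_oracle <- num / (1 + 2 * lam * (k - 2))
  df2_oracle <- 1 / (3 * lam)
  p_oracle <- pf(F_oracle, k - 1, df2_oracle, lower.tail = FALSE)
  expect_equal(res$F, F_oracle, tolerance = 1e-9)
  expect_equal(res$df2, df2_oracle, tolerance = 1e-9)
  expect_equal(res$p, p_oracle, tolerance = 1e-9)

  # no between-group effect
  set.seed(1)
  x <- rnorm(12)
  null_res <- welchAnova(rep(x[1:4], 3) + rnorm(12, sd = 1e-8),
                         rep(c("a", "b", "c"), each = 4))
  expect_gt(null_res$p, 0.9)
})

test_that("Welch ANOVA keeps its type-I rate under heteroscedastic nulls", {
  set.seed(99)
  rejections <- replicate(2000, {
    x <- c(rnorm(14, 0, 1), rnorm(14, 0, 2), rnorm(14, 0, 4))
    welchAnova(x, rep(1:3, each = 14))$p < 0.05
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("Games-Howell matches an independent formula evaluation", {
  set.seed(7)
  vals <- c(rnorm(6, 0), rnorm(8, 1, 2), rnorm(5, 3, 0.5))
  grp <- rep(c("a", "b", "c"), times = c(6, 8, 5))
  res <- gamesHowell(vals, grp)
  # oracle for the a-b pair
  a <- vals[grp == "a"]; b <- vals[grp == "b"]
  se2 <- var(a) / 6 + var(b) / 8
  t_o <- (mean(a) - mean(b)) / sqrt(se2)
  df_o <- se2^2 / ((var(a) / 6)^2 / 5 + (var(b) / 8)^2 / 7)
  p_o <- ptukey(abs(t_o) * sqrt(2), 3, df_o, lower.tail = FALSE)
  row <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_equal(row$t, t_o, tolerance = 1e-9)
  expect_equal(row$df, df_o, tolerance = 1e-9)
  expect_equal(row$p, p_o, tolerance = 1e-9)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("quality-graded low-level gains are detected, flat high-level gains are not", {
  # single-seed check of the direction (the multi-seed rates live in the
  # acceptance suite)
  st <- smallStudy()
  ict <- infoContentTable(st$repSet, rois = c("calcarine", "fusiform"))
  m <- aggregate(r ~ roi + quality, ict[ict$label_type == "semantic" &
                                          ict$quality != "all", ], mean)
  calc <- m$r[m$roi == "calcarine"][match(qualityLevels(),
                                          m$quality[m$roi == "calcarine"])]
  expect_true(all(diff(calc) > 0))
  fus <- m$r[m$roi == "fusiform"][match(qualityLevels(),
                                        m$quality[m$roi == "fusiform"])]
  expect_lt(max(fus) - min(fus), max(calc) - min(calc))
})
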