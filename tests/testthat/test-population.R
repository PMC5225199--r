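test_that("metric matrix building normalizes and flags degenerate columns", {
  X <- as.data.frame(simulateMetricMatrix(nCells = 43, seed = 5))
  X$constant <- 7
  mm <- buildMetricMatrix(X)
  expect_equal(mm$n_cells, 43)
  expect_true(all(abs(colMeans(mm$scaled[, !mm$near_constant])) < 1e-9))
  expect_true(all(abs(apply(mm$scaled[, !mm$near_constant], 2, sd) - 1) < 1e-9))
  expect_true(mm$near_constant[["constant"]])

  Xna <- X; Xna$m01[3] <- NA
  expect_warning(buildMetricMatrix(Xna), "excluded")
})

test_that("redundancy exclusion drops duplicates and listed correlates only", {
  set.seed(11)
  X <- as.data.frame(matrix(rnorm(100 * 4), 100,
                            dimnames = list(NULL, c("a", "b", "c", "d"))))
  X$dup_a <- X$a                                  # r = 1 duplicate
  mm <- normalizeAndExclude(buildMetricMatrix(X), candidates = character(0))
  expect_true("dup_a" %in% mm$excluded)           # duplicates always go
  expect_true(all(c("a", "b", "c", "d") %in% mm$included))  # |r| < 0.3 kept

  # a listed candidate strongly correlated with a retained metric is excluded
  X2 <- X[, 1:4]
  X2$seg_count <- X2$a * 2 + rnorm(100, 0, 0.1)   # r > 0.98 with a
  mm2 <- normalizeAndExclude(buildMetricMatrix(X2), candidates = "seg_count")
  expect_true("seg_count" %in% mm2$excluded)
  lg <- mm2$exclusion_log
  expect_equal(lg$reason[lg$metric == "seg_count"], "redundant")
  expect_equal(lg$partner[lg$metric == "seg_count"], "a")
  # the same column survives when not listed and below the duplicate bar
  mm3 <- normalizeAndExclude(buildMetricMatrix(X2), candidates = character(0))
  expect_true("seg_count" %in% mm3$included)
})

test_that("correlation-matrix PCA has the trace identity and stated fractions", {
  mm <- buildMetricMatrix(as.data.frame(simulateMetricMatrix(seed = 2)))
  pca <- runPCA(mm)
  expect_equal(sum(pca$eigenvalues), pca$n_metrics, tolerance = 1e-9)
  expect_equal(sum(pca$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  # eigenvalue 6.9 over 27 metrics accounts for 26 percent (rounded)
  expect_equal(round(100 * 6.9 / 27), 26)
  expect_equal(round(100 * 4.1 / 27), 15)
  # cross-check against prcomp on the same normalized data
  pr <- prcomp(mm$scaled, center = FALSE, scale. = FALSE)
  expect_equal(pca$eigenvalues, unname(pr$sdev^2 * (43 - 1) / (43 - 1)),
               tolerance = 1e-6)
})

test_that("eigenvalue significance: planted factors found, noise rejected", {
  X <- simulateMetricMatrix(nCells = 43, nFactors = 1,
                            loadingStrength = 2, seed = 31)
  mm <- buildMetricMatrix(as.data.frame(X))
  pca <- runPCA(mm)
  mc <- significantComponents(pca, nCells = 43, nNull = 500, seed = 1)
  bs <- significantComponents(pca, method = "broken_stick")
  expect_equal(mc$n_significant, 1L)
  expect_equal(bs$n_significant, 1L)
  expect_error(significantComponents(pca, nNull = 50), "at least 100")
  # broken-stick thresholds for 3 metrics
  l3 <- list(eigenvalues = c(2, 0.7, 0.3), n_metrics = 3,
             scores = matrix(0, 5, 3))
  class(l3) <- "PCAResult"
  b3 <- significantComponents(l3, method = "broken_stick")
  expect_equal(b3$thresholds, c(1 + 1 / 2 + 1 / 3, 1 / 2 + 1 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("bootstrap z-scores separate loaded from noise metrics deterministically", {
  X <- simulateMetricMatrix(nCells = 43, nFactors = 2, seed = 8)
  mm <- buildMetricMatrix(as.data.frame(X))
  pca <- runPCA(mm)
  b1 <- bootstrapCoefficients(mm, pca, nBoot = 400, seed = 99)
  b2 <- bootstrapCoefficients(mm, pca, nBoot = 400, seed = 99)
  expect_identical(b1$z, b2$z)
  # factor-1 block loads on PC1 with z > 2; most pure-noise metrics do not
  expect_true(all(b1$z[1:9, 1] > 2))
  expect_gt(mean(b1$z[19:27, 1] < 2), 0.8)
  expect_true(all(is.finite(b1$z)))
})

test_that("sign correction keeps bootstrapped components aligned", {
  # re-implement one replicate to confirm the non-negative scalar product
  X <- simulateMetricMatrix(nCells = 30, nFactors = 1, seed = 14)
  mm <- buildMetricMatrix(as.data.frame(X))
  pca <- runPCA(mm)
  set.seed(5)
  idx <- sample.int(30, 30, replace = TRUE)
  eg <- eigen(cor(mm$scaled[idx, ]), symmetric = TRUE)
  v <- eg$vectors[, 1]
  v <- v * sign(sum(v * pca$components[, 1]))
  expect_gte(sum(v * pca$components[, 1]), 0)
})

test_that("excluded-metric regressions recover carried variance", {
  X <- as.data.frame(simulateMetricMatrix(nCells = 43, nFactors = 1,
                                          loadingStrength = 2, seed = 21))
  X$dup <- X$m01                          # duplicate of a loaded metric
  mm <- normalizeAndExclude(buildMetricMatrix(X), candidates = character(0))
  pca <- runPCA(mm)
  reg <- regressExcluded(mm, pca, components = 1)
  r2dup <- reg$r_squared[reg$metric == "dup"]
  # the duplicate's variance is carried by the loaded component
  expect_gt(r2dup, 0.4)
  expect_true(reg$flagged[reg$metric == "dup"])
  # white noise regressed on scores explains almost nothing
  X2 <- X; X2$noise <- rnorm(43)
  mmn <- normalizeAndExclude(buildMetricMatrix(X2), candidates = "noise")
  # force-list the noise column as excluded for the regression interface
  mmn$excluded <- union(mmn$excluded, "noise")
  mmn$included <- setdiff(mmn$included, "noise")
  regn <- regressExcluded(mmn, runPCA(mmn), components = 1)
  expect_lt(regn$r_squared[regn$metric == "noise"], 0.2)
})

test_that("Ward clustering separates blobs and reports none for one cloud", {
  set.seed(3)
  blob <- rbind(matrix(rnorm(20 * 5), 20), matrix(rnorm(20 * 5) + 10, 20))
  colnames(blob) <- paste0("m", 1:5)
  wc <- wardClustering(buildMetricMatrix(as.data.frame(blob)))
  expect_true(wc$separable)
  expect_equal(wc$k, 2L)
  expect_equal(length(unique(wc$membership[1:20])), 1L)

  cloud <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("m", 1:5)))
  wc1 <- wardClustering(buildMetricMatrix(as.data.frame(cloud)))
  expect_false(wc1$separable)
  expect_equal(wc1$k, 1L)

  # permuting rows leaves the partition unchanged (labels are arbitrary)
  perm <- sample(40)
  wcp <- wardClustering(buildMetricMatrix(as.data.frame(blob[perm, ])))
  back <- wcp$membership[order(perm)]
  expect_equal(length(unique(back[1:20])), 1L)
  expect_equal(length(unique(back[21:40])), 1L)
  expect_true(back[1] != back[21])
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLinkageNewick(wc$hclust, nwk)
  expect_match(readLines(nwk), "^\\(")
})

test_that("random-branching baselines match their closed forms", {
  ab <- randomBranchingBaselines("analytic")
  expect_equal(ab$pair_angle_mean, 90)
  expect_equal(ab$pair_angle_sd, sqrt(pi^2 / 4 - 2) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(ab$tilt_mean, 67.5)
  expect_equal(ab$tilt_sd, sqrt(3 * pi^2 / 8 - 2 - (3 * pi / 8)^2) * 180 / pi,
               tolerance = 1e-12)
  mc <- randomBranchingBaselines("monte_carlo", nSamples = 2e5, seed = 12)
  expect_lt(abs(mc$pair_angle_mean - 90), 3 * mc$pair_angle_se)
  expect_lt(abs(mc$tilt_mean - 67.5), 3 * mc$tilt_se)
  expect_error(randomBranchingBaselines("monte_carlo", nSamples = 100),
               "at least 1000")
})
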