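test_that("layer binning follows the equal-strata rule with INL-ward ties", {
  ly <- LayerModel(0, 50)
  cases <- list(list(y = 15, bin = "S2"),     # 15/50 in [0.2, 0.4)
                list(y = -5, bin = "INL"),
                list(y = 20, bin = "S2"),     # boundary -> lower-index stratum
                list(y = 10, bin = "S1"),
                list(y = 0,  bin = "INL"),
                list(y = 50, bin = "S5"),
                list(y = 55, bin = "GCL"))
  for (cs in cases)
    expect_equal(as.character(annotateLayers(cs$y, ly)), cs$bin)
  # binning partitions the points of a full reconstruction
  m <- cachedCell()$morphology
  bins <- annotateLayers(m, morphMetadata(m)$layers)
  expect_equal(sum(table(bins)), nPoints(m))
  expect_error(LayerModel(10, 10), "degenerate")
})

test_that("major-axis alignment rotates the principal axis to vertical and is an isometry", {
  m <- makeFixture("caterpillar", k = 6)
  rot <- function(m, R) {
    p <- morphPoints(m)
    X <- t(R %*% t(cbind(p$x, p$y, p$z)))
    p$x <- X[, 1]; p$y <- X[, 2]; p$z <- X[, 3]
    new("Morphology", points = p, soma = list(), metadata = list())
  }
  a <- 30 * pi / 180
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  for (R in list(diag(3), Rz, Rx, Rx %*% Rz)) {
    mt <- rot(m, R)
    ma <- alignMajorAxis(mt)
    pa <- morphPoints(ma)
    axis <- eigen(stats::cov(cbind(pa$x, pa$y, pa$z)), symmetric = TRUE)$vectors[, 1]
    dev <- acos(min(1, abs(axis[2]))) * 180 / pi
    expect_lt(dev, 1)                                  # within 1 degree
    D0 <- stats::dist(cbind(morphPoints(mt)$x, morphPoints(mt)$y, morphPoints(mt)$z))
    D1 <- stats::dist(cbind(pa$x, pa$y, pa$z))
    expect_lt(max(abs(D0 - D1)) / max(D0), 1e-9)       # isometry
  }
  line <- makeFixture("cylinder")
  expect_error(alignMajorAxis(line), "collinear")
})

test_that("field splitting conserves surface area and recovers generator truth", {
  # uniform vertical cylinder, no soma: 50/50 split at the midpoint
  cyl <- makeFixture("cylinder", radius = 0.5, length = 10, n = 21)
  fs <- splitDendriticFields(cyl, 5)
  expect_equal(fs$distal_fraction, 50, tolerance = 1e-9)
  expect_equal(fs$distal_fraction + fs$proximal_fraction, 100, tolerance = 1e-9)
  expect_error(splitDendriticFields(cyl, 11), "within the arbor")

  g <- cachedCell()
  fs2 <- splitDendriticFields(g$morphology, g$truth$y_split)
  expect_equal(fs2$distal_fraction + fs2$proximal_fraction, 100,
               tolerance = 1e-9)
  # analysis recovers the generator's exact bookkeeping within 2 percent
  expect_equal(fs2$distal_fraction, g$truth$distal_fraction, tolerance = 0.02)
  expect_equal(sum(table(fs2$side)), nPoints(g$morphology))
})

test_that("the automatic split depth lands between the bistratified peaks", {
  m <- cachedCell()$morphology
  w <- autoSplitDepth(m)
  expect_gt(w, 12)   # below the lobular mass in S1-S2
  expect_lt(w, 36)   # above the arboreal mass in S4-S5
})
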