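test_that("the detector applies the 80 percent swelling criterion exactly", {
  hit <- detectVaricosities(profileMorphology(c(0.4, 0.4, 0.8, 0.4, 0.4)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$diameter, 0.8)

  miss <- detectVaricosities(profileMorphology(c(0.4, 0.7, 0.4)))
  expect_equal(nrow(miss), 0L)         # ratio 1.75 below 1.8

  # exactly at threshold: 0.72 / 0.4 = 1.8 counts (>= 80 percent increase)
  edge <- detectVaricosities(profileMorphology(c(0.4, 0.4, 0.72, 0.4, 0.4)))
  expect_equal(nrow(edge), 1L)

  # terminal swelling: distal flank requirement waived
  term <- detectVaricosities(profileMorphology(c(0.4, 0.4, 0.4, 0.9)))
  expect_equal(nrow(term), 1L)
  expect_true(term$terminal)
})

test_that("the detector is scale invariant and reports valid ratios", {
  g <- cachedCell()
  m <- g$morphology
  v1 <- detectVaricosities(m)
  p <- morphPoints(m)
  p$radius <- p$radius * 7.3
  v2 <- detectVaricosities(new("Morphology", points = p, soma = m@soma,
                               metadata = m@metadata))
  expect_equal(v1$point_id, v2$point_id)
  expect_equal(v2$diameter, 7.3 * v1$diameter, tolerance = 1e-12)
})

test_that("detection recovers every inserted varicosity and nothing else", {
  for (s in c(1, 4)) {
    g <- generateAII(seed = s)
    v <- detectVaricosities(g$morphology)
    expect_setequal(v$point_id, g$truth$varicosities$point_id)
    tr <- g$truth$varicosities[order(g$truth$varicosities$point_id), ]
    expect_equal(v$diameter, tr$diameter, tolerance = 1e-12)
    expect_equal(nrow(v), g$truth$n_varicosities)   # bookkeeping
  }
})

test_that("varicosity statistics match brute-force nearest neighbours", {
  two <- data.frame(x = c(0, 5), y = 0, z = 0, diameter = c(1, 1))
  st <- varicosityStats(two)
  expect_equal(st$nn_mean, 5)
  expect_equal(st$nn_min, 5)
  expect_equal(st$nn_max, 5)

  three <- data.frame(x = c(0, 2, 5), y = 0, z = 0, diameter = 1)
  st3 <- varicosityStats(three)
  expect_equal(st3$nn_mean, mean(c(2, 2, 3)))
  expect_equal(st3$nn_max, 3)

  set.seed(7)
  rnd <- data.frame(x = runif(40), y = runif(40), z = runif(40), diameter = 1)
  str <- varicosityStats(rnd)
  D <- as.matrix(dist(rnd[, 1:3])); diag(D) <- Inf
  expect_equal(str$nn_mean, mean(apply(D, 1, min)), tolerance = 1e-12)

  one <- varicosityStats(data.frame(x = 0, y = 0, z = 0, diameter = 1))
  expect_true(is.na(one$nn_mean))       # NN needs at least two
})

test_that("order/layer/shell varicosity profiles partition the total count", {
  g <- cachedCell()
  m <- g$morphology
  layers <- morphMetadata(m)$layers
  v <- detectVaricosities(m, layers = layers)
  pf <- varicosityProfiles(m, v, "central_shaft", layers = layers)
  expect_equal(sum(pf$by_order$n), nrow(v))
  expect_equal(sum(pf$by_layer$n), nrow(v))
  expect_equal(sum(pf$by_shell$n), nrow(v))
  # density definition: one varicosity on a 10 um order-2 segment -> 0.1/um
  shaft <- data.frame(id = 1:3, type = 0L, x = 0, y = c(0, 2, 4), z = 0,
                      radius = 0.4, parent = c(-1L, 1L, 2L))
  side <- data.frame(id = 4:13, type = 0L, x = 1:10, y = 2, z = 0,
                     radius = 0.2, parent = c(2L, 4:12))
  side$radius[5] <- 0.45                # one swelling mid-branch (ratio 2.25)
  ctv <- Morphology(rbind(shaft, side))
  vv <- detectVaricosities(ctv)
  expect_equal(nrow(vv), 1L)
  pf2 <- varicosityProfiles(ctv, vv, "central_shaft")
  d2 <- pf2$by_order$density[pf2$by_order$order == 2]
  expect_equal(d2, 1 / 10, tolerance = 1e-9)
})

test_that("lobular varicosities run larger than arboreal ones in synthesis", {
  g <- cachedCell()
  tr <- g$truth$varicosities
  expect_gt(mean(tr$diameter[tr$kind == "lobular"]),
            mean(tr$diameter[tr$kind == "arboreal"]))
  expect_true(all(tr$diameter >= 0.39 & tr$diameter <= 2.7))
})
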