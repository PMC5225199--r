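test_that("partition asymmetry anchors: tip 0, stub 1, mixed tree mean 0.6", {
  yt <- partitionAsymmetry(decomposeSegments(makeFixture("y_tree")))
  expect_equal(yt$per_bifurcation$value, 0)

  st <- partitionAsymmetry(decomposeSegments(stubTree()))
  root_pa <- st$per_bifurcation$value[st$per_bifurcation$node_id == 2]
  expect_equal(root_pa, 1)

  mx <- partitionAsymmetry(decomposeSegments(mixedTree()))
  expect_equal(sort(mx$per_bifurcation$value), c(0, 0, 1, 1, 1))
  expect_equal(mx$mean, 0.6)

  none <- partitionAsymmetry(decomposeSegments(makeFixture("cylinder")))
  expect_true(is.na(none$mean))
})

test_that("bifurcation angles use daughter chords and handle degenerate cases", {
  # planar Y with daughters at +-45 degrees from the parent axis -> 90
  ya <- bifurcationAngles(decomposeSegments(makeFixture("y_tree")),
                          makeFixture("y_tree"))
  expect_equal(unname(ya$angles), 90, tolerance = 1e-9)

  # collinear opposite daughters -> 180
  opp <- treeMorphology(x = c(0, 0, 1, -1), y = c(0, 1, 1, 1), z = rep(0, 4),
                        r = rep(0.3, 4), parent = c(-1, 1, 2, 2))
  oa <- bifurcationAngles(decomposeSegments(opp), opp)
  expect_equal(unname(oa$angles), 180, tolerance = 1e-9)
})

test_that("bifurcation tilts anchor at 180 forward and 0 backward", {
  # one daughter continues straight, one doubles back alongside the parent
  m <- treeMorphology(x = c(0, 0, 0, 0.05), y = c(0, 1, 2, 0.1),
                      z = rep(0, 4), r = rep(0.3, 4),
                      parent = c(-1, 1, 2, 2))
  bt <- bifurcationTilts(decomposeSegments(m), m)
  # the reported value is the smaller (most backward) of the two
  expect_lt(unname(bt$tilts), 5)
  fwd <- treeMorphology(x = c(0, 0, 0, 1), y = c(0, 1, 2, 1.0),
                        z = rep(0, 4), r = rep(0.3, 4),
                        parent = c(-1, 1, 2, 2))
  bt2 <- bifurcationTilts(decomposeSegments(fwd), fwd)
  # daughters: straight ahead (180) and sideways (90); min is 90
  expect_equal(unname(bt2$tilts), 90, tolerance = 1e-6)
})

test_that("fractal dimension is 1 for straight growth and near 2 for random walks", {
  straight <- fractalDimension(decomposeSegments(makeFixture("cylinder")),
                               makeFixture("cylinder"))
  expect_equal(straight$mean, 1, tolerance = 1e-9)

  # five independent 1e4-step walks as separate trees of one morphology;
  # the cell value averages the per-branch estimates
  set.seed(42)
  n <- 10000L
  walks <- lapply(1:5, function(w) {
    xyz <- apply(matrix(stats::rnorm(3 * n), ncol = 3), 2, cumsum)
    data.frame(id = (w - 1L) * n + seq_len(n), type = 0L,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = 0.1,
               parent = c(-1L, (w - 1L) * n + seq_len(n - 1L)))
  })
  rw <- Morphology(do.call(rbind, walks))
  d <- fractalDimension(decomposeSegments(rw), rw)
  expect_equal(d$mean, 2, tolerance = 0.1)

  hx <- makeFixture("helix", pitch = 1, radius = 1, turns = 3)
  dh <- fractalDimension(decomposeSegments(hx), hx)
  expect_gt(dh$mean, 1)
  expect_lt(dh$mean, 2)
})

test_that("helicity is zero for planar paths and signed for helices", {
  zig <- Morphology(data.frame(id = 1:8, type = 0L,
                               x = c(0, 1, 2, 3, 4, 5, 6, 7),
                               y = c(0, 1, 0, 1, 0, 1, 0, 1), z = 0,
                               radius = 0.2, parent = c(-1L, 1:7)))
  hz <- helicity(decomposeSegments(zig), zig)
  expect_equal(hz$mean, 0, tolerance = 1e-12)

  hr <- makeFixture("helix", handedness = 1)
  hl <- makeFixture("helix", handedness = -1)
  h1 <- helicity(decomposeSegments(hr), hr)
  h2 <- helicity(decomposeSegments(hl), hl)
  expect_gt(h1$mean, 0)
  expect_true(all(h1$per_window > 0))      # constant sign along the helix
  expect_equal(h2$mean, -h1$mean, tolerance = 1e-12)
})

test_that("euclidean distance statistics match brute force", {
  ray <- makeFixture("radial_ray", length = 10, n = 101)
  ed <- euclideanDistanceStats(ray)
  expect_equal(ed$mean, 5, tolerance = 1e-9)
  expect_equal(ed$max, 10, tolerance = 1e-9)

  m <- cachedCell()$morphology
  ctr <- somaCentroid(m)
  p <- morphPoints(m)
  brute <- sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2 + (p$z - ctr[3])^2)
  ed2 <- euclideanDistanceStats(m)
  expect_equal(ed2$mean, mean(brute), tolerance = 1e-12)
  expect_equal(ed2$max, max(brute), tolerance = 1e-12)
})

test_that("soma metrics approximate closed forms for spheres and cylinders", {
  sph <- sphericalSoma(R = 5, center = c(0, 0, 0), nContours = 50,
                       nVertices = 72)
  sm <- somaMetrics(sph)
  expect_equal(sm$volume, 4 / 3 * pi * 125, tolerance = 0.02)
  expect_equal(sm$surface_area, 4 * pi * 25, tolerance = 0.05)

  # stack of identical circles = cylinder h 10, r 2
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  cyl <- lapply(seq(0, 10, length.out = 21), function(zz)
    list(z = zz, x = 2 * cos(th), y = 2 * sin(th)))
  smc <- somaMetrics(cyl)
  expect_equal(smc$volume, pi * 4 * 10, tolerance = 0.01)

  # single circular contour r 3: projection only
  single <- list(list(z = 0, x = 3 * cos(th), y = 3 * sin(th)))
  sms <- somaMetrics(single)
  expect_true(is.na(sms$volume))
  expect_equal(sms$projection_area, pi * 9, tolerance = 0.01)
  expect_equal(sms$projection_perimeter, 2 * pi * 3, tolerance = 0.01)
  expect_equal(sms$feret_max, 6, tolerance = 0.01)
  expect_equal(sms$feret_min, 6, tolerance = 0.01)
})

test_that("diameter correction hits the target exactly and is idempotent", {
  g <- cachedCell()
  cd <- correctDiameters(g$morphology, target = 0.23)
  sg <- decomposeSegments(cd$morphology)
  thin10 <- sort(sg$segments$min_diameter)[1:10]
  expect_equal(mean(thin10), 0.23, tolerance = 1e-12)
  cd2 <- correctDiameters(cd$morphology, target = 0.23)
  expect_equal(cd2$shift, 0, tolerance = 1e-12)

  expect_error(correctDiameters(makeFixture("y_tree")), "at least 10")
})

test_that("capacitance is surface area times specific capacitance", {
  expect_equal(estimateCapacitance(1000), 10)
  cyl <- makeFixture("cylinder", radius = 0.5, length = 10)
  expect_equal(estimateCapacitance(cyl), 2 * pi * 0.5 * 10 * 0.01,
               tolerance = 1e-9)
  # arithmetic on the population-mean soma and dendrite areas
  expect_equal(estimateCapacitance(197 + 1770), 19.67, tolerance = 1e-9)
})

test_that("the cell summary row is complete, consistent and deterministic", {
  g <- cachedCell()
  m <- g$morphology
  cs <- cellSummary(m, ySplit = g$truth$y_split)
  expect_equal(cs$n_segments, cs$n_nodes + cs$n_endings)
  expect_equal(cs$n_primary_dendrites, g$truth$n_stems)
  cs2 <- cellSummary(generateAII(seed = 1)$morphology,
                     ySplit = g$truth$y_split)
  num <- vapply(cs, is.numeric, logical(1))
  expect_equal(unlist(cs[num]), unlist(cs2[num]), tolerance = 1e-12)

  cyl <- cellSummary(makeFixture("cylinder"))
  expect_equal(cyl$n_primary_dendrites, 1)
  expect_equal(cyl$n_nodes, 0)
  expect_equal(cyl$n_endings, 1)
})
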