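test_that("segment decomposition satisfies the node/ending identities on fixtures", {
  cases <- list(
    list(m = makeFixture("balanced_tree", depth = 2), nodes = 3, endings = 4),
    list(m = makeFixture("balanced_tree", depth = 3), nodes = 7, endings = 8),
    list(m = makeFixture("cylinder"), nodes = 0, endings = 1),
    list(m = makeFixture("caterpillar", k = 5), nodes = 5, endings = 6))
  for (cs in cases) {
    sg <- decomposeSegments(cs$m)
    expect_equal(sg$n_nodes, cs$nodes)
    expect_equal(sg$n_endings, cs$endings)
    expect_equal(nrow(sg$segments), cs$nodes + cs$endings)
    # every point belongs to exactly one segment: own points partition the
    # non-root points
    own <- unlist(lapply(sg$paths, `[`, -1L))
    expect_equal(sort(own),
                 sort(morphPoints(cs$m)$id[morphPoints(cs$m)$parent != -1L]))
  }
})

test_that("both branch-ordering schemes follow their increment rules", {
  yt <- decomposeSegments(makeFixture("y_tree"))
  expect_equal(sort(yt$segments$order_centrifugal), c(1, 2, 2))
  expect_equal(sort(yt$segments$order_shaft), c(1, 1, 2))
  # the thicker daughter continues at order 1
  thick <- yt$segments[yt$segments$order_shaft == 1 &
                         !is.na(yt$segments$parent_segment), ]
  thin <- yt$segments[yt$segments$order_shaft == 2, ]
  expect_gt(thick$first_radius, thin$first_radius)

  ct <- decomposeSegments(makeFixture("caterpillar", k = 5))
  expect_equal(max(ct$segments$order_shaft), 2)
  expect_equal(max(ct$segments$order_centrifugal), 6)

  g <- cachedCell()
  sg <- decomposeSegments(g$morphology)
  expect_true(all(sg$segments$order_shaft <= sg$segments$order_centrifugal))
  # centrifugal order = 1 + number of ancestor bifurcations
  for (k in sample(nrow(sg$segments), 20)) {
    depth <- 0L; pp <- sg$segments$parent_segment[k]
    while (!is.na(pp)) { depth <- depth + 1L; pp <- sg$segments$parent_segment[pp] }
    expect_equal(sg$segments$order_centrifugal[k], depth + 1L)
  }
})

test_that("segment geometry matches closed forms for cylinders, cones, arcs", {
  # cylinder r = 0.5, L = 10
  xyz <- cbind(0, seq(0, 10, length.out = 11), 0)
  gcyl <- segmentGeometry(xyz, rep(0.5, 11))
  expect_equal(gcyl$surface, 2 * pi * 0.5 * 10, tolerance = 1e-9)
  expect_equal(gcyl$volume, pi * 0.25 * 10, tolerance = 1e-9)
  expect_equal(gcyl$contraction, 1, tolerance = 1e-12)

  # single cone frustum r 1 -> 0.5, L = 4 (axial volume formula)
  gfr <- segmentGeometry(rbind(c(0, 0, 0), c(0, 4, 0)), c(1, 0.5))
  expect_equal(gfr$volume, pi * 4 / 3 * (1 + 0.5 + 0.25), tolerance = 1e-9)
  expect_equal(gfr$surface, pi * 1.5 * sqrt(16 + 0.25), tolerance = 1e-9)

  # semicircular arc: contraction -> 2 / pi as the sampling refines
  th <- seq(0, pi, length.out = 2001)
  garc <- segmentGeometry(cbind(cos(th), sin(th), 0), rep(0.1, 2001))
  expect_equal(garc$contraction, 2 / pi, tolerance = 1e-6)

  # coincident points are skipped, not fatal
  gdup <- segmentGeometry(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                          c(0.2, 0.2, 0.2))
  expect_equal(gdup$path_length, 1)
})

test_that("per-order profiles conserve whole-cell totals", {
  g <- cachedCell()
  sg <- decomposeSegments(g$morphology)
  for (scheme in c("central_shaft", "centrifugal")) {
    op <- orderProfiles(sg, scheme)
    expect_equal(sum(op$length), sum(sg$segments$path_length),
                 tolerance = 1e-9)
    expect_equal(sum(op$surface), sum(sg$segments$surface), tolerance = 1e-9)
    expect_equal(sum(op$n_segments), nrow(sg$segments))
    expect_equal(sum(op$n_nodes), sg$n_nodes)
    expect_equal(sum(op$n_endings), sg$n_endings)
  }
  ct <- decomposeSegments(makeFixture("caterpillar", k = 5))
  opc <- orderProfiles(ct, "central_shaft")
  expect_equal(opc$n_segments[opc$order == 2], 5)  # all side branches order 2
})
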