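test_that("Sholl crossings and shell sums behave on analytic fixtures", {
  ray <- makeFixture("radial_ray", length = 10.5, n = 106)
  sp <- shollProfile(ray, step = 1)
  expect_equal(sp$crossings[1:10], rep(1, 10))   # one crossing per sphere 1..10
  expect_equal(sum(sp$shells$length), 10.5, tolerance = 1e-9)

  g <- cachedCell()
  m <- g$morphology
  v <- detectVaricosities(m)
  sg <- decomposeSegments(m)
  sp2 <- shollProfile(m, step = 1, varicosities = v)
  expect_equal(sum(sp2$shells$length), sum(sg$segments$path_length),
               tolerance = 1e-9)
  expect_equal(sum(sp2$shells$surface), sum(sg$segments$surface),
               tolerance = 1e-9)
  expect_equal(sum(sp2$shells$volume), sum(sg$segments$volume),
               tolerance = 1e-9)
  expect_equal(sum(sp2$shells$n_nodes), sg$n_nodes)
  expect_equal(sum(sp2$shells$n_endings), sg$n_endings)
  expect_equal(sum(sp2$shells$n_varicosities), nrow(v))
  expect_error(shollProfile(m, step = 0), "positive")

  # a vertex exactly on a sphere: crossing counted once, point in inner shell
  onSphere <- Morphology(data.frame(id = 1:3, type = 0L,
                                    x = c(0, 2, 3.5), y = 0, z = 0,
                                    radius = 0.2, parent = c(-1L, 1L, 2L)))
  spo <- shollProfile(onSphere, step = 1, centroid = c(0, 0, 0))
  expect_equal(spo$crossings[2], 1)    # the r = 2 sphere crossed exactly once
  expect_equal(sum(spo$shells$length), 3.5, tolerance = 1e-12)
})

test_that("laminar profile clips edges and fractions sum to one", {
  ly <- LayerModel(0, 50)
  inS2 <- Morphology(data.frame(id = 1:5, type = 0L, x = 0:4,
                                y = 13, z = 0, radius = 0.2,
                                parent = c(-1L, 1:4)))
  lp <- laminarProfile(inS2, ly)
  expect_equal(lp$length_fraction[lp$layer == "S2"], 1)
  expect_equal(sum(lp$length_fraction), 1, tolerance = 1e-9)

  # edge spanning the S2/S3 boundary (y 18 -> 22, boundary 20): split 50/50
  span <- Morphology(data.frame(id = 1:2, type = 0L, x = 0, y = c(18, 22),
                                z = 0, radius = 0.2, parent = c(-1L, 1L)))
  ls <- laminarProfile(span, ly)
  expect_equal(ls$length[ls$layer == "S2"], 2, tolerance = 1e-9)
  expect_equal(ls$length[ls$layer == "S3"], 2, tolerance = 1e-9)

  g <- cachedCell()
  m <- g$morphology
  sg <- decomposeSegments(m)
  lg <- laminarProfile(m, morphMetadata(m)$layers)
  expect_equal(sum(lg$length), sum(sg$segments$path_length), tolerance = 1e-9)
  expect_equal(sum(lg$n_nodes), sg$n_nodes)
})

test_that("2D hulls match polygon closed forms with exact calipers", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))
  h <- convexHull2D(sq, "xz")
  expect_equal(h$area, 1, tolerance = 1e-12)
  expect_equal(h$perimeter, 4, tolerance = 1e-12)
  expect_equal(h$feret_max, sqrt(2), tolerance = 1e-12)
  expect_equal(h$feret_min, 1, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hex <- convexHull2D(cbind(cos(th), 0, sin(th)), "xz")
  expect_equal(hex$area, 3 * sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(hex$feret_min, sqrt(3), tolerance = 1e-9)
  expect_equal(hex$feret_max, 2, tolerance = 1e-9)

  # interior points change nothing
  h2 <- convexHull2D(rbind(sq, c(0.5, 0, 0.5), c(0.2, 0, 0.7)), "xz")
  expect_equal(h2$area, h$area)
  expect_equal(h2$feret_min, h$feret_min)
  expect_true(h$area <= h$feret_max * h$feret_min + 1e-12)

  expect_error(convexHull2D(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "xz"),
               "degenerate")
})

test_that("3D hulls match closed forms and are rotation invariant", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- convexHull3D(cube)
  expect_equal(h$volume, 1, tolerance = 1e-12)
  expect_equal(h$surface, 6, tolerance = 1e-12)

  a <- 2
  tet <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  ht <- convexHull3D(tet)
  expect_equal(ht$volume, a^3 / (6 * sqrt(2)), tolerance = 1e-9)

  g <- cachedCell()
  p <- morphPoints(g$morphology)
  X <- cbind(p$x, p$y, p$z)
  h0 <- convexHull3D(X)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  h1 <- convexHull3D(X %*% t(R))
  expect_equal(h1$volume, h0$volume, tolerance = 1e-9)
  expect_equal(h1$surface, h0$surface, tolerance = 1e-9)

  expect_error(convexHull3D(cbind(runif(10), runif(10), 0)), "coplanar")
})

test_that("field hulls: arboreal larger than lobular; projection ignores depth", {
  g <- cachedCell()
  fm <- fieldMetrics(g$morphology, g$truth$y_split)
  expect_true(fm$arboreal_larger)

  sqm <- makeFixture("square_arbor")
  fms <- fieldMetrics(sqm, 20)
  expect_equal(fms$arboreal$area, fms$lobular$area, tolerance = 1e-9)
  expect_equal(fms$arboreal$feret_max, fms$lobular$feret_max, tolerance = 1e-9)

  # translating a field along depth leaves its XZ hull unchanged
  p <- morphPoints(sqm)
  p$y[p$y > 20] <- p$y[p$y > 20] + 7
  fms2 <- fieldMetrics(new("Morphology", points = p, soma = list(),
                           metadata = list()), 20)
  expect_equal(fms2$arboreal$area, fms$arboreal$area, tolerance = 1e-9)
})

test_that("density scaling fit is exact on noiseless planted data", {
  V <- 10^seq(3, 4.5, length.out = 12)
  L <- 10^(0.26 - 0.37 * log10(V)) * V
  fit <- densityScalingFit(V, L)
  expect_equal(fit$slope, -0.37, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.26, tolerance = 1e-9)
  expect_equal(fit$data$density, L / V, tolerance = 1e-12)
  expect_equal(unname(fit$reference["slope"]), -0.55)

  two <- densityScalingFit(c(1000, 10000), c(500, 1500))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)   # exact interpolation
  expect_error(densityScalingFit(c(-1, 2), c(1, 1)), "positive")
})
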