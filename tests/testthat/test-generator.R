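test_that("generation is deterministic at the serialized-byte level", {
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeSWC(generateAII(seed = 3)$morphology, f1)
  writeSWC(generateAII(seed = 3)$morphology, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         {
                           f3 <- withr::local_tempfile(fileext = ".swc")
                           writeSWC(generateAII(seed = 4)$morphology, f3)
                           readBin(f3, "raw", file.size(f3))
                         }))
})

test_that("generated arbors are clean and match their ground truth exactly", {
  for (s in c(2, 9)) {
    g <- generateAII(seed = s)
    expect_equal(nrow(validateMorphology(g$morphology)), 0L)
    sg <- decomposeSegments(g$morphology)
    expect_equal(sg$n_nodes, g$truth$n_nodes)
    expect_equal(sg$n_stems, g$truth$n_stems)
    mo <- merge(g$truth$segment_orders,
                sg$segments[, c("end_id", "order_centrifugal", "order_shaft")],
                by = "end_id")
    expect_equal(nrow(mo), nrow(sg$segments))
    expect_equal(mo$order_centrifugal.x, mo$order_centrifugal.y)
    expect_equal(mo$order_shaft.x, mo$order_shaft.y)
  }
})

test_that("population statistics emulate the reconstructed cells", {
  cells <- lapply(1:15, function(i) generateAII(seed = 100 + i))
  stats <- t(vapply(cells, function(g) {
    sg <- decomposeSegments(g$morphology)
    c(segl = mean(sg$segments$path_length),
      nodes = sg$n_nodes,
      stems = sg$n_stems,
      nvar = g$truth$n_varicosities,
      maxsh = max(sg$segments$order_shaft))
  }, numeric(5)))
  # mean branch segment path length within the reported band 3.19 +- 0.56
  expect_gt(mean(stats[, "segl"]), 3.19 - 0.56)
  expect_lt(mean(stats[, "segl"]), 3.19 + 0.56)
  expect_true(all(stats[, "nodes"] >= 46 & stats[, "nodes"] <= 311))
  expect_true(all(stats[, "stems"] >= 1 & stats[, "stems"] <= 9))
  expect_true(all(stats[, "nvar"] >= 59 & stats[, "nvar"] <= 268))
  # every cell contains branch orders 1..10 under both schemes
  for (g in cells[1:5]) {
    sg <- decomposeSegments(g$morphology)
    expect_true(all(1:10 %in% sg$segments$order_shaft))
    expect_true(all(1:10 %in% sg$segments$order_centrifugal))
  }
})

test_that("the laminar profile of generated cells is bistratified", {
  fracs <- vapply(1:8, function(s) {
    g <- generateAII(seed = 200 + s)
    lp <- laminarProfile(g$morphology, morphMetadata(g$morphology)$layers)
    stats::setNames(lp$length_fraction, lp$layer)
  }, numeric(7))
  mf <- rowMeans(fracs)
  expect_gt(mf[["S2"]], mf[["S1"]])     # peak in S2 within sublamina a
  expect_gt(mf[["S2"]], mf[["S3"]])     # dip between the two bands
  expect_gt(mf[["S4"]] + mf[["S5"]], mf[["S3"]])
  expect_gt(mf[["S4"]] + mf[["S5"]], 0.35)
})

test_that("generatePopulation spreads sizes and respects its contract", {
  expect_error(generatePopulation(1), "at least 2")
  pop <- generatePopulation(2, seed = 42)
  expect_length(pop, 2L)
  # byte-identical regeneration under the same seed
  a <- writeSWC(pop[[1]]$morphology, withr::local_tempfile(fileext = ".swc"))
  pop2 <- generatePopulation(2, seed = 42)
  b <- writeSWC(pop2[[1]]$morphology, withr::local_tempfile(fileext = ".swc"))
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
})

test_that("inserted varicosities clear the detection threshold with margin", {
  g <- cachedCell()
  m <- g$morphology
  v <- detectVaricosities(m, ratio = 2.0)     # stricter than the default 1.8
  expect_setequal(v$point_id, g$truth$varicosities$point_id)
})
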