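test_that("downsampling averages blocks and preserves the global mean", {
  g <- SoilGrid(matrix(c(0, 1, 1, 0), 2, 2), pixelSize = 0.5)
  d <- downsampleGrid(g, 1)
  expect_equal(dim(gridValues(d)), c(1L, 1L))
  expect_equal(gridValues(d)[1, 1], 0.5)

  const <- SoilGrid(matrix(0.7, 12, 8), pixelSize = 0.25)
  d2 <- downsampleGrid(const, 1)
  expect_true(all(gridValues(d2) == 0.7))
  expect_equal(dim(gridValues(d2)), c(3L, 2L))

  set.seed(5)
  rnd <- SoilGrid(matrix(runif(400), 20, 20), pixelSize = 0.5)
  d3 <- downsampleGrid(rnd, 2)
  expect_equal(mean(gridValues(d3)), mean(gridValues(rnd)), tolerance = 1e-12)
  expect_equal(gridOrigin(d3), gridOrigin(rnd))
  expect_equal(pixelSize(d3), 2)

  expect_error(downsampleGrid(rnd, 0.75), "integer multiple")
  expect_error(downsampleGrid(rnd, 3), "not divisible")
})

test_that("distance map matches hand geometry and ties break by root id", {
  seg <- RootSystem(list(straightRoot("v", c(5, 0), c(5, 50), 0.1)),
                    extent = c(50, 50))
  dm <- distanceMap(seg, list(nrow = 50, ncol = 50, origin = c(0, 0),
                              pixelSize = 1))
  # pixel center (8.5, 10.5): horizontal offset from x = 5
  expect_equal(distanceValues(dm)[11, 9], 3.5)
  # pixel center (5.5, 22.5): half a pixel off the line
  expect_equal(distanceValues(dm)[23, 6], 0.5)
  expect_true(all(nearestRootId(dm) == "v"))
  expect_true(all(nearestRootOrder(dm) == 1L))

  # a pixel center lying on a segment has distance 0
  on <- RootSystem(list(straightRoot("h", c(0, 2.5), c(10, 2.5), 0.1)))
  dmo <- distanceMap(on, list(nrow = 5, ncol = 5, origin = c(0, 0),
                              pixelSize = 1))
  expect_equal(distanceValues(dmo)[3, 3], 0)

  # two equidistant roots: the lexicographically smaller id wins the tie
  two <- RootSystem(list(straightRoot("b", c(4, 0), c(4, 10), 0.1),
                         straightRoot("a", c(6, 0), c(6, 10), 0.1)))
  dmt <- distanceMap(two, list(nrow = 10, ncol = 10, origin = c(0.5, 0),
                               pixelSize = 1))
  expect_equal(nearestRootId(dmt)[5, 4], "b")  # center x = 4.0: on "b"
  expect_equal(nearestRootId(dmt)[5, 5], "a")  # center x = 5.0: tie -> "a"
  expect_equal(nearestRootId(dmt)[5, 6], "a")  # center x = 6.0: on "a"

  expect_error(distanceMap(RootSystem(), list(nrow = 2, ncol = 2,
                                              origin = c(0, 0),
                                              pixelSize = 1)),
               "empty system")
})

test_that("distance map equals the brute-force segment minimum", {
  for (s in c(3, 12)) {
    sys <- generateRootSystem(smallParams(), seed = s)
    geo <- list(nrow = 15, ncol = 15, origin = c(0, 0),
                pixelSize = rhizotronExtent(sys)[1] / 15)
    dm <- distanceMap(sys, geo)
    ref <- bruteDistanceGrid(sys, geo$nrow, geo$ncol, geo$origin,
                             geo$pixelSize)
    expect_lt(max(abs(distanceValues(dm) - ref)), 1e-9)
  }
})

test_that("distance map is translation-equivariant", {
  sys <- generateRootSystem(smallParams(), seed = 17)
  g1 <- list(nrow = 12, ncol = 12, origin = c(0, 0), pixelSize = 1.5)
  g2 <- list(nrow = 12, ncol = 12, origin = c(7.5, -2.25), pixelSize = 1.5)
  d1 <- distanceMap(sys, g1)
  d2 <- distanceMap(translateSystem(sys, 7.5, -2.25), g2)
  expect_equal(distanceValues(d1), distanceValues(d2), tolerance = 1e-9)
  expect_identical(nearestRootId(d1), nearestRootId(d2))
})

test_that("joinSoilRoot builds one row per pixel and timestamp", {
  sys <- RootSystem(list(straightRoot("v", c(1, 0), c(1, 2), 0.1)),
                    extent = c(2, 2))
  grids <- lapply(c(0, 4, 8), function(t)
    SoilGrid(matrix(0.6, 2, 2), pixelSize = 1, timestamp = t))
  dm <- distanceMap(sys, grids[[1]])
  tab <- joinSoilRoot(grids, dm)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$water_content == 0.6))
  expect_true(all(tab$nearest_root == "v"))

  # spot check a specific (pixel, time) row against direct indexing
  g2 <- grids
  v <- gridValues(g2[[2]]); v[2, 1] <- 0.42
  g2[[2]] <- SoilGrid(v, pixelSize = 1, timestamp = 4)
  tab2 <- joinSoilRoot(g2, dm)
  row <- tab2[tab2$row == 2 & tab2$col == 1 & tab2$time_h == 4, ]
  expect_equal(row$water_content, 0.42)
  expect_equal(row$distance_cm, distanceValues(dm)[2, 1])
  expect_equal(row$x_cm, 0.5)
  expect_equal(row$y_cm, 1.5)

  bad <- SoilGrid(matrix(0.5, 3, 2), pixelSize = 1, timestamp = 12)
  expect_error(joinSoilRoot(c(grids, list(bad)), dm), "join error")
})

test_that("distance-binned series aggregates, partitions and recombines", {
  sys <- RootSystem(list(straightRoot("v", c(10, 0), c(10, 30), 0.1)),
                    extent = c(30, 30))
  dm <- distanceMap(sys, list(nrow = 30, ncol = 30, origin = c(0, 0),
                              pixelSize = 1))
  uni <- lapply(c(0, 4), function(t)
    SoilGrid(matrix(0.6, 30, 30), pixelSize = 1, timestamp = t))
  tab <- joinSoilRoot(uni, dm)
  bs <- distanceBinnedSeries(tab, 0:15)
  expect_true(all(abs(bs$mean_water_content - 0.6) < 1e-12))
  # counts partition the pixels at each time
  expect_equal(as.numeric(tapply(bs$n, bs$time_h, sum)), c(900, 900))
  # n-weighted recombination reproduces the global mean
  for (t in c(0, 4)) {
    sub <- bs[bs$time_h == t, ]
    expect_equal(sum(sub$mean_water_content * sub$n) / sum(sub$n),
                 mean(tab$water_content[tab$time_h == t]), tolerance = 1e-9)
  }

  # deterministic depletion field: bin means strictly increase with distance
  dep <- SoilGrid(0.6 - 0.3 * exp(-distanceValues(dm) / 2), pixelSize = 1)
  tabd <- joinSoilRoot(list(dep), dm)
  bd <- distanceBinnedSeries(tabd, 0:15)
  expect_true(all(diff(bd$mean_water_content) > 0))

  expect_error(distanceBinnedSeries(tab[0, ], 0:15), "empty table")
  expect_error(distanceBinnedSeries(tab, c(0, 0, 1)), "strictly increasing")
})

test_that("depletion fits recover the generating parameters without noise", {
  sys <- generateRootSystem(smallParams(), seed = 7)
  geo <- list(nrow = 20, ncol = 20, origin = c(0, 0), pixelSize = 1)
  par <- waterModelParams(noiseSd = 0, timestamps = c(12, 16))
  ser <- generateWaterSeries(sys, geo, par, seed = 1)
  dm <- distanceMap(sys, geo)
  bn <- distanceBinnedSeries(joinSoilRoot(ser, dm), 0:15)
  fit <- fitDepletionProfile(bn, 16)
  cv <- waterModelCurves(16, par)
  expect_equal(unname(fit["ell"]), par$ell, tolerance = 0.05)
  expect_equal(unname(fit["W0"]), cv$W0, tolerance = 0.01)
  expect_equal(unname(fit["A"]), cv$A, tolerance = 0.05)
})
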