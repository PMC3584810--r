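test_that("distal cumulative surface matches the toy closed form", {
  sys <- toySystem()
  # whole tree from the base: pi*(0.1*10) + pi*(0.05*5) = 1.25*pi
  expect_equal(distalCumulative(sys, "main", 0, "surface"), 1.25 * pi)
  # beyond the lateral insertion at 5: only the distal 4 cm of the axis
  expect_equal(distalCumulative(sys, "main", 6, "surface"), 0.4 * pi)
  # boundary: a lateral inserted exactly at the query position is included
  expect_equal(distalCumulative(sys, "main", 5, "surface"),
               0.5 * pi + 0.25 * pi)
  # at the tip
  expect_equal(distalCumulative(sys, "main", 10, "surface"), 0)
  expect_error(distalCumulative(sys, "nope", 0, "surface"), "unknown root")
  expect_error(distalCumulative(sys, "main", 11, "surface"), "outside")
})

test_that("distal cumulative equals exhaustive tipward enumeration", {
  set.seed(33)
  for (s in 1:5) {
    sys <- generateRootSystem(smallParams(), seed = s)
    ids <- rootIds(sys)
    for (k in 1:10) {
      id <- sample(ids, 1)
      L <- polylineLength(getRoot(sys, id)@polyline)
      pos <- runif(1, 0, L)
      for (meas in c("length", "surface", "volume")) {
        expect_equal(distalCumulative(sys, id, pos, meas),
                     bruteDistal(sys, id, pos, meas), tolerance = 1e-9)
      }
    }
  }
})

test_that("distal cumulative at the base equals the whole-tree trait total", {
  sys <- generateRootSystem(smallParams(), seed = 8)
  tt <- rootTraits(sys)
  for (base in tt$id[tt$order == 1][1:2]) {
    inTree <- c(base, descendantIds(sys, base))
    expect_equal(distalCumulative(sys, base, 0, "surface"),
                 sum(tt$surface_cm2[tt$id %in% inTree]), tolerance = 1e-9)
    expect_equal(distalCumulative(sys, base, 0, "length"),
                 sum(tt$length_cm[tt$id %in% inTree]), tolerance = 1e-9)
  }
})

test_that("distal cumulative is non-increasing along a root", {
  sys <- generateRootSystem(smallParams(), seed = 4)
  id <- rootIds(sys)[which.max(rootTraits(sys)$length_cm)]
  L <- polylineLength(getRoot(sys, id)@polyline)
  vals <- vapply(seq(0, L, length.out = 25), function(p)
    distalCumulative(sys, id, p, "surface"), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("depth profile clips segments to slabs exactly", {
  vert <- RootSystem(list(straightRoot("v", c(5, 0), c(5, 10), 0.1)))
  dp <- depthProfile(vert, 1)
  expect_equal(nrow(dp), 10L)
  expect_equal(dp$length_cm, rep(1, 10))

  diag45 <- RootSystem(list(straightRoot("d", c(0, 0), c(10, 10), 0.1)))
  dp2 <- depthProfile(diag45, 1)
  expect_equal(dp2$length_cm, rep(sqrt(2), 10))

  # horizontal segment: all length in the slab containing its depth
  horiz <- RootSystem(list(straightRoot("h", c(0, 2.5), c(8, 2.5), 0.1)))
  dp3 <- depthProfile(horiz, 1)
  expect_equal(dp3$bin_lo, 2)
  expect_equal(dp3$length_cm, 8)
})

test_that("depth profile conserves per-order totals under bin refinement", {
  sys <- generateRootSystem(smallParams(), seed = 13)
  tt <- rootTraits(sys)
  for (bs in c(1, 0.5)) {
    dp <- depthProfile(sys, bs)
    sums <- tapply(dp$length_cm, dp$order, sum)
    ref <- tapply(tt$length_cm, tt$order, sum)
    expect_equal(as.numeric(sums), as.numeric(ref[names(sums)]),
                 tolerance = 1e-6)
  }
})

test_that("diameter letters separate clearly distinct orders", {
  set.seed(77)
  mkRoots <- function(prefix, n, ord, mu, sd, parent = NA_character_,
                      ins = if (is.na(parent)) NA_real_ else 1) {
    lapply(seq_len(n), function(i)
      straightRoot(sprintf("%s%02d", prefix, i), c(i, 0), c(i, 5),
                   max(rnorm(1, mu, sd), 1e-4), order = ord,
                   parentId = parent, insertion = ins))
  }
  ax <- straightRoot("ax", c(0, 0), c(0, 40), 0.9)
  sys <- RootSystem(c(list(ax),
                      mkRoots("a", 30, 1L, 0.9, 0.05),
                      mkRoots("b", 30, 2L, 0.15, 0.03, parent = "ax")))
  ds <- diameterStats(sys)
  expect_equal(ds$letter[ds$order == 1], "a")
  expect_equal(ds$letter[ds$order == 2], "b")
  # oracle: Welch test on the same per-root summaries rejects at p < 0.01
  tt <- rootTraits(sys)
  p <- t.test(tt$mean_diameter_cm[tt$order == 1],
              tt$mean_diameter_cm[tt$order == 2], var.equal = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("identical diameter samples share a letter; sparse orders get none", {
  ax <- straightRoot("ax", c(0, 0), c(0, 40), 0.2)
  same <- RootSystem(c(
    list(ax),
    lapply(1:5, function(i) straightRoot(sprintf("a%d", i), c(i, 0),
                                         c(i, 5), 0.2)),
    lapply(1:5, function(i) straightRoot(sprintf("b%d", i), c(i, 10),
                                         c(i + 2, 10), 0.2, order = 2L,
                                         parentId = "ax", insertion = i))))
  ds <- diameterStats(same)
  expect_equal(ds$letter[ds$order == 1], ds$letter[ds$order == 2])

  solo <- RootSystem(lapply(1:4, function(i)
    straightRoot(sprintf("r%d", i), c(i, 0), c(i, 5), 0.1 * i)))
  expect_equal(diameterStats(solo)$letter, "a")

  # an order with n < 2 is reported without a letter
  one <- RootSystem(list(
    straightRoot("a1", c(0, 0), c(0, 5), 0.3),
    straightRoot("a2", c(1, 0), c(1, 5), 0.31),
    straightRoot("l", c(0, 2), c(2, 2), 0.1, order = 2L, parentId = "a1",
                 insertion = 2)))
  ds2 <- diameterStats(one)
  expect_true(is.na(ds2$letter[ds2$order == 2]))
})

test_that("surface proportions follow the toy split and normalize", {
  prop <- surfaceProportions(toySystem())
  expect_equal(unname(prop["1"]), 0.8)
  expect_equal(unname(prop["2"]), 0.2)
  expect_equal(sum(prop), 1)

  single <- RootSystem(list(straightRoot("a", c(0, 0), c(0, 5), 0.1)))
  expect_equal(unname(surfaceProportions(single)), 1)

  sys <- generateRootSystem(smallParams(), seed = 21)
  expect_equal(sum(surfaceProportions(sys)), 1, tolerance = 1e-9)

  zero <- RootSystem(list(straightRoot("a", c(0, 0), c(0, 5), 0)))
  expect_error(surfaceProportions(zero), "undefined")
})

test_that("orientation is 0 for plumb roots, 90 for horizontal ones", {
  vert <- straightRoot("v", c(5, 0), c(5, 10), 0.1, n = 11)
  expect_equal(orientationProfile(vert, 1)$angle_deg, rep(0, 11))
  horiz <- straightRoot("h", c(0, 5), c(10, 5), 0.1, n = 11)
  expect_equal(orientationProfile(horiz, 1)$angle_deg, rep(90, 11))
  zero <- Root("z", cbind(x = 1, y = 1, diameter = 0.1))
  expect_error(orientationProfile(zero), "zero-length")
})

test_that("orientation tracks the analytic tangent of a quarter circle", {
  # quarter circle of radius 10 from vertical (at the base) to horizontal
  th <- seq(0, pi / 2, length.out = 200)
  qc <- Root("q", cbind(x = 10 * (1 - cos(th)), y = 10 * sin(th),
                        diameter = 0.1))
  op <- orientationProfile(qc, 0.2)
  # analytic: angle from vertical equals the turned arc in degrees
  expected <- op$arc_cm / 10 * 180 / pi
  interior <- op$arc_cm > 0.5 & op$arc_cm < max(op$arc_cm) - 0.5
  expect_lt(max(abs(op$angle_deg - expected)[interior]), 2)
  expect_true(all(diff(op$angle_deg) > -1e-6))
})

test_that("Fitter indices: herringbone altitude equals magnitude", {
  ax <- straightRoot("ax", c(5, 0), c(5, 20), 0.1)
  hb <- RootSystem(c(list(ax), lapply(1:3, function(i)
    straightRoot(sprintf("l%d", i), c(5, 5 * i), c(8, 5 * i), 0.05,
                 order = 2L, parentId = "ax", insertion = 5 * i))))
  fi <- fitterIndices(hb)
  expect_equal(fi$magnitude, 4L)
  expect_equal(fi$altitude, 4L)

  solo <- RootSystem(list(straightRoot("a", c(0, 0), c(0, 5), 0.1)))
  fs <- fitterIndices(solo)
  expect_equal(fs$magnitude, 1L)
  expect_equal(fs$altitude, 1L)
  expect_equal(fs$exterior_path_length, 1L)
})

test_that("Fitter indices agree with an explicit link-graph search", {
  skip_if_not_installed("igraph")
  for (s in c(6, 14)) {
    sys <- generateRootSystem(smallParams(), seed = s)
    fi <- fitterIndices(sys)
    for (i in seq_len(nrow(fi))) {
      ref <- igraphFitter(sys, fi$treeId[i])
      expect_equal(fi$magnitude[i], ref$magnitude)
      expect_equal(fi$altitude[i], as.integer(ref$altitude))
      expect_equal(fi$exterior_path_length[i],
                   as.integer(ref$exteriorPathLength))
    }
  }
})

test_that("trait computations are invariant under rigid translation", {
  sys <- generateRootSystem(smallParams(), seed = 9)
  sh <- translateSystem(sys, 3.2, -1.7)
  t1 <- rootTraits(sys); t2 <- rootTraits(sh)
  expect_equal(t1$length_cm, t2$length_cm, tolerance = 1e-9)
  expect_equal(t1$surface_cm2, t2$surface_cm2, tolerance = 1e-9)
  expect_equal(t1$volume_cm3, t2$volume_cm3, tolerance = 1e-9)
  expect_equal(surfaceProportions(sys), surfaceProportions(sh),
               tolerance = 1e-12)
  expect_identical(fitterIndices(sys), fitterIndices(sh))
})
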