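# Morphometric suite: hand values, brute-force oracle equivalence,
# invariances

test_that("hand-computed values of the Y tree are reproduced", {
  toy <- toyTree()
  expect_equal(totalLength(toy), 30)
  expect_equal(countTipsBifurcations(toy),
               c(n_tips = 2L, n_bifurcations = 1L))
  expect_equal(rgu(toy, "ratio"), 15)
  expect_equal(rgu(toy, "segment"), 10)
  expect_equal(maxEuclidean(toy), sqrt(360))
  expect_equal(bifurcationAngles(toy), acos(0.28) * 180 / pi)
  expect_equal(coverArea(toy), 108)
  rec <- morphometry(toy)
  expect_equal(rec$total_length, 30)
  expect_equal(rec$n_tips, 2L)
  expect_equal(rec$rgu_ratio, 15)
  expect_equal(rec$cover_area, 108)
})

test_that("degenerate trees give zero or missing metrics, not errors", {
  germ <- rootOnlyTree()
  expect_equal(totalLength(germ), 0)
  expect_equal(unname(countTipsBifurcations(germ)), c(0L, 0L))
  expect_equal(maxEuclidean(germ), 0)
  expect_equal(coverArea(germ), 0)
  expect_length(bifurcationAngles(germ), 0)
  rec <- morphometry(germ)
  expect_true(is.na(rec$rgu_ratio) && is.na(rec$rgu_segment))
  expect_equal(rec$surface_area, 0)
  expect_equal(rec$surface_area_total, 4 * pi * 2.5^2)
  # unbranched filament: one tip, no bifurcations, segment RGU undefined
  fil <- filamentTree(10)
  expect_equal(unname(countTipsBifurcations(fil)), c(1L, 0L))
  expect_warning(v <- rgu(fil, "segment"), "unbranched|branch")
  expect_true(is.na(v))
  expect_equal(coverArea(fil), 0)
})

test_that("surface area follows the frustum closed form", {
  # straight 10 um cylinder, both radii 0.5: lateral area 10*pi
  nd <- data.frame(id = 1:2, label = c("thallus", "rhizoid"),
                   x = c(0, 10), y = 0, z = 0, radius = 0.5,
                   parent = c(-1L, 1L))
  expect_equal(surfaceArea(TracedTree(nd)), 10 * pi)
  # frustum 2 -> 0.5 over 10 axial: slant = sqrt(100 + 1.5^2)
  nd$radius <- c(2, 0.5)
  expect_equal(surfaceArea(TracedTree(nd)), pi * 2.5 * sqrt(100 + 2.25))
  nd$radius <- 0
  expect_equal(surfaceArea(TracedTree(nd)), 0)
})

test_that("simple angle geometries are measured exactly", {
  ang <- function(p1, p2) {
    nd <- data.frame(id = 1:4, label = c("thallus", rep("rhizoid", 3)),
                     x = c(0, 0, p1[1], p2[1]), y = c(0, 5, 5 + p1[2], 5 + p2[2]),
                     z = 0, radius = 0.25, parent = c(-1L, 1L, 2L, 2L))
    bifurcationAngles(TracedTree(nd))
  }
  expect_equal(ang(c(0, 2), c(0, -2)), 180)   # antiparallel daughters
  expect_equal(ang(c(2, 0), c(0, 2)), 90)     # perpendicular daughters
})

test_that("all metrics agree with brute-force traversal on random trees", {
  for (seed in 1:20) {
    n <- sample(c(10, 40, 120, 300), 1)
    tr <- randomTree(n, seed = seed)
    expect_equal(totalLength(tr), oracleTotalLength(tr), tolerance = 1e-9)
    expect_equal(countTipsBifurcations(tr), oracleCounts(tr))
    expect_equal(maxEuclidean(tr), oracleMaxEuclidean(tr), tolerance = 1e-9)
    expect_equal(surfaceArea(tr), oracleSurfaceArea(tr), tolerance = 1e-9)
    expect_equal(surfaceArea(tr, TRUE), oracleSurfaceArea(tr, TRUE),
                 tolerance = 1e-9)
    expect_equal(suppressWarnings(rgu(tr, "segment")), oracleRguSegment(tr),
                 tolerance = 1e-9)
    expect_equal(sort(bifurcationAngles(tr)), sort(oracleBifAngles(tr)),
                 tolerance = 1e-9)
    expect_equal(coverArea(tr), oracleCoverArea(tr), tolerance = 1e-9)
  }
})

test_that("tips = bifurcations + 1 on strictly binary trees", {
  for (seed in 1:5) {
    tr <- randomBinaryTree(nInternal = 40, seed = seed)
    cnt <- countTipsBifurcations(tr)
    expect_equal(unname(cnt["n_tips"]), unname(cnt["n_bifurcations"]) + 1L)
  }
})

test_that("metrics are isometry invariant and scale covariantly", {
  tr <- randomTree(80, seed = 11)
  iso <- transformTree(tr, deg = 37, shift = c(5, -3, 2))
  expect_equal(totalLength(iso), totalLength(tr), tolerance = 1e-9)
  expect_equal(maxEuclidean(iso), maxEuclidean(tr), tolerance = 1e-9)
  expect_equal(sort(bifurcationAngles(iso)), sort(bifurcationAngles(tr)),
               tolerance = 1e-9)
  expect_equal(coverArea(iso), coverArea(tr), tolerance = 1e-9)
  expect_equal(countTipsBifurcations(iso), countTipsBifurcations(tr))
  sc <- transformTree(tr, scale = 2)
  expect_equal(totalLength(sc), 2 * totalLength(tr), tolerance = 1e-9)
  expect_equal(coverArea(sc), 4 * coverArea(tr), tolerance = 1e-9)
  expect_equal(surfaceArea(sc), 4 * surfaceArea(tr), tolerance = 1e-9)
  expect_equal(countTipsBifurcations(sc), countTipsBifurcations(tr))
})

test_that("adding a branch never decreases length, tips or cover area", {
  for (seed in 1:5) {
    tr <- randomTree(60, seed = 100 + seed)
    nd <- swcNodes(tr)
    set.seed(seed)
    host <- sample(nd$id, 1)
    hrow <- which(nd$id == host)
    newNode <- data.frame(id = max(nd$id) + 1L, label = "rhizoid",
                          x = nd$x[hrow] + rnorm(1, 0, 4),
                          y = nd$y[hrow] + rnorm(1, 0, 4),
                          z = nd$z[hrow] + rnorm(1, 0, 4),
                          radius = 0.25, parent = host)
    tr2 <- TracedTree(rbind(nd, newNode), cellId = "aug")
    expect_gte(totalLength(tr2), totalLength(tr))
    expect_gte(nTips(tr2), nTips(tr))
    expect_gte(coverArea(tr2), coverArea(tr))
  }
})

test_that("zero-length edges are contracted before measurement", {
  nd <- swcNodes(toyTree())
  dup <- data.frame(id = 5L, label = "rhizoid", x = 0, y = 10, z = 0,
                    radius = 0.25, parent = 2L)   # coincides with node 2
  tr <- TracedTree(rbind(nd, dup))
  expect_equal(totalLength(tr), 30)
  expect_equal(unname(countTipsBifurcations(tr)), c(2L, 1L))
  expect_equal(rgu(tr, "segment"), 10)
})

test_that("morphometry is deterministic and internally consistent", {
  tr <- randomTree(150, seed = 3)
  r1 <- morphometry(tr); r2 <- morphometry(tr)
  expect_identical(r1, r2)
  expect_equal(r1$rgu_ratio, r1$total_length / r1$n_tips)
  expect_lte(r1$max_euclidean,
             r1$total_length + sqrt(sum(swcNodes(tr)[2, c("x", "y", "z")]^2)))
})
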