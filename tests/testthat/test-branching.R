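# Branch-event detection and apical/lateral classification

# two-frame series: frame 2 adds a lateral branch at a known insertion
# point and an apical split at the filament tip
scriptedSeries <- function() {
  nd1 <- data.frame(id = 1:6, label = c("thallus", rep("rhizoid", 5)),
                    x = c(0, 2, 4, 6, 8, 10), y = 0, z = 0, radius = 0.25,
                    parent = c(-1L, 1L, 2L, 3L, 4L, 5L))
  # frame 2: lateral daughter inserted at node 3 (6 um from the tip along
  # the path), plus tip split at node 6 into two short daughters
  nd2 <- rbind(nd1,
               data.frame(id = 7L, label = "rhizoid", x = 4, y = 2, z = 0,
                          radius = 0.25, parent = 3L),
               data.frame(id = 8L, label = "rhizoid", x = 11, y = 0.3, z = 0,
                          radius = 0.25, parent = 6L),
               data.frame(id = 9L, label = "rhizoid", x = 11, y = -0.3, z = 0,
                          radius = 0.25, parent = 6L))
  rhizoidTimeSeries(list(TracedTree(nd1, "scripted"), TracedTree(nd2, "scripted")),
                    times = c(0, 1))
}

test_that("new bifurcations are detected with their geometry", {
  ev <- detectBranchEvents(scriptedSeries())
  expect_equal(nrow(ev), 2)
  lat <- ev[ev$parent_node_id == 3L, ]
  api <- ev[ev$parent_node_id == 6L, ]
  expect_equal(lat$distance_to_tip, 6)     # node 3 was 6 um up-path of the tip
  expect_equal(lat$axis_angle, 90)         # branch leaves at right angle
  expect_equal(lat$branch_class, "lateral")
  expect_equal(api$distance_to_tip, 0)     # inserted at the tip itself
  expect_equal(api$branch_class, "apical")
  expect_lt(api$axis_angle, 30)
})

test_that("static or purely elongating series yield no events", {
  tr <- filamentTree(6)
  s <- rhizoidTimeSeries(list(tr, tr), times = c(0, 1))
  expect_equal(nrow(detectBranchEvents(s)), 0)
  nd2 <- rbind(swcNodes(tr),
               data.frame(id = 7L, label = "rhizoid", x = 12, y = 0, z = 0,
                          radius = 0.25, parent = 6L))
  s2 <- rhizoidTimeSeries(list(tr, TracedTree(nd2, "filament")), times = c(0, 1))
  expect_equal(nrow(detectBranchEvents(s2)), 0)
  expect_equal(nrow(detectBranchEvents(rhizoidTimeSeries(tr, times = 0))), 0)
})

test_that("detection recovers every simulated branch insertion", {
  sim <- simulateRhizoid(rhizoidPreset("replete", duration = 4, seed = 5))
  ev <- detectBranchEvents(sim$series)
  expect_equal(nrow(ev), nrow(sim$events))
  expect_setequal(ev$parent_node_id, sim$events$branch_node)
  # event count balances tip production for strictly binary growth
  tipsFirst <- nTips(frames(sim$series)[[1]])
  tipsLast <- nTips(frames(sim$series)[[nFrames(sim$series)]])
  expect_equal(nrow(ev), tipsLast - tipsFirst)
})

test_that("classification is a monotone threshold rule", {
  expect_equal(classifyBranch(0.3, 10), "apical")
  expect_equal(classifyBranch(8, 10), "lateral")
  expect_equal(classifyBranch(0.3, 85), "lateral")
  # raising thresholds never converts apical to lateral
  d <- runif(50, 0, 5); a <- runif(50, 0, 120)
  base <- classifyBranch(d, a, dTip = 1, thetaPar = 30)
  wider <- classifyBranch(d, a, dTip = 2, thetaPar = 60)
  expect_true(all(!(base == "apical" & wider == "lateral")))
})

test_that("branch fractions sum to one and track the event log", {
  ev <- data.frame(branch_class = c(rep("lateral", 17), rep("apical", 3)))
  br <- branchRatio(ev)
  expect_equal(br$lateral_fraction, 0.85)
  expect_equal(br$apical_fraction, 0.15)
  expect_equal(br$lateral_fraction + br$apical_fraction, 1)
  expect_equal(branchRatio(data.frame(branch_class = rep("lateral", 5)))$lateral_fraction, 1)
  expect_warning(br0 <- branchRatio(data.frame(branch_class = character(0))))
  expect_true(is.na(br0$lateral_fraction))
})

test_that("simulated lateral fraction falls in the binomial CI of p_lat", {
  # pool event logs until >= 500 events; p_lat = 0.85
  evs <- list()
  for (seed in 1:12) {
    sim <- simulateRhizoid(rhizoidPreset("replete", duration = 10, seed = 300 + seed))
    evs[[seed]] <- sim$events
  }
  ev <- do.call(rbind, evs)
  expect_gte(nrow(ev), 500)
  br <- branchRatio(ev)
  ci <- qbinom(c(0.005, 0.995), nrow(ev), 0.85) / nrow(ev)
  expect_gte(br$lateral_fraction, ci[1])
  expect_lte(br$lateral_fraction, ci[2])
})

test_that("unstable ids are matched by position, ambiguity aborts", {
  s <- scriptedSeries()
  nd2 <- swcNodes(frames(s)[[2]])
  # relabel frame-2 ids arbitrarily
  perm <- c(11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L)
  notRoot <- nd2$parent != -1L
  nd2$parent[notRoot] <- perm[nd2$parent[notRoot]]
  nd2$id <- perm[nd2$id]
  s2 <- rhizoidTimeSeries(list(frames(s)[[1]], TracedTree(nd2, "scripted")),
                          times = c(0, 1), idStable = FALSE)
  ev <- detectBranchEvents(s2)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$branch_class, c("apical", "lateral"))
  # two frame-1 nodes collapsing onto one predecessor is ambiguous
  nd1 <- swcNodes(frames(s)[[1]])
  ndDup <- rbind(nd1, data.frame(id = 7L, label = "rhizoid", x = 10.1, y = 0,
                                 z = 0, radius = 0.25, parent = 6L))
  sAmb <- rhizoidTimeSeries(list(frames(s)[[1]], TracedTree(ndDup, "scripted")),
                            times = c(0, 1), idStable = FALSE)
  expect_error(detectBranchEvents(sAmb), "ambiguous")
})
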