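# Stochastic growth simulator: determinism, conservation, event statistics,
# presets and bead contact

test_that("parameter validation lists the offending fields", {
  expect_error(growthParams(elongationBudget = -1), "elongationBudget")
  expect_error(growthParams(lateralProb = 1.4), "lateralProb")
  expect_error(growthParams(angleMu = 190), "angleMu")
  expect_error(growthParams(dt = 0), "dt")
  expect_error(rhizoidPreset("unknown"), "unknown preset")
})

test_that("presets encode the observed growth statistics", {
  p <- rhizoidPreset("replete")
  expect_equal(p@angleMu, 81.4)
  expect_equal(p@elongationBudget, 110.8)
  expect_equal(p@branchRate, 4.6)
  expect_equal(p@lateralProb, 0.85)
  s <- rhizoidPreset("starved")
  expect_equal(s@elongationBudget, p@elongationBudget)  # budget maintained
  expect_lt(s@branchRate, p@branchRate)                 # sparser branching
  expect_gt(s@angleMu, p@angleMu)                       # wider insertions
  b <- rhizoidPreset("bead")
  expect_false(anyNA(b@beadCentre))
  expect_gt(b@contactBranchRate, b@branchRate)
})

test_that("zero branching gives a single filament of length V*T", {
  sim <- simulateRhizoid(growthParams(branchRate = 0, elongationBudget = 10,
                                      duration = 1, seed = 9))
  fin <- frames(sim$series)[[nFrames(sim$series)]]
  expect_equal(nrow(sim$events), 0)
  expect_equal(nTips(fin), 1L)
  expect_equal(totalLength(fin), 10, tolerance = 1e-9)
})

test_that("identical seeds give byte-identical SWC series", {
  p <- rhizoidPreset("replete", duration = 3, seed = 42)
  s1 <- simulateRhizoid(p); s2 <- simulateRhizoid(p)
  for (i in seq_len(nFrames(s1$series))) {
    f1 <- withr::local_tempfile(fileext = ".swc")
    f2 <- withr::local_tempfile(fileext = ".swc")
    writeSWC(frames(s1$series)[[i]], f1)
    writeSWC(frames(s2$series)[[i]], f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  expect_identical(s1$events, s2$events)
  s3 <- simulateRhizoid(rhizoidPreset("replete", duration = 3, seed = 43))
  expect_false(identical(swcNodes(frames(s1$series)[[4]]),
                         swcNodes(frames(s3$series)[[4]])))
})

test_that("total length is conserved at V*T under any branching history", {
  for (preset in c("replete", "starved")) {
    sim <- simulateRhizoid(rhizoidPreset(preset, duration = 6, seed = 11))
    for (i in seq_len(nFrames(sim$series))) {
      fr <- frames(sim$series)[[i]]
      expect_lt(abs(totalLength(fr) - 110.8 * frameTime(fr)),
                110.8 * 0.01)      # within one step's budget
    }
  }
})

test_that("tip counts are 1 + Poisson(lambda*T) across seeds", {
  lam <- 4.6; T <- 10
  tips <- vapply(1:20, function(s) {
    sim <- simulateRhizoid(rhizoidPreset("replete", seed = 500 + s))
    nTips(frames(sim$series)[[nFrames(sim$series)]])
  }, integer(1))
  counts <- tips - 1L
  # chi-square GOF against Poisson(46) on quartile bins
  qs <- qpois(c(0.25, 0.5, 0.75), lam * T)
  obs <- table(cut(counts, c(-Inf, qs, Inf)))
  pr <- diff(c(0, ppois(qs, lam * T), 1))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
  # each event adds exactly one tip
  sim <- simulateRhizoid(rhizoidPreset("replete", seed = 77))
  expect_equal(nTips(frames(sim$series)[[11]]), 1L + nrow(sim$events))
})

test_that("sampled branch angles match the measured bifurcation angles", {
  sim <- simulateRhizoid(rhizoidPreset("replete", seed = 13))
  fin <- frames(sim$series)[[nFrames(sim$series)]]
  measured <- bifurcationAngles(fin)
  expect_equal(length(measured), nrow(sim$events))
  expect_lt(abs(mean(measured) - mean(sim$events$angle)), 3)
})

test_that("the RGU trajectory rises early then plateaus near V/lambda", {
  rguAt <- function(sim, t) {
    fr <- frames(sim$series)[[t + 1]]
    suppressWarnings(rgu(fr, "ratio"))
  }
  sims <- lapply(1:5, function(s) simulateRhizoid(rhizoidPreset("replete",
                                                                seed = 600 + s)))
  early <- mean(vapply(sims, rguAt, numeric(1), t = 1))
  mid <- mean(vapply(sims, rguAt, numeric(1), t = 5))
  r8 <- mean(vapply(sims, rguAt, numeric(1), t = 8))
  r10 <- mean(vapply(sims, rguAt, numeric(1), t = 10))
  expect_gt(mid, early)
  # plateau: < 10% change per hour over 8-10 h, near V/lambda
  expect_lt(abs(r10 - r8) / ((r10 + r8) / 2) / 2, 0.10)
  expect_lt(abs(r10 - 110.8 / 4.6) / (110.8 / 4.6), 0.5)
})

test_that("starved phenotype searches: longer reach, higher RGU, wider cover", {
  okReach <- okRgu <- okCover <- okAngle <- logical(10)
  for (s in 1:10) {
    rep10 <- frames(simulateRhizoid(rhizoidPreset("replete", seed = 700 + s))$series)[[11]]
    st10 <- frames(simulateRhizoid(rhizoidPreset("starved", seed = 700 + s))$series)[[11]]
    mr <- morphometry(rep10); ms <- morphometry(st10)
    okReach[s] <- ms$max_euclidean > mr$max_euclidean
    okRgu[s] <- ms$rgu_ratio > mr$rgu_ratio
    okCover[s] <- ms$cover_area > mr$cover_area
    okAngle[s] <- ms$mean_bif_angle > mr$mean_bif_angle
  }
  expect_gte(sum(okReach), 9)
  expect_gte(sum(okRgu), 9)
  expect_gte(sum(okCover), 9)
  expect_gte(sum(okAngle), 9)
})

test_that("bead contact splits the system and drives local branching", {
  p <- rhizoidPreset("bead", seed = 5)
  sim <- simulateRhizoid(p)
  fin <- frames(sim$series)[[nFrames(sim$series)]]
  split <- beadContactSplit(fin, p@beadCentre, p@beadRadius, p@contactTol)
  expect_gt(nrow(split$contact), 0)
  expect_gt(nrow(split$free), 0)
  cs <- edgeSetSummary(split$contact); fs <- edgeSetSummary(split$free)
  expect_lt(cs$rgu_ratio, fs$rgu_ratio)   # feeding: more branched in contact
  # a system far from the bead is entirely free
  far <- simulateRhizoid(rhizoidPreset("replete", duration = 1, seed = 2))
  sp2 <- beadContactSplit(frames(far$series)[[2]], c(1e4, 1e4, 0), 8)
  expect_equal(nrow(sp2$contact), 0)
  expect_error(beadContactSplit(fin, c(NA, NA, NA), NA), "no bead")
})
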