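# brute-force k-nearest oracle: distances sorted with index tie-break
bruteGroup <- function(ages, year, k) {
  ord <- order(abs(ages - year), seq_along(ages))
  sort(ord[seq_len(k)])
}

test_that("buildAgeGroups matches the brute-force k-nearest oracle", {
  ages <- 1:100
  names(ages) <- sprintf("S%d", 1:100)
  idx <- buildAgeGroups(ages, fraction = 0.1)
  expect_true(all(lengths(groupMembers(idx)) == 10))
  # the year-50 group is ages 45..54 (45 vs 55 tie resolved to lower index)
  expect_setequal(groupMembers(idx, 50), sprintf("S%d", 45:54))
  for (y in c(1, 13, 37, 50, 99, 100)) {
    expect_setequal(groupMembers(idx, y),
                    names(ages)[bruteGroup(ages, y, 10)])
  }
  expect_equal(unname(groupMidpoints(idx)["50"]), median(45:54))
})

test_that("group size is ceil(fraction * n) and equal across years", {
  ages <- runif(20, 0, 80)
  idx <- buildAgeGroups(ages, fraction = 0.1)
  expect_true(all(lengths(groupMembers(idx)) == 2))  # ceil(2.0) = 2
  idx2 <- buildAgeGroups(runif(25, 0, 80), fraction = 0.1)
  expect_true(all(lengths(groupMembers(idx2)) == 3))  # ceil(2.5) = 3
  expect_error(buildAgeGroups(numeric(0)), "empty")
  expect_error(buildAgeGroups(runif(5, 0, 10)), "at least 10")
  expect_error(buildAgeGroups(ages, fraction = 0), "fraction")
})

test_that("identical ages give identical groups with that midpoint", {
  ages <- rep(40, 12)
  idx <- buildAgeGroups(ages, fraction = 0.25)
  expect_true(all(vapply(groupMembers(idx), identical, logical(1),
                         groupMembers(idx)[[1]])))
  expect_true(all(groupMidpoints(idx) == 40))
})

test_that("trimEdgeGroups drops years whose midpoint drifts", {
  # a lone young sample: the year-19 group reaches far older ages
  ages <- c(19, seq(40, 90, length.out = 49))
  idx <- buildAgeGroups(ages, fraction = 0.2)
  mid19 <- groupMidpoints(idx)["19"]
  expect_gt(mid19, 35)  # pulled way above the nominal year
  trimmed <- trimEdgeGroups(idx, tolerance = 2)
  expect_false(19 %in% retainedYears(trimmed))

  # permissive tolerance keeps everything
  all <- trimEdgeGroups(idx, tolerance = 100)
  expect_identical(retainedYears(all), groupYears(idx))

  # tolerance 0 retains exactly the years whose group median equals the year
  # (odd group size so integer-year medians are attainable)
  ages2 <- 1:101
  idx2 <- buildAgeGroups(ages2, fraction = 0.1)  # k = ceil(10.1) = 11
  t0 <- trimEdgeGroups(idx2, tolerance = 0)
  brute <- groupYears(idx2)[vapply(groupYears(idx2), function(y)
    median(ages2[bruteGroup(ages2, y, 11)]) == y, logical(1))]
  expect_identical(retainedYears(t0), brute)
  expect_gt(length(brute), 0)

  expect_error(trimEdgeGroups(idx, tolerance = -1), "tolerance")
  expect_error(trimEdgeGroups(buildAgeGroups(c(19, rep(60.5, 19))), 0.001),
               "no age group")
})

test_that("runningMedians matches sort-based oracles and conventions", {
  ages <- c(10, 10, 10, 50, 50, 50, 90, 90, 90, 90)
  b <- rbind(P1 = rep(0.3, 10),
             P2 = c(0.1, 0.4, 0.2, 0.1, 0.4, 0.2, 0.1, 0.4, 0.2, 0.35),
             P3 = runif(10))
  colnames(b) <- sprintf("S%d", 1:10)
  be <- BetaExperiment(b, data.frame(age = ages, row.names = colnames(b)))
  idx <- buildAgeGroups(be, fraction = 0.3)
  rms <- runningMedians(be, idx, years = groupYears(idx))
  # constant marker: every median 0.3
  expect_true(all(medianTracks(rms)["P1", ] == 0.3))
  # the year-10 group is S1..S3 with values {0.1, 0.4, 0.2} -> 0.2
  expect_setequal(groupMembers(idx, 10), c("S1", "S2", "S3"))
  expect_equal(medianTracks(rms)["P2", "10"], 0.2)
  # middle order statistic from an explicit sort
  expect_equal(medianTracks(rms)["P3", "50"],
               unname(sort(b["P3", groupMembers(idx, 50)])[2]))

  # even group: mean-of-middle-two convention
  be2 <- tinyBeta(matrix(c(0.1, 0.3), 1, 2), ages = c(20, 20))
  idx2 <- buildAgeGroups(rep(20, 10), fraction = 0.2)
  expect_equal(median(c(0.1, 0.3)), 0.2)  # convention used throughout

  expect_error(runningMedians(be, idx, years = c(5L, 10L)), "subset")
})

test_that("relative SD is SD/median per interval, +Inf at zero medians", {
  ages <- rep(c(10, 50), each = 5)
  b <- rbind(P1 = c(0.1, 0.2, 0.3, 0.2, 0.2, 0.1, 0.2, 0.3, 0.2, 0.2),
             P2 = rep(0.4, 10),
             P3 = c(rep(0, 5), rep(0.5, 5)))
  colnames(b) <- sprintf("S%d", 1:10)
  be <- BetaExperiment(b, data.frame(age = ages, row.names = colnames(b)))
  idx <- buildAgeGroups(be, fraction = 0.5)
  rms <- runningMedians(be, idx, years = groupYears(idx))
  # group {0.1,0.2,0.3,0.2,0.2}: SD/median with n-1 denominator
  g <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  expect_equal(relativeSD(rms)["P1", "10"], sd(g) / median(g))
  expect_true(all(relativeSD(rms)["P2", ] == 0))
  expect_equal(relativeSD(rms)["P3", "10"], Inf)
  # meanRelSD in both scopes
  mrs <- meanRelSD(rms, "all")
  expect_equal(unname(mrs["P2"]), 0)
  expect_equal(unname(mrs["P3"]), Inf)
  ext <- meanRelSD(rms, "extremes",
                   extremeYears = cbind(rep(10L, 3), rep(50L, 3)))
  expect_equal(unname(ext["P1"]),
               mean(c(sd(g) / median(g), sd(g) / median(g))))
})

test_that("running medians are permutation-invariant and track trajectories", {
  specs <- rbind(
    trajectorySpec("up", "sigmoid", baseline = 0.1, amplitude = 0.4,
                   midpointAge = 50, steepness = 0.15, noiseSd = 0),
    trajectorySpec("lin", "linear", baseline = 0.2, slope = 3e-3, noiseSd = 0))
  be <- plantedCohort(120, specs, seed = 6)
  idx <- trimEdgeGroups(buildAgeGroups(be), 2)
  rms <- runningMedians(be, idx)

  # permuting samples within the matrix leaves the medians unchanged
  perm <- sample(ncol(be))
  bePerm <- be[, perm]
  rmsPerm <- runningMedians(bePerm, buildAgeGroups(bePerm, 0.1) |>
                              trimEdgeGroups(2))
  expect_equal(medianTracks(rmsPerm), medianTracks(rms))

  # zero noise: median stays within the trajectory's span over the group
  for (y in retainedYears(idx)) {
    lim <- idx@limits[match(y, groupYears(idx)), ]
    v <- trajectoryEval(specs[1, ], c(lim[1], lim[2]))
    expect_gte(medianTracks(rms)["up", as.character(y)], min(v) - 1e-12)
    expect_lte(medianTracks(rms)["up", as.character(y)], max(v) + 1e-12)
  }
  # monotone trajectory -> monotone running median track
  expect_true(all(diff(medianTracks(rms)["up", ]) >= -1e-12))
  expect_true(all(diff(medianTracks(rms)["lin", ]) >= -1e-12))
})
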