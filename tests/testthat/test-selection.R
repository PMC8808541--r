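makeRMS <- function(med, years = seq_len(ncol(med))) {
  rel <- med * 0
  new("RunningMedianSet", medians = med, relSD = rel,
      nUsed = matrix(5L, nrow(med), ncol(med)), years = as.integer(years))
}

test_that("maxFoldChange / maxAbsChange find the extremes and agree with a
           pairwise oracle", {
  med <- rbind(A = c(0.10, 0.15, 0.25, 0.2),
               B = rep(0.4, 4),
               C = c(0.35, 0.2, 0.10, 0.3))
  rms <- makeRMS(med, years = c(10L, 20L, 30L, 40L))
  fc <- maxFoldChange(rms)
  expect_equal(fc$max_fc[1], 2.5)           # 0.25 / 0.10
  expect_equal(fc$max_fc[2], 1.0)           # constant track
  expect_equal(fc[fc$marker_id == "A", "year_min"], 10L)
  expect_equal(fc[fc$marker_id == "A", "year_max"], 30L)
  # same extreme years feed the absolute change
  ab <- maxAbsChange(rms)
  expect_equal(ab$max_delta, c(0.15, 0, 0.25))
  expect_equal(ab$year_min, fc$year_min)
  # O(Y^2) oracle: max over all year pairs of |m_i - m_j|
  for (m in rownames(med)) {
    brute <- max(abs(outer(med[m, ], med[m, ], "-")))
    expect_equal(ab$max_delta[ab$marker_id == m], brute)
  }
  # epsilon guard at a zero minimum, with the audit flag
  z <- makeRMS(rbind(Z = c(0, 0.3)), years = c(1L, 2L))
  fz <- maxFoldChange(z, epsilon = 1e-6)
  expect_equal(fz$max_fc, 0.3 / 1e-6)
  expect_true(fz$eps_guarded)
  expect_error(maxFoldChange(makeRMS(rbind(A = 0.5))), "2 retained years")
})

test_that("max_fc >= 1 and max_delta = 0 iff max_fc = 1 on random tracks", {
  set.seed(4)
  for (i in 1:20) {
    med <- matrix(runif(8, 0.05, 0.95), 1, dimnames = list("m", NULL))
    if (i %% 5 == 0) med[] <- med[1]
    fc <- maxFoldChange(makeRMS(med))
    expect_gte(fc$max_fc, 1)
    expect_gte(fc$max_delta, 0)
    expect_equal(fc$max_delta == 0, fc$max_fc == 1)
  }
})

test_that("extremesTTest equals the hand-evaluated Welch formula", {
  g1 <- c(0.10, 0.14, 0.12, 0.11, 0.13)
  g2 <- c(0.30, 0.26, 0.31, 0.24, 0.33)
  b <- rbind(M = c(g1, g2))
  colnames(b) <- sprintf("S%d", 1:10)
  ages <- c(rep(10, 5), rep(80, 5)); names(ages) <- colnames(b)
  be <- BetaExperiment(b, data.frame(age = ages, row.names = colnames(b)))
  idx <- buildAgeGroups(ages, fraction = 0.5)
  p <- extremesTTest(be, idx, "M", 10L, 80L)
  # Welch statistic and Welch-Satterthwaite df by the standard formulas
  n <- 5
  se2 <- var(g1) / n + var(g2) / n
  tt <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((var(g1) / n)^2 / (n - 1) + (var(g2) / n)^2 / (n - 1))
  expect_equal(p, 2 * pt(-abs(tt), df))

  # identical member groups: zero mean difference -> p = 1
  pSame <- extremesTTest(be, idx, "M", 10L, 10L)
  expect_equal(pSame, 1)

  # well-separated distributions are overwhelmingly significant
  set.seed(9)
  x <- c(rnorm(40, 0.2, 0.01), rnorm(40, 0.6, 0.01))
  b2 <- rbind(M = pmin(pmax(x, 0), 1)); colnames(b2) <- sprintf("S%d", 1:80)
  ages2 <- c(rep(20, 40), rep(70, 40)); names(ages2) <- colnames(b2)
  be2 <- BetaExperiment(b2, data.frame(age = ages2, row.names = colnames(b2)))
  idx2 <- buildAgeGroups(ages2, fraction = 0.5)
  expect_lt(extremesTTest(be2, idx2, "M", 20L, 70L), 1e-10)

  # degenerate group: fewer than 2 usable values -> NA
  b3 <- b; b3["M", 6:9] <- NA
  be3 <- BetaExperiment(b3, data.frame(age = ages, row.names = colnames(b3)))
  expect_true(is.na(extremesTTest(be3, idx, "M", 10L, 80L)))
})

test_that("bhFDR reproduces the step-up adjustment", {
  expect_equal(unname(bhFDR(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
  # min over j >= i of p_j * m / j, computed independently
  set.seed(5)
  p <- runif(50)
  m <- length(p); o <- order(p)
  manual <- numeric(m)
  manual[o] <- rev(cummin(rev(pmin(p[o] * m / seq_len(m), 1))))
  expect_equal(unname(bhFDR(p)), manual)
  expect_equal(bhFDR(0.37), 0.37)
  expect_equal(unname(bhFDR(rep(1, 5))), rep(1, 5))
  expect_equal(unname(bhFDR(c(0.01, NA, 0.04))), c(0.02, NA, 0.04))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("selectMarkers recovers planted trajectories and gates correctly", {
  specs <- rbind(
    trajectorySpec("sig", "sigmoid", baseline = 0.1, amplitude = 0.3,
                   midpointAge = 50, steepness = 0.15, noiseSd = 0.01),
    trajectorySpec("drift", "linear", baseline = 0.1, slope = 1e-4,
                   noiseSd = 0.001),
    do.call(rbind, lapply(1:30, function(i)
      trajectorySpec(sprintf("null%02d", i), "constant", baseline = 0.5,
                     noiseSd = 0.02))))
  be <- plantedCohort(400, specs, seed = 31)
  idx <- trimEdgeGroups(buildAgeGroups(be), 2)
  rms <- runningMedians(be, idx)
  sel <- selectMarkers(be, idx, rms)

  s <- as.data.frame(sel[sel$marker_id == "sig", ])
  expect_gt(s$max_fc, 2)
  expect_gte(s$max_delta, 0.25)
  expect_lt(s$q, 0.05)
  expect_true(s$fc_pass && s$abs_pass && s$overlap_pass)

  # the 1%-total-change drift marker fails both change gates
  d <- as.data.frame(sel[sel$marker_id == "drift", ])
  expect_lt(d$max_fc, 2)
  expect_lt(d$max_delta, 0.2)
  expect_false(d$fc_pass || d$abs_pass)
  # ... while Pearson flags it: r essentially 1
  pe <- pearsonSelection(be)
  expect_gt(pe[pe$marker_id == "drift", "pearson_r"], 0.9)
  expect_true(pe[pe$marker_id == "drift", "pearson_pass"])

  # flag algebra on every row
  expect_true(all(sel$overlap_pass == (sel$fc_pass & sel$abs_pass)))
  # no flat null passes the full selection
  expect_equal(sum(sel$fc_pass[grepl("null", sel$marker_id)]), 0)
})

test_that("pearsonSelection matches the covariance formula and conventions", {
  ages <- seq(0, 100, length.out = 40)
  b <- rbind(up = 0.1 + 1e-4 * ages,
             down = 0.5 - 1e-4 * ages,
             flat = rep(0.3, 40))
  colnames(b) <- sprintf("S%d", 1:40)
  be <- BetaExperiment(b, data.frame(age = ages, row.names = colnames(b)))
  pe <- pearsonSelection(be)
  expect_equal(pe[pe$marker_id == "up", "pearson_r"], 1.0)
  expect_equal(pe[pe$marker_id == "down", "pearson_r"], -1.0)
  # zero-variance convention: r = 0, p = 1
  expect_equal(pe[pe$marker_id == "flat", "pearson_r"], 0)
  expect_equal(pe[pe$marker_id == "flat", "p"], 1)

  # 5-point toy equals cov/(sd*sd) evaluated directly
  v <- c(0.2, 0.5, 0.4, 0.9, 0.3); a5 <- c(3, 9, 27, 60, 81)
  b5 <- rbind(m = v); colnames(b5) <- sprintf("S%d", 1:5)
  be5 <- BetaExperiment(b5, data.frame(age = a5, row.names = colnames(b5)))
  pe5 <- pearsonSelection(be5)
  expect_equal(pe5$pearson_r, cov(v, a5) / (sd(v) * sd(a5)))
})

test_that("genesMultiMarker counts genes with >= 2 markers, duplications and
           unmapped probes", {
  map <- data.frame(probe_id = c("m1", "m2", "m3", "m4", "m4"),
                    gene_id = c("G1", "G1", "G2", "G2", "G3"))
  res <- genesMultiMarker(c("m1", "m2", "m3"), map)
  expect_equal(res$genes$gene_id, "G1")
  expect_equal(res$genes$n_markers, 2)
  expect_equal(res$n_unmapped, 0)

  # probe mapped to two genes counts for both
  res2 <- genesMultiMarker(c("m3", "m4", "unmapped1"), map)
  expect_setequal(res2$genes$gene_id, "G2")
  expect_equal(res2$n_unmapped, 1)

  expect_equal(nrow(genesMultiMarker(character(0), map)$genes), 0)
})
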