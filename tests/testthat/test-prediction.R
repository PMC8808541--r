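test_that("fold partition covers every sample exactly once and reports are
           deterministic", {
  set.seed(20)
  feats <- matrix(runif(60 * 3), 60, 3,
                  dimnames = list(sprintf("S%d", 1:60), c("a", "b", "c")))
  ages <- runif(60, 0, 100)
  rep1 <- rfCV(feats, ages, folds = 5, seed = 2, ntree = 25)
  expect_equal(sort(rep1$predictions$sample), sort(rownames(feats)))
  expect_equal(as.vector(table(rep1$predictions$fold)), rep(12, 5))
  rep2 <- rfCV(feats, ages, folds = 5, seed = 2, ntree = 25)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_equal(rep1$mae_sd, sd(rep1$per_fold$mae))
})

test_that("a fully predictive feature yields small cross-validated error", {
  set.seed(21)
  ages <- runif(500, 0, 100)
  feats <- matrix(ages / 100, ncol = 1,
                  dimnames = list(sprintf("S%d", 1:500), "m"))
  rep <- rfCV(feats, ages, folds = 5, seed = 3)
  expect_lt(rep$mae_mean, 2)
  expect_gt(rep$r_mean, 0.99)
})

test_that("age-independent features score near the mean-age baseline and
           never below the leakage floor", {
  set.seed(22)
  n <- 200
  ages <- runif(n, 0, 100)
  feats <- matrix(runif(n * 20), n,
                  dimnames = list(sprintf("S%d", 1:n), sprintf("m%d", 1:20)))
  rep <- rfCV(feats, ages, folds = 5, seed = 4)
  # analytic per-fold baseline: predict the training-fold mean age
  base <- vapply(1:5, function(f) {
    te <- rep$predictions$fold == f
    mean(abs(ages[te] - mean(ages[!te])))
  }, numeric(1))
  expect_lt(abs(rep$mae_mean - mean(base)) / mean(base), 0.15)
  expect_gt(rep$mae_mean, mean(base) / 2)
})

test_that("missing features are imputed from the training fold and the run
           completes", {
  set.seed(23)
  ages <- runif(100, 0, 100)
  feats <- matrix(rep(ages / 100, 3), 100,
                  dimnames = list(sprintf("S%d", 1:100), sprintf("m%d", 1:3)))
  feats[sample(300, 30)] <- NA
  rep <- rfCV(feats, ages, folds = 5, seed = 5, ntree = 50)
  expect_true(all(is.finite(rep$predictions$predicted)))
  expect_lt(rep$mae_mean, 8)
})

test_that("applyLinearClock computes intercept + dot products, with the
           missing-marker contract", {
  b <- rbind(m1 = c(0.10, 0.20, 0.30, 0.40),
             m2 = c(0.50, 0.50, 0.25, 0.00),
             m3 = c(0.05, 0.10, 0.15, 0.20))
  colnames(b) <- sprintf("S%d", 1:4)
  clock <- list(intercept = 10, coefficients = c(m1 = 100, m2 = -20, m3 = 40))
  pred <- applyLinearClock(clock, b)
  hand <- 10 + 100 * b["m1", ] - 20 * b["m2", ] + 40 * b["m3", ]
  expect_equal(pred, hand)

  # all-zero coefficients: the intercept everywhere
  z <- list(intercept = 50, coefficients = c(m1 = 0, m2 = 0))
  expect_equal(unname(applyLinearClock(z, b)), rep(50, 4))

  # constructed identity: one coefficient 100 on beta = age/100
  ages <- c(12, 40, 77, 95)
  ib <- rbind(m1 = ages / 100); colnames(ib) <- sprintf("S%d", 1:4)
  ident <- list(intercept = 0, coefficients = c(m1 = 100))
  expect_equal(unname(applyLinearClock(ident, ib)), ages)

  bad <- list(intercept = 0, coefficients = c(m1 = 1, m9 = 1))
  expect_error(applyLinearClock(bad, b), "m9")
  expect_warning(p2 <- applyLinearClock(bad, b, dropMissing = TRUE), "dropping")
  expect_equal(unname(p2), unname(b["m1", ]))
})

test_that("clock round-trips through the coefficient TSV with intercept row", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(marker_id = c("(Intercept)", "m1", "m2"),
                         coefficient = c(5, 2.5, -1)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  clock <- readClock(f)
  expect_equal(clock$intercept, 5)
  expect_equal(clock$coefficients, c(m1 = 2.5, m2 = -1))
})

test_that("signedErrorByAge isolates the oldest-decile bias", {
  pred <- data.frame(age = seq(1, 100), predicted = seq(1, 100))
  expect_equal(signedErrorByAge(pred), 0)

  capped <- data.frame(age = seq(1, 100), predicted = pmin(seq(1, 100), 60))
  se <- signedErrorByAge(capped, quantile = 0.9)
  old <- capped$age >= quantile(capped$age, 0.9)
  expect_equal(se, mean(60 - capped$age[old]))
  expect_lt(se, 0)
  expect_error(signedErrorByAge(data.frame(age = numeric(0),
                                           predicted = numeric(0))),
               "quantile|no samples")
})

test_that("a linear clock trained on saturating markers underpredicts the
           oldest decile while the forest is less biased", {
  meta <- simulateCohort(250, 0, 100, "uniform", seed = 71)
  be <- simulateBetaMatrix(meta, saturatingSpecs(20, seed = 71), seed = 72)
  feats <- t(betaValues(be))
  ages <- sampleAges(be)
  lin <- linearCV(feats, ages, seed = 73)
  rf <- rfCV(feats, ages, seed = 73)
  seLin <- signedErrorByAge(lin)
  seRF <- signedErrorByAge(rf)
  expect_lt(seLin, 0)
  expect_lt(abs(seRF), abs(seLin))
})

test_that("trainLinearClock + applyLinearClock reproduce in-sample OLS", {
  set.seed(24)
  ages <- runif(80, 0, 100)
  b <- rbind(m1 = pmin(pmax(ages / 100 + rnorm(80, 0, 0.01), 0), 1),
             m2 = runif(80))
  colnames(b) <- sprintf("S%d", 1:80)
  clock <- trainLinearClock(t(b), ages)
  pred <- applyLinearClock(clock, b)
  ols <- lm(ages ~ t(b))
  expect_equal(unname(pred), unname(fitted(ols)))
})
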