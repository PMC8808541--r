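# Small in-code fixtures shared across test files.

# beta matrix with explicit values and ages; probes P1..Pp, samples S1..Sn
tinyBeta <- function(values, ages) {
  m <- as.matrix(values)
  rownames(m) <- sprintf("P%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  BetaExperiment(m, data.frame(age = ages, row.names = colnames(m)))
}

# a one-per-year cohort: ages 1..100, one constant probe
gridCohort <- function() {
  ages <- 1:100
  b <- matrix(0.3, 1, 100,
              dimnames = list("P1", sprintf("S%d", 1:100)))
  BetaExperiment(b, data.frame(age = ages, row.names = colnames(b)))
}

# standard synthetic cohort for planted-truth tests
plantedCohort <- function(n = 200, specs, seed = 42, missingRate = 0,
                          nOutliers = 0) {
  meta <- simulateCohort(n, 0, 102, "uniform", seed = seed)
  simulateBetaMatrix(meta, specs, missingRate = missingRate,
                     nOutliers = nOutliers, seed = seed + 1)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw all C(N, n) subsets, count those sharing >= x members with {1..D}
enumUpperTail <- function(x, n, D, N) {
  combos <- utils::combn(N, n)
  hits <- colSums(combos <= D)
  mean(hits >= x)
}

# adjusted Rand index (only used if mclust is available)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
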