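#' Define a marker trajectory
#'
#' One row of a trajectory specification table. Shapes cover the families
#' seen in ageing methylomes: flat markers, slow linear drifts, saturating
#' (logistic) trajectories, and step changes such as an abrupt drop around
#' a given age.
#'
#' @param markerId probe id.
#' @param shape one of "constant", "linear", "sigmoid", "step".
#' @param baseline beta value at the trajectory origin, in [0,1].
#' @param amplitude signed total beta change (sigmoid/step).
#' @param slope beta change per year (linear).
#' @param midpointAge inflection / step age in years (sigmoid/step).
#' @param steepness logistic rate, 1/years (sigmoid).
#' @param noiseSd additive Gaussian noise SD in beta units.
#' @return one-row data.frame; rbind rows to build a cohort spec table.
#' @export
trajectorySpec <- function(markerId, shape = c("constant", "linear", "sigmoid", "step"),
                           baseline = 0.3, amplitude = 0, slope = 0,
                           midpointAge = NA_real_, steepness = NA_real_,
                           noiseSd = 0.02) {
  shape <- match.arg(shape)
  if (baseline < 0 || baseline > 1)
    stop("baseline must lie in [0, 1]")
  if (shape %in% c("sigmoid", "step") && is.na(midpointAge))
    stop("shape '", shape, "' requires midpointAge")
  if (shape == "sigmoid" && is.na(steepness))
    stop("shape 'sigmoid' requires steepness")
  data.frame(marker_id = as.character(markerId), shape = shape,
             baseline = baseline, amplitude = amplitude, slope = slope,
             midpoint_age = midpointAge, steepness = steepness,
             noise_sd = noiseSd, stringsAsFactors = FALSE)
}

#' Noiseless expected beta of a trajectory at given ages
#'
#' Evaluates the mean trajectory, clipped to [0,1]:
#' constant: baseline; linear: baseline + slope*age;
#' sigmoid: baseline + amplitude / (1 + exp(-steepness*(age - midpoint)));
#' step: baseline before the midpoint age, baseline + amplitude at/after.
#'
#' @param spec a single trajectory spec (one-row data.frame or list) as made
#'   by \code{\link{trajectorySpec}}.
#' @param age numeric vector of ages (years, >= 0).
#' @return numeric vector of expected beta values in [0,1].
#' @examples
#' sp <- trajectorySpec("cg1", "linear", baseline = 0.10, slope = 1e-4)
#' trajectoryEval(sp, 100)  # 0.11: a 1% total change over a century
#' @export
trajectoryEval <- function(spec, age) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1L)
    spec <- as.list(spec)
  }
  if (any(age < 0)) stop("age must be non-negative")
  v <- switch(as.character(spec$shape),
    constant = rep(spec$baseline, length(age)),
    linear   = spec$baseline + spec$slope * age,
    sigmoid  = spec$baseline +
      spec$amplitude / (1 + exp(-spec$steepness * (age - spec$midpoint_age))),
    step     = spec$baseline + ifelse(age >= spec$midpoint_age, spec$amplitude, 0),
    stop("unknown trajectory shape: ", spec$shape))
  pmin(pmax(v, 0), 1)
}

#' Simulate an age-structured cohort
#'
#' Draws sample ages from a uniform or a truncated-Gaussian-mixture density
#' on [ageMin, ageMax]; the mixture emulates the non-uniform age densities
#' typical of clinical methylation cohorts (dense middle ages, sparse
#' extremes).
#'
#' @param n number of samples.
#' @param ageMin,ageMax age range in years.
#' @param ageDistribution "uniform" or "mixture".
#' @param mixture list of components (mean, sd, weight) for "mixture".
#' @param seed integer RNG seed; identical seed gives an identical table.
#' @return data.frame with sample_id, age, sex columns.
#' @export
simulateCohort <- function(n, ageMin = 0, ageMax = 102,
                           ageDistribution = c("uniform", "mixture"),
                           mixture = list(list(mean = 45, sd = 15, weight = 0.6),
                                          list(mean = 75, sd = 8, weight = 0.4)),
                           seed = 1L) {
  ageDistribution <- match.arg(ageDistribution)
  if (n < 1) stop("n must be >= 1")
  if (ageMin >= ageMax) stop("ageMin must be < ageMax")
  set.seed(seed)
  if (ageDistribution == "uniform") {
    ages <- runif(n, ageMin, ageMax)
  } else {
    w <- vapply(mixture, `[[`, numeric(1), "weight")
    comp <- sample(length(mixture), n, replace = TRUE, prob = w)
    ages <- numeric(n)
    for (i in seq_len(n)) {
      m <- mixture[[comp[i]]]
      repeat {  # rejection sampling keeps the truncation exact
        a <- rnorm(1, m$mean, m$sd)
        if (a >= ageMin && a <= ageMax) break
      }
      ages[i] <- a
    }
  }
  data.frame(sample_id = sprintf("S%04d", seq_len(n)), age = ages,
             sex = sample(c("F", "M"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a beta matrix with known ground truth
#'
#' Each entry is clip(trajectoryEval(spec, age) + N(0, noise_sd), 0, 1).
#' Whole-sample outliers are planted by permuting a sample's values across
#' probes: the marginal beta distribution is preserved but the probe-wise
#' correspondence with the cohort is destroyed, giving a detectable
#' mutual-information signal. Missing entries are then punched at random
#' coordinates. All planting is recorded in a truth object stored in
#' \code{metadata(x)$truth}.
#'
#' @param meta cohort table from \code{\link{simulateCohort}}.
#' @param specs trajectory spec table (rbind of \code{\link{trajectorySpec}} rows).
#' @param missingRate fraction of entries set missing, in [0,1].
#' @param nOutliers number of samples to probe-permute.
#' @param seed integer RNG seed.
#' @return a \linkS4class{BetaExperiment}; \code{metadata(x)$truth} holds
#'   \code{specs}, \code{outlier_samples}, \code{missing_coords} and the
#'   number of clip events.
#' @export
simulateBetaMatrix <- function(meta, specs, missingRate = 0, nOutliers = 0,
                               seed = 1L) {
  if (nrow(specs) == 0) stop("specs must be non-empty")
  if (missingRate < 0 || missingRate > 1)
    stop("missingRate must lie in [0, 1]")
  if (nOutliers > nrow(meta)) stop("more outliers than samples")
  set.seed(seed)
  ages <- meta$age
  p <- nrow(specs); n <- nrow(meta)
  beta <- matrix(NA_real_, p, n,
                 dimnames = list(specs$marker_id, meta$sample_id))
  clipEvents <- 0L
  for (i in seq_len(p)) {
    mu <- trajectoryEval(specs[i, ], ages)
    v <- mu + rnorm(n, 0, specs$noise_sd[i])
    clipEvents <- clipEvents + sum(v < 0 | v > 1)
    beta[i, ] <- pmin(pmax(v, 0), 1)
  }
  outliers <- character(0)
  if (nOutliers > 0) {
    outliers <- sample(meta$sample_id, nOutliers)
    for (s in outliers) beta[, s] <- beta[sample(p), s]
  }
  missCoords <- NULL
  if (missingRate > 0) {
    nmiss <- round(missingRate * p * n)
    idx <- sample(p * n, nmiss)
    beta[idx] <- NA_real_
    missCoords <- cbind(row = ((idx - 1L) %% p) + 1L,
                        col = ((idx - 1L) %/% p) + 1L)
  }
  truth <- list(specs = specs, outlier_samples = outliers,
                missing_coords = missCoords, clip_events = clipEvents,
                seed = seed)
  BetaExperiment(beta, meta, metadata = list(truth = truth))
}

#' Trajectory spec table for a standard simulation study
#'
#' Convenience builder for a realistic marker mix: \code{nSignal} planted
#' markers with large trajectories (split evenly across sigmoid/saturating,
#' step, and steep linear shapes), \code{nDrift} markers with a slow linear
#' drift (1\% total beta change per century: perfectly age-correlated yet
#' far below any fold-change or absolute-change gate, the family that a
#' direct Pearson selection flags and a fold-change selection ignores),
#' and \code{nNull} flat noise markers.
#'
#' @param nNull flat markers.
#' @param nSignal planted markers with large age trajectories.
#' @param nDrift slow-drift linear markers (slope 1e-4 beta/year).
#' @param baseline,amplitude,noiseSd shared planted-marker parameters.
#' @param seed seed for randomised midpoints/baselines.
#' @return spec table; planted ids start with "cg_sig", drifting ids with
#'   "cg_drift".
#' @export
studySpecs <- function(nNull = 850, nSignal = 50, nDrift = 100,
                       baseline = 0.1, amplitude = 0.3, noiseSd = 0.03,
                       seed = 1L) {
  set.seed(seed)
  nulls <- if (nNull > 0) do.call(rbind, lapply(seq_len(nNull), function(i)
    trajectorySpec(sprintf("cg_null%04d", i), "constant",
                   baseline = runif(1, 0.05, 0.95), noiseSd = noiseSd)))
    else NULL
  drift <- if (nDrift > 0) do.call(rbind, lapply(seq_len(nDrift), function(i)
    trajectorySpec(sprintf("cg_drift%04d", i), "linear",
                   baseline = runif(1, 0.1, 0.6), slope = 1e-4,
                   noiseSd = noiseSd)))
    else NULL
  shapes <- rep(c("sigmoid", "step", "linear"), length.out = nSignal)
  sig <- do.call(rbind, lapply(seq_len(nSignal), function(i) {
    sh <- shapes[i]
    trajectorySpec(sprintf("cg_sig%04d", i), sh, baseline = baseline,
                   amplitude = if (sh == "linear") 0 else amplitude,
                   slope = if (sh == "linear") amplitude / 100 else 0,
                   midpointAge = runif(1, 35, 65),
                   steepness = if (sh == "sigmoid") runif(1, 0.1, 0.3) else NA,
                   noiseSd = noiseSd)
  }))
  rbind(sig, drift, nulls)
}

#' Trajectory specs for an all-saturating cohort
#'
#' Every marker is a rising logistic that plateaus well before the oldest
#' ages (midpoints 25-55 years, rates 0.07-0.15 per year), emulating a
#' tissue whose methylation-age relationships all saturate: past the
#' plateau the beta values carry no further age information, the regime in
#' which linear age models systematically underpredict old ages.
#'
#' @param nMarkers number of markers.
#' @param baseline,amplitude,noiseSd trajectory parameters.
#' @param seed RNG seed for midpoints and rates.
#' @return spec table.
#' @export
saturatingSpecs <- function(nMarkers = 40, baseline = 0.1, amplitude = 0.35,
                            noiseSd = 0.02, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nMarkers), function(i)
    trajectorySpec(sprintf("cg_sat%03d", i), "sigmoid", baseline = baseline,
                   amplitude = amplitude, midpointAge = runif(1, 25, 55),
                   steepness = runif(1, 0.07, 0.15), noiseSd = noiseSd)))
}
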