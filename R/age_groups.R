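#' Build per-year closest-fraction age groups
#'
#' For each integer year from floor(min age) to ceil(max age), selects the
#' k = ceil(fraction * n) samples closest in age to that year. Equal
#' sampling per year avoids grouping effects from non-uniform age density.
#' Distance ties are broken by ascending sample index so the grouping is
#' deterministic across platforms.
#'
#' @param x a \linkS4class{BetaExperiment}, or a numeric age vector (years;
#'   names taken as sample ids, else S1..Sn).
#' @param fraction fraction of samples per group, in (0, 1]; default 0.1.
#' @return an \linkS4class{AgeGroupIndex} with all groups marked retained.
#' @export
buildAgeGroups <- function(x, fraction = 0.1) {
  ages <- if (is(x, "BetaExperiment")) sampleAges(x) else x
  if (length(ages) == 0) stop("empty age vector")
  if (length(ages) < 10) stop("need at least 10 samples")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (is.null(names(ages))) names(ages) <- sprintf("S%d", seq_along(ages))
  n <- length(ages)
  k <- as.integer(ceiling(fraction * n))
  years <- seq.int(floor(min(ages)), ceiling(max(ages)))
  members <- vector("list", length(years))
  midpoints <- numeric(length(years))
  limits <- matrix(NA_real_, length(years), 2,
                   dimnames = list(years, c("min_age", "max_age")))
  for (i in seq_along(years)) {
    d <- abs(ages - years[i])
    ord <- order(d, seq_along(ages))[seq_len(k)]  # ties -> lower index
    members[[i]] <- names(ages)[ord]
    midpoints[i] <- median(ages[ord])
    limits[i, ] <- range(ages[ord])
  }
  new("AgeGroupIndex", years = as.integer(years), members = members,
      midpoints = midpoints, limits = limits, k = k, fraction = fraction,
      retained = rep(TRUE, length(years)))
}

#' Trim edge groups whose midpoint drifts from the year it represents
#'
#' At the extremes of the age range the closest-fraction groups are pulled
#' toward the bulk of the cohort: a year represented by a single very young
#' sample gets a group spanning far older ages and a midpoint well away
#' from the nominal year. Such groups are excluded: year y is retained iff
#' |group midpoint(y) - y| <= tolerance. The retained span is the analysis
#' age range.
#'
#' @param index an \linkS4class{AgeGroupIndex}.
#' @param tolerance maximum midpoint deviation in years (default 2).
#' @return the index with its \code{retained} flags updated.
#' @export
trimEdgeGroups <- function(index, tolerance = 2) {
  stopifnot(is(index, "AgeGroupIndex"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  keep <- abs(index@midpoints - index@years) <= tolerance
  if (!any(keep))
    stop("no age group retained at tolerance ", tolerance,
         "; increase the tolerance or check the age distribution")
  index@retained <- keep
  index
}

# row-wise medians / SDs ignoring NA; plain apply is fast enough at the
# matrix sizes this package targets (<= a few thousand probes per call)
.rowMedians <- function(m) apply(m, 1, median, na.rm = TRUE)
.rowSDs <- function(m) apply(m, 1, sd, na.rm = TRUE)

#' Running medians of beta values across retained age groups
#'
#' Per marker and retained year: the median of the group members'
#' non-missing beta values (the median being less outlier-sensitive than a
#' mean), the relative standard deviation SD/median used by the spread
#' filter, and the count of values used. A marker-year with no non-missing
#' member values is recorded as missing; an interval with median 0 gets
#' relative SD +Inf so the marker fails the spread filter downstream.
#'
#' @param x a \linkS4class{BetaExperiment}.
#' @param index an \linkS4class{AgeGroupIndex} built on the same samples,
#'   typically after \code{\link{trimEdgeGroups}}.
#' @param years years to evaluate; defaults to \code{retainedYears(index)}.
#' @return a \linkS4class{RunningMedianSet}.
#' @export
runningMedians <- function(x, index, years = retainedYears(index)) {
  stopifnot(is(x, "BetaExperiment"), is(index, "AgeGroupIndex"))
  if (!all(years %in% index@years))
    stop("requested years are not a subset of the group grid")
  b <- betaValues(x)
  allMembers <- unique(unlist(index@members[match(years, index@years)]))
  if (!all(allMembers %in% colnames(b)))
    stop("group members missing from the beta matrix: ",
         paste(head(setdiff(allMembers, colnames(b))), collapse = ", "))
  p <- nrow(b)
  med <- sds <- matrix(NA_real_, p, length(years),
                       dimnames = list(rownames(b), years))
  nUsed <- matrix(0L, p, length(years), dimnames = dimnames(med))
  for (j in seq_along(years)) {
    sub <- b[, groupMembers(index, years[j]), drop = FALSE]
    med[, j] <- .rowMedians(sub)
    sds[, j] <- .rowSDs(sub)
    nUsed[, j] <- rowSums(!is.na(sub))
  }
  med[is.nan(med)] <- NA_real_
  relSD <- sds / med
  relSD[!is.na(med) & med == 0] <- Inf
  new("RunningMedianSet", medians = med, relSD = relSD, nUsed = nUsed,
      years = as.integer(years))
}

#' Mean relative standard deviation per marker
#'
#' Averages the per-interval relative SD over either all retained
#' intervals (\code{scope = "all"}) or only the two intervals that realise
#' the marker's extreme medians (\code{scope = "extremes"}; requires the
#' extreme years). Markers with any infinite interval value get +Inf under
#' scope "all".
#'
#' @param rms a \linkS4class{RunningMedianSet}.
#' @param scope "all" or "extremes".
#' @param extremeYears two-column matrix (min-year, max-year) per marker,
#'   as returned in \code{\link{maxFoldChange}} output; required for
#'   \code{scope = "extremes"}.
#' @return named numeric vector of mean relative SDs.
#' @export
meanRelSD <- function(rms, scope = c("all", "extremes"), extremeYears = NULL) {
  scope <- match.arg(scope)
  r <- relativeSD(rms)
  if (scope == "all") return(rowMeans(r, na.rm = TRUE))
  if (is.null(extremeYears))
    stop("scope = 'extremes' requires extremeYears")
  ji <- match(extremeYears[, 1], trackYears(rms))
  ja <- match(extremeYears[, 2], trackYears(rms))
  out <- (r[cbind(seq_len(nrow(r)), ji)] + r[cbind(seq_len(nrow(r)), ja)]) / 2
  names(out) <- rownames(r)
  out
}
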