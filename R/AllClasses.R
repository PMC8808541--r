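#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' Container for a methylation beta-value matrix with sample ages
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"beta"} (CpG probes in rows, samples in columns, values in
#' \eqn{[0,1]} with \code{NA} for missing entries) and a numeric
#' non-negative \code{age} column (years) in \code{colData}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots.
#' @export
setClass("BetaExperiment", contains = "SummarizedExperiment")

setValidity("BetaExperiment", function(object) {
  msg <- NULL
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    if (!is.numeric(b))
      msg <- c(msg, "'beta' assay must be numeric")
    else {
      rng <- suppressWarnings(range(b, na.rm = TRUE))
      if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
        msg <- c(msg, "non-missing beta values must lie in [0, 1]")
    }
  }
  if (!"age" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain an 'age' column (years)")
  else {
    a <- colData(object)$age
    if (!is.numeric(a) || anyNA(a) || any(a < 0))
      msg <- c(msg, "'age' must be numeric, non-missing and non-negative")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BetaExperiment
#'
#' @param beta numeric matrix, probes x samples, values in [0,1] or NA.
#'   Must have row (probe) and column (sample) names.
#' @param sampleData data.frame or DataFrame with one row per sample and at
#'   least an \code{age} column; rownames (or a \code{sample_id} column)
#'   must match \code{colnames(beta)}.
#' @param metadata optional list stored in \code{metadata()}.
#' @return A \linkS4class{BetaExperiment}.
#' @examples
#' b <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' be <- BetaExperiment(b, data.frame(age = c(20, 50, 80),
#'                                    row.names = colnames(b)))
#' sampleAges(be)
#' @export
BetaExperiment <- function(beta, sampleData, metadata = list()) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must have probe rownames and sample colnames")
  cd <- DataFrame(sampleData)
  if ("sample_id" %in% colnames(cd) && is.null(rownames(sampleData)))
    rownames(cd) <- cd$sample_id
  if (is.null(rownames(cd))) rownames(cd) <- colnames(beta)
  cd <- cd[colnames(beta), , drop = FALSE]
  se <- SummarizedExperiment(assays = list(beta = beta), colData = cd,
                             metadata = metadata)
  new("BetaExperiment", se)
}

#' @rdname BetaExperiment
#' @param object,x a BetaExperiment
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname BetaExperiment
#' @export
setMethod("betaValues", "BetaExperiment", function(x) assay(x, "beta"))

#' @rdname BetaExperiment
#' @export
setGeneric("sampleAges", function(x) standardGeneric("sampleAges"))

#' @rdname BetaExperiment
#' @export
setMethod("sampleAges", "BetaExperiment", function(x) {
  a <- colData(x)$age
  names(a) <- colnames(x)
  a
})

#' @rdname BetaExperiment
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname BetaExperiment
#' @export
setMethod("qcReport", "BetaExperiment", function(x) metadata(x)$qc)

setMethod("show", "BetaExperiment", function(object) {
  cat("BetaExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  a <- sampleAges(object)
  cat("  ages:", sprintf("%.1f-%.1f", min(a), max(a)), "years\n")
  nm <- sum(is.na(assay(object, "beta")))
  cat("  missing beta entries:", nm, "\n")
  if (!is.null(metadata(object)$truth))
    cat("  synthetic cohort with planted ground truth (metadata(x)$truth)\n")
  if (!is.null(metadata(object)$qc))
    cat("  QC report attached (qcReport(x))\n")
})

#' Per-year age groups of the age-nearest fraction of samples
#'
#' One group per integer year from floor(min age) to ceil(max age); each
#' group holds the k = ceil(fraction * n) samples closest in age to that
#' year (ties by ascending sample index), ordered by |age - year|.
#'
#' @slot years integer grid of group centres.
#' @slot members list of character sample-id vectors, one per year.
#' @slot midpoints numeric median member age per group (years).
#' @slot limits numeric matrix (years x 2) of min/max member age.
#' @slot k integer group size.
#' @slot fraction numeric fraction of samples per group.
#' @slot retained logical, set by \code{\link{trimEdgeGroups}}.
#' @export
setClass("AgeGroupIndex",
  representation(years = "integer", members = "list", midpoints = "numeric",
                 limits = "matrix", k = "integer", fraction = "numeric",
                 retained = "logical"))

setValidity("AgeGroupIndex", function(object) {
  ny <- length(object@years)
  if (length(object@members) != ny || length(object@midpoints) != ny ||
      nrow(object@limits) != ny || length(object@retained) != ny)
    return("per-year slots must have one entry per year")
  if (!all(lengths(object@members) == object@k))
    return("every group must have exactly k members")
  if (ny > 1 && any(diff(object@years) != 1L))
    return("years must be a consecutive integer grid")
  TRUE
})

#' @rdname AgeGroupIndex
#' @param x an AgeGroupIndex
#' @export
setGeneric("groupYears", function(x) standardGeneric("groupYears"))
#' @rdname AgeGroupIndex
#' @export
setMethod("groupYears", "AgeGroupIndex", function(x) x@years)

#' @rdname AgeGroupIndex
#' @param year integer year, or NULL for all groups
#' @export
setGeneric("groupMembers", function(x, year = NULL) standardGeneric("groupMembers"))
#' @rdname AgeGroupIndex
#' @export
setMethod("groupMembers", "AgeGroupIndex", function(x, year = NULL) {
  if (is.null(year)) return(x@members)
  i <- match(year, x@years)
  if (anyNA(i)) stop("year ", year[is.na(i)][1], " not in the group grid")
  if (length(i) == 1L) x@members[[i]] else x@members[i]
})

#' @rdname AgeGroupIndex
#' @export
setGeneric("groupMidpoints", function(x) standardGeneric("groupMidpoints"))
#' @rdname AgeGroupIndex
#' @export
setMethod("groupMidpoints", "AgeGroupIndex", function(x) {
  m <- x@midpoints
  names(m) <- x@years
  m
})

#' @rdname AgeGroupIndex
#' @export
setGeneric("retainedYears", function(x) standardGeneric("retainedYears"))
#' @rdname AgeGroupIndex
#' @export
setMethod("retainedYears", "AgeGroupIndex", function(x) x@years[x@retained])

setMethod("show", "AgeGroupIndex", function(object) {
  cat("AgeGroupIndex:", length(object@years), "yearly groups of k =",
      object@k, sprintf("samples (fraction %.3g)\n", object@fraction))
  cat("  year grid:", min(object@years), "-", max(object@years), "\n")
  r <- retainedYears(object)
  if (length(r) && length(r) < length(object@years))
    cat("  retained after edge trim:", min(r), "-", max(r),
        sprintf("(%d groups)\n", length(r)))
})

#' Running-median beta trajectories per marker
#'
#' Markers in rows, retained years in columns: the per-group median beta
#' (\code{medians}), per-group relative standard deviation SD/median
#' (\code{relSD}, +Inf where the median is 0), and the number of
#' non-missing member values used (\code{nUsed}).
#'
#' @slot medians,relSD numeric matrices, markers x retained years.
#' @slot nUsed integer matrix of like shape.
#' @slot years integer retained years (column grid).
#' @export
setClass("RunningMedianSet",
  representation(medians = "matrix", relSD = "matrix", nUsed = "matrix",
                 years = "integer"))

setValidity("RunningMedianSet", function(object) {
  d <- dim(object@medians)
  if (!identical(dim(object@relSD), d) || !identical(dim(object@nUsed), d))
    return("medians, relSD and nUsed must share dimensions")
  if (length(object@years) != d[2])
    return("one column per retained year required")
  if (is.unsorted(object@years, strictly = TRUE))
    return("years must be strictly increasing")
  m <- object@medians
  if (any(m < 0 | m > 1, na.rm = TRUE))
    return("medians must lie in [0, 1]")
  TRUE
})

#' @rdname RunningMedianSet
#' @param x a RunningMedianSet
#' @export
setGeneric("medianTracks", function(x) standardGeneric("medianTracks"))
#' @rdname RunningMedianSet
#' @export
setMethod("medianTracks", "RunningMedianSet", function(x) x@medians)

#' @rdname RunningMedianSet
#' @export
setGeneric("relativeSD", function(x) standardGeneric("relativeSD"))
#' @rdname RunningMedianSet
#' @export
setMethod("relativeSD", "RunningMedianSet", function(x) x@relSD)

#' @rdname RunningMedianSet
#' @export
setGeneric("trackYears", function(x) standardGeneric("trackYears"))
#' @rdname RunningMedianSet
#' @export
setMethod("trackYears", "RunningMedianSet", function(x) x@years)

setMethod("show", "RunningMedianSet", function(object) {
  cat("RunningMedianSet:", nrow(object@medians), "markers x",
      length(object@years), "retained years (",
      min(object@years), "-", max(object@years), ")\n")
})

#' Result of a set-overlap significance test
#'
#' Contingency of two marker sets in a finite universe and the upper-tail
#' probability of their overlap: x markers shared between a set of size n
#' and a set of size D drawn from N.
#'
#' @slot x,n,D,N overlap count and the three set/universe sizes.
#' @slot p upper-tail probability P(X >= x).
#' @slot method "exact" (log-space hypergeometric) or "normal_approx".
#' @slot Z normal deviate (NA for the exact method).
#' @export
setClass("OverlapTest",
  representation(x = "numeric", n = "numeric", D = "numeric", N = "numeric",
                 p = "numeric", method = "character", Z = "numeric"))

setValidity("OverlapTest", function(object) {
  if (object@x < 0 || object@x > min(object@n, object@D))
    return("x must satisfy 0 <= x <= min(n, D)")
  if (object@p < 0 || object@p > 1) return("p must be a probability")
  TRUE
})

#' @rdname OverlapTest
#' @param x an OverlapTest
#' @export
setGeneric("overlapP", function(x) standardGeneric("overlapP"))
#' @rdname OverlapTest
#' @export
setMethod("overlapP", "OverlapTest", function(x) x@p)

setMethod("show", "OverlapTest", function(object) {
  cat("OverlapTest: x =", object@x, "shared of n =", object@n, "vs D =",
      object@D, "in universe N =", object@N, "\n")
  cat(sprintf("  P(X >= %d) = %.4g  [method: %s", object@x, object@p,
              object@method))
  if (!is.na(object@Z)) cat(sprintf(", Z = %.3f", object@Z))
  cat("]\n")
})
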