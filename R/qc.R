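#' Probe-level quality filtering
#'
#' Removes probes named on any blacklist (SNP-overlapping, cross-reactive,
#' or any user list) and probes with more than \code{maxMissing} missing
#' beta values (strictly more: a probe with exactly \code{maxMissing}
#' missing entries is retained). Probe order is preserved. Beta values are
#' deliberately left unnormalized.
#'
#' @param x a \linkS4class{BetaExperiment}.
#' @param blacklists named list of character vectors of probe ids (e.g.
#'   \code{list(snp_overlap = ..., cross_reactive = ...)}); ids absent from
#'   the matrix are ignored.
#' @param maxMissing maximum tolerated missing count per probe (default 10).
#' @return the filtered BetaExperiment; \code{qcReport(x)$probe_filter}
#'   itemizes removals per rule.
#' @export
filterProbes <- function(x, blacklists = list(), maxMissing = 10) {
  stopifnot(is(x, "BetaExperiment"))
  b <- betaValues(x)
  removedBy <- lapply(blacklists, function(ids) intersect(rownames(b), ids))
  onList <- unique(unlist(removedBy, use.names = FALSE))
  missCount <- rowSums(is.na(b))
  tooMissing <- setdiff(rownames(b)[missCount > maxMissing], onList)
  keep <- setdiff(rownames(b), c(onList, tooMissing))
  if (length(keep) == 0) {
    rule <- if (length(onList) >= length(tooMissing)) "blacklist" else "missing-value"
    stop("no probes survive filtering; the ", rule, " rule removed the last probes")
  }
  report <- list(
    input_probes = nrow(b),
    removed_blacklist = lengths(removedBy),
    removed_blacklist_total = length(onList),
    removed_missing = length(tooMissing),
    retained = length(keep),
    max_missing = maxMissing)
  out <- x[keep, ]
  qc <- metadata(out)$qc
  qc$probe_filter <- report
  metadata(out)$qc <- qc
  out
}

#' Mutual information between two binned beta distributions
#'
#' Plug-in MI (nats) of the joint histogram obtained by pairing the two
#' vectors positionally (probe by probe) and binning both into
#' \code{bins} equal-width bins on [0,1]. Pairs with a missing entry in
#' either vector are dropped.
#'
#' @param sampleValues,referenceValues beta vectors of equal length.
#' @param bins number of equal-width bins (default 10).
#' @return non-negative mutual information in nats.
#' @export
miScore <- function(sampleValues, referenceValues, bins = 10) {
  if (length(sampleValues) != length(referenceValues))
    stop("vectors must have equal length")
  ok <- !is.na(sampleValues) & !is.na(referenceValues)
  xs <- sampleValues[ok]; ys <- referenceValues[ok]
  if (length(xs) == 0) stop("no complete probe pairs (all-missing sample?)")
  if (length(xs) < bins)
    stop("need at least 'bins' complete pairs")
  brk <- seq(0, 1, length.out = bins + 1L)
  bx <- findInterval(xs, brk, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(ys, brk, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins))) / length(xs)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Flag and remove whole-sample outliers by mutual information
#'
#' Scores every sample's binned beta distribution against the cohort
#' reference (the per-probe mean over samples, missing entries excluded)
#' and flags samples whose MI falls below mean(MI) - kSD * SD(MI). Only
#' low MI flags an outlier, and the pass is run once (not iterated).
#'
#' @param x a \linkS4class{BetaExperiment} with at least 3 samples.
#' @param bins histogram bins for \code{\link{miScore}}.
#' @param kSD flagging threshold in SD units (default 3).
#' @return the BetaExperiment with flagged samples removed;
#'   \code{qcReport(x)$outliers} holds per-sample MI scores and the
#'   flagged ids.
#' @export
flagOutlierSamples <- function(x, bins = 10, kSD = 3) {
  stopifnot(is(x, "BetaExperiment"))
  b <- betaValues(x)
  if (ncol(b) < 3) stop("need at least 3 samples to estimate the MI spread")
  reference <- rowMeans(b, na.rm = TRUE)
  mi <- vapply(seq_len(ncol(b)),
               function(j) miScore(b[, j], reference, bins = bins),
               numeric(1))
  names(mi) <- colnames(b)
  s <- sd(mi)
  cutoff <- if (s == 0) -Inf else mean(mi) - kSD * s
  flagged <- names(mi)[mi < cutoff]
  keep <- setdiff(colnames(b), flagged)
  out <- x[, keep]
  qc <- metadata(out)$qc
  qc$outliers <- list(mi = mi, mean_mi = mean(mi), sd_mi = s,
                      cutoff = cutoff, k_sd = kSD, bins = bins,
                      flagged = flagged)
  metadata(out)$qc <- qc
  out
}

#' Read a probe blacklist file
#'
#' Plain text, one probe id per line; blank lines and \code{#} comments
#' are ignored.
#'
#' @param path file path.
#' @return character vector of probe ids.
#' @export
readBlacklist <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
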