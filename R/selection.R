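#' Maximum fold change and absolute change of running-median tracks
#'
#' Per marker, the relative change between the minimum and maximum running
#' medians: maxFC = max(median) / max(min(median), epsilon), together with
#' the years realising the extremes. The same extreme years realise the
#' maximum absolute change max(median) - min(median), so both statistics
#' share them. A zero (or sub-epsilon) minimum is guarded by epsilon and
#' flagged so affected markers remain auditable.
#'
#' @param rms a \linkS4class{RunningMedianSet}.
#' @param epsilon lower guard for the minimum median (default 1e-6).
#' @return \code{DataFrame} with max_fc, max_delta, year_min, year_max,
#'   eps_guarded per marker.
#' @export
maxFoldChange <- function(rms, epsilon = 1e-6) {
  m <- medianTracks(rms)
  yrs <- trackYears(rms)
  if (ncol(m) < 2) stop("need at least 2 retained years")
  res <- t(apply(m, 1, function(v) {
    ok <- which(!is.na(v))
    if (length(ok) == 0) return(c(NA, NA, NA, NA, NA))
    imin <- ok[which.min(v[ok])]; imax <- ok[which.max(v[ok])]
    mn <- v[imin]; mx <- v[imax]
    c(mx / max(mn, epsilon), mx - mn, yrs[imin], yrs[imax], mn < epsilon)
  }))
  if (any(is.na(res[, 1])))
    stop("marker(s) with all medians missing: ",
         paste(head(rownames(m)[is.na(res[, 1])]), collapse = ", "))
  DataFrame(marker_id = rownames(m), max_fc = unname(res[, 1]),
            max_delta = unname(res[, 2]),
            year_min = as.integer(unname(res[, 3])),
            year_max = as.integer(unname(res[, 4])),
            eps_guarded = as.logical(unname(res[, 5])))
}

#' @rdname maxFoldChange
#' @export
maxAbsChange <- function(rms) {
  fc <- maxFoldChange(rms)
  DataFrame(marker_id = fc$marker_id, max_delta = fc$max_delta,
            year_min = fc$year_min, year_max = fc$year_max)
}

#' Two-sided t-test between a marker's extreme age groups
#'
#' Compares the raw beta values of the group members at the year of the
#' minimum running median against those at the year of the maximum. The
#' adjacent-year groups can share members; the test is still computed as
#' two independent samples, mirroring the selection procedure.
#'
#' @param x a \linkS4class{BetaExperiment}.
#' @param index an \linkS4class{AgeGroupIndex}.
#' @param markerId marker (row) id.
#' @param yearMin,yearMax the extreme years from \code{\link{maxFoldChange}}.
#' @param variant "welch" (unequal variances, default) or "pooled".
#' @return two-sided p-value; NA if either group has fewer than 2
#'   non-missing values.
#' @export
extremesTTest <- function(x, index, markerId, yearMin, yearMax,
                          variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  b <- betaValues(x)
  g1 <- b[markerId, groupMembers(index, yearMin)]
  g2 <- b[markerId, groupMembers(index, yearMax)]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2 || length(g2) < 2) return(NA_real_)
  if (sd(g1) == 0 && sd(g2) == 0)
    return(if (mean(g1) == mean(g2)) 1 else 0)
  t.test(g1, g2, var.equal = (variant == "pooled"))$p.value
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH over the non-missing p-values; missing entries stay missing.
#'
#' @param pvals p-values in [0,1] (NA allowed).
#' @return q-values, capped at 1, in the input order.
#' @export
bhFDR <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- p.adjust(pvals[ok], method = "BH")
  names(q) <- names(pvals)
  q
}

#' Select markers by fold change and absolute change
#'
#' Computes per-marker extreme statistics and significance, then applies
#' the selection gates: \code{fc_pass} requires q < fdr, max FC strictly
#' above \code{fcThreshold} and mean relative SD <= \code{relSdMax};
#' \code{abs_pass} requires q < fdr, max absolute change of at least
#' \code{deltaThreshold} (inclusive) and the same spread gate;
#' \code{overlap_pass} is their conjunction (the joint selection). BH is
#' applied once over the chosen universe and reused by both gates.
#'
#' @param x a \linkS4class{BetaExperiment} (QC-filtered).
#' @param index an \linkS4class{AgeGroupIndex} on the same samples.
#' @param rms running medians from \code{\link{runningMedians}}.
#' @param fcThreshold FC gate, strict (default 2).
#' @param deltaThreshold absolute-change gate, inclusive (default 0.2).
#' @param fdr FDR level (default 0.05).
#' @param relSdMax spread gate on mean relative SD (default 0.5).
#' @param relSdScope see \code{\link{meanRelSD}}.
#' @param tVariant see \code{\link{extremesTTest}}.
#' @param fdrUniverse "all" applies BH over every QC-surviving marker;
#'   "spread_pass" restricts the BH universe to markers passing the
#'   relative-SD gate.
#' @param epsilon FC epsilon guard.
#' @return \code{DataFrame}, one row per marker: statistics, p, q, flags.
#' @export
selectMarkers <- function(x, index, rms, fcThreshold = 2, deltaThreshold = 0.2,
                          fdr = 0.05, relSdMax = 0.5,
                          relSdScope = c("all", "extremes"),
                          tVariant = c("welch", "pooled"),
                          fdrUniverse = c("all", "spread_pass"),
                          epsilon = 1e-6) {
  relSdScope <- match.arg(relSdScope)
  tVariant <- match.arg(tVariant)
  fdrUniverse <- match.arg(fdrUniverse)
  fc <- maxFoldChange(rms, epsilon = epsilon)
  mrs <- meanRelSD(rms, scope = relSdScope,
                   extremeYears = cbind(fc$year_min, fc$year_max))
  p <- vapply(seq_len(nrow(fc)), function(i)
    extremesTTest(x, index, fc$marker_id[i], fc$year_min[i], fc$year_max[i],
                  variant = tVariant), numeric(1))
  pForBH <- p
  if (fdrUniverse == "spread_pass") pForBH[!(mrs <= relSdMax)] <- NA_real_
  q <- bhFDR(pForBH)
  sig <- !is.na(q) & q < fdr
  spreadOK <- !is.na(mrs) & mrs <= relSdMax
  fcPass <- sig & fc$max_fc > fcThreshold & spreadOK
  absPass <- sig & fc$max_delta >= deltaThreshold & spreadOK
  DataFrame(marker_id = fc$marker_id, max_fc = fc$max_fc,
            max_delta = fc$max_delta, year_min = fc$year_min,
            year_max = fc$year_max, eps_guarded = fc$eps_guarded,
            mean_rel_sd = unname(mrs), t_p = p, q = unname(q),
            fc_pass = fcPass, abs_pass = absPass,
            overlap_pass = fcPass & absPass)
}

#' Pearson-correlation marker selection (the linear baseline)
#'
#' Per marker, the Pearson correlation between raw beta values and sample
#' age, its p-value from the usual t-transform, BH q-values and the q <
#' fdr pass flag. This is the direct linear-association selection that the
#' running-median procedure is contrasted with: a marker drifting 0.0001
#' per year over a century correlates perfectly with age yet changes only
#' 1% in total.
#'
#' @param x a \linkS4class{BetaExperiment}.
#' @param fdr FDR level (default 0.05).
#' @return \code{DataFrame} with pearson_r, p, q, pearson_pass per marker.
#' @export
pearsonSelection <- function(x, fdr = 0.05) {
  b <- betaValues(x)
  age <- sampleAges(x)
  res <- t(apply(b, 1, function(v) {
    ok <- !is.na(v)
    n <- sum(ok)
    if (n < 3) return(c(NA, NA))
    if (sd(v[ok]) == 0 || sd(age[ok]) == 0) return(c(0, 1))
    r <- cor(v[ok], age[ok])
    if (abs(r) >= 1) return(c(r, 0))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    c(r, 2 * pt(-abs(tt), df = n - 2))
  }))
  q <- bhFDR(res[, 2])
  DataFrame(marker_id = rownames(b), pearson_r = unname(res[, 1]),
            p = unname(res[, 2]), q = unname(q),
            pearson_pass = unname(!is.na(q) & q < fdr))
}

#' Genes carrying at least two selected markers
#'
#' Groups selected markers by mapped gene and returns the genes supported
#' by two or more markers. A probe mapped to several genes counts for each
#' of them; unmapped probes are ignored but counted.
#'
#' @param markerIds character vector of selected marker ids.
#' @param probeGeneMap data.frame with columns probe_id, gene_id.
#' @return list with \code{genes} (data.frame gene_id, n_markers,
#'   marker_ids) restricted to n_markers >= 2, and \code{n_unmapped}.
#' @export
genesMultiMarker <- function(markerIds, probeGeneMap) {
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probeGeneMap)))
  hit <- probeGeneMap[probeGeneMap$probe_id %in% markerIds, , drop = FALSE]
  nUnmapped <- length(setdiff(markerIds, probeGeneMap$probe_id))
  if (nrow(hit) == 0)
    return(list(genes = data.frame(gene_id = character(0),
                                   n_markers = integer(0),
                                   marker_ids = character(0)),
                n_unmapped = nUnmapped))
  byGene <- split(unique(hit)[, "probe_id"], unique(hit)[, "gene_id"])
  n <- lengths(byGene)
  keep <- n >= 2
  list(genes = data.frame(gene_id = names(byGene)[keep],
                          n_markers = unname(n[keep]),
                          marker_ids = vapply(byGene[keep], paste,
                                              character(1), collapse = ";"),
                          stringsAsFactors = FALSE, row.names = NULL),
       n_unmapped = nUnmapped)
}
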