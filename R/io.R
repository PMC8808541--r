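#' Read / write the beta-matrix TSV dialect
#'
#' First column \code{probe_id}, remaining columns one per sample; empty
#' fields or "NA" are missing entries.
#'
#' @param path TSV path.
#' @param metaPath sample metadata TSV (columns sample_id, age, ...);
#'   required by \code{readBetaTSV} to build a \linkS4class{BetaExperiment}.
#' @return \code{readBetaTSV}: a BetaExperiment.
#' @export
readBetaTSV <- function(path, metaPath) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "probe_id")
    stop("first column of a beta matrix TSV must be 'probe_id'")
  b <- as.matrix(tab[, -1, drop = FALSE])
  rownames(b) <- tab$probe_id
  meta <- readSampleMeta(metaPath)
  if (!all(colnames(b) %in% meta$sample_id))
    stop("matrix samples missing from the metadata: ",
         paste(head(setdiff(colnames(b), meta$sample_id)), collapse = ", "))
  BetaExperiment(b, meta[match(colnames(b), meta$sample_id), , drop = FALSE])
}

#' @rdname readBetaTSV
#' @param x a BetaExperiment
#' @export
writeBetaTSV <- function(x, path) {
  b <- betaValues(x)
  # 17 significant digits so a write/read cycle reproduces the doubles bit
  # for bit (stage re-runs from artifacts must equal in-memory runs)
  ch <- matrix(sprintf("%.17g", b), nrow(b), dimnames = dimnames(b))
  ch[is.na(b)] <- "NA"
  out <- data.frame(probe_id = rownames(b), ch, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readBetaTSV
#' @export
readSampleMeta <- function(metaPath) {
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "age") %in% colnames(meta)))
  meta
}

#' @rdname readBetaTSV
#' @param meta sample metadata data.frame
#' @export
writeSampleMeta <- function(meta, path) {
  meta <- as.data.frame(meta)
  for (j in seq_along(meta))  # full precision: see writeBetaTSV
    if (is.double(meta[[j]])) meta[[j]] <- sprintf("%.17g", meta[[j]])
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (probe_id, gene_id); a probe may map to several genes
#' on separate rows.
#'
#' @param path TSV path.
#' @return data.frame with probe_id, gene_id.
#' @export
readProbeGeneMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(tab)))
  tab
}

.writeTSV <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
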