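#' Default pipeline configuration
#'
#' Every stage parameter with its default: the closest-sample fraction
#' (0.1), edge-trim tolerance (2 years), MI bins (10) and SD multiplier
#' (3), the selection gates (FC > 2, delta >= 0.2, FDR 0.05, mean relative
#' SD <= 0.5), cluster count (2), CV folds (5) and the seed. Simulation
#' settings describe the bundled synthetic cohort used when no input files
#' are given.
#'
#' @return nested list; edit fields and pass to \code{\link{runPipeline}}.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    output_dir = tempfile("methyltrend_run_"),
    simulate = list(enabled = TRUE, n_samples = 300, age_min = 0,
                    age_max = 102, age_distribution = "uniform",
                    n_null = 400, n_signal = 50, n_drift = 50,
                    baseline = 0.1, amplitude = 0.3, noise_sd = 0.03,
                    missing_rate = 0.005, n_outliers = 1),
    input = list(beta = NULL, meta = NULL, blacklists = list(),
                 gene_map = NULL, clock = NULL, reference_markers = NULL),
    qc = list(max_missing = 10, mi_bins = 10, k_sd = 3),
    medians = list(fraction = 0.1, edge_tolerance = 2),
    select = list(fc_threshold = 2, delta_threshold = 0.2, fdr = 0.05,
                  rel_sd_max = 0.5, rel_sd_scope = "all",
                  t_variant = "welch", fdr_universe = "all"),
    gradients = list(k = 2, n_init = 10, savgol_window = 21,
                     savgol_polyorder = 2, perplexity = NULL),
    predict = list(folds = 5, ntree = 100)
  )
}

.validateConfig <- function(config) {
  fail <- function(...) stop("config: ", ..., call. = FALSE)
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  if (!num1(config$seed)) fail("seed must be a single number")
  md <- config$medians
  if (!num1(md$fraction) || md$fraction <= 0 || md$fraction > 1)
    fail("medians$fraction must lie in (0, 1]")
  if (!num1(md$edge_tolerance) || md$edge_tolerance < 0)
    fail("medians$edge_tolerance must be >= 0")
  sl <- config$select
  if (!num1(sl$fdr) || sl$fdr <= 0 || sl$fdr >= 1)
    fail("select$fdr must lie in (0, 1)")
  if (!num1(sl$fc_threshold) || sl$fc_threshold < 1)
    fail("select$fc_threshold must be >= 1")
  if (!num1(sl$delta_threshold) || sl$delta_threshold < 0)
    fail("select$delta_threshold must be >= 0")
  if (!is.numeric(config$qc$k_sd)) fail("qc$k_sd must be numeric")
  if (!num1(config$gradients$k) || config$gradients$k < 1)
    fail("gradients$k must be >= 1")
  if (!num1(config$predict$folds) || config$predict$folds < 2)
    fail("predict$folds must be >= 2")
  invisible(TRUE)
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override \code{\link{defaultConfig}}.
#'
#' @param path .yaml/.yml or .json file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  config <- utils::modifyList(defaultConfig(), raw)
  .validateConfig(config)
  config
}

#' Run the trajectory-discovery pipeline (whole or by stage)
#'
#' Executes the requested stages in order — simulate (or load inputs), QC,
#' running medians, marker selection, gradient clustering, overlap test,
#' age prediction — writing every intermediate table as TSV plus a JSON
#' run manifest (parameters, seeds, per-stage record counts, timings, and
#' input checksums) into \code{config$output_dir}. A stage that needs an
#' upstream result not in the requested subset recomputes it from the
#' artifacts already in the output directory, so per-stage runs compose to
#' the same results as a full run. Deterministic: identical config and
#' seed give byte-identical TSV artifacts.
#'
#' @param config list from \code{\link{defaultConfig}} or
#'   \code{\link{readRunConfig}}, or a path to a YAML/JSON config.
#' @param stages character subset of
#'   c("simulate","qc","medians","select","gradients","overlap","predict").
#' @return invisibly, a list with the output directory, artifact paths,
#'   in-memory stage results and the manifest.
#' @export
runPipeline <- function(config = defaultConfig(),
                        stages = c("simulate", "qc", "medians", "select",
                                   "gradients", "overlap", "predict")) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- utils::modifyList(defaultConfig(), config)
  .validateConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("methylTrend")),
                   config = config, stages = list())
  results <- list()

  ensureBeta <- function() {
    if (!is.null(results$beta)) return()
    if (file.exists(out("beta_qc.tsv")))
      results$beta <<- readBetaTSV(out("beta_qc.tsv"), out("sample_meta.tsv"))
    else if (file.exists(out("beta_matrix.tsv")))
      results$beta <<- readBetaTSV(out("beta_matrix.tsv"), out("sample_meta.tsv"))
    else stop("config: input$beta and input$meta are required when simulation ",
              "is disabled and no prior artifacts exist in output_dir",
              call. = FALSE)
  }
  ensureMedians <- function() {
    if (!is.null(results$rms)) return()
    ensureBeta()
    idx <- buildAgeGroups(results$beta, fraction = config$medians$fraction)
    results$index <<- trimEdgeGroups(idx, tolerance = config$medians$edge_tolerance)
    results$rms <<- runningMedians(results$beta, results$index)
  }
  ensureSelection <- function() {
    if (!is.null(results$selection)) return()
    ensureMedians()
    sl <- config$select
    sel <- selectMarkers(results$beta, results$index, results$rms,
                         fcThreshold = sl$fc_threshold,
                         deltaThreshold = sl$delta_threshold, fdr = sl$fdr,
                         relSdMax = sl$rel_sd_max, relSdScope = sl$rel_sd_scope,
                         tVariant = sl$t_variant, fdrUniverse = sl$fdr_universe)
    pearson <- pearsonSelection(results$beta, fdr = sl$fdr)
    sel$pearson_r <- pearson$pearson_r
    sel$pearson_pass <- pearson$pearson_pass
    results$selection <<- sel
  }

  # --- simulate or load ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if ("simulate" %in% stages && isTRUE(config$simulate$enabled) &&
      is.null(config$input$beta)) {
    sm <- config$simulate
    meta <- simulateCohort(sm$n_samples, sm$age_min, sm$age_max,
                           sm$age_distribution, seed = config$seed)
    specs <- studySpecs(nNull = sm$n_null, nSignal = sm$n_signal,
                        nDrift = sm$n_drift, baseline = sm$baseline,
                        amplitude = sm$amplitude, noiseSd = sm$noise_sd,
                        seed = config$seed)
    be <- simulateBetaMatrix(meta, specs, sm$missing_rate, sm$n_outliers,
                             seed = config$seed + 1L)
    writeBetaTSV(be, out("beta_matrix.tsv"))
    writeSampleMeta(meta, out("sample_meta.tsv"))
    jsonlite::write_json(
      list(outlier_samples = metadata(be)$truth$outlier_samples,
           planted_markers = specs$marker_id[grepl("^cg_sig", specs$marker_id)],
           clip_events = metadata(be)$truth$clip_events),
      out("cohort_truth.json"), auto_unbox = TRUE, null = "null")
    manifest <- .stageLog(manifest, "simulate", t0,
                          probes = nrow(be), samples = ncol(be))
    results$beta <- be
  } else if (!is.null(config$input$beta)) {
    if (is.null(config$input$meta))
      stop("config: input$meta is required with input$beta", call. = FALSE)
    results$beta <- readBetaTSV(config$input$beta, config$input$meta)
    manifest$input_checksums <- as.list(tools::md5sum(
      unlist(c(config$input$beta, config$input$meta,
               config$input$blacklists), use.names = FALSE)))
    manifest <- .stageLog(manifest, "load", t0,
                          probes = nrow(results$beta),
                          samples = ncol(results$beta))
  }

  # --- qc --------------------------------------------------------------
  if ("qc" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ensureBeta()
    bl <- lapply(config$input$blacklists, function(p)
      if (is.character(p) && length(p) == 1 && file.exists(p)) readBlacklist(p)
      else p)
    be <- filterProbes(results$beta, blacklists = bl,
                       maxMissing = config$qc$max_missing)
    be <- flagOutlierSamples(be, bins = config$qc$mi_bins,
                             kSD = config$qc$k_sd)
    qc <- qcReport(be)
    jsonlite::write_json(list(probe_filter = qc$probe_filter,
                              outliers = qc$outliers[c("mean_mi", "sd_mi",
                                                       "cutoff", "flagged")]),
                         out("qc_report.json"), auto_unbox = TRUE)
    writeBetaTSV(be, out("beta_qc.tsv"))
    manifest <- .stageLog(manifest, "qc", t0, probes = nrow(be),
                          samples = ncol(be), flagged = qc$outliers$flagged)
    results$beta <- be
  }

  # --- running medians -------------------------------------------------
  if ("medians" %in% stages) {
    t0 <- as.numeric(Sys.time())
    results$rms <- NULL
    ensureMedians()
    idx <- results$index; rms <- results$rms
    .writeTSV(data.frame(marker_id = rownames(medianTracks(rms)),
                         medianTracks(rms), check.names = FALSE),
              out("running_medians.tsv"))
    .writeTSV(data.frame(marker_id = rownames(relativeSD(rms)),
                         relativeSD(rms), check.names = FALSE),
              out("relative_sd.tsv"))
    jsonlite::write_json(
      list(k = idx@k, fraction = idx@fraction, years = idx@years,
           retained = retainedYears(idx), midpoints = round(idx@midpoints, 3)),
      out("age_groups.json"))
    manifest <- .stageLog(manifest, "medians", t0,
                          retained_years = length(retainedYears(idx)))
  }

  # --- selection -------------------------------------------------------
  if ("select" %in% stages) {
    t0 <- as.numeric(Sys.time())
    results$selection <- NULL
    ensureSelection()
    sel <- results$selection
    .writeTSV(sel, out("marker_selection.tsv"))
    if (!is.null(config$input$gene_map)) {
      gm <- readProbeGeneMap(config$input$gene_map)
      genes <- genesMultiMarker(sel$marker_id[sel$fc_pass], gm)
      .writeTSV(genes$genes, out("genes_multi_marker.tsv"))
    }
    manifest <- .stageLog(manifest, "select", t0,
                          fc_pass = sum(sel$fc_pass),
                          abs_pass = sum(sel$abs_pass),
                          overlap_pass = sum(sel$overlap_pass),
                          pearson_pass = sum(sel$pearson_pass))
  }

  # --- gradients -------------------------------------------------------
  if ("gradients" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ensureSelection()
    sel <- results$selection
    chosen <- sel$marker_id[sel$fc_pass]
    if (length(chosen) >= 2) {
      gr <- config$gradients
      norm <- normalizeTracks(medianTracks(results$rms)[chosen, , drop = FALSE])
      grad <- trackGradients(norm, trackYears(results$rms))
      smooth <- savgolSmooth(grad, window = gr$savgol_window,
                             polyorder = gr$savgol_polyorder)
      k <- min(gr$k, length(chosen))
      cl <- clusterGradients(grad, k = k, seed = config$seed, nInit = gr$n_init)
      emb <- if (length(chosen) >= 5)
        tsneEmbed(grad, seed = config$seed, perplexity = gr$perplexity)
      else NULL
      .writeTSV(data.frame(marker_id = chosen, cluster = cl$labels,
                           grad, check.names = FALSE), out("gradients.tsv"))
      .writeTSV(data.frame(marker_id = chosen, smooth, check.names = FALSE),
                out("gradients_smoothed.tsv"))
      if (!is.null(emb))
        .writeTSV(data.frame(marker_id = chosen, emb), out("tsne.tsv"))
      ksug <- if (nrow(unique(grad)) < 2) list(k = 1L)
              else if (!is.null(emb)) suggestK(emb, seed = config$seed)
              else list(k = NA)
      jsonlite::write_json(
        list(k = cl$k, sizes = as.integer(table(cl$labels)),
             suggested_k = ksug$k,
             mean_gradient = lapply(split(as.data.frame(grad), cl$labels),
                                    function(d) round(colMeans(d), 6))),
        out("cluster_summary.json"), auto_unbox = TRUE)
      manifest <- .stageLog(manifest, "gradients", t0,
                            clustered = length(chosen), k = cl$k)
      results$gradients <- list(gradients = grad, smoothed = smooth,
                                clusters = cl, embedding = emb)
    } else {
      manifest <- .stageLog(manifest, "gradients", t0, clustered = 0L,
                            note = "fewer than 2 fc-selected markers")
    }
  }

  # --- overlap ---------------------------------------------------------
  if ("overlap" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ensureSelection()
    be <- results$beta
    ref <- config$input$reference_markers
    if (is.character(ref) && length(ref) == 1 && file.exists(ref))
      ref <- readBlacklist(ref)
    if (is.null(ref) && file.exists(out("cohort_truth.json")))
      ref <- intersect(unlist(jsonlite::read_json(
        out("cohort_truth.json"))$planted_markers), rownames(be))
    if (is.null(ref) && !is.null(metadata(be)$truth))
      ref <- intersect(metadata(be)$truth$specs$marker_id[
        metadata(be)$truth$specs$shape != "constant"], rownames(be))
    if (!is.null(ref)) {
      sel <- results$selection
      selIds <- sel$marker_id[sel$fc_pass]
      ov <- overlapProbability(length(intersect(selIds, ref)), length(selIds),
                               length(intersect(ref, rownames(be))), nrow(be))
      jsonlite::write_json(list(x = ov@x, n = ov@n, D = ov@D, N = ov@N,
                                p = ov@p, method = ov@method,
                                Z = if (is.na(ov@Z)) NULL else ov@Z),
                           out("overlap.json"), auto_unbox = TRUE, null = "null")
      manifest <- .stageLog(manifest, "overlap", t0, p = ov@p,
                            method = ov@method)
      results$overlap <- ov
    }
  }

  # --- predict ---------------------------------------------------------
  if ("predict" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ensureSelection()
    be <- results$beta
    sel <- results$selection
    chosen <- sel$marker_id[sel$fc_pass]
    if (length(chosen) >= 1) {
      feats <- t(betaValues(be)[chosen, , drop = FALSE])
      rep <- rfCV(feats, sampleAges(be), folds = config$predict$folds,
                  seed = config$seed, ntree = config$predict$ntree)
      .writeTSV(rep$predictions, out("predictions.tsv"))
      pr <- list(mae_mean = rep$mae_mean, mae_sd = rep$mae_sd,
                 r_mean = rep$r_mean, per_fold = rep$per_fold,
                 oldest_decile_signed_error = signedErrorByAge(rep))
      if (!is.null(config$input$clock)) {
        clock <- readClock(config$input$clock)
        cp <- applyLinearClock(clock, be, dropMissing = TRUE)
        pr$clock_mae <- mean(abs(cp - sampleAges(be)))
        .writeTSV(data.frame(sample = names(cp), predicted = cp,
                             age = sampleAges(be)),
                  out("clock_predictions.tsv"))
      }
      jsonlite::write_json(pr, out("prediction_report.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      manifest <- .stageLog(manifest, "predict", t0, mae_mean = rep$mae_mean)
      results$prediction <- rep
    }
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(list(output_dir = config$output_dir,
                 artifacts = list.files(config$output_dir, full.names = TRUE),
                 results = results, manifest = manifest))
}

.stageLog <- function(manifest, stage, t0, ...) {
  manifest$stages[[stage]] <- c(list(seconds = round(as.numeric(Sys.time()) - t0, 2)),
                                list(...))
  manifest
}
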