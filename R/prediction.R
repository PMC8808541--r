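#' @importFrom randomForest randomForest
NULL

.makeFolds <- function(n, folds, seed) {
  if (n < folds) stop("need at least as many samples as folds")
  set.seed(seed)
  idx <- sample(n)
  # contiguous chunks of the shuffled order, sizes differing by at most 1
  sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds), rep(0, folds - n %% folds))
  split(idx, rep(seq_len(folds), times = sizes))
}

.imputeTrainMedian <- function(train, test) {
  med <- apply(train, 2, median, na.rm = TRUE)
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = fill(test), imputed = anyNA(c(train, test)))
}

.cvLoop <- function(features, ages, folds, seed, fitPredict) {
  features <- as.matrix(features)
  n <- nrow(features)
  foldIdx <- .makeFolds(n, folds, seed)
  pred <- numeric(n); foldOf <- integer(n)
  for (f in seq_along(foldIdx)) {
    test <- foldIdx[[f]]
    train <- setdiff(seq_len(n), test)
    im <- .imputeTrainMedian(features[train, , drop = FALSE],
                             features[test, , drop = FALSE])
    pred[test] <- fitPredict(im$train, ages[train], im$test, seed + f)
    foldOf[test] <- f
  }
  perFold <- do.call(rbind, lapply(seq_along(foldIdx), function(f) {
    i <- foldIdx[[f]]
    r <- if (sd(ages[i]) == 0 || sd(pred[i]) == 0) NA_real_
         else cor(pred[i], ages[i])
    data.frame(fold = f, n = length(i), mae = mean(abs(pred[i] - ages[i])),
               medae = median(abs(pred[i] - ages[i])), pearson_r = r)
  }))
  if (anyNA(perFold$pearson_r))
    warning("Pearson r undefined in at least one fold (constant ages or predictions)")
  list(predictions = data.frame(sample = rownames(features) %||% seq_len(n),
                                age = ages, predicted = pred, fold = foldOf,
                                stringsAsFactors = FALSE),
       per_fold = perFold,
       mae_mean = mean(perFold$mae), mae_sd = sd(perFold$mae),
       r_mean = mean(perFold$pearson_r, na.rm = TRUE),
       folds = folds, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated random-forest age prediction
#'
#' Shuffles the samples with the seed, splits them into \code{folds}
#' disjoint validation sets, and per fold trains a random-forest regressor
#' on the remaining samples (training on 80\% and validating 20\% at the
#' default 5 folds). Missing features are imputed by the training-fold
#' marker median only, so no information leaks from validation samples.
#' Forest defaults: 100 trees, all features considered at each split,
#' fully grown trees, bootstrap resampling, variance split criterion.
#'
#' @param features samples x markers matrix (e.g.
#'   \code{t(betaValues(x)[selected, ])}).
#' @param ages true ages (years), one per sample.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed; identical seed and inputs give identical reports.
#' @param ntree,mtry,nodesize forest parameters; \code{mtry = NULL} uses
#'   all features.
#' @return prediction report: per-sample predictions with fold ids,
#'   per-fold mean/median absolute error and Pearson r, and their
#'   mean +/- SD across folds.
#' @export
rfCV <- function(features, ages, folds = 5, seed = 1L, ntree = 100,
                 mtry = NULL, nodesize = 1) {
  features <- as.matrix(features)
  if (is.null(mtry)) mtry <- ncol(features)
  .cvLoop(features, ages, folds, seed, function(xtr, ytr, xte, s) {
    set.seed(s)
    rf <- randomForest(x = xtr, y = ytr, ntree = ntree, mtry = mtry,
                       nodesize = nodesize)
    as.numeric(predict(rf, xte))
  })
}

#' Cross-validated linear (least-squares) age prediction
#'
#' The linear-clock counterpart of \code{\link{rfCV}}: per fold an
#' ordinary least-squares linear combination of the marker beta values is
#' fitted on the training samples and applied to the held-out samples.
#' Same fold construction, imputation and report format as \code{rfCV},
#' so the two are directly comparable.
#'
#' @inheritParams rfCV
#' @return prediction report (see \code{\link{rfCV}}).
#' @export
linearCV <- function(features, ages, folds = 5, seed = 1L) {
  .cvLoop(as.matrix(features), ages, folds, seed, function(xtr, ytr, xte, s) {
    fit <- lm.fit(cbind(1, xtr), ytr)
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    as.numeric(cbind(1, xte) %*% cf)
  })
}

#' Fit a linear clock on a training cohort
#'
#' Ordinary least squares of age on marker beta values; returns the
#' intercept and per-marker coefficients in the clock-model format used
#' by \code{\link{applyLinearClock}}.
#'
#' @param features samples x markers matrix.
#' @param ages training ages (years).
#' @return list with \code{intercept} and named \code{coefficients}.
#' @export
trainLinearClock <- function(features, ages) {
  features <- as.matrix(features)
  fit <- lm.fit(cbind(`(Intercept)` = 1, features), ages)
  cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  list(intercept = unname(cf[1]),
       coefficients = cf[-1])
}

#' Apply a linear clock to a beta matrix
#'
#' Predicted age per sample = intercept + sum(coefficient * beta) over the
#' clock's markers, followed by the clock's inverse age transform if one
#' is supplied.
#'
#' @param clock list with \code{intercept}, named \code{coefficients}, and
#'   optionally \code{inverse} (a function applied to the linear score).
#' @param x a \linkS4class{BetaExperiment} or probes x samples matrix.
#' @param dropMissing if TRUE, clock markers absent from the matrix are
#'   dropped with a warning instead of erroring.
#' @return named numeric vector of predicted ages.
#' @export
applyLinearClock <- function(clock, x, dropMissing = FALSE) {
  b <- if (is(x, "BetaExperiment")) betaValues(x) else as.matrix(x)
  ids <- names(clock$coefficients)
  missing <- setdiff(ids, rownames(b))
  if (length(missing)) {
    if (!dropMissing)
      stop("clock markers absent from the matrix: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ..." else "")
    warning("dropping ", length(missing), " clock markers absent from the matrix")
    ids <- setdiff(ids, missing)
  }
  score <- clock$intercept +
    as.numeric(crossprod(b[ids, , drop = FALSE], clock$coefficients[ids]))
  names(score) <- colnames(b)
  if (!is.null(clock$inverse)) score <- clock$inverse(score)
  score
}

#' Read a linear clock coefficient table
#'
#' TSV with columns marker_id and coefficient; an optional
#' \code{(Intercept)} row supplies the intercept (default 0).
#'
#' @param path TSV path.
#' @return clock model list for \code{\link{applyLinearClock}}.
#' @export
readClock <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "coefficient") %in% colnames(tab)))
  ic <- tab$marker_id == "(Intercept)"
  cf <- tab$coefficient[!ic]
  names(cf) <- tab$marker_id[!ic]
  list(intercept = if (any(ic)) tab$coefficient[ic][1] else 0,
       coefficients = cf)
}

#' Mean signed prediction error among the oldest samples
#'
#' Mean of (predicted - true) over samples whose true age is at or above
#' the given age quantile; a negative value means the model underpredicts
#' age at the old end, the signature of saturating methylation
#' trajectories pushed through a linear model.
#'
#' @param predictions data.frame with columns age and predicted (e.g. the
#'   \code{$predictions} of a CV report), or a CV report list.
#' @param quantile age quantile defining "oldest" (default 0.9).
#' @return mean signed error in years.
#' @export
signedErrorByAge <- function(predictions, quantile = 0.9) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      !is.null(predictions$predictions))
    predictions <- predictions$predictions
  thr <- stats::quantile(predictions$age, quantile)
  old <- predictions$age >= thr
  if (!any(old)) stop("no samples in the top age quantile")
  mean(predictions$predicted[old] - predictions$age[old])
}
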