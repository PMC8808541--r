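#' Normalize running-median tracks to their own maximum
#'
#' Divides each marker's track by its highest median so every marker
#' expresses relative change and the gradients become comparable across
#' markers with different absolute methylation levels.
#'
#' @param rms a \linkS4class{RunningMedianSet} or a numeric matrix
#'   (markers x years).
#' @return matrix of normalized tracks; each row has maximum 1.
#' @export
normalizeTracks <- function(rms) {
  m <- if (is(rms, "RunningMedianSet")) medianTracks(rms) else rms
  mx <- apply(m, 1, max, na.rm = TRUE)
  if (any(mx <= 0))
    stop("all-zero track for marker(s): ",
         paste(head(rownames(m)[mx <= 0]), collapse = ", "))
  m / mx
}

#' Per-year gradients of trajectory tracks
#'
#' Central finite differences at interior years, one-sided differences at
#' the two ends, using the actual year spacing (edge trimming can in
#' principle leave gaps; they are handled by the spacing, not assumed
#' away). Exact on linear tracks, including the endpoints.
#'
#' @param tracks matrix (markers x years), e.g. from
#'   \code{\link{normalizeTracks}}.
#' @param years strictly increasing numeric year grid.
#' @return gradient matrix of the same shape, units 1/year.
#' @export
trackGradients <- function(tracks, years) {
  tracks <- as.matrix(tracks)
  if (length(years) != ncol(tracks)) stop("years must match track columns")
  if (length(years) < 2) stop("need at least 2 points")
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  p <- ncol(tracks)
  g <- matrix(NA_real_, nrow(tracks), p, dimnames = dimnames(tracks))
  g[, 1] <- (tracks[, 2] - tracks[, 1]) / (years[2] - years[1])
  g[, p] <- (tracks[, p] - tracks[, p - 1]) / (years[p] - years[p - 1])
  if (p > 2) {
    i <- 2:(p - 1)
    g[, i] <- (tracks[, i + 1, drop = FALSE] - tracks[, i - 1, drop = FALSE]) /
      rep(years[i + 1] - years[i - 1], each = nrow(tracks))
  }
  g
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing: each output point is the
#' window-centre value of the degree-\code{polyorder} polynomial fitted to
#' the surrounding \code{window} points; the two edges are handled by
#' evaluating the edge-window polynomial at the off-centre positions, so
#' polynomials up to the filter order are reproduced exactly everywhere.
#' Intended for the noisy gradients, for reporting and display; clustering
#' uses the unsmoothed gradients.
#'
#' @param x numeric vector (or matrix: rows smoothed independently).
#' @param window odd window length (default 21); if \code{x} is shorter
#'   the window shrinks to the largest valid odd size, with a message.
#' @param polyorder polynomial degree (default 2), must be < window.
#' @return smoothed vector/matrix.
#' @export
savgolSmooth <- function(x, window = 21, polyorder = 2) {
  if (is.matrix(x))
    return(t(apply(x, 1, savgolSmooth, window = window, polyorder = polyorder)))
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (n < window) {
    window <- max(polyorder + 1 + (polyorder %% 2 == 0), n - (1 - n %% 2))
    if (window %% 2 == 0) window <- window - 1
    if (window <= polyorder)
      stop("input too short to fit polyorder ", polyorder)
    message("savgolSmooth: window shrunk to ", window, " for length-", n,
            " input")
  }
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' k-means clustering of gradient curves
#'
#' Lloyd-type k-means (Hartigan-Wong) with \code{nInit} random restarts,
#' best within-cluster sum of squares kept; deterministic for a fixed
#' seed. Markers whose gradients share sign and magnitude profile land in
#' the same cluster, grouping trajectory families (steady rise, late drop,
#' saturating, ...).
#'
#' @param gradients matrix, markers x years.
#' @param k number of clusters (1 <= k <= markers).
#' @param seed RNG seed.
#' @param nInit random restarts (default 10).
#' @return list: \code{labels} (named integer vector in 1..k),
#'   \code{centers}, \code{tot_withinss}, \code{k}, \code{seed}.
#' @export
clusterGradients <- function(gradients, k, seed = 1L, nInit = 10) {
  gradients <- as.matrix(gradients)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(gradients)) stop("k exceeds the number of markers")
  set.seed(seed)
  if (k == 1) {
    labels <- rep(1L, nrow(gradients))
    names(labels) <- rownames(gradients)
    ctr <- matrix(colMeans(gradients), 1)
    return(list(labels = labels, centers = ctr,
                tot_withinss = sum(scale(gradients, scale = FALSE)^2),
                k = 1L, seed = seed))
  }
  km <- kmeans(gradients, centers = k, nstart = nInit, iter.max = 100)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(gradients)
  list(labels = labels, centers = km$centers,
       tot_withinss = km$tot.withinss, k = as.integer(k), seed = seed)
}

# Shannon entropy / perplexity calibration for one row of affinities
.tsneRowP <- function(d2, perplexity, tol = 1e-5, maxIter = 50) {
  target <- log(perplexity)
  beta <- 1; lo <- -Inf; hi <- Inf
  for (iter in seq_len(maxIter)) {
    p <- exp(-d2 * beta)
    s <- sum(p)
    if (s == 0) { p <- rep(1 / length(d2), length(d2)); break }
    H <- log(s) + beta * sum(d2 * p) / s
    p <- p / s
    if (abs(H - target) < tol) break
    if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  p
}

#' t-SNE embedding of gradient curves
#'
#' Exact (non-approximated) t-SNE: Gaussian input affinities calibrated to
#' the requested perplexity by bisection, Student-t low-dimensional
#' kernel, momentum gradient descent with early exaggeration. O(n^2) per
#' iteration, intended for the post-selection marker counts this package
#' works at (tens to a few thousand curves). The embedding is a diagnostic
#' for choosing the cluster count, not an inference step.
#'
#' @param gradients matrix, markers x years (>= 5 markers).
#' @param seed RNG seed; fixed seed reproduces the embedding.
#' @param perplexity effective neighbour count; must be < markers
#'   (default min(30, (n-1)/3)).
#' @param maxIter gradient-descent iterations (default 400).
#' @return markers x 2 coordinate matrix.
#' @export
tsneEmbed <- function(gradients, seed = 1L, perplexity = NULL, maxIter = 400) {
  X <- as.matrix(gradients)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 markers to embed")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity >= n) stop("perplexity must be smaller than the number of markers")
  d2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) P[i, -i] <- .tsneRowP(d2[i, -i], perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5; eta <- 100
  exag <- 12
  Pe <- P * exag
  for (iter in seq_len(maxIter)) {
    if (iter == 101) Pe <- P
    if (iter == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Advisory cluster-count suggestion from an embedding
#'
#' Scans k in 2..kmax, clustering the 2-D embedding and scoring the mean
#' silhouette width; returns the best k, falling back to 1 for degenerate
#' input (fewer than 2 distinct points, or no k achieving positive
#' silhouette). Advisory only: it is never applied silently.
#'
#' @param embedding markers x 2 matrix from \code{\link{tsneEmbed}} (any
#'   feature matrix works).
#' @param kmax largest k scanned (default 6).
#' @param seed RNG seed for the k-means restarts.
#' @return list: \code{k}, \code{silhouette} (per scanned k).
#' @export
suggestK <- function(embedding, kmax = 6, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (nrow(unique(embedding)) < 2 || n < 3)
    return(list(k = 1L, silhouette = numeric(0)))
  ks <- 2:min(kmax, n - 1)
  d <- dist(embedding)
  sil <- vapply(ks, function(k) {
    set.seed(seed + k)
    km <- kmeans(embedding, centers = k, nstart = 5, iter.max = 50)
    mean(cluster::silhouette(km$cluster, d)[, 3])
  }, numeric(1))
  names(sil) <- ks
  if (all(!is.finite(sil)) || max(sil, na.rm = TRUE) <= 0)
    return(list(k = 1L, silhouette = sil))
  list(k = as.integer(ks[which.max(sil)]), silhouette = sil)
}
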