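#' DivIK parameters
#'
#' Tuning knobs of the divisive clustering. `max_k` bounds the candidate
#' cluster counts scored by the gap statistic at each node; `B` is the
#' number of uniform reference datasets; a node is split only when every
#' prospective child holds at least `max(min_cluster_cells,
#' min_cluster_fraction * n_root_cells)` cells and the node is above
#' `max_depth`. `amplitude_filter_at_root_only` restricts the
#' noise-floor amplitude filtration to the root node, matching the
#' reference description of the algorithm; variance filtration runs at
#' every node.
#'
#' @param max_k maximum clusters per split (default 10).
#' @param B reference draws for the gap statistic (default 10).
#' @param min_cluster_fraction minimum leaf size as a fraction of the
#'   root cell count (default 0.01).
#' @param min_cluster_cells absolute minimum leaf size (default 20).
#' @param max_depth maximum recursion depth (default 5).
#' @param kmeans_restarts random restarts per k-means run (default 10).
#' @param distance distance for k-means; only `"euclidean"` is currently
#'   implemented.
#' @param amplitude_filter_at_root_only logical, default TRUE.
#' @param seed integer RNG seed; the whole tree is deterministic given it.
#' @return list of class `DivikParams`.
#' @export
divikParams <- function(max_k = 10, B = 10, min_cluster_fraction = 0.01,
                        min_cluster_cells = 20, max_depth = 5,
                        kmeans_restarts = 10,
                        distance = c("euclidean", "correlation"),
                        amplitude_filter_at_root_only = TRUE, seed = 1) {
  distance <- match.arg(distance)
  stopifnot(max_k >= 2, B >= 1, min_cluster_cells >= 2, max_depth >= 1)
  structure(list(max_k = max_k, B = B,
                 min_cluster_fraction = min_cluster_fraction,
                 min_cluster_cells = min_cluster_cells,
                 max_depth = max_depth, kmeans_restarts = kmeans_restarts,
                 distance = distance,
                 amplitude_filter_at_root_only = amplitude_filter_at_root_only,
                 seed = as.integer(seed)),
            class = "DivikParams")
}

#' Gap statistic for choosing the number of k-means clusters
#'
#' For each k in 1..`max_k`, the within-cluster dispersion `W_k` (total
#' within-cluster sum of squares; best of `kmeans_restarts` seeded
#' restarts) is compared with its expectation over `B` reference datasets
#' drawn uniformly over the feature-wise bounding box of the data:
#' `gap(k) = E*[log W_k] - log W_k`, with
#' `s_k = sd*(log W_k) * sqrt(1 + 1/B)`. The chosen k is the smallest k
#' with `gap(k) >= gap(k+1) - s_(k+1)` (one-standard-error rule); a
#' chosen k of 1 means the data support no split. Zero dispersions
#' (coincident points) are handled with a log floor.
#'
#' @param x numeric matrix, observations in rows, features in columns.
#' @param params [divikParams()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return a [GapResult-class].
#' @export
gapStatistic <- function(x, params = divikParams(), seed = params$seed) {
  x <- as.matrix(x)
  n <- nrow(x)
  ndistinct <- nrow(unique(x))
  kmax <- min(params$max_k, ndistinct, n - 1L)
  if (ndistinct < 2 || kmax < 1) {
    return(new("GapResult", k = 1L, logW = logGuard(totalSS(x)),
               ElogW = logGuard(totalSS(x)), gap = 0, s_k = 0,
               chosen_k = 1L))
  }
  ks <- seq_len(max(kmax, 1L))
  withSeed(seed, {
    logW <- vapply(ks, function(k) logGuard(kmeansW(x, k, params)),
                   numeric(1))
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    logWref <- matrix(0, params$B, length(ks))
    for (b in seq_len(params$B)) {
      ref <- matrix(stats::runif(n * ncol(x)), n, ncol(x))
      ref <- sweep(sweep(ref, 2, hi - lo, `*`), 2, lo, `+`)
      logWref[b, ] <- vapply(ks, function(k)
        logGuard(kmeansW(ref, k, params)), numeric(1))
    }
  })
  ElogW <- colMeans(logWref)
  s_k <- apply(logWref, 2, stats::sd) * sqrt(1 + 1 / params$B)
  s_k[is.na(s_k)] <- 0
  gap <- ElogW - logW
  chosen <- length(ks)
  if (length(ks) > 1) {
    for (i in seq_len(length(ks) - 1)) {
      if (gap[i] >= gap[i + 1] - s_k[i + 1]) { chosen <- i; break }
    }
  } else chosen <- 1L
  new("GapResult", k = as.integer(ks), logW = logW, ElogW = ElogW,
      gap = gap, s_k = s_k, chosen_k = as.integer(ks[chosen]))
}

kmeansW <- function(x, k, params) {
  if (k == 1) return(totalSS(x))
  km <- fitKmeans(x, k, params)
  if (is.null(km)) return(totalSS(x))
  km$tot.withinss
}

# best-of-restarts k-means; returns NULL when k exceeds the number of
# distinct rows (kmeans would error)
fitKmeans <- function(x, k, params) {
  if (nrow(unique(x)) < k) return(NULL)
  tryCatch(
    stats::kmeans(x, centers = k, nstart = params$kmeans_restarts,
                  iter.max = 100),
    error = function(e) {
      tryCatch(stats::kmeans(x, centers = k, nstart = params$kmeans_restarts,
                             iter.max = 100, algorithm = "Lloyd"),
               error = function(e2) NULL)
    })
}

totalSS <- function(x) {
  mu <- colMeans(x)
  sum(sweep(x, 2, mu)^2)
}

logGuard <- function(w) log(max(w, 1e-300))
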