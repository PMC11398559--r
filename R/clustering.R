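#' K-means clustering of CFS trajectories under DTW
#'
#' Partitions 13-day trajectories into `K` groups by K-means with the
#' DTW distance: rows are assigned to the nearest centroid (ties to the
#' lowest centroid index) and centroids are refit by DTW barycenter
#' averaging initialized at the within-cluster medoid.  `n_init`
#' restarts are run from distinct centroid draws (sub-seeds derived
#' deterministically from `seed`) and the restart with minimal inertia
#' (sum of squared assigned DTW distances) is returned.  An emptied
#' cluster is reseeded with the row farthest from its centroid.  Groups
#' of the returned model are renumbered by ascending mean of the
#' centroid's first three days, so "Group 1 = lowest early CFS" is
#' stable across seeds.
#'
#' @param m numeric matrix of trajectories (rows = patients) or the
#'   `$matrix` element of [trajectory_matrix()].
#' @param K number of groups, `2 <= K <= nrow(m)`.
#' @param n_init number of random restarts.
#' @param seed integer seed governing all randomness.
#' @param max_iter maximum assignment/update iterations per restart.
#' @param tol relative inertia change declaring convergence.
#' @param band optional Sakoe-Chiba half-width passed to the distance.
#' @param znorm z-normalize each row before clustering.  Off by
#'   default: the CFS scale is absolute, and groups differ by level as
#'   well as shape.
#' @return object of class `dtw_kmeans`: list with `K`, `centroids`
#'   (K x 13), `labels` (1..K, named by patient), `inertia`, `n_iter`,
#'   `seed`, `converged`, and `inertia_trace` (per-iteration inertia of
#'   the winning restart).
#' @export
kmeans_dtw <- function(m, K, n_init = 10L, seed = 42L, max_iter = 50L,
                       tol = 1e-6, band = NULL, znorm = FALSE) {
  m <- as.matrix(m)
  N <- nrow(m)
  if (K < 2L) stop("K must be at least 2")
  if (K > N) stop("K (", K, ") exceeds the number of trajectories (", N, ")")
  X <- if (znorm) t(apply(m, 1L, function(r) (r - mean(r)) / max(sd(r), 1e-12))) else m
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_init)
  best <- NULL
  for (s in sub_seeds) {
    set.seed(s)
    fit <- kmeans_dtw_once(X, K, max_iter, tol, band)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  # canonical group numbering: ascending early (days 1-3) centroid mean
  ord <- order(rowMeans(best$centroids[, 1:3, drop = FALSE]))
  relabel <- match(seq_len(K), ord)
  labels <- relabel[best$labels]
  names(labels) <- rownames(m)
  centroids <- best$centroids[ord, , drop = FALSE]
  rownames(centroids) <- paste0("group", seq_len(K))
  colnames(centroids) <- colnames(m)
  structure(list(K = K, centroids = centroids, labels = labels,
                 inertia = best$inertia, n_iter = best$n_iter,
                 seed = seed, converged = best$converged,
                 inertia_trace = best$trace, znorm = znorm, band = band),
            class = "dtw_kmeans")
}

# one restart of DTW K-means; assumes the RNG is already seeded
kmeans_dtw_once <- function(X, K, max_iter, tol, band) {
  N <- nrow(X)
  centroids <- X[sample.int(N, K), , drop = FALSE]
  prev_labels <- NULL
  prev_inertia <- Inf
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    D <- dtw_cross_dist(X, centroids, band)^2
    labels <- max.col(-D, ties.method = "first")
    # reseed any emptied cluster with the row farthest from its centroid
    for (k in which(tabulate(labels, K) == 0L)) {
      far <- which.max(D[, k])
      centroids[k, ] <- X[far, ]
      D[, k] <- dtw_cross_dist(X, centroids[k, , drop = FALSE], band)^2
      labels <- max.col(-D, ties.method = "first")
    }
    inertia <- sum(D[cbind(seq_len(N), labels)])
    trace <- c(trace, inertia)
    if (!is.null(prev_labels) && all(labels == prev_labels)) { converged <- TRUE; break }
    if (is.finite(prev_inertia) &&
        abs(prev_inertia - inertia) <= tol * max(prev_inertia, 1e-12)) {
      converged <- TRUE; break
    }
    if (it >= max_iter) break
    prev_labels <- labels
    prev_inertia <- inertia
    for (k in seq_len(K)) {
      members <- X[labels == k, , drop = FALSE]
      Dm <- dtw_dist_matrix(members, band)
      medoid <- members[which.min(rowSums(Dm^2)), ]
      cand <- dba_barycenter(members, init = medoid, max_iter = 10L,
                             tol = 1e-4, band = band)
      # keep the better of the refit and the previous centroid so the
      # within-restart inertia never increases
      cost_new <- sum(dtw_cross_dist(members, rbind(cand), band)^2)
      cost_old <- sum(dtw_cross_dist(members, centroids[k, , drop = FALSE], band)^2)
      if (cost_new <= cost_old) centroids[k, ] <- cand
    }
  }
  list(centroids = centroids, labels = labels, inertia = inertia,
       n_iter = it, converged = converged, trace = trace)
}

#' @export
print.dtw_kmeans <- function(x, ...) {
  cat("DTW K-means:", x$K, "groups,", length(x$labels), "trajectories\n")
  cat("inertia:", format(x$inertia, digits = 6),
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  cat("group sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Within-group error as a function of the number of groups
#'
#' Fits [kmeans_dtw()] for each `k` and records the best-of-restarts
#' inertia, producing the curve used by the elbow method.
#'
#' @inheritParams kmeans_dtw
#' @param k_range increasing integer vector of group counts.
#' @return data.frame of class `elbow_curve` with columns `k`, `inertia`.
#' @export
inertia_curve <- function(m, k_range = 2:6, n_init = 10L, seed = 42L,
                          max_iter = 50L, tol = 1e-6, band = NULL,
                          znorm = FALSE) {
  k_range <- as.integer(k_range)
  if (any(diff(k_range) <= 0)) stop("k_range must be strictly increasing")
  inertias <- vapply(k_range, function(k) {
    kmeans_dtw(m, k, n_init = n_init, seed = seed, max_iter = max_iter,
               tol = tol, band = band, znorm = znorm)$inertia
  }, numeric(1L))
  structure(data.frame(k = k_range, inertia = inertias),
            class = c("elbow_curve", "data.frame"))
}

#' Pick the number of groups at the elbow of an inertia curve
#'
#' Returns the interior `k` maximizing the discrete second difference
#' `inertia(k-1) - 2*inertia(k) + inertia(k+1)`, the point where adding
#' a further group starts to yield diminishing returns.  Ties go to the
#' smallest `k`.  The full curve should always be reported alongside the
#' automatic choice so a judgment-based override (e.g. on clinical
#' relevance of the groupings) remains possible.
#'
#' @param curve an `elbow_curve` (or data.frame with `k` and `inertia`),
#'   at least 3 points.
#' @return the selected `k`.
#' @examples
#' select_k_elbow(data.frame(k = 1:5, inertia = c(100, 60, 30, 28, 27)))
#' @export
select_k_elbow <- function(curve) {
  k <- curve$k
  inertia <- curve$inertia
  if (length(k) < 3L) stop("elbow selection needs at least 3 curve points")
  d2 <- inertia[-c(length(k), length(k) - 1L)] -
    2 * inertia[-c(1L, length(k))] + inertia[-(1:2)]
  k[-c(1L, length(k))][which.max(d2)]
}

#' Per-group mean trajectories
#'
#' @param m trajectory matrix (rows = patients).
#' @param labels integer group labels, 1..K, aligned with rows of `m`.
#' @return K x ncol(m) matrix of per-day arithmetic means.
#' @export
group_mean_trajectories <- function(m, labels) {
  m <- as.matrix(m)
  if (length(labels) != nrow(m)) stop("labels must match rows of the matrix")
  K <- max(labels)
  if (any(tabulate(labels, K) == 0L)) {
    stop("empty group(s): ", paste(setdiff(seq_len(K), labels), collapse = ", "))
  }
  out <- t(vapply(seq_len(K),
                  function(g) colMeans(m[labels == g, , drop = FALSE]),
                  numeric(ncol(m))))
  rownames(out) <- paste0("group", seq_len(K))
  colnames(out) <- colnames(m)
  out
}

#' Mean silhouette coefficient under the DTW distance
#'
#' Diagnostic of cluster cohesion/separation computed on the pairwise
#' DTW distance matrix: for each trajectory, `a` is the mean distance to
#' its own cluster, `b` the smallest mean distance to another cluster,
#' and the silhouette is `(b - a) / max(a, b)` (0 for singletons).
#'
#' @inheritParams group_mean_trajectories
#' @param band optional Sakoe-Chiba half-width.
#' @return mean silhouette in [-1, 1], with per-sample values in
#'   attribute `silhouettes`.
#' @export
silhouette_dtw <- function(m, labels, band = NULL) {
  m <- as.matrix(m)
  if (length(labels) != nrow(m)) stop("labels must match rows of the matrix")
  if (length(unique(labels)) < 2L) stop("silhouette needs at least 2 clusters")
  D <- dtw_dist_matrix(m, band)
  n <- nrow(m)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ks[ks != labels[i]],
                    function(g) mean(D[i, labels == g]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  structure(mean(s), silhouettes = s)
}
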