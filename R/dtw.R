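check_dtw_args <- function(x, y, band) {
  if (length(x) == 0L || length(y) == 0L) stop("DTW sequences must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("DTW sequences must not contain NA")
  if (is.null(band)) return(-1L)
  band <- as.integer(band)
  if (band < abs(length(x) - length(y))) {
    stop("Sakoe-Chiba band half-width ", band,
         " is infeasible for lengths ", length(x), " and ", length(y))
  }
  band
}

#' Dynamic time warping distance
#'
#' The DTW distance between two numeric sequences: the square root of
#' the minimal accumulated squared pointwise difference over all
#' monotone warping paths with steps (1,0), (0,1), (1,1) and both
#' endpoints aligned.  With the squared local cost the diagonal path
#' recovers the Euclidean distance, so `dtw_distance(x, y) <=
#' euclidean(x, y)` for equal-length inputs.  DTW is symmetric and
#' `dtw_distance(x, x) == 0`, but it is not a metric: the triangle
#' inequality can fail.
#'
#' @param x,y non-empty numeric vectors.
#' @param band optional Sakoe-Chiba band half-width; must be at least
#'   `abs(length(x) - length(y))`.  `NULL` (default) means unconstrained.
#' @return non-negative scalar distance.
#' @examples
#' dtw_distance(c(0, 1, 0), c(0, 0, 1, 1, 0, 0))  # 0
#' @export
dtw_distance <- function(x, y, band = NULL) {
  b <- check_dtw_args(x, y, band)
  sqrt(dtw_cost_cpp(as.numeric(x), as.numeric(y), b))
}

#' Optimal DTW warping path
#'
#' Returns the index pairs of an optimal alignment between `x` and `y`:
#' a two-column integer matrix (columns `i`, `j`, 1-based) starting at
#' (1, 1), ending at (length(x), length(y)), monotone in both columns.
#' The accumulated squared difference along the path equals
#' `dtw_distance(x, y)^2`.  When several paths are optimal the
#' backtracking tie-break prefers the diagonal step.
#'
#' @inheritParams dtw_distance
#' @return integer matrix with attribute `distance`.
#' @export
dtw_path <- function(x, y, band = NULL) {
  b <- check_dtw_args(x, y, band)
  p <- dtw_path_cpp(as.numeric(x), as.numeric(y), b)
  colnames(p) <- c("i", "j")
  attr(p, "distance") <- sqrt(sum((x[p[, 1L]] - y[p[, 2L]])^2))
  p
}

#' Pairwise DTW distance matrix
#'
#' @param m numeric matrix, one series per row.
#' @inheritParams dtw_distance
#' @return symmetric matrix of DTW distances between rows.
#' @export
dtw_dist_matrix <- function(m, band = NULL) {
  m <- as.matrix(m)
  b <- if (is.null(band)) -1L else as.integer(band)
  D <- dtw_pdist_cpp(m, b)
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

dtw_cross_dist <- function(a, b, band = NULL) {
  bb <- if (is.null(band)) -1L else as.integer(band)
  dtw_cdist_cpp(as.matrix(a), as.matrix(b), bb)
}

#' DTW barycenter averaging (DBA)
#'
#' Iteratively refines a centroid sequence for a collection of
#' equal-length series: each iteration aligns every series to the
#' current barycenter with [dtw_path()] and replaces each barycenter
#' coordinate with the mean of all series values aligned to it.  The
#' total squared DTW cost of the collection to the barycenter is
#' non-increasing across iterations; the procedure stops when the
#' largest coordinate change falls below `tol` or after `max_iter`
#' iterations.
#'
#' @param series numeric matrix, one series per row (at least one row).
#' @param init initial barycenter; defaults to the medoid of `series`
#'   under DTW (ties to the first row).
#' @param max_iter,tol stopping controls.
#' @inheritParams dtw_distance
#' @return numeric barycenter with attributes `iterations` and `costs`
#'   (total squared DTW cost after each iteration).
#' @export
dba_barycenter <- function(series, init = NULL, max_iter = 30L,
                           tol = 1e-6, band = NULL) {
  series <- as.matrix(series)
  if (nrow(series) == 0L) stop("DBA needs at least one series")
  if (is.null(init)) {
    D <- dtw_dist_matrix(series, band)
    init <- series[which.min(rowSums(D^2)), ]
  }
  if (length(init) != ncol(series)) {
    stop("init must have the same length as the series")
  }
  bary <- as.numeric(init)
  L <- length(bary)
  costs <- numeric()
  for (it in seq_len(max_iter)) {
    sums <- numeric(L)
    counts <- numeric(L)
    for (r in seq_len(nrow(series))) {
      p <- dtw_path(bary, series[r, ], band)
      v <- series[r, p[, 2L]]
      sums <- sums + unname(tapply(v, factor(p[, 1L], levels = seq_len(L)),
                                   sum, default = 0))
      counts <- counts + tabulate(p[, 1L], nbins = L)
    }
    new <- ifelse(counts > 0, sums / counts, bary)
    delta <- max(abs(new - bary))
    bary <- new
    costs <- c(costs, sum(dtw_cross_dist(series, rbind(bary), band)^2))
    if (delta < tol) break
  }
  attr(bary, "iterations") <- length(costs)
  attr(bary, "costs") <- costs
  bary
}
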