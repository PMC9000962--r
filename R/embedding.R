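# 2-D map of the feature matrix: t-SNE with deterministic initialization,
# PCA baseline, and the Delaunay triadic-difference smoothness diagnostic.

#' Deterministic initial coordinates for the embedding
#'
#' `isi_based` (default, mirrors the pipeline's fixed initialization): the
#' x-axis is the shortest ISI of each window (minimum over neurons of the
#' 10th-percentile ISI feature, pre-z-score) and the y-axis the maximum over
#' neurons of the second-to-first-order ISI ratio. `pca`: scores on the first
#' two principal components of the z-scored matrix. `random`: seeded standard
#' normal draws. All modes are centered and rescaled to column SD 1e-4, the
#' standard small-norm t-SNE initialization.
#'
#' @param fm A `feature_matrix` (z-scored for `pca` mode).
#' @param mode One of "isi_based", "pca", "random".
#' @param seed Integer seed (used by `random` mode).
#' @return N x 2 numeric matrix.
#' @export
initial_coords <- function(fm, mode = c("isi_based", "pca", "random"),
                           seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(fm$values)
  ns <- fm$neuron_set
  y0 <- switch(mode,
    isi_based = {
      p10 <- fm$values[, paste0("isi_", ns, "_p10"), drop = FALSE]
      ratio <- fm$values[, paste0("isi_order_ratio_", ns), drop = FALSE]
      cbind(apply(p10, 1, min), apply(ratio, 1, max))
    },
    pca = {
      if (is.null(fm$z)) stop("initial_coords: pca mode needs z-scored features")
      stats::prcomp(fm$z, center = FALSE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    },
    random = {
      set.seed(seed)
      matrix(stats::rnorm(2L * n), n, 2L)
    })
  y0 <- sweep(y0, 2, colMeans(y0), "-")
  s <- apply(y0, 2, stats::sd)
  s[s < 1e-300] <- 1
  sweep(y0, 2, s / 1e-4, "/")
}

#' Embed a feature matrix into two dimensions with t-SNE
#'
#' Runs t-SNE on the z-scored feature matrix. The exact gradient is used
#' below `exact_below` rows (default 5000) for reproducibility; larger
#' problems use Barnes-Hut. The effective perplexity is capped at
#' `floor((N - 1) / 3)`. With a fixed seed, initialization and settings the
#' result is bit-reproducible.
#'
#' @param fm A `feature_matrix`; z-scored automatically if needed.
#' @param perplexity Neighborhood-size parameter (default 100).
#' @param init Initialization mode, see [initial_coords()], or an N x 2
#'   matrix of coordinates.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @param eta Learning rate; default `N / 12`.
#' @param exaggeration_factor Early exaggeration (default 12, first 250
#'   iterations).
#' @param exact_below Use the exact gradient when `N < exact_below`.
#' @param theta Barnes-Hut accuracy parameter when the approximate gradient
#'   is used.
#' @return An object of class `embedding_result` with `coords` (N x 2),
#'   `perplexity` (effective), `init_mode`, `backend`, `seed` and `settings`.
#' @export
embed_map <- function(fm, perplexity = 100, init = "isi_based", seed = 1L,
                      max_iter = 1000L, eta = NULL, exaggeration_factor = 12,
                      exact_below = 5000L, theta = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$z)) fm <- zscore_features(fm)
  x <- fm$z
  n <- nrow(x)
  if (any(!is.finite(x))) stop("embed_map: non-finite feature values")
  if (n < 4L) stop("embed_map: need at least 4 windows")
  perp_eff <- min(perplexity, floor((n - 1) / 3))
  if (is.null(eta)) eta <- max(n / 12, 1)
  use_theta <- if (n < exact_below) 0 else theta
  init_mode <- if (is.matrix(init)) "matrix" else init
  y0 <- if (is.matrix(init)) init else initial_coords(fm, init, seed = seed)
  set.seed(seed)
  res <- Rtsne::Rtsne(x, dims = 2L, perplexity = perp_eff, theta = use_theta,
                      check_duplicates = FALSE, pca = FALSE, normalize = FALSE,
                      max_iter = max_iter, Y_init = y0,
                      stop_lying_iter = 250L, mom_switch_iter = 250L,
                      eta = eta, exaggeration_factor = exaggeration_factor,
                      num_threads = 1L)
  structure(list(coords = res$Y, perplexity = perp_eff, init_mode = init_mode,
                 backend = "Rtsne", seed = as.integer(seed),
                 settings = list(requested_perplexity = perplexity,
                                 theta = use_theta, max_iter = max_iter,
                                 eta = eta,
                                 exaggeration_factor = exaggeration_factor,
                                 stop_lying_iter = 250L,
                                 mom_switch_iter = 250L),
                 info = fm$info),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result>", nrow(x$coords), "points; backend", x$backend,
      "(theta =", x$settings$theta, "), perplexity", x$perplexity,
      ", init", x$init_mode, ", seed", x$seed, "\n")
  invisible(x)
}

#' PCA baseline projection
#'
#' Scores on the first two principal components of the z-scored feature
#' matrix; the linear control the nonlinear map is compared against.
#'
#' @param fm A `feature_matrix`; z-scored automatically if needed.
#' @return N x 2 matrix of component scores.
#' @export
pca_baseline <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$z)) fm <- zscore_features(fm)
  stats::prcomp(fm$z, center = FALSE, scale. = FALSE)$x[, 1:2, drop = FALSE]
}

#' Triadic differences over a Delaunay triangulation
#'
#' Builds a Delaunay triangulation over the embedded points and, for each
#' triangle, records the maximum pairwise absolute difference of a
#' per-window metric across its three vertices, together with the triangle's
#' incenter (for plotting). Points with undefined (NA/NaN) metric are
#' excluded before triangulation; exact duplicate coordinates are collapsed
#' to their first occurrence.
#'
#' @param coords N x 2 coordinate matrix (or an `embedding_result`).
#' @param metric Numeric vector of length N (NA where undefined).
#' @param name Metric name recorded in the report.
#' @return Object of class `triadic_report`: data frame with columns
#'   `triangle`, vertex indices `i`, `j`, `k` (into the included points),
#'   `inc_x`, `inc_y`, `difference`; attributes `metric` and `n_points`.
#' @export
triadic_differences <- function(coords, metric, name = "metric") {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  stopifnot(nrow(coords) == length(metric))
  keep <- which(is.finite(metric))
  if (length(keep) < 3L) stop("triadic_differences: metric defined on < 3 windows")
  pts <- coords[keep, , drop = FALSE]
  m <- metric[keep]
  dup <- duplicated(pts)
  pts <- pts[!dup, , drop = FALSE]
  m <- m[!dup]
  if (nrow(pts) < 3L) stop("triadic_differences: < 3 distinct points")
  sv <- svd(sweep(pts, 2, colMeans(pts)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1e-300)) {
    stop("triadic_differences: points are collinear")
  }
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tri <- tryCatch(deldir::triMat(dd), error = function(e) NULL)
  if (is.null(tri) || nrow(tri) == 0L) {
    stop("triadic_differences: triangulation produced no triangles (collinear points?)")
  }
  a <- pts[tri[, 1], , drop = FALSE]
  b <- pts[tri[, 2], , drop = FALSE]
  cc <- pts[tri[, 3], , drop = FALSE]
  # incenter = side-length-weighted vertex mean
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  per <- la + lb + lc
  inc <- (a * la + b * lb + cc * lc) / per
  mv <- cbind(m[tri[, 1]], m[tri[, 2]], m[tri[, 3]])
  d <- apply(mv, 1, max) - apply(mv, 1, min)
  out <- data.frame(triangle = seq_len(nrow(tri)), i = tri[, 1], j = tri[, 2],
                    k = tri[, 3], inc_x = inc[, 1], inc_y = inc[, 2],
                    difference = d)
  attr(out, "metric") <- name
  attr(out, "n_points") <- nrow(pts)
  class(out) <- c("triadic_report", "data.frame")
  out
}

#' Shuffle a metric for the smoothness null control
#'
#' Random permutation of the metric values over points (equivalent, under
#' exchangeability, to shuffling the map itself).
#'
#' @param metric Numeric vector.
#' @param seed Integer seed.
#' @return Permuted copy of `metric`.
#' @export
shuffle_metric <- function(metric, seed = 1L) {
  set.seed(seed)
  sample(metric)
}

#' Map-smoothness test against control embeddings
#'
#' One-sided two-sample Kolmogorov-Smirnov tests of whether the map's
#' triadic differences are stochastically smaller than each control's
#' (PCA baseline, shuffled map). Small p-values mean the metric varies more
#' smoothly across the map than across the control.
#'
#' @param map_report `triadic_report` for the map.
#' @param ... Named `triadic_report` controls (e.g. `pca = ..., shuffle = ...`).
#' @return Data frame with one row per control: `control`, `ks_statistic`,
#'   `p_value`, or NULL (with a warning) when fewer than 10 triangles.
#' @export
smoothness_test <- function(map_report, ...) {
  controls <- list(...)
  stopifnot(length(controls) >= 1L)
  if (nrow(map_report) < 10L ||
      any(vapply(controls, nrow, integer(1)) < 10L)) {
    warning("smoothness_test: fewer than 10 triangles; test skipped")
    return(NULL)
  }
  if (is.null(names(controls)) || any(names(controls) == "")) {
    names(controls) <- paste0("control", seq_along(controls))
  }
  res <- lapply(names(controls), function(nm) {
    # alternative = "greater": ECDF of x lies above y, i.e. x stochastically smaller
    kt <- suppressWarnings(stats::ks.test(map_report$difference,
                                          controls[[nm]]$difference,
                                          alternative = "greater"))
    data.frame(control = nm, ks_statistic = unname(kt$statistic),
               p_value = kt$p.value)
  })
  do.call(rbind, res)
}

#' k-nearest-neighbor class purity in a 2-D map
#'
#' For each point, the fraction of its k nearest neighbors (Euclidean,
#' excluding itself) sharing its class; averaged per class. Used to score
#' how well an embedding separates known classes.
#'
#' @param coords N x 2 coordinate matrix (or an `embedding_result`).
#' @param classes Vector of true class labels, length N.
#' @param k Number of neighbors (default 10).
#' @return Named numeric vector: mean purity per class.
#' @export
knn_purity <- function(coords, classes, k = 10L) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  n <- nrow(coords)
  stopifnot(length(classes) == n, n > k)
  classes <- as.character(classes)
  d2 <- as.matrix(stats::dist(coords))^2
  diag(d2) <- Inf
  pur <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    mean(classes[nb] == classes[i])
  }, numeric(1))
  vapply(split(pur, classes), mean, numeric(1))
}

#' Random 2-D projection of a feature matrix
#'
#' Seeded Gaussian random projection of the z-scored features; the weakest
#' sensible control for class-separation scoring.
#'
#' @param fm A `feature_matrix` (z-scored automatically if needed).
#' @param seed Integer seed.
#' @return N x 2 matrix.
#' @export
random_projection <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$z)) fm <- zscore_features(fm)
  set.seed(seed)
  w <- matrix(stats::rnorm(ncol(fm$z) * 2L), ncol(fm$z), 2L)
  fm$z %*% w
}
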