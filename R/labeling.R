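# Assign state labels to embedded windows via cluster boundary polygons,
# propagate labels to new data, and compute map-speed statistics.

#' Construct a cluster boundary polygon
#'
#' @param label State label assigned to points inside the polygon.
#' @param vertices Numeric matrix (>= 3 rows, 2 columns) of ring vertices in
#'   map units; the ring is closed implicitly and must not self-intersect.
#' @return Object of class `cluster_polygon`.
#' @export
cluster_polygon <- function(label, vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L)
  if (nrow(vertices) >= 2L &&
      all(vertices[1L, ] == vertices[nrow(vertices), ])) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]  # drop closing vertex
  }
  if (nrow(vertices) < 3L) stop("cluster_polygon: need at least 3 vertices")
  if (.ring_self_intersects(vertices)) {
    stop("cluster_polygon: ring for label '", label, "' self-intersects")
  }
  structure(list(label = as.character(label), vertices = vertices),
            class = "cluster_polygon")
}

# does the closed ring have any crossing between non-adjacent edges?
.ring_self_intersects <- function(v) {
  n <- nrow(v)
  e1 <- cbind(v, v[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (.segments_cross(e1[i, 1:2], e1[i, 3:4], e1[j, 1:2], e1[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# proper or improper intersection of segments ab and cd
.segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    sign(v)
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(p, q, r) {
    o(p, q, r) == 0 && min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  on_seg(a, b, c) || on_seg(a, b, d) || on_seg(c, d, a) || on_seg(c, d, b)
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param vertices Polygon vertex matrix (ring, not closed).
#' @param tol Distance tolerance for boundary membership.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vertices, tol = 1e-12) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  nxt <- c(2:n, 1L)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    for (e in seq_len(n)) {
      x1 <- vx[e]; y1 <- vy[e]; x2 <- vx[nxt[e]]; y2 <- vy[nxt[e]]
      # boundary: distance from point to segment <= tol
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 > 0) max(0, min(1, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
      qx <- x1 + t * dx; qy <- y1 + t * dy
      if ((x - qx)^2 + (y - qy)^2 <= tol^2) return(TRUE)
      # even-odd ray crossing (ray to +x)
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * dx
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Validate a set of cluster polygons
#'
#' Checks each ring and rejects overlapping polygons (edge crossings or one
#' polygon's vertex strictly inside another).
#'
#' @param polygons List of [cluster_polygon()] objects.
#' @return The validated list, invisibly.
#' @export
validate_polygons <- function(polygons) {
  stopifnot(length(polygons) >= 1L,
            all(vapply(polygons, inherits, logical(1), "cluster_polygon")))
  np <- length(polygons)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        a <- polygons[[i]]$vertices; b <- polygons[[j]]$vertices
        na <- nrow(a); nb <- nrow(b)
        for (ea in seq_len(na)) {
          for (eb in seq_len(nb)) {
            if (.segments_cross(a[ea, ], a[if (ea == na) 1L else ea + 1L, ],
                                b[eb, ], b[if (eb == nb) 1L else eb + 1L, ])) {
              stop("validate_polygons: polygons '", polygons[[i]]$label,
                   "' and '", polygons[[j]]$label, "' overlap")
            }
          }
        }
        if (any(point_in_polygon(a[, 1], a[, 2], b)) ||
            any(point_in_polygon(b[, 1], b[, 2], a))) {
          stop("validate_polygons: polygons '", polygons[[i]]$label,
               "' and '", polygons[[j]]$label, "' overlap")
        }
      }
    }
  }
  invisible(polygons)
}

#' Label embedded windows by cluster polygons
#'
#' Each point takes the label of the polygon containing it (even-odd rule,
#' boundary points inside); points in no polygon are "unlabeled".
#'
#' @param coords N x 2 coordinate matrix or `embedding_result`.
#' @param polygons List of [cluster_polygon()]s (validated on entry).
#' @return Character vector of labels, length N.
#' @export
label_by_polygons <- function(coords, polygons) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  validate_polygons(polygons)
  labels <- rep("unlabeled", nrow(coords))
  for (pg in polygons) {
    hit <- point_in_polygon(coords[, 1], coords[, 2], pg$vertices)
    labels[hit] <- pg$label
  }
  labels
}

#' A stable content hash for an embedding
#'
#' Used to bind a polygon file to the map it was drawn on, so stale polygon
#' files are rejected after the embedding changes.
#'
#' @param coords N x 2 coordinate matrix or `embedding_result`.
#' @return Character MD5 digest.
#' @export
embedding_hash <- function(coords) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%.12g,%.12g", coords[, 1], coords[, 2]), f)
  unname(tools::md5sum(f))
}

#' Write cluster polygons to a JSON file
#'
#' @param polygons List of [cluster_polygon()]s.
#' @param path Output path.
#' @param coords Optional embedding (or coordinate matrix) whose hash is
#'   stored alongside the polygons.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path, coords = NULL) {
  validate_polygons(polygons)
  obj <- list(
    embedding_hash = if (is.null(coords)) NA_character_ else embedding_hash(coords),
    polygons = lapply(polygons, function(p) {
      list(label = p$label, vertices = unname(p$vertices))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cluster polygons from a JSON file
#'
#' @param path Polygon JSON file written by [write_polygons()].
#' @param coords Optional embedding to check the stored hash against; a
#'   mismatch is an error (stale polygon file).
#' @return List of [cluster_polygon()]s.
#' @export
read_polygons <- function(path, coords = NULL) {
  obj <- jsonlite::read_json(path)
  if (!is.null(coords) && !is.null(obj$embedding_hash) &&
      !is.na(obj$embedding_hash)) {
    if (!identical(obj$embedding_hash, unname(embedding_hash(coords)))) {
      stop("read_polygons: polygon file was drawn on a different embedding ",
           "(hash mismatch)")
    }
  }
  polys <- lapply(obj$polygons, function(p) {
    v <- do.call(rbind, lapply(p$vertices, function(q) unlist(q)))
    cluster_polygon(p$label, v)
  })
  validate_polygons(polys)
  polys
}

#' Propagate labels to new map points by k-nearest neighbors
#'
#' Majority label among the k nearest labeled points; ties are broken by the
#' single nearest neighbor's label. A convenience for labeling held-out data
#' without re-drawing polygons or re-inspecting it by hand.
#'
#' @param coords_labeled M x 2 coordinates of labeled points.
#' @param labels Labels for the M points.
#' @param coords_new N x 2 coordinates to label.
#' @param k Odd integer >= 1.
#' @return Character vector of N labels.
#' @export
propagate_labels <- function(coords_labeled, labels, coords_new, k = 1L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (!nrow(coords_labeled)) stop("propagate_labels: no labeled points")
  stopifnot(nrow(coords_labeled) == length(labels))
  labels <- as.character(labels)
  k <- min(k, nrow(coords_labeled))
  vapply(seq_len(nrow(coords_new)), function(i) {
    d2 <- (coords_labeled[, 1] - coords_new[i, 1])^2 +
          (coords_labeled[, 2] - coords_new[i, 2])^2
    nb <- order(d2)[seq_len(k)]
    tab <- table(labels[nb])
    win <- names(tab)[tab == max(tab)]
    if (length(win) == 1L) win else labels[nb[1L]]
  }, character(1))
}

#' Instantaneous speed of motion in the map
#'
#' Speed at window j is the Euclidean distance between the coordinates of
#' windows j and j+1 of the same contiguous segment, divided by the bin
#' width; undefined (NA) at the last window of each segment.
#'
#' @param coords N x 2 coordinates or `embedding_result` (rows aligned with
#'   `store` windows).
#' @param store The [data_store()] the embedding was computed from.
#' @return Numeric vector of speeds (map units per second), NA across
#'   breakpoints.
#' @export
map_speed <- function(coords, store) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  stopifnot(nrow(coords) == n_windows(store))
  speed <- rep(NA_real_, nrow(coords))
  for (seg in find_breakpoints(store)) {
    if (length(seg) < 2L) next
    idx <- seg[-length(seg)]
    nxt <- seg[-1L]
    speed[idx] <- sqrt((coords[nxt, 1] - coords[idx, 1])^2 +
                       (coords[nxt, 2] - coords[idx, 2])^2) / store$bin_width
  }
  speed
}

#' Pairwise permutation tests of map speed between states
#'
#' For each pair of states with at least `min_n` defined speeds, a two-sided
#' permutation test on the difference of mean speeds (state labels shuffled
#' over speed values). Raw and Bonferroni-corrected p-values are reported.
#'
#' @param speeds Numeric vector from [map_speed()].
#' @param labels State labels, same length.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param min_n Minimum defined speeds per state (default 10).
#' @return Data frame with columns `state_a`, `state_b`, `mean_a`, `mean_b`,
#'   `p_value`, `p_bonferroni`.
#' @export
speed_by_state_test <- function(speeds, labels, n_perm = 1000L, seed = 1L,
                                min_n = 10L) {
  ok <- is.finite(speeds)
  speeds <- speeds[ok]
  labels <- as.character(labels)[ok]
  counts <- table(labels)
  states <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts), states)
  if (length(dropped)) {
    warning("speed_by_state_test: skipping state(s) with < ", min_n,
            " speeds: ", paste(dropped, collapse = ", "))
  }
  if (length(states) < 2L) {
    stop("speed_by_state_test: need >= 2 states with >= ", min_n, " speeds")
  }
  set.seed(seed)
  rows <- list()
  for (i in seq_len(length(states) - 1L)) {
    for (j in (i + 1L):length(states)) {
      xa <- speeds[labels == states[i]]
      xb <- speeds[labels == states[j]]
      obs <- abs(mean(xa) - mean(xb))
      pool <- c(xa, xb)
      na <- length(xa)
      null <- vapply(seq_len(n_perm), function(r) {
        p <- sample(pool)
        abs(mean(p[seq_len(na)]) - mean(p[-seq_len(na)]))
      }, numeric(1))
      p <- (1 + sum(null >= obs - 1e-15)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        state_a = states[i], state_b = states[j],
        mean_a = mean(xa), mean_b = mean(xb), p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
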