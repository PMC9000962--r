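test_that("isi-based initialization preserves ordering and handles fillers", {
  st <- make_store(
    pd = list(c(1, 1.01, 1.02, 2, 2.01, 2.02),          # short ISIs
              20 + c(1, 2, 3, 5, 9, 13),                 # long ISIs
              numeric(0)),                               # silent
    lp = list(c(1.5, 1.51, 1.52, 2.5, 2.51), 20 + c(4, 6, 8, 10), numeric(0)),
    t_starts = c(0, 20, 40))
  fm <- assemble_features(st)
  y0 <- initial_coords(fm, "isi_based")
  expect_equal(dim(y0), c(3L, 2L))
  expect_lt(y0[1, 1], y0[2, 1])    # shorter ISI -> smaller x after rescaling
  expect_gt(y0[3, 1], y0[2, 1])    # silent filler (20 s) sits at the far end
  expect_near(apply(y0, 2, sd), c(1e-4, 1e-4), tol = 1e-6)
  # random mode is seed-deterministic
  expect_identical(initial_coords(fm, "random", seed = 5),
                   initial_coords(fm, "random", seed = 5))
  expect_error(initial_coords(fm, "banana"))
})

test_that("embedding is deterministic and separates well-separated blobs", {
  set.seed(10)
  n <- 400
  cls <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  x[cls == "b", 1] <- x[cls == "b", 1] + 20   # 20 SD apart
  fm <- make_fm(x)
  e1 <- embed_map(fm, perplexity = 30, init = "random", seed = 2,
                  max_iter = 500)
  e2 <- embed_map(fm, perplexity = 30, init = "random", seed = 2,
                  max_iter = 500)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(n, 2L))
  expect_equal(e1$settings$theta, 0)          # exact gradient below N=5000
  pur <- knn_purity(e1, cls, k = 1)
  expect_equal(unname(pur), c(1, 1))
  expect_error(embed_map(make_fm(matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 4))),
               "non-finite")
})

test_that("the effective perplexity is capped at floor((N-1)/3)", {
  set.seed(2)
  fm <- make_fm(matrix(rnorm(160), 16))
  e <- embed_map(fm, perplexity = 100, init = "random", seed = 1,
                 max_iter = 50)
  expect_equal(e$perplexity, 5)
  expect_equal(e$settings$requested_perplexity, 100)
})

test_that("PCA baseline matches an eigendecomposition oracle", {
  set.seed(6)
  x <- matrix(rnorm(200 * 6), 200)
  fm <- make_fm(x)
  sc <- pca_baseline(fm)
  # oracle: eigenvectors of the covariance of the z-scored matrix
  z <- fm$z
  ev <- eigen(crossprod(z) / nrow(z), symmetric = TRUE)
  oracle <- z %*% ev$vectors[, 1:2]
  expect_near(abs(cor(sc[, 1], oracle[, 1])), 1, tol = 1e-6)
  expect_near(abs(cor(sc[, 2], oracle[, 2])), 1, tol = 1e-6)
  expect_lt(abs(sum(sc[, 1] * sc[, 2])), 1e-6)  # orthogonal scores
  # rank-1 data: second component carries nothing
  r1 <- outer(rnorm(50), c(1, 2, 3))
  sc1 <- pca_baseline(make_fm(r1))
  expect_lt(max(abs(sc1[, 2])), 1e-6)
})

test_that("triadic differences match a brute-force scan of the triangulation", {
  # 4 points forming a square -> 2 triangles
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  td <- triadic_differences(sq, c(1, 1, 1, 1))
  expect_equal(nrow(td), 2L)
  expect_equal(td$difference, c(0, 0))       # constant metric
  # metric = x coordinate on a jittered grid: per-triangle difference equals
  # the x-spread of its vertices (brute force over reported triangles)
  set.seed(12)
  g <- expand.grid(x = 1:8, y = 1:8)
  pts <- as.matrix(g) + matrix(runif(128, -0.2, 0.2), 64)
  metric <- pts[, 1]
  td2 <- triadic_differences(pts, metric)
  brute <- vapply(seq_len(nrow(td2)), function(r) {
    v <- c(td2$i[r], td2$j[r], td2$k[r])
    max(metric[v]) - min(metric[v])
  }, numeric(1))
  expect_near(td2$difference, brute)
  # incenters lie inside their triangle's bounding box
  for (r in seq_len(nrow(td2))) {
    v <- c(td2$i[r], td2$j[r], td2$k[r])
    expect_true(td2$inc_x[r] >= min(pts[v, 1]) && td2$inc_x[r] <= max(pts[v, 1]))
  }
  expect_error(triadic_differences(rbind(c(0, 0), c(1, 1), c(2, 2)), 1:3),
               "collinear")
  expect_error(triadic_differences(sq, c(1, NA, NA, 2)), "< 3")
})

test_that("windows with undefined metric are excluded before triangulation", {
  set.seed(3)
  pts <- matrix(runif(40), 20)
  metric <- runif(20)
  metric[c(3, 7)] <- NA
  td <- triadic_differences(pts, metric)
  expect_false(any(c(3, 7) %in% c(td$i, td$j, td$k))
               && attr(td, "n_points") != 18)
  expect_equal(attr(td, "n_points"), 18L)
})

test_that("the smoothness KS test behaves on identical, smooth and shuffled inputs", {
  set.seed(5)
  g <- expand.grid(x = 1:12, y = 1:12)
  pts <- as.matrix(g) + matrix(runif(288, -0.2, 0.2), 144)
  smooth_metric <- pts[, 1] + rnorm(144, 0, 0.05)
  td_map <- triadic_differences(pts, smooth_metric)
  td_same <- triadic_differences(pts, smooth_metric)
  res_same <- smoothness_test(td_map, copy = td_same)
  expect_gt(res_same$p_value, 0.5)          # identical -> no evidence
  td_shuf <- triadic_differences(pts, shuffle_metric(smooth_metric, seed = 2))
  res <- smoothness_test(td_map, shuffle = td_shuf)
  expect_lt(res$p_value, 0.01)              # smooth beats shuffled control
  # KS statistic agrees with a brute-force one-sided ECDF oracle
  a <- td_map$difference; b <- td_shuf$difference
  grid <- sort(unique(c(a, b)))
  d_plus <- max(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                       numeric(1)))
  expect_near(res$ks_statistic, d_plus)
  expect_warning(
    expect_null(smoothness_test(td_map[1:5, ], shuffle = td_shuf[1:5, ])),
    "skipped")
})

test_that("deldir triangles satisfy the empty-circumcircle property (oracle)", {
  set.seed(8)
  pts <- matrix(runif(30), 15)
  td <- triadic_differences(pts, runif(15))
  circumcenter <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    c(ux, uy)
  }
  for (r in seq_len(nrow(td))) {
    v <- c(td$i[r], td$j[r], td$k[r])
    cc <- circumcenter(pts[v[1], ], pts[v[2], ], pts[v[3], ])
    rad <- sqrt(sum((pts[v[1], ] - cc)^2))
    others <- setdiff(seq_len(15), v)
    dmin <- sqrt(rowSums(sweep(pts[others, , drop = FALSE], 2, cc)^2))
    expect_true(all(dmin >= rad - 1e-9))
  }
})

test_that("coarse class purity is robust to the perplexity choice", {
  b <- benchmark_dataset(60, seed = 19,
                         classes = c("regular", "irregular", "silent",
                                     "LP-silent", "sparse-irregular",
                                     "LP-weak-skipped"))
  fm <- zscore_features(assemble_features(b$store))
  med_pur <- vapply(c(30, 100, 300), function(px) {
    e <- embed_map(fm, perplexity = px, seed = 1, max_iter = 500)
    median(knn_purity(e, b$truth$class, k = 10))
  }, numeric(1))
  expect_lt(max(med_pur) - min(med_pur), 0.1)
})

test_that("the embedding is insensitive to +/-50% changes of the filler values", {
  b <- benchmark_dataset(60, seed = 23,
                         classes = c("regular", "irregular", "silent",
                                     "LP-silent", "sparse-irregular",
                                     "LP-weak-skipped"))
  med_pur <- vapply(c(0.5, 1, 1.5), function(fac) {
    fl <- feature_fillers()
    fl <- lapply(fl, function(v) v * fac)
    fm <- zscore_features(assemble_features(b$store, fillers = fl))
    e <- embed_map(fm, perplexity = 30, seed = 1, max_iter = 500)
    median(knn_purity(e, b$truth$class, k = 10))
  }, numeric(1))
  expect_lt(max(med_pur) - min(med_pur), 0.1)
})
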