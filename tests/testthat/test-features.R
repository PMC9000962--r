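test_that("higher-order ISIs match their definition", {
  expect_equal(compute_isis(c(0, 1, 2), 1), c(1, 1))
  expect_equal(compute_isis(c(0, 1, 3), 2), 3)
  expect_equal(compute_isis(c(0, 1), 2), numeric(0))
  # telescoping-sum oracle: first-order ISIs sum to the spanned time
  set.seed(3)
  t <- sort(runif(500, 0, 100))
  expect_near(sum(compute_isis(t, 1)), max(t) - min(t))
})

test_that("spike phases follow the flanking-interval formula", {
  expect_equal(spike_phases(1.2, c(1.0, 2.0)), 0.2)
  expect_equal(spike_phases(1.0, c(1.0, 2.0)), 0)      # coincident -> 0
  expect_equal(spike_phases(1.5, c(1.0, 2.0)), 0.5)    # midway -> 0.5
  # spikes without flanking partners are omitted
  expect_equal(spike_phases(c(0.5, 1.2, 2.5), c(1.0, 2.0)), 0.2)
  expect_equal(spike_phases(numeric(0), c(1, 2)), numeric(0))
  expect_equal(spike_phases(1.5, 1.0), numeric(0))     # single y spike
})

test_that("phases always lie in [0, 1) for random trains", {
  set.seed(9)
  for (r in 1:20) {
    x <- sort(runif(sample(1:50, 1), 0, 20))
    y <- sort(runif(sample(2:50, 1), 0, 20))
    ph <- spike_phases(x, y)
    if (length(ph)) {
      expect_true(all(ph >= 0 & ph < 1))
    }
  }
})

test_that("decile summary interpolates linearly and fills empty input", {
  expect_equal(decile_summary(rep(0.3, 1000)), rep(0.3, 10))
  # frozen values for 1..100, cross-checked against a sorting-based oracle
  expect_near(decile_summary(1:100),
              c(10.9, 20.8, 30.7, 40.6, 50.5, 60.4, 70.3, 80.2, 90.1, 100))
  brute_quantile <- function(v, p) {
    # linear interpolation between order statistics at h = (n-1)p + 1
    s <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  set.seed(4)
  v <- rexp(137)
  expect_near(decile_summary(v),
              vapply(seq(0.1, 1, 0.1), function(p) brute_quantile(v, p),
                     numeric(1)))
  expect_equal(decile_summary(numeric(0), filler = 20), rep(20, 10))
  # raw decile blocks are non-decreasing
  expect_true(all(diff(decile_summary(rnorm(50))) >= 0))
})

test_that("ISI-order ratio, top-gap ratio and their degenerate fillers", {
  periodic <- seq(0, 2, by = 0.1)
  expect_near(isi_order_ratio(periodic), 2)
  # two bursts of 3 spikes: intra-ISI 0.05, gap 1.0
  bursts <- c(0, 0.05, 0.10, 1.10, 1.15, 1.20)
  expect_near(top_gap_ratio(bursts), 1.0 / 0.05)
  expect_equal(isi_order_ratio(c(0, 1)), 0)
  expect_equal(top_gap_ratio(c(0, 1)), 0)
})

test_that("burstiness matches hand enumeration and separates firing modes", {
  # ISIs {0.05,0.05,0.06,1.0}: sorted gaps {0,0.01,0.94}, upper element 1.0
  t <- cumsum(c(0, 0.05, 0.05, 0.06, 1.0))
  expect_near(burstiness(t), 0.94)
  expect_equal(burstiness(c(0, 1, 2, 3)), 0)   # tonic
  expect_equal(burstiness(c(0, 1)), -1)        # filler
  # simulation oracle: bimodal bursts high, Poisson low
  set.seed(21)
  for (r in 1:5) {
    bursty <- as.vector(outer(seq(0, 0.1, by = 0.02), seq(0, 18, by = 1.2), "+"))
    bursty <- sort(bursty + runif(length(bursty), 0, 1e-3))
    expect_gt(burstiness(bursty), 0.8)
    tonic <- sort(runif(150, 0, 20))
    expect_lt(burstiness(tonic), 0.5)
  }
})

test_that("burstiness tie-break picks the gap with the larger upper element", {
  # two equal maximal gaps 0.5: between 0.1|0.6 and 0.6|1.1
  t <- cumsum(c(0, 0.1, 0.6, 1.1))
  expect_near(burstiness(t), 0.5 / 1.1)
})

test_that("silent windows are all fillers and shapes are invariant", {
  st <- make_store(pd = list(numeric(0), c(0.1, 0.2, 0.3, 5, 5.1, 5.2) + 20),
                   lp = list(numeric(0), c(2, 2.1, 2.2, 8, 8.1, 8.15) + 20))
  fm <- assemble_features(st)
  expect_equal(dim(fm$values), c(2L, 48L))
  f <- fm$values[1, ]
  expect_true(all(f[grep("^isi_(PD|LP)_p", names(f))] == 20))
  expect_true(all(f[grep("^phase_", names(f))] == 2))
  expect_true(all(f[grep("^rate_", names(f))] == 0))
  expect_true(all(f[grep("^isi_order_ratio_", names(f))] == 0))
  expect_true(all(f[grep("^top_gap_ratio_", names(f))] == 0))
  expect_true(all(f[grep("^burstiness_", names(f))] == -1))
  # the active window has no fillers anywhere
  g <- fm$values[2, ]
  expect_true(all(g[grep("^isi_(PD|LP)_p", names(g))] < 20))
  expect_true(all(g[grep("^phase_", names(g))] <= 1))
  expect_true(all(g[grep("^burstiness_", names(g))] >= 0))
})

test_that("features are per-window pure functions: permuting windows permutes rows", {
  b <- benchmark_dataset(50, seed = 8, classes = c("regular", "irregular"))
  fm <- assemble_features(b$store)
  # reverse window order via a new store
  st <- b$store
  perm <- rev(seq_len(n_windows(st)))
  st_r <- data_store(st$windows[perm, ],
                     st$spikes[perm], st$neuron_set, st$bin_width)
  # data_store re-sorts by (preparation, t_start); map rows by key
  fm_r <- assemble_features(st_r)
  key <- paste(fm$info$preparation, fm$info$t_start)
  key_r <- paste(fm_r$info$preparation, fm_r$info$t_start)
  expect_identical(fm_r$values[match(key, key_r), ], fm$values)
})

test_that("swapping the neuron labels swaps the corresponding feature blocks", {
  st <- make_store(pd = list(c(1, 1.1, 1.2, 3, 3.1)),
                   lp = list(c(2, 2.05, 2.2, 4, 4.4)))
  sw <- make_store(pd = list(c(2, 2.05, 2.2, 4, 4.4)),
                   lp = list(c(1, 1.1, 1.2, 3, 3.1)))
  f1 <- assemble_features(st)$values[1, ]
  f2 <- assemble_features(sw)$values[1, ]
  swap_name <- function(nm) {
    nm <- gsub("PD", "@@", nm, fixed = TRUE)
    nm <- gsub("LP", "PD", nm, fixed = TRUE)
    gsub("@@", "LP", nm, fixed = TRUE)
  }
  expect_near(unname(f2[swap_name(names(f1))]), unname(f1))
})

test_that("z-scoring is exact, stores reusable statistics, and zeroes constant columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  fm <- make_fm(x)
  fm2 <- zscore_features(structure(fm[setdiff(names(fm), c("z", "stats"))],
                                   class = "feature_matrix"))
  expect_near(fm2$z[, "a"], c(-1.224744871391589, 0, 1.224744871391589))
  expect_equal(fm2$z[, "b"], c(0, 0, 0))
  # stored stats reproduce the z-scored matrix bit-for-bit
  expect_identical(apply_zscore(x, fm2$stats), fm2$z)
  expect_error(zscore_features(make_fm(x[1, , drop = FALSE])), "at least 2")
  # non-constant columns have mean 0 and population SD 1
  expect_lt(max(abs(colMeans(fm2$z))), 1e-9)
  sdp <- sqrt(colMeans(fm2$z^2))
  expect_near(sdp[c("a", "c")], c(a = 1, c = 1))
})
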