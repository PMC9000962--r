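# Fixture builders shared across test files; everything is generated in
# code so tests carry no data files.

# a data_store built directly from named lists of spike times, one window
# per element of `pd` / `lp` (absolute times within [t_start, t_start + 20))
make_store <- function(pd, lp, t_starts = NULL, preparation = "prep1",
                       condition = NULL, bin_width = 20) {
  n <- length(pd)
  stopifnot(length(lp) == n)
  if (is.null(t_starts)) t_starts <- (seq_len(n) - 1) * bin_width
  if (is.null(condition)) condition <- rep("baseline", n)
  windows <- data.frame(preparation = rep(preparation, length.out = n),
                        t_start = t_starts,
                        condition = rep(condition, length.out = n))
  spikes <- lapply(seq_len(n), function(i) list(PD = pd[[i]], LP = lp[[i]]))
  data_store(windows, spikes, c("PD", "LP"), bin_width)
}

# wrap a bare numeric matrix as a feature_matrix so embedding utilities can
# be exercised on arbitrary geometry
make_fm <- function(x, info = NULL) {
  if (is.null(info)) {
    info <- data.frame(preparation = "p", t_start = (seq_len(nrow(x)) - 1) * 20,
                       condition = "baseline")
  }
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
  fm <- structure(list(values = x, info = info, probs = seq(0.1, 1, 0.1),
                       fillers = feature_fillers(), neuron_set = c("PD", "LP"),
                       z = NULL, stats = list(mean = mu, sd = sd)),
                  class = "feature_matrix")
  fm$z <- apply_zscore(x, fm$stats)
  fm
}

# a simple unit-square polygon
unit_square <- function(label = "regular") {
  cluster_polygon(label, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

expect_near <- function(x, y, tol = 1e-9) expect_equal(x, y, tolerance = tol)
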