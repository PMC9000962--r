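# ISI / spike-phase featurization: each 20 s window becomes a fixed-length
# vector of decile blocks plus scalar burst descriptors, later z-scored.

#' Higher-order interspike intervals
#'
#' The nth-order ISI set I(n) contains the times spanned by n consecutive
#' intervals: `values[j] = t[j+n] - t[j]`. I(1) is the ordinary ISI set.
#'
#' @param times Sorted numeric vector of spike times (seconds).
#' @param n Interval order, integer >= 1.
#' @return Numeric vector of length `max(length(times) - n, 0)`.
#' @export
compute_isis <- function(times, n = 1L) {
  stopifnot(n >= 1L)
  k <- length(times)
  if (k <= n) return(numeric(0))
  times[(n + 1L):k] - times[seq_len(k - n)]
}

#' Spike phases of one neuron with respect to another
#'
#' The phase of the i-th spike of neuron X w.r.t. neuron Y is
#' `(t_i^X - t_-^Y) / (t_+^Y - t_-^Y)`, where `t_-^Y` is the last Y spike at
#' or before `t_i^X` and `t_+^Y` the first strictly after. X spikes with no
#' Y spike on one side are omitted. A spike coincident with a Y spike has
#' phase 0. All phases lie in [0, 1).
#'
#' @param x_times,y_times Sorted spike time vectors for neurons X and Y.
#' @return Numeric vector of phases (possibly empty).
#' @export
spike_phases <- function(x_times, y_times) {
  if (!length(x_times) || length(y_times) < 2L) return(numeric(0))
  idx <- findInterval(x_times, y_times)  # index of last y <= x (0 if none)
  keep <- idx >= 1L & idx < length(y_times)
  if (!any(keep)) return(numeric(0))
  x <- x_times[keep]; i <- idx[keep]
  lo <- y_times[i]; hi <- y_times[i + 1L]
  (x - lo) / (hi - lo)
}

#' Decile summary of a value set
#'
#' Percentiles at 10, 20, ..., 100 with linear interpolation
#' (`stats::quantile` type 7). An empty input yields the filler repeated.
#'
#' @param values Numeric vector.
#' @param probs Percentile grid (default `seq(0.1, 1, 0.1)`).
#' @param filler Value substituted (repeated) when `values` is empty.
#' @return Numeric vector of `length(probs)` non-decreasing values.
#' @export
decile_summary <- function(values, probs = seq(0.1, 1, by = 0.1), filler = NA_real_) {
  if (!length(values)) return(rep(filler, length(probs)))
  unname(stats::quantile(values, probs = probs, type = 7, names = FALSE))
}

#' Ratio of maximal second-order to maximal first-order ISI
#'
#' `max I(2) / max I(1)`; separates single-spike "bursts" from true bursts.
#' Requires at least 3 spikes, otherwise returns `filler`.
#'
#' @param times Sorted spike time vector.
#' @param filler Value when undefined (default 0, below the attainable
#'   minimum of 1).
#' @return A single number.
#' @export
isi_order_ratio <- function(times, filler = 0) {
  if (length(times) < 3L) return(filler)
  max(compute_isis(times, 2L)) / max(compute_isis(times, 1L))
}

#' Ratio of largest to second-largest ISI
#'
#' Requires at least 3 spikes (two ISIs); >= 1 when defined.
#'
#' @param times Sorted spike time vector.
#' @param filler Value when undefined (default 0).
#' @return A single number.
#' @export
top_gap_ratio <- function(times, filler = 0) {
  if (length(times) < 3L) return(filler)
  s <- sort(compute_isis(times, 1L), decreasing = TRUE)
  s[1L] / s[2L]
}

#' Burstiness of a spike train
#'
#' Let `s` be the ascending sorted ISIs and `diff(s)` their consecutive
#' differences. The statistic is `max diff(s) / s_max`, where `s_max` is the
#' upper element of the maximal gap. It approaches 1 for strongly bimodal
#' (bursty) ISI distributions and 0 for tonic firing. When several gaps tie
#' for maximal, the gap with the largest upper element is used (the smaller,
#' more conservative statistic).
#'
#' @param times Sorted spike time vector.
#' @param filler Value when fewer than 3 spikes (default -1, below the
#'   attainable minimum of 0).
#' @return A single number in [0, 1) when defined.
#' @export
burstiness <- function(times, filler = -1) {
  if (length(times) < 3L) return(filler)
  s <- sort(compute_isis(times, 1L))
  g <- diff(s)
  mg <- max(g)
  if (mg == 0) return(0)
  upper <- s[-1L][g >= mg - .time_tol * max(s)]
  mg / max(upper)
}

#' Default filler values for undefined features
#'
#' Fillers sit well off the extremes of each feature's defined range: ISI
#' deciles 20 s (the bin width), phase deciles 2 (above the maximum of 1),
#' ISI-order and top-gap ratios 0 (below their minimum of 1), burstiness -1
#' (below its minimum of 0). Firing rate is always defined (0 when silent).
#'
#' @return Named list of filler values.
#' @export
feature_fillers <- function() {
  list(isi_decile = 20, phase_decile = 2, isi_order_ratio = 0,
       top_gap_ratio = 0, burstiness = -1)
}

#' Feature column names for a neuron set
#'
#' Column order is fixed: per-neuron ISI decile blocks, per ordered neuron
#' pair phase decile blocks, then firing rates, ISI-order ratios, top-gap
#' ratios and burstiness per neuron. For two neurons this gives 48 columns.
#'
#' @param neuron_set Ordered character vector of neuron ids.
#' @param probs Percentile grid.
#' @return Character vector of column names.
#' @export
feature_names <- function(neuron_set, probs = seq(0.1, 1, by = 0.1)) {
  pct <- paste0("p", round(probs * 100))
  pairs <- expand.grid(y = neuron_set, x = neuron_set,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, c("x", "y")]
  pairs <- pairs[order(match(pairs$x, neuron_set), match(pairs$y, neuron_set)), ]
  c(unlist(lapply(neuron_set, function(n) paste0("isi_", n, "_", pct))),
    unlist(lapply(seq_len(nrow(pairs)), function(i) {
      paste0("phase_", pairs$x[i], "_wrt_", pairs$y[i], "_", pct)
    })),
    paste0("rate_", neuron_set),
    paste0("isi_order_ratio_", neuron_set),
    paste0("top_gap_ratio_", neuron_set),
    paste0("burstiness_", neuron_set))
}

#' Assemble the per-window feature matrix
#'
#' Computes, for every window: per-neuron ISI deciles, per ordered-pair spike
#' phase deciles, firing rates (spike count / bin width), ISI-order ratios,
#' top-gap ratios and burstiness. Undefined features carry the documented
#' filler values so every row has the same fixed length (48 for two neurons).
#'
#' @param store A [data_store()].
#' @param probs Percentile grid for the decile blocks.
#' @param fillers Filler values, see [feature_fillers()].
#' @return An object of class `feature_matrix`: list with `values` (raw
#'   numeric matrix, named columns), `info` (window metadata), `probs`,
#'   `fillers`, `neuron_set`; z-scored values are added by
#'   [zscore_features()].
#' @export
assemble_features <- function(store, probs = seq(0.1, 1, by = 0.1),
                              fillers = feature_fillers()) {
  n <- n_windows(store)
  if (n == 0L) stop("assemble_features: empty data store")
  ns <- store$neuron_set
  cols <- feature_names(ns, probs)
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  pairs <- expand.grid(y = ns, x = ns, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, c("x", "y")]
  pairs <- pairs[order(match(pairs$x, ns), match(pairs$y, ns)), ]
  for (i in seq_len(n)) {
    row <- numeric(0)
    trains <- store$spikes[[i]]
    for (nrn in ns) {
      row <- c(row, decile_summary(compute_isis(trains[[nrn]], 1L), probs,
                                   filler = fillers$isi_decile))
    }
    for (j in seq_len(nrow(pairs))) {
      ph <- spike_phases(trains[[pairs$x[j]]], trains[[pairs$y[j]]])
      row <- c(row, decile_summary(ph, probs, filler = fillers$phase_decile))
    }
    row <- c(row,
             vapply(ns, function(nrn) length(trains[[nrn]]) / store$bin_width,
                    numeric(1)),
             vapply(ns, function(nrn) isi_order_ratio(trains[[nrn]],
                                                      fillers$isi_order_ratio),
                    numeric(1)),
             vapply(ns, function(nrn) top_gap_ratio(trains[[nrn]],
                                                    fillers$top_gap_ratio),
                    numeric(1)),
             vapply(ns, function(nrn) burstiness(trains[[nrn]],
                                                 fillers$burstiness),
                    numeric(1)))
    vals[i, ] <- row
  }
  structure(list(values = vals, info = store$windows, probs = probs,
                 fillers = fillers, neuron_set = ns, z = NULL, stats = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "windows x", ncol(x$values),
      "features;", if (is.null(x$z)) "raw" else "z-scored", "\n")
  invisible(x)
}

#' Z-score a feature matrix column-wise
#'
#' Each column is centered and scaled by its population standard deviation
#' (divisor n) across the dataset; zero-variance columns map to 0. The
#' statistics are stored in the result so they can be re-applied to held-out
#' windows.
#'
#' @param fm A `feature_matrix` from [assemble_features()].
#' @return The same object with elements `z` (z-scored matrix) and `stats`
#'   (list of per-column `mean` and `sd`).
#' @export
zscore_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2L) stop("zscore_features: need at least 2 windows")
  mu <- colMeans(fm$values)
  sd <- sqrt(colMeans(sweep(fm$values, 2, mu, "-")^2))  # population SD
  fm$stats <- list(mean = mu, sd = sd)
  fm$z <- apply_zscore(fm$values, fm$stats)
  fm
}

#' Apply stored z-score statistics to a raw feature matrix
#'
#' @param values Raw numeric feature matrix (same column order as used to
#'   compute `stats`).
#' @param stats List with per-column `mean` and `sd`, as stored by
#'   [zscore_features()].
#' @return Z-scored matrix; zero-variance columns map to 0.
#' @export
apply_zscore <- function(values, stats) {
  z <- sweep(values, 2, stats$mean, "-")
  s <- stats$sd
  s[s < 1e-12] <- Inf  # constant columns -> 0
  sweep(z, 2, s, "/")
}
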