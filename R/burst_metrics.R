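# Burst detection by ISI thresholding and the period / duty-cycle / phase /
# delay metrics of the pyloric rhythm, computed per window.

#' Detect bursts in a spike train by ISI thresholding
#'
#' Bursty trains have bimodal ISI distributions; ISIs above a threshold are
#' inter-burst intervals and maximal runs of spikes joined by sub-threshold
#' ISIs with at least `min_spikes` spikes form bursts. The automatic
#' threshold is the geometric mean of the two sorted ISIs flanking the
#' maximal sorted-ISI gap, which adapts across rhythm periods without
#' tuning. Trains with burstiness below `min_burstiness` (no clear
#' bimodality) or fewer than 4 spikes yield no bursts.
#'
#' @param times Sorted spike time vector (seconds).
#' @param threshold "auto" or a fixed ISI threshold in seconds.
#' @param min_burstiness Minimum [burstiness()] required (default 0.5);
#'   ignored when a fixed threshold is given.
#' @param min_spikes Minimum spikes per burst (default 2).
#' @return Data frame of class `burst_train` with columns `start`, `end`,
#'   `n_spikes` (possibly zero rows).
#' @export
detect_bursts <- function(times, threshold = "auto", min_burstiness = 0.5,
                          min_spikes = 2L) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  class(empty) <- c("burst_train", "data.frame")
  if (length(times) < 4L) return(empty)
  isis <- compute_isis(times, 1L)
  if (identical(threshold, "auto")) {
    if (burstiness(times) < min_burstiness) return(empty)
    s <- sort(isis)
    g <- diff(s)
    i <- which.max(g)
    thr <- sqrt(s[i] * s[i + 1L])
  } else {
    thr <- as.numeric(threshold)
  }
  brk <- which(isis > thr)  # inter-burst intervals
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(times))
  keep <- (ends - starts + 1L) >= min_spikes
  out <- data.frame(start = times[starts[keep]], end = times[ends[keep]],
                    n_spikes = as.integer(ends[keep] - starts[keep] + 1L))
  class(out) <- c("burst_train", "data.frame")
  out
}

#' Burst metrics for one window
#'
#' Computes, from detected bursts of the reference (pacemaker, PD) and
#' follower (LP) neurons within one window: the reference burst period
#' (mean start-to-start interval), burst durations, duty cycles (duration /
#' same-neuron cycle period), and the follower's on/off delays (burst
#' start/end minus the most recent preceding reference burst start) and
#' phases (delay / that cycle's period, wrapped to [0, 1)). Per-window means
#' and SDs over cycles are reported; undefined metrics are missing rows
#' (never fillers).
#'
#' @param ref_bursts `burst_train` of the reference neuron (PD).
#' @param fol_bursts `burst_train` of the follower neuron (LP).
#' @param ref_name,fol_name Neuron names used in metric labels.
#' @return Data frame with columns `metric`, `mean`, `sd`, `n_cycles`.
#' @export
compute_burst_metrics <- function(ref_bursts, fol_bursts,
                                  ref_name = "PD", fol_name = "LP") {
  rows <- list()
  add <- function(metric, values) {
    values <- values[is.finite(values)]
    if (!length(values)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, mean = mean(values),
      sd = if (length(values) > 1L) stats::sd(values) else 0,
      n_cycles = length(values))
  }
  nr <- nrow(ref_bursts)
  periods <- if (nr >= 2L) diff(ref_bursts$start) else numeric(0)
  add(paste0(ref_name, "_burst_period"), periods)
  add(paste0(ref_name, "_burst_duration"), ref_bursts$end - ref_bursts$start)
  if (length(periods)) {
    dur <- (ref_bursts$end - ref_bursts$start)[seq_along(periods)]
    add(paste0(ref_name, "_duty_cycle"), dur / periods)
  }
  nf <- nrow(fol_bursts)
  add(paste0(fol_name, "_burst_duration"), fol_bursts$end - fol_bursts$start)
  fol_periods <- if (nf >= 2L) diff(fol_bursts$start) else numeric(0)
  if (length(fol_periods)) {
    dur <- (fol_bursts$end - fol_bursts$start)[seq_along(fol_periods)]
    add(paste0(fol_name, "_duty_cycle"), dur / fol_periods)
  }
  if (nf >= 1L && length(periods)) {
    # assign each follower burst to the most recent preceding reference cycle
    cyc <- findInterval(fol_bursts$start, ref_bursts$start)
    ok <- cyc >= 1L & cyc <= length(periods)  # cycle must have a next ref start
    if (any(ok)) {
      d_on <- fol_bursts$start[ok] - ref_bursts$start[cyc[ok]]
      d_off <- fol_bursts$end[ok] - ref_bursts$start[cyc[ok]]
      p <- periods[cyc[ok]]
      add(paste0(fol_name, "_delay_on"), d_on)
      add(paste0(fol_name, "_delay_off"), d_off)
      add(paste0(fol_name, "_phase_on"), (d_on / p) %% 1)
      add(paste0(fol_name, "_phase_off"), (d_off / p) %% 1)
    }
  }
  if (!length(rows)) {
    return(data.frame(metric = character(0), mean = numeric(0),
                      sd = numeric(0), n_cycles = integer(0)))
  }
  do.call(rbind, rows)
}

#' The nine burst metrics reported by the pipeline
#' @param ref_name,fol_name Neuron names.
#' @return Character vector of metric names.
#' @export
burst_metric_names <- function(ref_name = "PD", fol_name = "LP") {
  c(paste0(ref_name, c("_burst_period", "_burst_duration", "_duty_cycle")),
    paste0(fol_name, c("_burst_duration", "_duty_cycle", "_delay_on",
                       "_delay_off", "_phase_on", "_phase_off")))
}

#' Burst metrics restricted to windows in a given state
#'
#' Burst metrics are only meaningful where the rhythm is regular enough to
#' define them; this computes them on windows carrying the requested label
#' only, tagging rows with preparation, window start and condition.
#'
#' @param store A [data_store()].
#' @param labels State labels per window (defaults to `store$labels`).
#' @param state Label to restrict to (default "regular").
#' @param ref_neuron,fol_neuron Reference (pacemaker) and follower neuron
#'   ids; default the store's neuron set entries "PD" and "LP" when present.
#' @param threshold,min_burstiness Passed to [detect_bursts()].
#' @return Data frame with columns `preparation`, `t_start`, `condition`,
#'   `metric`, `mean`, `sd`, `n_cycles` (possibly empty, with a warning).
#' @export
metrics_on_state <- function(store, labels = NULL, state = "regular",
                             ref_neuron = NULL, fol_neuron = NULL,
                             threshold = "auto", min_burstiness = 0.5) {
  if (is.null(labels)) labels <- store$labels
  stopifnot(!is.null(labels), length(labels) == n_windows(store))
  ns <- store$neuron_set
  if (is.null(ref_neuron)) ref_neuron <- if ("PD" %in% ns) "PD" else ns[1L]
  if (is.null(fol_neuron)) fol_neuron <- if ("LP" %in% ns) "LP" else ns[2L]
  idx <- which(labels == state)
  if (!length(idx)) {
    warning("metrics_on_state: no windows labeled '", state, "'")
    return(data.frame(preparation = character(0), t_start = numeric(0),
                      condition = character(0), metric = character(0),
                      mean = numeric(0), sd = numeric(0),
                      n_cycles = integer(0)))
  }
  out <- lapply(idx, function(i) {
    rb <- detect_bursts(window_spikes(store, i, ref_neuron), threshold,
                        min_burstiness)
    fb <- detect_bursts(window_spikes(store, i, fol_neuron), threshold,
                        min_burstiness)
    m <- compute_burst_metrics(rb, fb, ref_neuron, fol_neuron)
    if (!nrow(m)) return(NULL)
    cbind(data.frame(preparation = store$windows$preparation[i],
                     t_start = store$windows$t_start[i],
                     condition = store$windows$condition[i]), m)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("metrics_on_state: no metrics defined on qualifying windows")
    out <- data.frame(preparation = character(0), t_start = numeric(0),
                      condition = character(0), metric = character(0),
                      mean = numeric(0), sd = numeric(0),
                      n_cycles = integer(0))
  }
  rownames(out) <- NULL
  out
}
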