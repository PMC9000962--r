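# Seeded generators for labeled spike patterns in all 12 dynamic states and
# for Markov label sequences, so every pipeline stage is testable without
# recorded data. Class parameters emulate the pyloric rhythm (period ~1 s,
# PD duty ~0.2, LP following at ~0.45 of the cycle).

#' The twelve generator classes
#' @return Character vector of generatable state names.
#' @export
synthetic_classes <- function() {
  setdiff(pyloric_states(), "unlabeled")
}

#' Parameters for a synthetic spike-pattern class
#'
#' Defaults encode a canonical slow pyloric rhythm; class-specific overrides
#' produce each atypical state: weak-skipped classes skip or reduce one
#' neuron's burst stochastically, irregular-bursting adds heavy period
#' jitter and cycle dropout, irregular/sparse-irregular are homogeneous
#' Poisson trains, one-neuron-silent classes zero one train, and
#' aberrant-spikes superimposes stray Poisson spikes on a regular rhythm.
#'
#' @param class One of [synthetic_classes()].
#' @param period Burst period T in seconds (default 1).
#' @param duty Named duty cycles, `c(PD = 0.2, LP = 0.3)`.
#' @param lp_phase LP burst onset as a fraction of the PD cycle (default 0.45).
#' @param intra_rate Named intra-burst firing rates in Hz,
#'   `c(PD = 40, LP = 30)`.
#' @param jitter_cv CV of cycle-to-cycle period jitter.
#' @param spike_jitter_frac Within-burst spike timing jitter, as a fraction
#'   of the intra-burst spike spacing (default 0.05).
#' @param skip_prob Per-cycle probability the affected neuron skips its
#'   burst (weak-skipped classes).
#' @param single_spike_prob Per-cycle probability the affected neuron's
#'   burst is reduced to a single spike (weak-skipped classes).
#' @param dropout Per-cycle, per-neuron burst dropout probability
#'   (irregular-bursting).
#' @param tonic_rate Poisson rate in Hz for tonic classes.
#' @param aberrant_rate Rate of stray spikes outside bursts in Hz.
#' @return Named list of class `generator_params`.
#' @export
generator_params <- function(class,
                             period = 1,
                             duty = c(PD = 0.2, LP = 0.3),
                             lp_phase = 0.45,
                             intra_rate = c(PD = 40, LP = 30),
                             jitter_cv = 0.05,
                             spike_jitter_frac = 0.05,
                             skip_prob = 0.3,
                             single_spike_prob = 0.2,
                             dropout = 0.2,
                             tonic_rate = 8,
                             aberrant_rate = 0.5) {
  class <- match.arg(class, synthetic_classes())
  stopifnot(period > 0, all(duty > 0 & duty < 1), lp_phase >= 0, lp_phase < 1,
            all(intra_rate > 0), jitter_cv >= 0,
            skip_prob >= 0, skip_prob <= 1,
            single_spike_prob >= 0, single_spike_prob <= 1,
            dropout >= 0, dropout <= 1, tonic_rate >= 0, aberrant_rate >= 0)
  p <- list(class = class, period = period, duty = duty, lp_phase = lp_phase,
            intra_rate = intra_rate, jitter_cv = jitter_cv,
            spike_jitter_frac = spike_jitter_frac, skip_prob = skip_prob,
            single_spike_prob = single_spike_prob, dropout = dropout,
            tonic_rate = tonic_rate, aberrant_rate = aberrant_rate)
  if (class == "irregular-bursting" && jitter_cv < 0.3) p$jitter_cv <- 0.35
  if (class == "sparse-irregular") p$tonic_rate <- 1
  structure(p, class = c("generator_params", "list"))
}

# evenly spaced burst spikes on [start, start + dur] with optional jitter
.burst_spikes <- function(start, dur, rate, jitter_frac) {
  n_sp <- max(2L, floor(rate * dur) + 1L)
  t <- seq(start, start + dur, length.out = n_sp)
  if (jitter_frac > 0 && n_sp > 2L) {
    gap <- dur / (n_sp - 1L)
    mid <- 2:(n_sp - 1L)
    t[mid] <- t[mid] + stats::runif(length(mid), -1, 1) * jitter_frac * gap
    t <- sort(t)
  }
  t
}

# homogeneous Poisson train on [0, total)
.poisson_spikes <- function(rate, total) {
  n <- stats::rpois(1L, rate * total)
  sort(stats::runif(n, 0, total))
}

# continuous paired PD/LP spike trains of one class over [0, total) seconds
.generate_class_trains <- function(params, total) {
  p <- params
  pd <- numeric(0); lp <- numeric(0)
  bursty <- p$class %in% c("regular", "LP-weak-skipped", "PD-weak-skipped",
                           "irregular-bursting", "aberrant-spikes",
                           "LP-silent-PD-bursting", "PD-silent-LP-bursting")
  if (bursty) {
    # cycle starts with multiplicative period jitter
    starts <- numeric(0); t <- 0
    while (t < total + p$period) {
      starts <- c(starts, t)
      fac <- max(0.1, 1 + p$jitter_cv * stats::rnorm(1L))
      t <- t + p$period * fac
    }
    nc <- length(starts) - 1L
    pd_bursts <- rep(TRUE, nc); lp_bursts <- rep(TRUE, nc)
    lp_single <- rep(FALSE, nc); pd_single <- rep(FALSE, nc)
    if (p$class == "LP-weak-skipped") {
      lp_bursts <- stats::runif(nc) >= p$skip_prob
      lp_single <- lp_bursts & (stats::runif(nc) < p$single_spike_prob)
    }
    if (p$class == "PD-weak-skipped") {
      pd_bursts <- stats::runif(nc) >= p$skip_prob
      pd_single <- pd_bursts & (stats::runif(nc) < p$single_spike_prob)
    }
    if (p$class == "irregular-bursting") {
      pd_bursts <- stats::runif(nc) >= p$dropout
      lp_bursts <- stats::runif(nc) >= p$dropout
    }
    if (p$class == "LP-silent-PD-bursting") lp_bursts[] <- FALSE
    if (p$class == "PD-silent-LP-bursting") pd_bursts[] <- FALSE
    for (k in seq_len(nc)) {
      cyc <- starts[k + 1L] - starts[k]
      if (pd_bursts[k]) {
        if (pd_single[k]) {
          pd <- c(pd, starts[k])
        } else {
          pd <- c(pd, .burst_spikes(starts[k], p$duty[["PD"]] * cyc,
                                    p$intra_rate[["PD"]],
                                    p$spike_jitter_frac))
        }
      }
      if (lp_bursts[k]) {
        lp_on <- starts[k] + p$lp_phase * cyc
        if (lp_single[k]) {
          lp <- c(lp, lp_on)
        } else {
          lp <- c(lp, .burst_spikes(lp_on, p$duty[["LP"]] * cyc,
                                    p$intra_rate[["LP"]],
                                    p$spike_jitter_frac))
        }
      }
    }
    if (p$class == "aberrant-spikes" && p$aberrant_rate > 0) {
      for (nrn in c("PD", "LP")) {
        stray <- .poisson_spikes(p$aberrant_rate, total)
        have <- if (nrn == "PD") pd else lp
        # keep stray spikes clear of existing bursts
        if (length(have)) {
          near <- vapply(stray, function(s) min(abs(s - have)), numeric(1))
          stray <- stray[near > 0.05]
        }
        if (nrn == "PD") pd <- sort(c(pd, stray)) else lp <- sort(c(lp, stray))
      }
    }
  } else if (p$class %in% c("irregular", "sparse-irregular")) {
    pd <- .poisson_spikes(p$tonic_rate, total)
    lp <- .poisson_spikes(p$tonic_rate, total)
  } else if (p$class == "LP-silent") {
    pd <- .poisson_spikes(p$tonic_rate, total)
  } else if (p$class == "PD-silent") {
    lp <- .poisson_spikes(p$tonic_rate, total)
  } # silent: nothing
  list(PD = unique(pd[pd >= 0 & pd < total]),
       LP = unique(lp[lp >= 0 & lp < total]))
}

#' Generate labeled windows of one synthetic class
#'
#' @param params A [generator_params()] object.
#' @param n_windows Number of 20 s windows to generate.
#' @param bin_width Bin width in seconds (default 20).
#' @param preparation_id Preparation identifier (default derived from class).
#' @param seed Integer seed.
#' @param condition Condition recorded in the window metadata.
#' @return A [data_store()] with true labels attached.
#' @export
generate_windows <- function(params, n_windows, bin_width = 20,
                             preparation_id = NULL, seed = 1L,
                             condition = "baseline") {
  stopifnot(inherits(params, "generator_params"), n_windows >= 1L)
  if (is.null(preparation_id)) preparation_id <- paste0("synth-", params$class)
  set.seed(seed)
  total <- n_windows * bin_width
  tr <- .generate_class_trains(params, total)
  raw <- rbind(
    if (length(tr$PD)) data.frame(preparation = preparation_id, neuron = "PD",
                                  time_s = tr$PD),
    if (length(tr$LP)) data.frame(preparation = preparation_id, neuron = "LP",
                                  time_s = tr$LP))
  if (is.null(raw)) {
    raw <- data.frame(preparation = character(0), neuron = character(0),
                      time_s = numeric(0))
  }
  md <- data.frame(preparation = preparation_id, t_start = 0, t_end = total,
                   condition = condition)
  store <- bin_spikes(raw, bin_width = bin_width, metadata = md,
                      neuron_set = c("PD", "LP"),
                      t_max = stats::setNames(total, preparation_id),
                      preparations = preparation_id)
  set_labels(store, rep(params$class, n_windows(store)))
}

#' Balanced multi-class benchmark dataset
#'
#' One preparation per class, `n_per_class` windows each, with documented
#' default parameters; true class labels are retained for purity scoring of
#' the embedding.
#'
#' @param n_per_class Windows per class (>= 50).
#' @param seed Integer seed (per-class sub-seeds are derived from it).
#' @param classes Classes to include (default all 12).
#' @param bin_width Bin width in seconds.
#' @return List with `store` (a labeled [data_store()]) and `truth` (data
#'   frame: `preparation`, `t_start`, `class`).
#' @export
benchmark_dataset <- function(n_per_class = 200L, seed = 1L,
                              classes = synthetic_classes(), bin_width = 20) {
  stopifnot(n_per_class >= 50L)
  stores <- lapply(seq_along(classes), function(i) {
    generate_windows(generator_params(classes[i]), n_per_class,
                     bin_width = bin_width,
                     seed = seed * 1000L + i)
  })
  store <- .bind_stores(stores)
  truth <- data.frame(preparation = store$windows$preparation,
                      t_start = store$windows$t_start,
                      class = store$labels)
  list(store = store, truth = truth)
}

# concatenate data stores sharing neuron set and bin width
.bind_stores <- function(stores) {
  stopifnot(length(stores) >= 1L)
  ns <- stores[[1L]]$neuron_set
  bw <- stores[[1L]]$bin_width
  windows <- do.call(rbind, lapply(stores, function(s) s$windows))
  spikes <- do.call(c, lapply(stores, function(s) s$spikes))
  labels <- unlist(lapply(stores, function(s) {
    if (is.null(s$labels)) rep("unlabeled", n_windows(s)) else s$labels
  }))
  data_store(windows, spikes, ns, bw, labels)
}

#' Regular windows with a smooth gradient of burst periods
#'
#' Used for embedding-smoothness diagnostics: each window is drawn from the
#' regular generator with its own period, graded linearly across windows.
#'
#' @param n Number of windows.
#' @param period_range Range of periods in seconds (default 0.6 to 1.4).
#' @param seed Integer seed.
#' @param bin_width Bin width in seconds.
#' @return List with `store` (labeled [data_store()]) and `period` (the true
#'   per-window generator period).
#' @export
graded_period_dataset <- function(n = 500L, period_range = c(0.6, 1.4),
                                  seed = 1L, bin_width = 20) {
  periods <- seq(period_range[1], period_range[2], length.out = n)
  stores <- lapply(seq_len(n), function(i) {
    generate_windows(generator_params("regular", period = periods[i]),
                     n_windows = 1L, bin_width = bin_width,
                     preparation_id = sprintf("graded-%04d", i),
                     seed = seed * 10000L + i)
  })
  list(store = .bind_stores(stores), period = periods)
}

#' Specification of a Markov label-sequence generator
#'
#' @param states State names.
#' @param transition Row-stochastic K x K matrix including self-transitions.
#' @param initial Initial distribution (default uniform).
#' @param length Sequence length in bins.
#' @param bin_width Bin spacing in seconds.
#' @return Object of class `markov_spec`.
#' @export
markov_spec <- function(states, transition, initial = NULL, length = 100L,
                        bin_width = 20) {
  transition <- as.matrix(transition)
  k <- base::length(states)
  stopifnot(nrow(transition) == k, ncol(transition) == k,
            all(abs(rowSums(transition) - 1) < 1e-9), all(transition >= 0))
  if (is.null(initial)) initial <- rep(1 / k, k)
  stopifnot(abs(sum(initial) - 1) < 1e-9, base::length(initial) == k)
  structure(list(states = states, transition = transition, initial = initial,
                 length = as.integer(length), bin_width = bin_width),
            class = "markov_spec")
}

#' Sample a Markov state-label sequence
#'
#' @param spec A [markov_spec()].
#' @param seed Integer seed.
#' @param preparation_id Preparation id for the sequence.
#' @return A [state_sequence()] with contiguous timestamps at bin spacing.
#' @export
generate_label_sequence <- function(spec, seed = 1L,
                                    preparation_id = "markov") {
  stopifnot(inherits(spec, "markov_spec"))
  set.seed(seed)
  k <- length(spec$states)
  s <- integer(spec$length)
  s[1L] <- sample.int(k, 1L, prob = spec$initial)
  for (i in seq_len(spec$length - 1L)) {
    s[i + 1L] <- sample.int(k, 1L, prob = spec$transition[s[i], ])
  }
  state_sequence(preparation = rep(preparation_id, spec$length),
                 t_start = (seq_len(spec$length) - 1L) * spec$bin_width,
                 label = spec$states[s], bin_width = spec$bin_width)
}

#' Regular segments with controlled pre-transition period jitter
#'
#' Generates per-segment recordings of `n_regular` regular windows followed
#' by one irregular (Poisson) window, with the regular generator's period
#' jitter either constant or ramping linearly from `base_cv` to `peak_cv`
#' over the final `ramp_span` seconds before the transition. Used to probe
#' the variability-before-transition trend analysis under known dynamics.
#'
#' @param n_segments Number of independent segments (one preparation each).
#' @param n_regular Regular windows per segment before the transition.
#' @param base_cv Baseline period-jitter CV.
#' @param peak_cv Jitter CV at the transition (default `base_cv`, i.e.
#'   constant).
#' @param ramp_span Seconds over which the ramp unfolds (default 200).
#' @param period Burst period in seconds.
#' @param bin_width Bin width in seconds.
#' @param seed Integer seed.
#' @return List with `store` (labeled [data_store()]) and `seq` (the
#'   corresponding [state_sequence()]).
#' @export
generate_pretransition_segments <- function(n_segments, n_regular = 10L,
                                            base_cv = 0.02, peak_cv = NULL,
                                            ramp_span = 200, period = 1,
                                            bin_width = 20, seed = 1L) {
  if (is.null(peak_cv)) peak_cv <- base_cv
  stores <- list()
  for (g in seq_len(n_segments)) {
    set.seed(seed * 10000L + g)
    prep <- sprintf("seg-%04d", g)
    reg_total <- n_regular * bin_width
    # cycle-by-cycle generation with time-varying jitter
    pd <- numeric(0); lp <- numeric(0); t <- 0
    duty <- c(PD = 0.2, LP = 0.3); lp_phase <- 0.45
    while (t < reg_total + period) {
      frac <- max(0, min(1, (t - (reg_total - ramp_span)) / ramp_span))
      cv_t <- base_cv + (peak_cv - base_cv) * frac
      cyc <- period * max(0.1, 1 + cv_t * stats::rnorm(1L))
      pd <- c(pd, .burst_spikes(t, duty[["PD"]] * cyc, 40, 0.05))
      lp <- c(lp, .burst_spikes(t + lp_phase * cyc, duty[["LP"]] * cyc, 30,
                                0.05))
      t <- t + cyc
    }
    pd <- pd[pd < reg_total]; lp <- lp[lp < reg_total]
    # transition window: irregular Poisson firing
    pd <- c(pd, reg_total + .poisson_spikes(8, bin_width))
    lp <- c(lp, reg_total + .poisson_spikes(8, bin_width))
    raw <- rbind(data.frame(preparation = prep, neuron = "PD", time_s = pd),
                 data.frame(preparation = prep, neuron = "LP", time_s = lp))
    total <- reg_total + bin_width
    st <- bin_spikes(raw, bin_width = bin_width,
                     neuron_set = c("PD", "LP"),
                     t_max = stats::setNames(total, prep),
                     preparations = prep)
    st <- set_labels(st, c(rep("regular", n_regular), "irregular"))
    stores[[g]] <- st
  }
  store <- .bind_stores(stores)
  list(store = store, seq = state_sequence_from_store(store))
}

#' Simulated per-window burst-metric values across animals
#'
#' Draws per-animal metric means with a chosen across-animal CV and
#' per-window values around each animal's mean with a chosen within-animal
#' CV; the input expected by [within_across_variability()] under controlled
#' conditions.
#'
#' @param n_animals Number of animals.
#' @param n_windows Windows per animal.
#' @param across_cv CV of the animal means (0 = exchangeable animals).
#' @param within_cv CV of values within each animal.
#' @param grand_mean Population mean of the metric (default 1).
#' @param metric Metric name recorded in the table.
#' @param seed Integer seed.
#' @return Data frame with columns `preparation`, `metric`, `mean`.
#' @export
simulate_metric_values <- function(n_animals, n_windows, across_cv,
                                   within_cv, grand_mean = 1,
                                   metric = "PD_burst_period", seed = 1L) {
  set.seed(seed)
  mu <- grand_mean * (1 + across_cv * stats::rnorm(n_animals))
  mu <- pmax(mu, 0.05 * grand_mean)
  do.call(rbind, lapply(seq_len(n_animals), function(a) {
    v <- mu[a] * (1 + within_cv * stats::rnorm(n_windows))
    data.frame(preparation = sprintf("animal-%03d", a), metric = metric,
               mean = v)
  }))
}
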