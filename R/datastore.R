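# Immutable container binding spike times, labels and metadata per 20 s window.

#' Canonical ordering of pyloric dynamic states
#'
#' The thirteen state labels used throughout the package, ordered from the
#' canonical triphasic rhythm ("regular") through progressively degraded
#' dynamics to "silent", with "unlabeled" last. Transition matrices and state
#' probability tables use this ordering by default.
#'
#' @return Character vector of state names.
#' @export
pyloric_states <- function() {
  c("regular", "LP-weak-skipped", "irregular-bursting", "irregular",
    "LP-silent", "LP-silent-PD-bursting", "PD-silent", "PD-silent-LP-bursting",
    "PD-weak-skipped", "sparse-irregular", "aberrant-spikes", "silent",
    "unlabeled")
}

# numeric comparisons on spike times use this tolerance (seconds)
.time_tol <- 1e-9

#' Construct a spike train
#'
#' @param neuron_id Identifier of the neuron (e.g. "PD", "LP").
#' @param times Numeric vector of spike times in seconds, strictly increasing,
#'   all non-negative.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, times) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) {
    stop("spike_train: non-finite spike times for neuron '", neuron_id, "'")
  }
  if (any(times < 0)) {
    stop("spike_train: negative spike times for neuron '", neuron_id, "'")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike_train: spike times not strictly increasing for neuron '",
         neuron_id, "'")
  }
  structure(list(neuron_id = neuron_id, times = times), class = "spike_train")
}

#' Construct a data store of binned windows
#'
#' Low-level constructor; most users should call [bin_spikes()].
#'
#' @param windows Data frame with one row per window: columns `preparation`,
#'   `t_start`, `condition` plus any further metadata columns.
#' @param spikes List (length `nrow(windows)`) of named lists of numeric spike
#'   time vectors, one entry per neuron in `neuron_set`.
#' @param neuron_set Ordered character vector of neuron identifiers.
#' @param bin_width Window duration in seconds.
#' @param labels Optional character vector of state labels per window.
#' @return An object of class `data_store`.
#' @export
data_store <- function(windows, spikes, neuron_set, bin_width, labels = NULL) {
  stopifnot(is.data.frame(windows), length(spikes) == nrow(windows),
            bin_width > 0)
  if (!all(c("preparation", "t_start", "condition") %in% names(windows))) {
    stop("data_store: windows must have preparation, t_start, condition columns")
  }
  o <- order(windows$preparation, windows$t_start)
  windows <- windows[o, , drop = FALSE]
  rownames(windows) <- NULL
  spikes <- spikes[o]
  if (!is.null(labels)) {
    labels <- as.character(labels)[o]
    stopifnot(length(labels) == nrow(windows))
  }
  for (i in seq_along(spikes)) {
    w <- spikes[[i]]
    stopifnot(all(neuron_set %in% names(w)))
    for (nrn in neuron_set) {
      t <- w[[nrn]]
      lo <- windows$t_start[i] - .time_tol
      hi <- windows$t_start[i] + bin_width - .time_tol
      if (length(t) && (any(t < lo) || any(t >= hi + 2 * .time_tol))) {
        stop("data_store: spike outside window ", i, " for neuron ", nrn)
      }
    }
  }
  structure(list(windows = windows, spikes = spikes, neuron_set = neuron_set,
                 bin_width = bin_width, labels = labels),
            class = "data_store")
}

#' @export
print.data_store <- function(x, ...) {
  cat("<data_store>", n_windows(x), "windows of", x$bin_width, "s,",
      length(unique(x$windows$preparation)), "preparation(s), neurons:",
      paste(x$neuron_set, collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", paste(utils::head(sort(unique(x$labels)), 6), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of windows in a data store
#' @param store A `data_store`.
#' @return Integer count of windows.
#' @export
n_windows <- function(store) nrow(store$windows)

#' Spike times of one neuron in one window
#' @param store A `data_store`.
#' @param i Window index.
#' @param neuron Neuron identifier.
#' @return Numeric vector of spike times (absolute seconds).
#' @export
window_spikes <- function(store, i, neuron) store$spikes[[i]][[neuron]]

#' Bin raw spike tables into fixed nonoverlapping windows
#'
#' Splits each preparation's recording into half-open bins
#' `[k*w, (k+1)*w)`; a spike exactly on a boundary belongs to the later bin.
#' Trailing data shorter than one bin is discarded. Windows with zero spikes
#' are retained so that silent stretches remain part of the time series.
#'
#' @param raw Data frame with columns `preparation`, `neuron`, `time_s`; spike
#'   times must be sorted (strictly increasing) within each
#'   preparation/neuron and non-negative.
#' @param bin_width Bin width in seconds (default 20).
#' @param metadata Optional data frame with columns `preparation`, `t_start`,
#'   `t_end`, `condition` and any further metadata columns; each window
#'   inherits the metadata row covering its start time (a window spanning a
#'   condition switch is kept under the condition at its start and flagged in
#'   column `condition_switch`).
#' @param neuron_set Ordered character vector of expected neuron ids; defaults
#'   to sorted unique neurons present. Unknown neurons in `raw` are an error.
#' @param t_max Total recording duration per preparation in seconds: a single
#'   number, or a named vector by preparation. Defaults to each preparation's
#'   last spike time.
#' @param preparations Preparations to bin (default those present in `raw`);
#'   supplying ids explicitly allows windows for silent preparations with no
#'   spikes at all (requires `t_max`).
#' @return A [data_store()].
#' @export
bin_spikes <- function(raw, bin_width = 20, metadata = NULL, neuron_set = NULL,
                       t_max = NULL, preparations = NULL) {
  stopifnot(is.data.frame(raw), bin_width > 0)
  need <- c("preparation", "neuron", "time_s")
  if (!all(need %in% names(raw))) {
    stop("bin_spikes: raw table must have columns ",
         paste(need, collapse = ", "))
  }
  raw$preparation <- as.character(raw$preparation)
  raw$neuron <- as.character(raw$neuron)
  if (is.null(neuron_set)) neuron_set <- sort(unique(raw$neuron))
  if (!length(neuron_set)) {
    stop("bin_spikes: empty spike table and no declared neuron set")
  }
  bad <- setdiff(unique(raw$neuron), neuron_set)
  if (length(bad)) {
    stop("bin_spikes: unknown neuron id(s) not in declared set: ",
         paste(bad, collapse = ", "))
  }
  preps <- if (!is.null(preparations)) as.character(preparations)
    else if (!is.null(metadata)) {
      union(unique(raw$preparation), unique(as.character(metadata$preparation)))
    } else unique(raw$preparation)
  win_rows <- list(); spk <- list(); k <- 0L
  for (p in preps) {
    sub <- raw[raw$preparation == p, , drop = FALSE]
    per_neuron <- lapply(neuron_set, function(nrn) {
      t <- sub$time_s[sub$neuron == nrn]
      if (any(!is.finite(t))) {
        stop("bin_spikes: non-finite spike times in preparation '", p,
             "', neuron '", nrn, "'")
      }
      if (any(t < 0)) {
        stop("bin_spikes: negative spike times in preparation '", p,
             "', neuron '", nrn, "'")
      }
      if (is.unsorted(t, strictly = TRUE)) {
        stop("bin_spikes: unsorted spike times in preparation '", p,
             "', neuron '", nrn, "'")
      }
      t
    })
    names(per_neuron) <- neuron_set
    tm <- if (is.null(t_max)) {
      # recorded duration: the metadata's interval end when declared,
      # otherwise the last spike time
      m <- if (!is.null(metadata) &&
               any(as.character(metadata$preparation) == p)) {
        max(metadata$t_end[as.character(metadata$preparation) == p])
      } else suppressWarnings(max(unlist(per_neuron), -Inf))
      if (!is.finite(m)) 0 else m
    } else if (length(t_max) > 1L || !is.null(names(t_max))) {
      if (!p %in% names(t_max)) stop("bin_spikes: no t_max for preparation ", p)
      t_max[[p]]
    } else t_max
    nb <- floor(tm / bin_width + .time_tol)
    if (nb < 1L) next
    md <- if (!is.null(metadata)) {
      metadata[as.character(metadata$preparation) == p, , drop = FALSE]
    } else NULL
    for (b in seq_len(nb) - 1L) {
      t0 <- b * bin_width
      t1 <- t0 + bin_width
      k <- k + 1L
      row <- list(preparation = p, t_start = t0, condition = "baseline")
      if (!is.null(md) && nrow(md)) {
        hit <- which(md$t_start <= t0 + .time_tol & md$t_end > t0 + .time_tol)
        if (length(hit)) {
          h <- hit[1L]
          extra <- md[h, setdiff(names(md), c("preparation", "t_start", "t_end")),
                      drop = FALSE]
          row[names(extra)] <- as.list(extra)
          # flag bins whose covering metadata interval ends before the bin does
          row$condition_switch <- md$t_end[h] < t1 - .time_tol
        }
      }
      win_rows[[k]] <- row
      spk[[k]] <- lapply(per_neuron, function(t) t[t >= t0 - .time_tol &
                                                   t < t1 - .time_tol])
    }
  }
  if (k == 0L) {
    return(data_store(
      windows = data.frame(preparation = character(), t_start = numeric(),
                           condition = character()),
      spikes = list(), neuron_set = neuron_set, bin_width = bin_width))
  }
  all_names <- unique(unlist(lapply(win_rows, names)))
  windows <- do.call(rbind, lapply(win_rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  data_store(windows = windows, spikes = spk, neuron_set = neuron_set,
             bin_width = bin_width)
}

#' Read a delimited spike table
#'
#' @param path Path to a delimited text file with header columns
#'   `preparation`, `neuron`, `time_s`.
#' @param delim Field delimiter ("," or "\\t").
#' @param neuron_set Optional declared neuron set; unknown ids are an error.
#' @return Data frame suitable for [bin_spikes()], sorted by preparation,
#'   neuron and time.
#' @export
read_spike_table <- function(path, delim = ",", neuron_set = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("preparation", "neuron", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_spike_table: ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(t)) {
    ln <- which(is.na(t))[1L]
    stop("read_spike_table: non-numeric time_s at data line ", ln, " of ", path)
  }
  df$time_s <- t
  if (!is.null(neuron_set)) {
    bad <- setdiff(unique(df$neuron), neuron_set)
    if (length(bad)) {
      stop("read_spike_table: unknown neuron id(s): ", paste(bad, collapse = ", "))
    }
  }
  df <- df[order(df$preparation, df$neuron, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a spike table to delimited text
#'
#' Times are written with full double precision so that a
#' write/read round trip preserves them to better than 1e-9 s.
#'
#' @param raw Data frame with `preparation`, `neuron`, `time_s`, or a
#'   `data_store` (windows are flattened back to one row per spike).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(raw, path, delim = ",") {
  if (inherits(raw, "data_store")) raw <- spike_table(raw)
  out <- data.frame(preparation = raw$preparation, neuron = raw$neuron,
                    time_s = sprintf("%.12g", raw$time_s))
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a data store back to a spike table
#' @param store A `data_store`.
#' @return Data frame with columns `preparation`, `neuron`, `time_s`.
#' @export
spike_table <- function(store) {
  rows <- list()
  for (i in seq_len(n_windows(store))) {
    for (nrn in store$neuron_set) {
      t <- window_spikes(store, i, nrn)
      if (length(t)) {
        rows[[length(rows) + 1L]] <- data.frame(
          preparation = store$windows$preparation[i], neuron = nrn, time_s = t)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(preparation = character(), neuron = character(),
                      time_s = numeric()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$preparation, df$neuron, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find contiguous segments of a data store
#'
#' A breakpoint is inserted between consecutive windows of one preparation
#' whose start times differ by more than one bin width or whose `condition`
#' differs. Windows of different preparations never share a segment.
#'
#' @param store A `data_store`.
#' @return List of integer vectors of window indices; disjoint, ordered, and
#'   jointly covering all windows.
#' @export
find_breakpoints <- function(store) {
  n <- n_windows(store)
  if (n == 0L) return(list())
  w <- store$windows
  segs <- list(); cur <- 1L
  for (i in seq_len(n - 1L)[n > 1L]) {
    gap <- w$preparation[i + 1L] != w$preparation[i] ||
      (w$t_start[i + 1L] - w$t_start[i]) > store$bin_width + .time_tol ||
      !identical(w$condition[i + 1L], w$condition[i])
    if (gap) {
      segs[[length(segs) + 1L]] <- cur:i
      cur <- i + 1L
    }
  }
  segs[[length(segs) + 1L]] <- cur:n
  segs
}

#' Per-window segment ids
#' @param store A `data_store`.
#' @return Integer vector assigning each window to its contiguous segment.
#' @export
segment_ids <- function(store) {
  segs <- find_breakpoints(store)
  ids <- integer(n_windows(store))
  for (s in seq_along(segs)) ids[segs[[s]]] <- s
  ids
}

#' Export windows (and labels, if any) as a data frame
#' @param store A `data_store`.
#' @param labels Optional label vector overriding `store$labels`.
#' @return Data frame, one row per window, with metadata columns and `label`.
#' @export
window_table <- function(store, labels = NULL) {
  out <- store$windows
  if (is.null(labels)) labels <- store$labels
  out$label <- if (is.null(labels)) "unlabeled" else as.character(labels)
  out$n_spikes <- vapply(store$spikes, function(w) sum(lengths(w)), integer(1))
  out
}

#' Attach state labels to a data store
#'
#' Returns a new store; the input is never modified.
#' @param store A `data_store`.
#' @param labels Character vector of labels, one per window.
#' @return A new `data_store` with labels set.
#' @export
set_labels <- function(store, labels) {
  stopifnot(length(labels) == n_windows(store))
  store$labels <- as.character(labels)
  store
}
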