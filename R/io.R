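# Plain-text interchange (CSV/JSON) between pipeline stages; numbers are
# written with enough digits that a write/read round trip is lossless at
# the 1e-9 s comparison tolerance, and formatting is deterministic so
# identical runs produce byte-identical files.

.fmt <- function(x) sprintf("%.15g", x)

#' Write a feature matrix to CSV (with a JSON sidecar)
#'
#' The CSV holds the window metadata columns followed by the raw feature
#' columns; a `<path>.meta.json` sidecar records the neuron set, percentile
#' grid, fillers and (if computed) the z-score statistics.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- as.data.frame(apply(fm$values, 2, .fmt))
  info <- fm$info[, c("preparation", "t_start", "condition")]
  info$t_start <- .fmt(info$t_start)
  utils::write.csv(cbind(info, vals), path, row.names = FALSE, quote = FALSE)
  meta <- list(neuron_set = fm$neuron_set, probs = fm$probs,
               fillers = fm$fillers)
  if (!is.null(fm$stats)) {
    meta$zscore_stats <- list(mean = as.list(fm$stats$mean),
                              sd = as.list(fm$stats$sd))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV path (the `.meta.json` sidecar must sit beside it).
#' @return A `feature_matrix` (raw; z-scored if stats were stored).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  info_cols <- c("preparation", "t_start", "condition")
  vals <- as.matrix(df[, setdiff(names(df), info_cols)])
  fm <- structure(list(values = vals, info = df[, info_cols],
                       probs = meta$probs,
                       fillers = as.list(meta$fillers),
                       neuron_set = meta$neuron_set, z = NULL, stats = NULL),
                  class = "feature_matrix")
  if (!is.null(meta$zscore_stats)) {
    fm$stats <- list(mean = unlist(meta$zscore_stats$mean),
                     sd = unlist(meta$zscore_stats$sd))
    fm$z <- apply_zscore(fm$values, fm$stats)
  }
  fm
}

#' Write embedding coordinates to CSV
#' @param emb An `embedding_result` (or N x 2 matrix with `info` attached
#'   separately via `info`).
#' @param path Output CSV path.
#' @param info Optional window metadata data frame (used when `emb` is a
#'   bare matrix).
#' @return `path`, invisibly.
#' @export
write_coords <- function(emb, path, info = NULL) {
  if (inherits(emb, "embedding_result")) {
    coords <- emb$coords
    info <- emb$info
    meta <- list(backend = emb$backend, perplexity = emb$perplexity,
                 init_mode = emb$init_mode, seed = emb$seed,
                 settings = emb$settings,
                 embedding_hash = embedding_hash(coords))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  } else coords <- emb
  out <- data.frame(preparation = info$preparation, t_start = .fmt(info$t_start),
                    condition = info$condition,
                    x = .fmt(coords[, 1]), y = .fmt(coords[, 2]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read embedding coordinates written by [write_coords()]
#' @param path CSV path.
#' @return Data frame with `preparation`, `t_start`, `condition`, `x`, `y`.
#' @export
read_coords <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Export a transition matrix as CSVs and a JSON bundle
#'
#' Writes `<stem>_counts.csv`, `<stem>_probs.csv`, `<stem>_significance.csv`
#' (when annotated) and `<stem>.json`.
#'
#' @param tm A `transition_matrix`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_transition_matrix <- function(tm, stem) {
  utils::write.csv(as.data.frame(tm$counts), paste0(stem, "_counts.csv"),
                   quote = FALSE)
  utils::write.csv(as.data.frame(tm$probs), paste0(stem, "_probs.csv"),
                   quote = FALSE)
  bundle <- list(states = tm$states, counts = tm$counts, probs = tm$probs,
                 n_transitions = tm$n_transitions)
  if (!is.null(tm$significance)) {
    utils::write.csv(as.data.frame(tm$significance),
                     paste0(stem, "_significance.csv"), quote = FALSE)
    bundle$significance <- tm$significance
    bundle$p_high <- tm$p_high
    bundle$p_low <- tm$p_low
    bundle$null <- tm$null
  }
  jsonlite::write_json(bundle, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(stem)
}
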