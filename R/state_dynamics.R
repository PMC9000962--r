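# Categorical time-series analytics: state probabilities, transition
# matrices with a resampling null model, conditional distributions, and
# variability statistics across conditions and animals.

#' Construct a per-preparation state sequence
#'
#' Contiguous segments are delimited by timestamp gaps larger than one bin
#' width, changes of `condition`, or changes of preparation; transitions are
#' never counted across segment boundaries.
#'
#' @param preparation Preparation id per window.
#' @param t_start Window start times (seconds).
#' @param label State label per window.
#' @param bin_width Bin width in seconds (default 20).
#' @param condition Optional condition per window (default constant).
#' @return Object of class `state_sequence`: data frame plus a `segments`
#'   attribute (list of row-index vectors).
#' @export
state_sequence <- function(preparation, t_start, label, bin_width = 20,
                           condition = NULL) {
  n <- length(t_start)
  if (is.null(condition)) condition <- rep("baseline", n)
  df <- data.frame(preparation = as.character(preparation),
                   t_start = as.numeric(t_start),
                   label = as.character(label),
                   condition = as.character(condition))
  o <- order(df$preparation, df$t_start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  segs <- list(); cur <- 1L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (df$t_start[i + 1L] <= df$t_start[i] &&
          df$preparation[i + 1L] == df$preparation[i]) {
        stop("state_sequence: timestamps not strictly increasing within ",
             "preparation ", df$preparation[i])
      }
      gap <- df$preparation[i + 1L] != df$preparation[i] ||
        (df$t_start[i + 1L] - df$t_start[i]) > bin_width + 1e-9 ||
        df$condition[i + 1L] != df$condition[i]
      if (gap) { segs[[length(segs) + 1L]] <- cur:i; cur <- i + 1L }
    }
  }
  if (n >= 1L) segs[[length(segs) + 1L]] <- cur:n
  structure(df, segments = segs, bin_width = bin_width,
            class = c("state_sequence", "data.frame"))
}

#' State sequence from a labeled data store
#' @param store A [data_store()].
#' @param labels Labels per window (defaults to `store$labels`).
#' @return A [state_sequence()].
#' @export
state_sequence_from_store <- function(store, labels = NULL) {
  if (is.null(labels)) labels <- store$labels
  stopifnot(!is.null(labels))
  w <- store$windows
  state_sequence(w$preparation, w$t_start, labels, store$bin_width,
                 w$condition)
}

# within-segment consecutive (from, to) label pairs; pairs touching
# "unlabeled" windows are dropped (unlabeled breaks a run)
.transition_pairs <- function(seq) {
  segs <- attr(seq, "segments")
  from <- character(0); to <- character(0)
  for (s in segs) {
    if (length(s) < 2L) next
    a <- seq$label[s[-length(s)]]
    b <- seq$label[s[-1L]]
    keep <- a != "unlabeled" & b != "unlabeled"
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  data.frame(from = from, to = to)
}

#' Between-state transition matrix
#'
#' Counts within-segment consecutive label pairs, zeroes the diagonal
#' (self-pairs are dwell, not transitions) and row-normalizes, yielding a
#' right-stochastic matrix of conditional transition probabilities
#' `T[i, j] = P(next state j | current state i, a transition occurred)`.
#' Rows with no outgoing transitions are all-zero.
#'
#' @param seq A [state_sequence()].
#' @param states Ordered state list; defaults to [pyloric_states()]
#'   restricted to observed labels (plus any unexpected labels, appended).
#' @return Object of class `transition_matrix`: list with `states`, `counts`
#'   (raw K x K pair counts including the diagonal), `probs` (zero-diagonal,
#'   row-stochastic), `n_transitions`.
#' @export
transition_matrix <- function(seq, states = NULL) {
  pairs <- .transition_pairs(seq)
  if (is.null(states)) {
    seen <- setdiff(unique(seq$label), "unlabeled")
    states <- c(intersect(pyloric_states(), seen), setdiff(seen, pyloric_states()))
  }
  k <- length(states)
  counts <- matrix(0L, k, k, dimnames = list(states, states))
  if (nrow(pairs)) {
    tab <- table(factor(pairs$from, states), factor(pairs$to, states))
    counts <- counts + unclass(tab)
    storage.mode(counts) <- "integer"
  }
  off <- counts
  diag(off) <- 0L
  rs <- rowSums(off)
  probs <- off / ifelse(rs > 0, rs, 1)
  structure(list(states = states, counts = counts, probs = probs,
                 n_transitions = sum(off)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>", length(x$states), "states,", x$n_transitions,
      "transitions\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Annotate transition-matrix cells against a resampling null model
#'
#' Null model: transitions occur at random, with destination probabilities
#' proportional to the marginal distribution of post-transition states
#' (pooled over all transitions, self-pairs excluded). For each initial
#' state i with `n_i` outgoing transitions, `n_i` destinations are drawn
#' i.i.d. from that marginal restricted to states other than i
#' (renormalized), `n_draws` times. Per cell, `p_high` is the fraction of
#' null counts at or above the observed count and `p_low` the fraction at
#' or below. Cells are annotated "more" (`p_high < alpha`), "less"
#' (`p_low < alpha`, observed > 0), "never-but-expected" (observed = 0,
#' `p_low < alpha`), otherwise "n.s.".
#'
#' @param tm A [transition_matrix()].
#' @param n_draws Null-model resamples (default 1000).
#' @param alpha Per-cell significance level (default 0.05).
#' @param seed Integer seed.
#' @return `tm` with added elements `significance` (character matrix),
#'   `p_high`, `p_low` (numeric matrices; NA on the diagonal and for rows
#'   with no transitions).
#' @export
transition_significance <- function(tm, n_draws = 1000L, alpha = 0.05,
                                    seed = 1L) {
  stopifnot(inherits(tm, "transition_matrix"))
  k <- length(tm$states)
  off <- tm$counts
  diag(off) <- 0L
  if (sum(off) < 1L) stop("transition_significance: no transitions")
  marg <- colSums(off) / sum(off)
  p_high <- matrix(NA_real_, k, k, dimnames = dimnames(tm$counts))
  p_low <- matrix(NA_real_, k, k, dimnames = dimnames(tm$counts))
  sig <- matrix(NA_character_, k, k, dimnames = dimnames(tm$counts))
  set.seed(seed)
  for (i in seq_len(k)) {
    n_i <- sum(off[i, ])
    if (n_i == 0L) next
    p <- marg
    p[i] <- 0
    if (sum(p) <= 0) next
    p <- p / sum(p)
    null_counts <- stats::rmultinom(n_draws, n_i, p)  # k x n_draws
    for (j in seq_len(k)[-i]) {
      obs <- off[i, j]
      p_high[i, j] <- mean(null_counts[j, ] >= obs)
      p_low[i, j] <- mean(null_counts[j, ] <= obs)
      sig[i, j] <- if (p_high[i, j] < alpha) "more"
        else if (obs == 0L && p_low[i, j] < alpha) "never-but-expected"
        else if (obs > 0L && p_low[i, j] < alpha) "less"
        else "n.s."
    }
  }
  tm$significance <- sig
  tm$p_high <- p_high
  tm$p_low <- p_low
  tm$null <- list(n_draws = n_draws, alpha = alpha, seed = seed,
                  marginal = marg)
  tm
}

#' Distribution of states adjacent to transitions into/out of a target state
#'
#' The empirical distribution of the state immediately before transitions
#' into `target` (`direction = "preceding"`) or immediately after
#' transitions out of it (`"following"`), within segments.
#'
#' @param seq A [state_sequence()].
#' @param target Target state label.
#' @param direction "preceding" or "following".
#' @return Named numeric vector summing to 1, or an empty vector when no
#'   qualifying transitions exist.
#' @export
conditional_state_distribution <- function(seq, target,
                                           direction = c("preceding",
                                                         "following")) {
  direction <- match.arg(direction)
  pairs <- .transition_pairs(seq)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  adj <- if (direction == "preceding") {
    pairs$from[pairs$to == target]
  } else {
    pairs$to[pairs$from == target]
  }
  if (!length(adj)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(adj)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Per-preparation and population state probabilities
#'
#' For each preparation, the fraction of its windows in each state; the
#' population value is the unweighted mean over preparations (each
#' preparation contributes equally, the treemap convention), not pooled
#' counts.
#'
#' @param labels State labels per window.
#' @param preparation Preparation id per window.
#' @param states State ordering; defaults to [pyloric_states()] restricted
#'   to observed labels.
#' @return List with `per_preparation` (preparations x states matrix, rows
#'   summing to 1) and `population` (named vector).
#' @export
state_probabilities <- function(labels, preparation, states = NULL) {
  labels <- as.character(labels)
  preparation <- as.character(preparation)
  stopifnot(length(labels) == length(preparation), length(labels) >= 1L)
  if (is.null(states)) {
    seen <- unique(labels)
    states <- c(intersect(pyloric_states(), seen),
                setdiff(seen, pyloric_states()))
  }
  tab <- table(factor(preparation), factor(labels, states))
  per <- unclass(tab) / rowSums(tab)
  list(per_preparation = per, population = colMeans(per))
}

#' Per-state fold change in probability between two conditions
#'
#' Ratios are computed per preparation and then summarized by their mean
#' over preparations with a defined (finite) ratio; states observed in
#' neither or only the "after" condition of a preparation yield undefined
#' per-preparation ratios, which are flagged.
#'
#' @param p_before,p_after `per_preparation` matrices from
#'   [state_probabilities()] on the same preparations and states.
#' @return Data frame with columns `state`, `fold_change` (mean of defined
#'   per-preparation ratios; NA when none), `n_defined`, `flagged`.
#' @export
fold_change <- function(p_before, p_after) {
  stopifnot(identical(dimnames(p_before), dimnames(p_after)))
  ratios <- p_after / p_before  # 0/0 -> NaN, x/0 -> Inf
  out <- lapply(colnames(ratios), function(st) {
    r <- ratios[, st]
    ok <- is.finite(r)
    data.frame(state = st,
               fold_change = if (any(ok)) mean(r[ok]) else NA_real_,
               n_defined = sum(ok), flagged = !all(ok))
  })
  do.call(rbind, out)
}

#' Paired permutation test of state probabilities between two conditions
#'
#' Statistic per state: mean over preparations of the change in that
#' state's probability from condition `a` to condition `b`. The null is
#' generated by randomly swapping the two condition labels within each
#' preparation (equivalently, flipping the sign of each preparation's
#' difference). Enumeration is exhaustive over all `2^n` sign patterns when
#' that is no more work than `n_perm` draws. Two-sided p-values, raw and
#' Bonferroni-corrected over states.
#'
#' @param labels State labels per window.
#' @param preparation Preparation id per window.
#' @param condition Condition per window.
#' @param condition_a,condition_b The two conditions compared.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Integer seed.
#' @param states State ordering (default observed, canonical order).
#' @return Data frame with columns `state`, `delta` (mean change b - a),
#'   `p_value`, `p_bonferroni`, plus attributes `n_preparations` and
#'   `exhaustive`.
#' @export
paired_permutation_state_test <- function(labels, preparation, condition,
                                          condition_a, condition_b,
                                          n_perm = 10000L, seed = 1L,
                                          states = NULL) {
  labels <- as.character(labels)
  preparation <- as.character(preparation)
  condition <- as.character(condition)
  in_a <- condition == condition_a
  in_b <- condition == condition_b
  preps <- intersect(unique(preparation[in_a]), unique(preparation[in_b]))
  dropped <- setdiff(unique(preparation[in_a | in_b]), preps)
  if (length(dropped)) {
    warning("paired_permutation_state_test: dropping unpaired preparation(s): ",
            paste(dropped, collapse = ", "))
  }
  if (length(preps) < 3L) {
    stop("paired_permutation_state_test: need >= 3 preparations in both ",
         "conditions")
  }
  if (is.null(states)) {
    seen <- unique(labels[(in_a | in_b) & preparation %in% preps])
    states <- c(intersect(pyloric_states(), seen),
                setdiff(seen, pyloric_states()))
  }
  pa <- state_probabilities(labels[in_a & preparation %in% preps],
                            preparation[in_a & preparation %in% preps],
                            states)$per_preparation
  pb <- state_probabilities(labels[in_b & preparation %in% preps],
                            preparation[in_b & preparation %in% preps],
                            states)$per_preparation
  pa <- pa[preps, , drop = FALSE]
  pb <- pb[preps, , drop = FALSE]
  delta <- pb - pa  # preparations x states
  obs <- colMeans(delta)
  np <- length(preps)
  exhaustive <- (2^np) <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), np)))
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * np, replace = TRUE), ncol = np)
  }
  null <- abs(signs %*% delta) / np  # draws x states
  tol <- 1e-12
  p <- vapply(seq_along(obs), function(s) {
    cnt <- sum(null[, s] >= abs(obs[s]) - tol)
    if (exhaustive) cnt / nrow(signs) else (1 + cnt) / (nrow(signs) + 1)
  }, numeric(1))
  out <- data.frame(state = states, delta = unname(obs), p_value = p,
                    p_bonferroni = pmin(1, p * length(states)))
  attr(out, "n_preparations") <- np
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Burst-period variability before transitions away from a state
#'
#' For each window in `from_state`, the time to the next transition away
#' from that state (within its segment) is computed; windows falling in
#' `[-horizon, 0)` seconds before a transition are binned at the bin width,
#' the per-window CV (SD/mean of within-window burst periods) is averaged
#' per bin, and a Spearman rank correlation between bin time and mean CV
#' tests whether variability rises toward the transition.
#'
#' @param seq A [state_sequence()].
#' @param metrics Long metrics table from [metrics_on_state()] (columns
#'   `preparation`, `t_start`, `metric`, `mean`, `sd`).
#' @param metric Metric whose CV is tracked (default "PD_burst_period").
#' @param from_state State transitions leave from (default "regular").
#' @param horizon Look-back horizon in seconds (default 200).
#' @param bin Bin width for the time axis in seconds (default 20).
#' @return List with `table` (data frame: `bin_time` (left edge, negative
#'   seconds), `mean_cv`, `n`), `rho`, `p_value`, `n_transitions`. With
#'   fewer than 3 non-empty bins the test is skipped (`rho`, `p_value` NA,
#'   with a warning).
#' @export
cv_before_transition <- function(seq, metrics, metric = "PD_burst_period",
                                 from_state = "regular", horizon = 200,
                                 bin = 20) {
  m <- metrics[metrics$metric == metric & is.finite(metrics$mean) &
                 metrics$mean > 0, , drop = FALSE]
  cv_map <- stats::setNames(m$sd / m$mean,
                            paste(m$preparation, format(m$t_start, digits = 12)))
  segs <- attr(seq, "segments")
  time_to <- rep(NA_real_, nrow(seq))
  n_trans <- 0L
  for (s in segs) {
    lab <- seq$label[s]
    ts <- seq$t_start[s]
    trans_at <- which(lab[-length(lab)] == from_state &
                        lab[-1L] != from_state) + 1L  # first non-from window
    n_trans <- n_trans + length(trans_at)
    if (!length(trans_at)) next
    for (i in seq_along(s)) {
      if (lab[i] != from_state) next
      nxt <- trans_at[trans_at > i]
      if (!length(nxt)) next
      # only if the run from i is unbroken up to the transition
      if (any(lab[i:(nxt[1L] - 1L)] != from_state)) next
      time_to[s[i]] <- ts[i] - ts[nxt[1L]]
    }
  }
  sel <- which(is.finite(time_to) & time_to >= -horizon & time_to < 0)
  key <- paste(seq$preparation[sel], format(seq$t_start[sel], digits = 12))
  cv <- unname(cv_map[key])
  keep <- is.finite(cv)
  sel <- sel[keep]; cv <- cv[keep]
  bin_time <- floor(time_to[sel] / bin) * bin
  if (!length(sel)) {
    warning("cv_before_transition: no windows with defined CV before transitions")
    return(list(table = data.frame(bin_time = numeric(0), mean_cv = numeric(0),
                                   n = integer(0)),
                rho = NA_real_, p_value = NA_real_, n_transitions = n_trans))
  }
  tab <- data.frame(bin_time = sort(unique(bin_time)))
  tab$mean_cv <- vapply(tab$bin_time, function(b) mean(cv[bin_time == b]),
                        numeric(1))
  tab$n <- vapply(tab$bin_time, function(b) sum(bin_time == b), integer(1))
  if (nrow(tab) < 3L) {
    warning("cv_before_transition: fewer than 3 non-empty bins; test skipped")
    return(list(table = tab, rho = NA_real_, p_value = NA_real_,
                n_transitions = n_trans))
  }
  ct <- suppressWarnings(stats::cor.test(tab$bin_time, tab$mean_cv,
                                         method = "spearman"))
  list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value,
       n_transitions = n_trans)
}

# grouped mean and cv of x by integer group index g (1..k); groups with < 2
# values get NA cv
.group_mean_cv <- function(x, g, k) {
  n <- tabulate(g, k)
  s <- rowsum(cbind(x, x * x), g)
  sums <- numeric(k); sqs <- numeric(k)
  idx <- as.integer(rownames(s))
  sums[idx] <- s[, 1]; sqs[idx] <- s[, 2]
  mu <- sums / n
  va <- (sqs - n * mu^2) / (n - 1)
  va[n < 2L] <- NA_real_
  va[va < 0] <- 0
  list(mean = mu, cv = sqrt(va) / mu, n = n)
}

#' Within- versus across-animal variability of burst metrics
#'
#' For each metric, the within-animal variability proxy is the mean over
#' animals of the per-animal CV, and the across-animal proxy is the CV of
#' the per-animal means. Their difference (across - within) is tested by
#' shuffling the animal assignment of windows and recomputing, `n_shuffle`
#' times; p is the fraction of null differences at or above the observed
#' one (add-one corrected). Significance is assessed at
#' `alpha / n_metrics` (Bonferroni over metrics).
#'
#' @param metrics_table Data frame with columns `preparation`, `metric`,
#'   `mean` (one row per window and metric, as from [metrics_on_state()]),
#'   or columns `animal`/`value` equivalently named.
#' @param n_shuffle Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @param alpha Family significance level (default 0.05).
#' @param min_animals Minimum number of animals with >= 2 windows required
#'   per metric (default 5).
#' @return Data frame with one row per metric: `metric`, `within`, `across`,
#'   `difference`, `p_value`, `significant`, `n_animals`.
#' @export
within_across_variability <- function(metrics_table, n_shuffle = 1000L,
                                      seed = 1L, alpha = 0.05,
                                      min_animals = 5L) {
  dt <- metrics_table
  if (!"animal" %in% names(dt)) dt$animal <- dt$preparation
  if (!"value" %in% names(dt)) dt$value <- dt$mean
  metrics <- unique(dt$metric)
  set.seed(seed)
  rows <- list()
  for (mt in metrics) {
    sub <- dt[dt$metric == mt & is.finite(dt$value), , drop = FALSE]
    g <- as.integer(factor(sub$animal))
    k <- max(g)
    counts <- tabulate(g, k)
    usable <- counts >= 2L
    if (sum(usable) < min_animals) {
      stop("within_across_variability: metric '", mt, "' has fewer than ",
           min_animals, " animals with >= 2 windows")
    }
    keep <- usable[g]
    x <- sub$value[keep]
    g2 <- as.integer(factor(g[keep]))
    k2 <- max(g2)
    stat <- function(gr) {
      gm <- .group_mean_cv(x, gr, k2)
      across <- stats::sd(gm$mean) / mean(gm$mean)
      within <- mean(gm$cv)
      across - within
    }
    obs <- stat(g2)
    null <- vapply(seq_len(n_shuffle), function(r) stat(sample(g2)),
                   numeric(1))
    p <- (1 + sum(null >= obs - 1e-12)) / (n_shuffle + 1)
    gm <- .group_mean_cv(x, g2, k2)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mt, within = mean(gm$cv),
      across = stats::sd(gm$mean) / mean(gm$mean),
      difference = obs, p_value = p, n_animals = k2)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha / nrow(out)
  out
}
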