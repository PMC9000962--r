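seq_of <- function(labels, t0 = 0, prep = "p1", bin = 20, cond = NULL) {
  state_sequence(rep(prep, length(labels)),
                 t0 + (seq_along(labels) - 1) * bin, labels, bin,
                 condition = cond)
}

test_that("transition matrices match hand counts with a zeroed diagonal", {
  tm <- transition_matrix(seq_of(c("A", "A", "B", "A", "C")))
  expect_equal(tm$states, c("A", "B", "C"))
  expect_equal(unname(diag(tm$probs)), c(0, 0, 0))
  expect_near(tm$probs["A", "B"], 0.5)
  expect_near(tm$probs["A", "C"], 0.5)
  expect_near(tm$probs["B", "A"], 1)
  expect_equal(unname(tm$probs["C", ]), c(0, 0, 0))   # no outgoing
  expect_equal(tm$n_transitions, 3L)
  # constant sequence -> all-zero matrix
  tm2 <- transition_matrix(seq_of(rep("A", 6)))
  expect_true(all(tm2$probs == 0))
  # a pair spanning a timestamp gap is not counted
  s3 <- state_sequence(rep("p", 4), c(0, 20, 100, 120), c("A", "B", "B", "A"), 20)
  tm3 <- transition_matrix(s3)
  expect_equal(sum(tm3$counts), 2L)   # A->B and B->A within segments only
  expect_equal(unname(tm3$counts["B", "A"]), 1L)
})

test_that("transition counts agree with a brute-force pair scanner", {
  set.seed(23)
  for (r in 1:5) {
    labs <- sample(c("A", "B", "C", "unlabeled"), 200, TRUE)
    ts <- cumsum(sample(c(20, 20, 20, 60), 200, TRUE))
    s <- state_sequence(rep("p", 200), ts, labs, 20)
    tm <- transition_matrix(s, states = c("A", "B", "C"))
    # brute force: scan consecutive rows, skipping gaps and unlabeled
    cnt <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    for (i in 1:199) {
      if (ts[i + 1] - ts[i] > 20) next
      if (labs[i] == "unlabeled" || labs[i + 1] == "unlabeled") next
      cnt[labs[i], labs[i + 1]] <- cnt[labs[i], labs[i + 1]] + 1L
    }
    expect_equal(tm$counts, cnt)
    off <- cnt; diag(off) <- 0L
    rs <- rowSums(off)
    for (i in 1:3) {
      if (rs[i] > 0) expect_near(sum(tm$probs[i, ]), 1, tol = 1e-12)
      else expect_equal(unname(tm$probs[i, ]), c(0, 0, 0))
    }
    # reordering the state list permutes rows/columns consistently
    tm_r <- transition_matrix(s, states = c("C", "A", "B"))
    expect_equal(tm_r$counts[c("A", "B", "C"), c("A", "B", "C")], tm$counts)
  }
})

test_that("a two-state system is never flagged: destinations are forced", {
  labs <- rep(c("A", "B"), 30)
  tm <- transition_significance(transition_matrix(seq_of(labs)),
                                n_draws = 500, seed = 2)
  expect_true(all(tm$significance[!is.na(tm$significance)] == "n.s."))
})

test_that("forced transitions are flagged against the marginal null (binomial oracle)", {
  # 60 segments A->B and 60 segments B->C: marginal over destinations is
  # {B: 0.5, C: 0.5}; row A draws from {B, C} at 0.5 each
  segs <- c(replicate(60, c("A", "B"), simplify = FALSE),
            replicate(60, c("B", "C"), simplify = FALSE))
  prep <- rep(sprintf("s%03d", seq_along(segs)), each = 2)
  labs <- unlist(segs)
  ts <- rep(c(0, 20), length(segs))
  s <- state_sequence(prep, ts, labs, 20)
  tm <- transition_matrix(s, states = c("A", "B", "C"))
  expect_equal(unname(tm$counts["A", "B"]), 60L)
  tm <- transition_significance(tm, n_draws = 2000, alpha = 0.05, seed = 7)
  expect_equal(unname(tm$significance["A", "B"]), "more")
  expect_equal(unname(tm$significance["A", "C"]), "never-but-expected")
  # oracle: P(Binom(60, 0.5) >= 60) ~ 8.7e-19, so no null draw reaches 60
  expect_equal(unname(tm$p_high["A", "B"]), 0)
})

test_that("conditional state distributions around a target state", {
  s <- seq_of(c("A", "B", "silent", "A", "C", "silent"))
  d <- conditional_state_distribution(s, "silent", "preceding")
  expect_near(d[["B"]], 0.5)
  expect_near(d[["C"]], 0.5)
  expect_near(sum(d), 1)
  expect_equal(length(conditional_state_distribution(seq_of(c("A", "B")),
                                                     "silent", "preceding")),
               0L)
  d2 <- conditional_state_distribution(s, "silent", "following")
  expect_near(d2[["A"]], 1)   # only the first silent has a follower
})

test_that("state probabilities weight preparations equally", {
  labs <- c(rep("regular", 1), rep(c("regular", "irregular", "irregular",
                                     "irregular", "irregular"), 1))
  prep <- c("a", rep("b", 5))
  sp <- state_probabilities(labs, prep)
  expect_near(sp$per_preparation["a", "regular"], 1)
  expect_near(sp$per_preparation["b", "regular"], 0.2)
  expect_near(sp$population[["regular"]], 0.6)   # (1 + 0.2) / 2, not pooled 2/6
  expect_near(sum(sp$population), 1)
})

test_that("fold changes are per-preparation ratios with undefined cases flagged", {
  before <- state_probabilities(c("regular", "regular", "irregular", "regular"),
                                c("a", "a", "b", "b"),
                                states = c("regular", "irregular", "silent"))
  after <- state_probabilities(c("irregular", "regular", "irregular", "silent"),
                               c("a", "a", "b", "b"),
                               states = c("regular", "irregular", "silent"))
  fc <- fold_change(before$per_preparation, after$per_preparation)
  expect_equal(fc$state, c("regular", "irregular", "silent"))
  reg <- fc[fc$state == "regular", ]
  expect_near(reg$fold_change, mean(c(0.5 / 1, 0 / 0.5)))
  sil <- fc[fc$state == "silent", ]
  expect_true(sil$flagged)       # absent before in both preparations
  expect_equal(sil$n_defined, 0L)
})

test_that("the paired permutation test matches exhaustive sign-flip enumeration", {
  # 8 preparations all shifting regular 1.0 -> 0.0
  prep <- rep(sprintf("p%d", 1:8), each = 4)
  cond <- rep(rep(c("before", "after"), each = 2), 8)
  labs <- rep(c("regular", "regular", "irregular", "irregular"), 8)
  res <- paired_permutation_state_test(labs, prep, cond, "before", "after",
                                       seed = 1)
  expect_true(attr(res, "exhaustive"))
  expect_near(res$p_value[res$state == "regular"], 2 / 2^8)
  expect_near(res$delta[res$state == "regular"], -1)
  # identical label sets in both conditions -> p ~ 1
  labs2 <- rep(c("regular", "irregular"), 16)
  res2 <- paired_permutation_state_test(labs2, prep, cond, "before", "after",
                                        seed = 1)
  expect_gt(min(res2$p_value), 0.99)
  # unpaired preparations are dropped with a warning
  prep3 <- c(prep, "p9", "p9")
  cond3 <- c(cond, "before", "before")
  labs3 <- c(labs, "regular", "regular")
  expect_warning(paired_permutation_state_test(labs3, prep3, cond3,
                                               "before", "after", seed = 1),
                 "unpaired")
})

test_that("CV before transition: monotone case gives rho = 1 and gaps are respected", {
  labs <- c(rep("regular", 10), "irregular")
  s <- seq_of(labs)
  # per-window CV rises strictly toward the transition at t = 200 s
  metrics <- data.frame(preparation = "p1",
                        t_start = (0:9) * 20,
                        metric = "PD_burst_period",
                        mean = 1,
                        sd = seq(0.01, 0.1, by = 0.01))
  out <- cv_before_transition(s, metrics)
  expect_equal(nrow(out$table), 10L)
  expect_near(out$rho, 1)
  expect_lt(out$p_value, 0.05)
  expect_equal(out$n_transitions, 1L)
  # windows more than `horizon` before the transition are excluded
  out2 <- cv_before_transition(s, metrics, horizon = 100)
  expect_equal(nrow(out2$table), 5L)
})

test_that("within/across variability proxies and their degenerate case", {
  # identical constant values -> both proxies zero
  const <- data.frame(preparation = rep(sprintf("a%d", 1:6), each = 5),
                      metric = "PD_burst_period", mean = 1)
  res <- within_across_variability(const, n_shuffle = 100, seed = 2)
  expect_equal(res$within, 0)
  expect_equal(res$across, 0)
  expect_equal(res$difference, 0)
  # strong across-animal structure is detected
  sim <- simulate_metric_values(12, 20, across_cv = 0.3, within_cv = 0.05,
                                seed = 5)
  res2 <- within_across_variability(sim, n_shuffle = 500, seed = 3)
  expect_gt(res2$across, res2$within)
  expect_lt(res2$p_value, 0.01)
  expect_true(res2$significant)
  expect_error(within_across_variability(sim[sim$preparation %in%
                                               sprintf("animal-%03d", 1:3), ],
                                         n_shuffle = 10),
               "fewer than")
})

test_that("Markov label sequences respect their specification", {
  # absorbing silent state
  P <- rbind(c(0.5, 0.5), c(0, 1))
  sp <- markov_spec(c("regular", "silent"), P, length = 200)
  s <- generate_label_sequence(sp, seed = 3)
  first_silent <- match("silent", s$label)
  expect_true(all(s$label[first_silent:200] == "silent"))
  expect_equal(nrow(s), 200L)
  expect_equal(length(attr(s, "segments")), 1L)
  # empirical transition frequencies converge to the spec (LLN at n = 1e5)
  P2 <- rbind(c(0.7, 0.2, 0.1), c(0.3, 0.4, 0.3), c(0.05, 0.05, 0.9))
  sp2 <- markov_spec(c("A", "B", "C"), P2, length = 1e5)
  s2 <- generate_label_sequence(sp2, seed = 11)
  lab <- s2$label
  for (i in 1:3) {
    from <- c("A", "B", "C")[i]
    idx <- which(lab[-1e5] == from)
    emp <- table(factor(lab[idx + 1], c("A", "B", "C"))) / length(idx)
    expect_lt(max(abs(emp - P2[i, ])), 3 / sqrt(length(idx)))
  }
  # self-probability 0.99 gives mean run length near 100
  sp3 <- markov_spec(c("A", "B"), rbind(c(0.99, 0.01), c(0.01, 0.99)),
                     length = 5e4)
  s3 <- generate_label_sequence(sp3, seed = 7)
  runs <- rle(s3$label)$lengths
  expect_lt(abs(mean(runs) - 100) / 100, 0.25)
  expect_error(markov_spec(c("A", "B"), rbind(c(0.5, 0.4), c(0, 1))))
})
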