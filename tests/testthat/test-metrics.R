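test_that("type-2 AUROC matches hand-worked examples", {
  expect_equal(type2_auroc(c(90, 70, 50, 30), c(1, 1, 0, 0)), 1)
  expect_equal(type2_auroc(c(80, 40, 80, 40), c(1, 1, 0, 0)), 0.5)
  # correct {90, 60, 60} vs incorrect {60, 30}: 6 pairs, one tie -> 5/6
  expect_equal(type2_auroc(c(90, 60, 60, 60, 30), c(1, 1, 1, 0, 0)), 5 / 6)
})

test_that("the type-2 curve is a proper ROC and flags undefined input", {
  roc <- type2_roc(c(90, 60, 60, 30, 10), c(1, 1, 0, 0, 1))
  expect_false(roc$undefined)
  expect_equal(roc$hr2[1], 0)
  expect_equal(roc$far2[1], 0)
  expect_equal(roc$hr2[length(roc$hr2)], 1)
  expect_equal(roc$far2[length(roc$far2)], 1)
  expect_true(all(diff(roc$hr2) >= 0))
  expect_true(all(diff(roc$far2) >= 0))

  und <- type2_roc(c(10, 20, 30), c(1, 1, 1))
  expect_true(und$undefined)
  expect_true(is.na(und$auroc))
  expect_error(type2_roc(c(1, 2), c(1, 2)),
    class = "metasense_validation_error")
})

test_that("trapezoidal AUROC equals the tie-aware rank-pair oracle", {
  set.seed(421)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    correct <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    confidence <- sample(seq(0, 100, by = 10), n, replace = TRUE)
    expect_equal(type2_auroc(confidence, correct),
      auroc_pair_oracle(confidence, correct), tolerance = 1e-12)
  }
})

test_that("meta_j reproduces the entropy-identity oracle and hand value", {
  # counts: correct&high 4, correct&low 1, incorrect&high 1, incorrect&low 4
  confidence <- c(rep(80, 4), 20, 80, rep(20, 4))
  correct <- c(rep(1, 5), rep(0, 5))
  expect_equal(meta_j(confidence, correct, 50), 0.278072, tolerance = 1e-5)
  expect_equal(meta_j(confidence, correct, 50),
    mi_entropy_oracle(confidence, correct, 50), tolerance = 1e-12)

  # constant confidence -> degenerate margin -> 0 bits
  expect_equal(meta_j(rep(70, 6), c(1, 0, 1, 0, 1, 0), 50), 0)

  # perfectly separating threshold with balanced accuracy: 1 bit = H(A)
  expect_identical(meta_j(c(90, 90, 10, 10), c(1, 1, 0, 0), 50), 1)
})

test_that("meta_j_max equals an exhaustive threshold scan", {
  res <- meta_j_max(c(90, 60, 30), c(1, 1, 0))
  expect_equal(res$threshold, 45)
  expect_equal(res$meta_j, shannon_entropy(1 / 3), tolerance = 1e-12)
  expect_equal(res$meta_j2r, 1)

  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    correct <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    confidence <- sample(seq(0, 100, by = 5), n, replace = TRUE)
    got <- meta_j_max(confidence, correct)
    expect_equal(got$meta_j, meta_j_scan_oracle(confidence, correct),
      tolerance = 1e-12)
    # bounds: 0 <= meta_j <= H(A) <= 1
    expect_gte(got$meta_j, 0)
    expect_lte(got$meta_j, got$accuracy_entropy + 1e-12)
    if (!is.na(got$meta_j2r)) {
      expect_gte(got$meta_j2r, 0)
      expect_lte(got$meta_j2r, 1 + 1e-12)
    }
  }
})

test_that("meta_j_max tie-break picks the lowest threshold and handles
           zero-entropy margins", {
  # symmetric data: thresholds 45 and 75 give identical information
  res <- meta_j_max(c(90, 60, 30), c(1, 0, 1))
  cand_vals <- vapply(c(45, 75), function(th)
    meta_j(c(90, 60, 30), c(1, 0, 1), th), numeric(1))
  expect_equal(cand_vals[1], cand_vals[2])
  expect_equal(res$threshold, 45)

  all_correct <- meta_j_max(c(80, 90, 70), c(1, 1, 1))
  expect_equal(all_correct$meta_j, 0)
  expect_equal(all_correct$accuracy_entropy, 0)
  expect_true(is.na(all_correct$meta_j2r))
})

test_that("AUROC and meta_j_max are invariant under strictly increasing
           transforms of confidence", {
  set.seed(7)
  for (i in 1:20) {
    n <- 30
    correct <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    confidence <- sample(0:100, n, replace = TRUE)
    trans <- 100 * stats::plogis((confidence - 50) / 12)
    expect_equal(type2_auroc(trans, correct),
      type2_auroc(confidence, correct), tolerance = 1e-12)
    expect_equal(meta_j_max(trans, correct)$meta_j,
      meta_j_max(confidence, correct)$meta_j, tolerance = 1e-12)
  }
})

test_that("shannon_entropy follows the closed form", {
  expect_identical(shannon_entropy(0.5), 1)
  expect_identical(shannon_entropy(0), 0)
  expect_identical(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(0.78),
    -0.78 * log2(0.78) - 0.22 * log2(0.22), tolerance = 1e-12)
  expect_equal(shannon_entropy(0.78), 0.760167, tolerance = 1e-6)
  expect_error(shannon_entropy(1.2), class = "metasense_domain_error")
})

test_that("normalized discriminability rescales by chance level", {
  expect_equal(normalized_discriminability(0.75, 0.5), 0.5)
  expect_equal(normalized_discriminability(0.25, 0.25), 0)
  expect_equal(normalized_discriminability(0.78, 0), 0.78)
  # below-chance values stay signed
  expect_equal(normalized_discriminability(0.4, 0.5), -0.2)
  expect_error(normalized_discriminability(0.5, 1),
    class = "metasense_domain_error")
})

test_that("folded_x_table bins items into order-preserving quartiles", {
  # 8 items in OP (chance 0): discriminability equals the correct rate
  rates <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  n_agents <- 10
  rows <- do.call(rbind, lapply(seq_along(rates), function(j) {
    n_hit <- round(rates[j] * n_agents)
    correct <- c(rep(1, n_hit), rep(0, n_agents - n_hit))
    data.frame(
      agent_id = paste0("a", seq_len(n_agents)), agent_group = "human",
      condition = "OP", item_id = paste0("q", j), correct = correct,
      confidence = 10 * j + correct * 5)
  }))
  fx <- folded_x_table(trial_table(rows))
  # 4 quartiles x 2 branches, 2 items each in sorted order
  expect_equal(sort(unique(fx$quartile)), 1:4)
  per_bin <- tapply(fx$n_trials, fx$quartile, sum)
  expect_equal(as.vector(per_bin), rep(2 * n_agents, 4))
  expect_equal(fx$q_lo[fx$quartile == 1][1], 0.1)
  expect_equal(fx$q_hi[fx$quartile == 4][1], 0.9)
})

test_that("folded_x_table reports empty branches as missing and falls back
           to a single bin under ties", {
  # every item has the same correct rate -> degenerate quantile edges
  rows <- do.call(rbind, lapply(1:6, function(j) {
    data.frame(
      agent_id = c("a1", "a2"), agent_group = "human", condition = "2C",
      item_id = paste0("q", j), correct = c(1, 0),
      confidence = c(50 + j, 40 - j))
  }))
  expect_warning(fx <- folded_x_table(trial_table(rows)),
    class = "metasense_degenerate_bins")
  expect_equal(unique(fx$quartile), 1L)

  # top-quartile items are answered perfectly: incorrect branch is
  # reported missing with 0 trials, not as zero confidence
  hits <- c(2, 4, 5, 6, 7, 8, 10, 10)
  rows2 <- do.call(rbind, lapply(seq_along(hits), function(j) {
    data.frame(
      agent_id = paste0("a", 1:10), agent_group = "human",
      condition = "OP", item_id = paste0("q", j),
      correct = c(rep(1, hits[j]), rep(0, 10 - hits[j])),
      confidence = 40 + j)
  }))
  fx2 <- suppressWarnings(folded_x_table(trial_table(rows2)))
  empty <- fx2[fx2$n_trials == 0, ]
  expect_true(nrow(empty) > 0)
  expect_true(all(is.na(empty$mean_confidence)))
})

test_that("agent_metric_table propagates undefined cells and
           group_metric_summary counts exclusions", {
  tt <- trial_table(data.frame(
    agent_id = rep(c("a1", "a2"), each = 4),
    agent_group = "g",
    condition = rep(c("2C", "2C", "OP", "OP"), 2),
    item_id = rep(paste0("q", 1:4), 2),
    correct = c(1, 1, 1, 0, 1, 0, 1, 1),
    confidence = c(90, 80, 70, 30, 85, 40, 75, 65)))
  m <- agent_metric_table(tt)
  a1_2c <- m[m$agent_id == "a1" & m$condition == "2C", ]
  expect_true(is.na(a1_2c$auroc)) # all correct: sensitivity undefined
  expect_true(is.na(a1_2c$meta_j2r))
  expect_equal(a1_2c$meta_j, 0)

  gs <- group_metric_summary(m)
  ex <- gs[gs$condition == "2C" & gs$metric == "auroc", ]
  expect_equal(ex$n_excluded, 1)
  expect_equal(ex$n, 1)
})
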