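make_splitplot_data <- function(n_per_group = 8, seed = 55, null = FALSE) {
  set.seed(seed)
  conds <- c("2C", "4C", "OP")
  cond_eff <- if (null) c(0, 0, 0) else c(0, -3, -8)
  grp_eff <- if (null) c(g1 = 0, g2 = 0) else c(g1 = 0, g2 = 6)
  rows <- list()
  for (g in c("g1", "g2")) {
    for (i in seq_len(n_per_group)) {
      subj_int <- stats::rnorm(1, 0, 2)
      for (k in seq_along(conds)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = paste0(g, "_s", i), group = g, condition = conds[k],
          value = 50 + grp_eff[[g]] + cond_eff[k] + subj_int +
            stats::rnorm(1, 0, 1.5))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("mixed_anova matches the brute-force split-plot oracle on a
           balanced design", {
  dat <- make_splitplot_data()
  got <- mixed_anova(dat, dv = "value", subject = "subject",
    between = "group", within = "condition", gg = "never")
  oracle <- splitplot_oracle(dat, "value", "subject", "group", "condition")

  g_row <- got[got$effect == "group", ]
  expect_equal(g_row$F, oracle$F_A, tolerance = 1e-8)
  expect_equal(c(g_row$df_num, g_row$df_den), oracle$df$A)

  c_row <- got[got$effect == "condition", ]
  expect_equal(c_row$F, oracle$F_B, tolerance = 1e-8)
  expect_equal(c(c_row$df_num, c_row$df_den), oracle$df$B)

  i_row <- got[got$effect == "group:condition", ]
  expect_equal(i_row$F, oracle$F_AB, tolerance = 1e-8)

  # generalized eta squared: SS_eff / (SS_eff + all error SS)
  err <- oracle$ss$S + oracle$ss$E
  expect_equal(g_row$ges, oracle$ss$A / (oracle$ss$A + err),
    tolerance = 1e-8)
  expect_equal(c_row$ges, oracle$ss$B / (oracle$ss$B + err),
    tolerance = 1e-8)
  expect_true(all(got$ges >= 0 & got$ges <= 1))
})

test_that("reported epsilon equals Box's estimate from the pooled
           within-group covariance", {
  dat <- make_splitplot_data(n_per_group = 12, seed = 77)
  got <- mixed_anova(dat, dv = "value", subject = "subject",
    between = "group", within = "condition", gg = "always")
  wide <- tidyr::pivot_wider(dat, id_cols = c("subject", "group"),
    names_from = "condition", values_from = "value")
  y <- as.matrix(wide[, c("2C", "4C", "OP")])
  covs <- lapply(split(as.data.frame(y), wide$group), stats::cov)
  ns <- table(wide$group)
  pooled <- Reduce(`+`, Map(function(s, n) s * (n - 1), covs,
    as.list(as.numeric(ns)))) / (sum(ns) - length(ns))
  eps <- gg_epsilon(pooled)
  c_row <- got[got$effect == "condition", ]
  expect_equal(c_row$epsilon, eps, tolerance = 1e-8)
  expect_true(c_row$gg_applied)
  expect_equal(c_row$df_num, eps * 2, tolerance = 1e-8)
})

test_that("gg_epsilon follows the closed-form trace formula and its
           bounds", {
  # compound symmetry: sphericity holds exactly
  cs <- matrix(0.3, 4, 4)
  diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)

  # two levels: epsilon is 1 by definition
  expect_identical(gg_epsilon(matrix(c(2, 0.5, 0.5, 9), 2, 2)), 1)

  s3 <- matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3, 3)
  expect_equal(gg_epsilon(s3), box_eps_oracle(s3), tolerance = 1e-12)
  expect_gte(gg_epsilon(s3), 0.5)
  expect_lte(gg_epsilon(s3), 1)

  expect_error(gg_epsilon(matrix(c(1, 2, 3, 4), 2, 2)),
    class = "metasense_domain_error")
})

test_that("two-level within factors report epsilon 1 and the three-way
           design runs", {
  dat <- make_splitplot_data()
  dat$correct <- ifelse(dat$condition == "OP", 0, 1) # collapse to 2 levels
  two <- dat[dat$condition != "OP", ]
  got <- mixed_anova(two, dv = "value", subject = "subject",
    between = "group", within = "condition", gg = "auto")
  expect_equal(got$epsilon[got$effect == "condition"], 1)
  expect_false(any(got$gg_applied))

  # two within factors (2 x 3) on crossed data
  set.seed(6)
  grid <- expand.grid(subject = paste0("s", 1:10),
    correct = c("0", "1"), condition = c("2C", "4C", "OP"))
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= 5,
    "g1", "g2")
  grid$value <- 50 + (grid$correct == "1") * 10 + stats::rnorm(60, 0, 2)
  got3 <- mixed_anova(grid, dv = "value", subject = "subject",
    between = "group", within = c("correct", "condition"))
  expect_setequal(got3$effect,
    c("group", "correct", "group:correct", "condition",
      "group:condition", "correct:condition", "group:correct:condition"))
  expect_lt(got3$p[got3$effect == "correct"], 0.001)
})

test_that("null designs produce no significant effects", {
  dat <- make_splitplot_data(seed = 2024, null = TRUE)
  got <- mixed_anova(dat, dv = "value", subject = "subject",
    between = "group", within = "condition")
  expect_true(all(got$p > 0.05))
})

test_that("design violations raise errors instead of imputing", {
  dat <- make_splitplot_data()
  expect_error(mixed_anova(dat[-1, ], dv = "value", subject = "subject",
    between = "group", within = "condition"),
    class = "metasense_design_error")
  one_subj <- dat[dat$subject %in% c("g1_s1", "g2_s1", "g2_s2"), ]
  expect_error(mixed_anova(one_subj, dv = "value", subject = "subject",
    between = "group", within = "condition"),
    class = "metasense_design_error")

  # single within level reduces to a between-subjects ANOVA
  flat <- dat[dat$condition == "2C", ]
  got <- mixed_anova(flat, dv = "value", subject = "subject",
    between = "group", within = NULL)
  expect_equal(nrow(got), 1)
  expect_equal(got$df_num, 1)
})

test_that("bonferroni_pairwise multiplies by the family size and caps at
           1", {
  set.seed(10)
  dat <- data.frame(
    subject = rep(paste0("s", 1:12), 3),
    condition = rep(c("2C", "4C", "OP"), each = 12),
    value = stats::rnorm(36, 50, 5))

  one <- bonferroni_pairwise(dat, "value", "condition",
    family = list(c("2C", "4C")))
  expect_equal(one$p_adj, one$p_raw) # m = 1
  expect_equal(one$m, 1)

  all3 <- bonferroni_pairwise(dat, "value", "condition",
    subject = "subject")
  expect_equal(unique(all3$m), 3)
  expect_equal(all3$p_adj, pmin(1, 3 * all3$p_raw))
  expect_true(all(all3$p_adj <= 1))
  # adjusted p monotone in raw p within the family
  expect_true(all(diff(all3$p_adj[order(all3$p_raw)]) >= 0))

  expect_error(bonferroni_pairwise(dat, "value", "condition",
    family = list()), class = "metasense_domain_error")
})

test_that("bonferroni correction controls the familywise type-I error on
           null data", {
  set.seed(1)
  hits <- 0L
  for (rep in 1:200) {
    dat <- data.frame(
      subject = rep(paste0("s", 1:10), 3),
      condition = rep(c("a", "b", "c"), each = 10),
      value = stats::rnorm(30))
    ph <- bonferroni_pairwise(dat, "value", "condition",
      subject = "subject")
    if (any(ph$p_adj < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 10L) # no significant comparison in >= 95% of datasets
})

test_that("paired comparisons match by subject", {
  dat <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), 2),
    condition = rep(c("x", "y"), each = 4),
    value = c(10, 12, 14, 16, 11, 14, 15, 19))
  ph <- bonferroni_pairwise(dat, "value", "condition",
    subject = "subject")
  expect_equal(ph$mean_diff, mean(c(10, 12, 14, 16) - c(11, 14, 15, 19)))
  expect_equal(ph$df, 3)
  tt <- stats::t.test(c(10, 12, 14, 16), c(11, 14, 15, 19), paired = TRUE)
  expect_equal(ph$t, unname(tt$statistic))
})
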