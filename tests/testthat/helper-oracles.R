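# Independent oracles used to pin down expected values. These deliberately
# avoid the implementation's code paths: the AUROC oracle enumerates pairs,
# the information oracle goes through the entropy-difference identity, and
# the split-plot oracle sums squares from cell means.

# tie-aware rank statistic: P(conf_correct > conf_incorrect) + 0.5 P(tie)
auroc_pair_oracle <- function(confidence, correct) {
  cc <- confidence[correct == 1]
  ci <- confidence[correct == 0]
  s <- 0
  for (a in cc) {
    for (b in ci) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(cc) * length(ci))
}

# plug-in mutual information via H(A) + H(B) - H(A, B)
mi_entropy_oracle <- function(confidence, correct, threshold) {
  high <- as.integer(confidence >= threshold)
  n <- length(confidence)
  joint <- as.vector(table(factor(correct, 0:1), factor(high, 0:1))) / n
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  pa <- c(joint[1] + joint[3], joint[2] + joint[4])
  pb <- c(joint[1] + joint[2], joint[3] + joint[4])
  h(pa) + h(pb) - h(joint)
}

# exhaustive threshold scan over a dense grid covering every binarization
meta_j_scan_oracle <- function(confidence, correct) {
  u <- sort(unique(confidence))
  grid <- sort(unique(c(
    u, u - 1e-6, u + 1e-6,
    seq(min(u) - 1, max(u) + 1, length.out = 501))))
  max(vapply(grid, function(th) mi_entropy_oracle(confidence, correct, th),
    numeric(1)))
}

# classical balanced split-plot sums of squares (one between, one within)
splitplot_oracle <- function(df, dv, subject, between, within) {
  y <- df[[dv]]
  A <- factor(df[[between]])
  B <- factor(df[[within]])
  S <- factor(df[[subject]])
  a <- nlevels(A)
  b <- nlevels(B)
  n <- nlevels(S) / a
  gm <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  mS <- tapply(y, S, mean)
  grp_of <- tapply(as.character(A), S, function(x) x[1])
  ss_a <- n * b * sum((mA - gm)^2)
  ss_s <- b * sum((mS - mA[grp_of[names(mS)]])^2)
  ss_b <- a * n * sum((mB - gm)^2)
  ss_ab <- n * sum((mAB - outer(mA, rep(1, b)) -
    outer(rep(1, a), mB) + gm)^2)
  ss_e <- sum((y - gm)^2) - ss_a - ss_s - ss_b - ss_ab
  df_s <- a * (n - 1)
  df_e <- a * (n - 1) * (b - 1)
  list(
    F_A = (ss_a / (a - 1)) / (ss_s / df_s),
    F_B = (ss_b / (b - 1)) / (ss_e / df_e),
    F_AB = (ss_ab / ((a - 1) * (b - 1))) / (ss_e / df_e),
    df = list(A = c(a - 1, df_s), B = c(b - 1, df_e),
      AB = c((a - 1) * (b - 1), df_e)),
    ss = list(A = ss_a, S = ss_s, B = ss_b, AB = ss_ab, E = ss_e)
  )
}

# closed-form Box epsilon from the trace formula, written independently
box_eps_oracle <- function(S) {
  k <- nrow(S)
  J <- diag(k) - matrix(1 / k, k, k)
  D <- J %*% S %*% J
  sum(diag(D))^2 / ((k - 1) * sum(D^2))
}

# small hand-built trial table: two agents, one condition
toy_trials <- function() {
  trial_table(data.frame(
    agent_id = rep(c("a1", "a2"), each = 4),
    agent_group = "human",
    condition = "2C",
    item_id = rep(paste0("q", 1:4), 2),
    correct = c(1, 1, 0, 1, 0, 1, 0, 0),
    confidence = c(80, 90, 40, 70, 30, 60, 20, 50)
  ))
}

# cohort whose agent-level confidence is linear in realized accuracy:
# conf_ij = alpha + beta_g * correct_rate_i + noise
make_linear_cohort <- function(betas, alpha = 15, n_agents = 60,
                               n_items = 100, sigma = 6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(betas)) {
    for (i in seq_len(n_agents)) {
      p <- stats::runif(1, 0.2, 0.9)
      correct <- stats::rbinom(n_items, 1, p)
      cr <- mean(correct)
      conf <- pmin(100, pmax(0,
        alpha + betas[[g]] * cr + stats::rnorm(n_items, 0, sigma)))
      rows[[length(rows) + 1]] <- data.frame(
        agent_id = sprintf("%s_%03d", g, i), agent_group = g,
        condition = "OP", item_id = paste0("q", seq_len(n_items)),
        correct = correct, confidence = conf)
    }
  }
  trial_table(do.call(rbind, rows))
}
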