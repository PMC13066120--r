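#' Stimulus-level or agent-level means of accuracy and confidence
#'
#' Produces the point clouds of the two-level confidence-accuracy
#' association analysis. At the stimulus level, correct rates and
#' confidence are averaged across agents for each item (one point per item
#' per group). At the agent level they are averaged across items for each
#' agent; `agent_aggregation` switches between one pooled point per agent
#' (the default) and one point per agent per condition.
#'
#' @param table A [trial_table()].
#' @param level `"stimulus"` or `"agent"`.
#' @param agent_aggregation For `level = "agent"`: `"pooled"` (one point
#'   per agent across all trials) or `"per_condition"` (one point per
#'   agent and condition).
#' @return Tibble with columns `group` (agent group), `unit_id`,
#'   `condition` (`"All"` for pooled agent points), `correct_rate` and
#'   `mean_confidence`; the `level` is attached as an attribute.
#' @export
level_means <- function(table, level = c("stimulus", "agent"),
                        agent_aggregation = c("pooled", "per_condition")) {
  level <- match.arg(level)
  agent_aggregation <- match.arg(agent_aggregation)
  stopifnot(inherits(table, "trial_table"))
  if (level == "stimulus") {
    pts <- summarize_by_item(table) |>
      dplyr::transmute(
        group = .data$agent_group, unit_id = .data$item_id,
        condition = .data$condition,
        correct_rate = .data$correct_rate,
        mean_confidence = .data$mean_confidence)
  } else if (agent_aggregation == "pooled") {
    pts <- summarize_by_agent(table, include_pooled = TRUE) |>
      dplyr::filter(.data$condition == "All") |>
      dplyr::transmute(
        group = .data$agent_group, unit_id = .data$agent_id,
        condition = "All",
        correct_rate = .data$correct_rate,
        mean_confidence = .data$mean_confidence)
  } else {
    pts <- summarize_by_agent(table, include_pooled = FALSE) |>
      dplyr::transmute(
        group = .data$agent_group, unit_id = .data$agent_id,
        condition = .data$condition,
        correct_rate = .data$correct_rate,
        mean_confidence = .data$mean_confidence)
  }
  structure(pts, level = level)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Thin, validated wrapper around the product-moment correlation. Constant
#' input makes the correlation undefined: a classed warning
#' (`metasense_undefined_correlation`) is emitted and `NA`s are returned,
#' distinct from the errors raised on malformed input.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("x and y must have equal length",
      class = "metasense_validation_error")
  }
  if (length(x) < 3) {
    rlang::abort("pearson_r requires n >= 3",
      class = "metasense_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    rlang::abort("missing values are not allowed",
      class = "metasense_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("correlation undefined for constant input",
      class = "metasense_undefined_correlation")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson",
    alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample comparison of Pearson correlations via Fisher's z
#'
#' Tests whether two independent correlation coefficients differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`,
#' referred to the standard normal, two-sided. Swapping the two samples
#' negates `z`.
#'
#' @param r1,r2 Pearson coefficients, strictly inside `(-1, 1)`.
#' @param n1,n2 Sample sizes, both `> 3`.
#' @return List with `r1`, `n1`, `r2`, `n2`, `z` and two-sided `p`.
#' @export
#' @examples
#' fisher_z_compare(0.83, 60, 0.33, 60)$z # about 4.51
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    rlang::abort("|r| must be < 1", class = "metasense_domain_error")
  }
  if (n1 <= 3 || n2 <= 3) {
    rlang::abort("both sample sizes must exceed 3",
      class = "metasense_domain_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
    z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Between-group difference of regression slopes
#'
#' Fits a single ordinary-least-squares model of mean confidence on correct
#' rate with a group indicator and a group-by-correct-rate interaction;
#' the interaction coefficient is the slope difference
#' `delta_beta = beta_group2 - beta_group1` (group order follows the factor
#' levels, i.e. order of first appearance). Its t statistic has
#' `n_points - 4` residual degrees of freedom. Algebraically the per-group
#' slopes of this model equal two independently fitted per-group OLS
#' slopes.
#'
#' @param points A [level_means()] table (or any data frame with columns
#'   `group`, `correct_rate`, `mean_confidence`) containing exactly two
#'   groups, each with at least 3 points and non-constant correct rates.
#' @return List with `groups`, `beta_per_group` (named slopes),
#'   `delta_beta`, `t`, `df`, `p` and `degenerate` (`TRUE` when the model
#'   has zero residual variance, which makes `t` unbounded).
#' @export
slope_difference <- function(points) {
  df <- tibble::as_tibble(points)
  needed <- c("group", "correct_rate", "mean_confidence")
  if (!all(needed %in% names(df))) {
    rlang::abort(paste0("points must have columns: ",
      paste(needed, collapse = ", ")),
      class = "metasense_validation_error")
  }
  groups <- unique(df$group)
  if (length(groups) != 2) {
    rlang::abort("slope_difference requires exactly two groups",
      class = "metasense_validation_error")
  }
  for (g in groups) {
    sub <- df[df$group == g, ]
    if (nrow(sub) < 3) {
      rlang::abort("each group needs at least 3 points",
        class = "metasense_validation_error")
    }
    if (stats::sd(sub$correct_rate) == 0) {
      rlang::abort(paste0("correct_rate is constant within group ", g),
        class = "metasense_singular_fit_error")
    }
  }
  df$group <- factor(df$group, levels = groups)
  fit <- stats::lm(mean_confidence ~ correct_rate * group, data = df)
  if (qr(stats::model.matrix(fit))$rank < 4) {
    rlang::abort("rank-deficient design",
      class = "metasense_singular_fit_error")
  }
  cf <- stats::coef(fit)
  int_name <- paste0("correct_rate:group", groups[2])
  delta <- unname(cf[int_name])
  sm <- summary(fit)
  n <- nrow(df)
  dof <- n - 4L
  sigma <- sm$sigma
  degenerate <- sigma < 1e-10
  if (degenerate) {
    tval <- sign(delta) * Inf
    p <- 0
  } else {
    se <- sm$coefficients[int_name, "Std. Error"]
    tval <- delta / se
    p <- 2 * stats::pt(-abs(tval), df = dof)
  }
  beta1 <- unname(cf["correct_rate"])
  list(
    groups = as.character(groups),
    beta_per_group = stats::setNames(c(beta1, beta1 + delta),
      as.character(groups)),
    delta_beta = delta, t = tval, df = dof, p = p,
    degenerate = degenerate
  )
}
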