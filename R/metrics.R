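#' Type-2 receiver operating characteristic curve
#'
#' Builds the type-2 ROC of a set of trials: confidence treated as a
#' classifier of the agent's own correctness. For every criterion `theta`
#' (swept over the distinct observed confidence values, descending, plus a
#' sentinel above the maximum) the type-2 hit rate is
#' `P(confidence >= theta | correct)` and the type-2 false-alarm rate is
#' `P(confidence >= theta | incorrect)`. The area under the curve is
#' computed by trapezoidal integration, which is algebraically identical to
#' the tie-aware rank statistic
#' `P(conf_correct > conf_incorrect) + 0.5 * P(tie)`.
#'
#' @param confidence Numeric vector of confidence ratings.
#' @param correct Parallel 0/1 vector of correctness.
#' @return An object of class `type2_roc` with elements `thresholds`,
#'   `hr2`, `far2`, `auroc`, `n_correct`, `n_incorrect` and `undefined`.
#'   When all trials are correct or all incorrect the curve is undefined:
#'   `undefined` is `TRUE` and `auroc` is `NA` (this is a signal, not an
#'   error; malformed input does raise an error).
#' @export
#' @examples
#' type2_roc(c(90, 70, 50, 30), c(1, 1, 0, 0))$auroc # 1
type2_roc <- function(confidence, correct) {
  check_conf_correct(confidence, correct)
  n1 <- sum(correct == 1)
  n0 <- sum(correct == 0)
  if (n1 == 0L || n0 == 0L) {
    return(structure(
      list(thresholds = numeric(0), hr2 = numeric(0), far2 = numeric(0),
        auroc = NA_real_, n_correct = n1, n_incorrect = n0,
        undefined = TRUE),
      class = "type2_roc"
    ))
  }
  u <- sort(unique(confidence), decreasing = TRUE)
  thresholds <- c(u[1] + 1, u)
  conf_c <- confidence[correct == 1]
  conf_i <- confidence[correct == 0]
  hr2 <- vapply(thresholds, function(th) mean(conf_c >= th), numeric(1))
  far2 <- vapply(thresholds, function(th) mean(conf_i >= th), numeric(1))
  auroc <- sum(diff(far2) * (hr2[-length(hr2)] + hr2[-1]) / 2)
  structure(
    list(thresholds = thresholds, hr2 = hr2, far2 = far2, auroc = auroc,
      n_correct = n1, n_incorrect = n0, undefined = FALSE),
    class = "type2_roc"
  )
}

#' Type-2 AUROC as a scalar
#'
#' Convenience wrapper around [type2_roc()] returning only the area;
#' `NA` when sensitivity is undefined (all trials correct or all
#' incorrect).
#'
#' @inheritParams type2_roc
#' @return A number in `[0, 1]`, or `NA`.
#' @export
type2_auroc <- function(confidence, correct) {
  type2_roc(confidence, correct)$auroc
}

check_conf_correct <- function(confidence, correct) {
  if (length(confidence) != length(correct)) {
    rlang::abort("confidence and correct must have equal length",
      class = "metasense_validation_error")
  }
  if (any(is.na(confidence)) || any(!is.finite(confidence))) {
    rlang::abort("confidence must be finite and non-missing",
      class = "metasense_validation_error")
  }
  if (any(is.na(correct)) || !all(correct %in% c(0, 1))) {
    rlang::abort("correct must be a 0/1 vector without missing values",
      class = "metasense_validation_error")
  }
  invisible(TRUE)
}

#' Binary Shannon entropy
#'
#' `H(p) = -p log2 p - (1 - p) log2 (1 - p)` with the convention
#' `0 log 0 = 0`. This is the upper bound of the mutual information between
#' accuracy and any function of confidence, and the denominator of the
#' efficiency measure meta-J2r.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Entropy in bits, in `[0, 1]`.
#' @export
#' @examples
#' shannon_entropy(0.5) # 1
shannon_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("p must lie in [0, 1]", class = "metasense_domain_error")
  }
  plog2 <- function(q) ifelse(q > 0, q * log2(q), 0)
  -plog2(p) - plog2(1 - p)
}

#' Mutual information between accuracy and binarized confidence (meta-J)
#'
#' Binarizes confidence at `threshold` (high when
#' `confidence >= threshold`) and returns the plug-in mutual information of
#' the resulting 2x2 joint frequency table, in bits, with `0 log 0 = 0`.
#' Degenerate margins (constant accuracy or constant binarized confidence)
#' yield 0 by that convention.
#'
#' @inheritParams type2_roc
#' @param threshold Binarization criterion on the confidence scale.
#' @return Mutual information in bits, in `[0, H(accuracy)]`.
#' @export
meta_j <- function(confidence, correct, threshold) {
  check_conf_correct(confidence, correct)
  n <- length(correct)
  if (n < 2) {
    rlang::abort("meta_j requires at least 2 trials",
      class = "metasense_validation_error")
  }
  high <- confidence >= threshold
  p11 <- sum(correct == 1 & high) / n
  p10 <- sum(correct == 1 & !high) / n
  p01 <- sum(correct == 0 & high) / n
  p00 <- sum(correct == 0 & !high) / n
  pa <- c(p10 + p11, p00 + p01) # P(accuracy = 1), P(accuracy = 0)
  ph <- c(p11 + p01, p10 + p00) # P(high), P(low)
  cell <- function(p, pr, pc) if (p > 0) p * log2(p / (pr * pc)) else 0
  cell(p11, pa[1], ph[1]) + cell(p10, pa[1], ph[2]) +
    cell(p01, pa[2], ph[1]) + cell(p00, pa[2], ph[2])
}

#' Maximum-information binarization: meta-J and meta-J2r
#'
#' Scans candidate thresholds — the midpoints between consecutive distinct
#' observed confidence values, plus one below the minimum and one above the
#' maximum — and returns the threshold maximizing the mutual information
#' between accuracy and the binarized confidence ([meta_j()]). Because the
#' information is constant between consecutive midpoints, this scan is an
#' exhaustive search over every achievable binarization. Ties on the
#' information value are broken toward the lowest threshold, so the result
#' is deterministic.
#'
#' Meta-J2r, the efficiency measure, is meta-J normalized by the Shannon
#' entropy of accuracy; it is undefined (`NA`) when the agent is entirely
#' correct or entirely incorrect (zero-entropy margin), in which case
#' meta-J is 0.
#'
#' @inheritParams type2_roc
#' @return An object of class `meta_j_result`: a list with `meta_j` (bits),
#'   `threshold`, `accuracy_entropy` (bits), `meta_j2r` and `n_trials`.
#' @export
#' @examples
#' meta_j_max(c(90, 60, 30), c(1, 1, 0))
meta_j_max <- function(confidence, correct) {
  check_conf_correct(confidence, correct)
  n <- length(correct)
  if (n < 2) {
    rlang::abort("meta_j_max requires at least 2 trials",
      class = "metasense_validation_error")
  }
  acc <- mean(correct)
  h_a <- shannon_entropy(acc)
  if (h_a == 0) {
    return(structure(
      list(meta_j = 0, threshold = NA_real_, accuracy_entropy = 0,
        meta_j2r = NA_real_, n_trials = n),
      class = "meta_j_result"
    ))
  }
  u <- sort(unique(confidence))
  candidates <- c(u[1] - 1,
    if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
    u[length(u)] + 1)
  mi <- vapply(candidates, function(th) meta_j(confidence, correct, th),
    numeric(1))
  best <- which.max(mi) # first maximum = lowest threshold on ties
  structure(
    list(meta_j = mi[best], threshold = candidates[best],
      accuracy_entropy = h_a, meta_j2r = mi[best] / h_a, n_trials = n),
    class = "meta_j_result"
  )
}

#' Normalized discriminability
#'
#' Rescales a correct rate by the chance level of the answering format:
#' `(correct_rate - chance) / (1 - chance)`. Puts conditions with different
#' guess rates (0.5 for two-choice, 0.25 for four-choice, 0 for open-ended)
#' on a common scale where 0 is chance performance and 1 is perfect.
#' Below-chance values are kept signed, not clipped.
#'
#' @param correct_rate Proportion(s) in `[0, 1]`.
#' @param chance Chance level(s) in `[0, 1)`.
#' @return Normalized discriminability (may be negative).
#' @export
#' @examples
#' normalized_discriminability(0.75, 0.5) # 0.5
normalized_discriminability <- function(correct_rate, chance) {
  if (any(is.na(chance)) || any(chance >= 1) || any(chance < 0)) {
    rlang::abort("chance must lie in [0, 1)",
      class = "metasense_domain_error")
  }
  (correct_rate - chance) / (1 - chance)
}

#' Folded X-pattern table
#'
#' For each agent group and condition, items are scored by their
#' group-level correct rate, mapped to normalized discriminability, and
#' binned into `n_bins` equal-probability bins by within-condition
#' empirical quantiles (items falling exactly on an interior edge go to the
#' lower bin). Trials of the binned items are pooled and mean confidence is
#' reported separately for correct and incorrect responses. In agents whose
#' confidence tracks discriminability this produces the folded X: the
#' correct branch rises and the incorrect branch falls across bins.
#'
#' If the item discriminabilities within a (group, condition) cell are too
#' tied for distinct quantile edges, the cell degenerates to a single bin
#' and a warning is emitted. A bin with no trials of one correctness branch
#' is reported with `mean_confidence = NA` and `n_trials = 0`, not zero.
#'
#' @param table A [trial_table()].
#' @param n_bins Number of discriminability bins; default 4 (quartiles).
#' @return Tibble with columns `agent_group`, `condition`, `quartile`,
#'   `q_lo`, `q_hi` (bin edges on the normalized discriminability scale),
#'   `correct` (branch), `mean_confidence`, `n_trials`.
#' @export
folded_x_table <- function(table, n_bins = 4) {
  stopifnot(inherits(table, "trial_table"))
  df <- tibble::as_tibble(table)
  cm <- chance_map(table)
  item_disc <- df |>
    dplyr::group_by(.data$agent_group, .data$condition, .data$item_id) |>
    dplyr::summarise(correct_rate = mean(.data$correct), .groups = "drop") |>
    dplyr::mutate(disc = normalized_discriminability(
      .data$correct_rate, cm[.data$condition]))

  cells <- dplyr::distinct(item_disc, .data$agent_group, .data$condition)
  binned <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- item_disc[item_disc$agent_group == cells$agent_group[i] &
      item_disc$condition == cells$condition[i], ]
    if (nrow(sub) < n_bins) {
      rlang::abort(paste0("need at least ", n_bins, " items per ",
        "(agent_group, condition) cell; got ", nrow(sub), " in ",
        cells$agent_group[i], "/", cells$condition[i]),
        class = "metasense_validation_error")
    }
    edges <- stats::quantile(sub$disc, probs = seq(0, 1,
      length.out = n_bins + 1), names = FALSE, type = 7)
    if (anyDuplicated(edges) > 0) {
      rlang::warn(paste0("tied discriminabilities in ",
        cells$agent_group[i], "/", cells$condition[i],
        ": falling back to a single bin"),
        class = "metasense_degenerate_bins")
      sub$quartile <- 1L
      sub$q_lo <- min(sub$disc)
      sub$q_hi <- max(sub$disc)
    } else {
      # right-closed intervals: an item exactly on an interior edge is the
      # upper endpoint of the lower bin
      bin <- cut(sub$disc, breaks = edges, include.lowest = TRUE,
        right = TRUE, labels = FALSE)
      sub$quartile <- as.integer(bin)
      sub$q_lo <- edges[sub$quartile]
      sub$q_hi <- edges[sub$quartile + 1L]
    }
    binned[[i]] <- sub
  }
  item_bins <- dplyr::bind_rows(binned)

  trials <- dplyr::inner_join(df,
    item_bins[, c("agent_group", "condition", "item_id", "quartile",
      "q_lo", "q_hi")],
    by = c("agent_group", "condition", "item_id"))
  observed_bins <- dplyr::distinct(item_bins, .data$agent_group,
    .data$condition, .data$quartile, .data$q_lo, .data$q_hi)
  branches <- tidyr::crossing(observed_bins, correct = c(0L, 1L))
  trials |>
    dplyr::group_by(.data$agent_group, .data$condition, .data$quartile,
      .data$q_lo, .data$q_hi, .data$correct) |>
    dplyr::summarise(
      mean_confidence = mean(.data$confidence),
      n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(branches,
      by = c("agent_group", "condition", "quartile", "q_lo", "q_hi",
        "correct")) |>
    dplyr::mutate(n_trials = dplyr::coalesce(.data$n_trials, 0L)) |>
    dplyr::arrange(.data$agent_group, .data$condition, .data$quartile,
      .data$correct)
}

#' Per-agent metacognition metrics
#'
#' Applies [type2_roc()] and [meta_j_max()] to every agent, separately per
#' condition and for the pooled `"All"` pseudo-condition (the binarization
#' threshold is re-optimized on the pooled trials, not averaged over
#' conditions). Agents with all-correct or all-incorrect responses in a
#' cell have an undefined AUROC and meta-J2r there; those cells propagate
#' as `NA`, never silently dropped rows.
#'
#' @param table A [trial_table()].
#' @param include_pooled Include the `"All"` rows? Default `TRUE`.
#' @return Tibble with one row per (agent, condition) and columns
#'   `agent_id`, `agent_group`, `condition`, `n_trials`, `correct_rate`,
#'   `auroc`, `meta_j`, `threshold`, `accuracy_entropy`, `meta_j2r`.
#' @export
agent_metric_table <- function(table, include_pooled = TRUE) {
  stopifnot(inherits(table, "trial_table"))
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0) {
    rlang::abort("cannot compute metrics on an empty trial table",
      class = "metasense_validation_error")
  }
  one_cell <- function(sub, cond) {
    if (nrow(sub) < 2) { # a single trial defines neither measure
      return(tibble::tibble(
        agent_id = sub$agent_id[1],
        agent_group = sub$agent_group[1],
        condition = cond,
        n_trials = nrow(sub),
        correct_rate = mean(sub$correct),
        auroc = NA_real_,
        meta_j = NA_real_,
        threshold = NA_real_,
        accuracy_entropy = NA_real_,
        meta_j2r = NA_real_
      ))
    }
    mj <- meta_j_max(sub$confidence, sub$correct)
    tibble::tibble(
      agent_id = sub$agent_id[1],
      agent_group = sub$agent_group[1],
      condition = cond,
      n_trials = nrow(sub),
      correct_rate = mean(sub$correct),
      auroc = type2_auroc(sub$confidence, sub$correct),
      meta_j = mj$meta_j,
      threshold = mj$threshold,
      accuracy_entropy = mj$accuracy_entropy,
      meta_j2r = mj$meta_j2r
    )
  }
  per_cond <- df |>
    dplyr::group_by(.data$agent_id, .data$agent_group, .data$condition) |>
    dplyr::group_map(~ one_cell(dplyr::mutate(.x,
      agent_id = .y$agent_id, agent_group = .y$agent_group), .y$condition)) |>
    dplyr::bind_rows()
  out <- per_cond
  if (include_pooled) {
    pooled <- df |>
      dplyr::group_by(.data$agent_id, .data$agent_group) |>
      dplyr::group_map(~ one_cell(dplyr::mutate(.x,
        agent_id = .y$agent_id, agent_group = .y$agent_group), "All")) |>
      dplyr::bind_rows()
    out <- dplyr::bind_rows(per_cond, pooled)
  }
  dplyr::arrange(out, .data$agent_group, .data$agent_id, .data$condition)
}

#' Group-level summary of per-agent metrics
#'
#' Means and SDs over agents, per (agent group, condition), of the metrics
#' computed by [agent_metric_table()]. Agents whose value is undefined in a
#' cell (e.g. AUROC with an all-correct record) are excluded from that
#' cell's mean and counted in `n_excluded`, so the exclusion behaviour is
#' auditable rather than silent.
#'
#' @param metrics Output of [agent_metric_table()].
#' @return Tibble with columns `agent_group`, `condition`, `metric`,
#'   `mean`, `sd`, `n`, `n_excluded`.
#' @export
group_metric_summary <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(
      cols = c("correct_rate", "auroc", "meta_j", "meta_j2r"),
      names_to = "metric", values_to = "value")
  long |>
    dplyr::group_by(.data$agent_group, .data$condition, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value[!is.na(.data$value)]),
      sd = stats::sd(.data$value[!is.na(.data$value)]),
      n = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      .groups = "drop"
    )
}
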