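#' @importFrom rlang abort warn .data
#' @importFrom stats setNames
NULL

#' Default chance levels for the three answering formats
#'
#' Two-alternative choice (`2C`) has a guess-success probability of 0.5,
#' four-alternative choice (`4C`) 0.25, and open-ended response (`OP`) 0
#' (not in a strict mathematical sense, but for all practical purposes).
#'
#' @return Named numeric vector mapping condition label to chance level.
#' @export
#' @examples
#' default_chance_map()
default_chance_map <- function() {
  c("2C" = 0.5, "4C" = 0.25, "OP" = 0)
}

trial_columns <- c(
  "agent_id", "agent_group", "condition", "item_id", "correct", "confidence"
)

#' Construct a validated trial table
#'
#' A trial table is the canonical long-format container for
#' confidence-judgement data: one row per (agent, condition, item) with a
#' binary correctness score and a confidence rating on the 0-100 scale.
#' Every downstream computation in the package consumes this container.
#'
#' @param trials A data frame with columns `agent_id`, `agent_group`,
#'   `condition`, `item_id`, `correct` (0/1) and `confidence` (0-100).
#'   Extra columns are dropped. Confidence is kept as a real number;
#'   integer inputs are not rounded.
#' @param chance_map Named numeric vector mapping every condition label
#'   occurring in `trials` to its chance level in `[0, 1)`. Defaults to
#'   [default_chance_map()].
#' @return A tibble of class `trial_table` with a `chance_map` attribute.
#' @export
#' @examples
#' tt <- trial_table(data.frame(
#'   agent_id = "a1", agent_group = "human", condition = "2C",
#'   item_id = c("q1", "q2"), correct = c(1, 0), confidence = c(80, 40)
#' ))
#' chance_map(tt)
trial_table <- function(trials, chance_map = default_chance_map()) {
  df <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "metasense_schema_error"
    )
  }
  df <- df[trial_columns]
  df$agent_id <- as.character(df$agent_id)
  df$agent_group <- as.character(df$agent_group)
  df$condition <- as.character(df$condition)
  df$item_id <- as.character(df$item_id)
  df$correct <- as.integer(df$correct)
  df$confidence <- as.numeric(df$confidence)
  validate_trials(df, chance_map)
  new_trial_table(df, chance_map)
}

new_trial_table <- function(df, chance_map) {
  structure(
    df,
    chance_map = chance_map,
    class = c("trial_table", class(tibble::tibble())))
}

validate_chance_map <- function(chance_map) {
  if (is.null(names(chance_map)) || any(!nzchar(names(chance_map)))) {
    abort("chance_map must be a fully named numeric vector",
      class = "metasense_validation_error")
  }
  if (!is.numeric(chance_map) || any(chance_map < 0) || any(chance_map >= 1)) {
    abort("chance levels must lie in [0, 1)",
      class = "metasense_validation_error")
  }
  invisible(chance_map)
}

validate_trials <- function(df, chance_map) {
  validate_chance_map(chance_map)
  bad_correct <- which(is.na(df$correct) | !(df$correct %in% c(0L, 1L)))
  if (length(bad_correct) > 0) {
    abort(
      paste0("`correct` must be 0 or 1; first offending row: ",
        bad_correct[1]),
      class = "metasense_validation_error"
    )
  }
  bad_conf <- which(is.na(df$confidence) |
    df$confidence < 0 | df$confidence > 100)
  if (length(bad_conf) > 0) {
    abort(
      paste0("`confidence` must lie in [0, 100]; first offending row: ",
        bad_conf[1]),
      class = "metasense_validation_error"
    )
  }
  unknown <- setdiff(unique(df$condition), names(chance_map))
  if (length(unknown) > 0) {
    abort(
      paste0("unknown condition label(s): ", paste(unknown, collapse = ", "),
        " (admitted: ", paste(names(chance_map), collapse = ", "), ")"),
      class = "metasense_validation_error"
    )
  }
  key <- paste(df$agent_id, df$condition, df$item_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(
      paste0("duplicated (agent_id, condition, item_id) triple at row ",
        dup[1]),
      class = "metasense_validation_error"
    )
  }
  invisible(df)
}

#' Chance-level map of a trial table
#'
#' @param x A `trial_table`.
#' @return Named numeric vector of chance levels by condition.
#' @export
chance_map <- function(x) {
  cm <- attr(x, "chance_map", exact = TRUE)
  if (is.null(cm)) default_chance_map() else cm
}

#' Read a trial table from delimited text
#'
#' Expects a header row naming the six canonical columns; files with other
#' headers are absorbed through `col_map`. Row order is preserved.
#'
#' @param path Path to an existing delimited text file (UTF-8).
#' @param delim Field delimiter, `","` by default (use `"\t"` for TSV).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(agent_id = "subject", confidence = "conf")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param chance_map Condition-to-chance-level mapping; see [trial_table()].
#' @return A validated [trial_table()].
#' @export
read_trials <- function(path, delim = ",", col_map = NULL,
                        chance_map = default_chance_map()) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path),
      class = "metasense_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE, col_types = readr::cols(.default = readr::col_guess()))
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), trial_columns)
    if (length(bad) > 0) {
      abort(paste0("col_map names must be canonical columns; unknown: ",
        paste(bad, collapse = ", ")), class = "metasense_schema_error")
    }
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        abort(paste0("missing column: ", src, " (mapped to ", canon, ")"),
          class = "metasense_schema_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  trial_table(raw, chance_map = chance_map)
}

#' Write a trial table to delimited text
#'
#' Writes the six canonical columns with a header row. Reading the file
#' back with [read_trials()] reproduces the table field for field
#' (confidence values are written at full precision).
#'
#' @param table A `trial_table`.
#' @param path Output file path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "trial_table"))
  df <- tibble::as_tibble(table)[trial_columns]
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Per-agent summaries of accuracy and confidence
#'
#' Computes, for every (agent, condition) cell, the number of trials, the
#' correct rate (plain proportion of correct trials) and the mean
#' confidence. When `include_pooled` is `TRUE` a pooled pseudo-condition
#' `"All"` aggregating every trial of the agent is appended, mirroring how
#' summary tables report an "All" row alongside the per-condition rows.
#'
#' @param table A `trial_table`.
#' @param include_pooled Append the pooled `"All"` rows? Default `TRUE`.
#' @return Tibble with columns `agent_id`, `agent_group`, `condition`,
#'   `n_trials`, `correct_rate`, `mean_confidence`.
#' @export
summarize_by_agent <- function(table, include_pooled = TRUE) {
  stopifnot(inherits(table, "trial_table"))
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0) {
    abort("cannot summarize an empty trial table",
      class = "metasense_validation_error")
  }
  per_cond <- df |>
    dplyr::group_by(.data$agent_id, .data$agent_group, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      correct_rate = mean(.data$correct),
      mean_confidence = mean(.data$confidence),
      .groups = "drop"
    )
  out <- per_cond
  if (include_pooled) {
    pooled <- df |>
      dplyr::group_by(.data$agent_id, .data$agent_group) |>
      dplyr::summarise(
        n_trials = dplyr::n(),
        correct_rate = mean(.data$correct),
        mean_confidence = mean(.data$confidence),
        .groups = "drop"
      ) |>
      dplyr::mutate(condition = "All", .after = "agent_group")
    out <- dplyr::bind_rows(per_cond, pooled)
  }
  dplyr::arrange(out, .data$agent_group, .data$agent_id, .data$condition)
}

#' Per-item summaries across the agents of each group
#'
#' For every (item, agent group) pair, averages correctness and confidence
#' over all agents of that group who answered the item. These item-level
#' means are the stimulus-level points of the association analyses and the
#' input to the folded X-pattern binning.
#'
#' @param table A `trial_table`.
#' @return Tibble with columns `item_id`, `condition`, `agent_group`,
#'   `n_agents`, `correct_rate`, `mean_confidence`.
#' @export
summarize_by_item <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0) {
    abort("cannot summarize an empty trial table",
      class = "metasense_validation_error")
  }
  df |>
    dplyr::group_by(.data$item_id, .data$condition, .data$agent_group) |>
    dplyr::summarise(
      n_agents = dplyr::n_distinct(.data$agent_id),
      correct_rate = mean(.data$correct),
      mean_confidence = mean(.data$confidence),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$agent_group, .data$condition, .data$item_id)
}
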