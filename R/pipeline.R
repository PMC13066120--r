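#' Run configuration for the full analysis pipeline
#'
#' Exactly one of `input` (path to a trials file) and `sim` (a
#' [sim_config()] describing a cohort to generate) must be supplied.
#'
#' @param out_dir Directory for the report bundle (created if absent).
#' @param input Optional path to a delimited trials file.
#' @param sim Optional [sim_config()].
#' @param seed Integer seed for any simulation stage; overrides the seed
#'   embedded in `sim` when given.
#' @param delim Delimiter of `input` (default `","`).
#' @param col_map Optional column mapping passed to [read_trials()].
#' @param chance_map Condition chance levels; default
#'   [default_chance_map()].
#' @param agent_aggregation Agent-level aggregation for the association
#'   stage: `"pooled"` or `"per_condition"`.
#' @param gg Greenhouse-Geisser policy for the ANOVA stages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, sim = NULL, seed = NULL,
                       delim = ",", col_map = NULL,
                       chance_map = default_chance_map(),
                       agent_aggregation = c("pooled", "per_condition"),
                       gg = c("auto", "always", "never")) {
  agent_aggregation <- match.arg(agent_aggregation)
  gg <- match.arg(gg)
  if (is.null(input) == is.null(sim)) {
    rlang::abort("exactly one of `input` and `sim` must be set",
      class = "metasense_parameter_error")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    rlang::abort("`sim` must be a sim_config",
      class = "metasense_parameter_error")
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, input = input, sim = sim,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      delim = delim, col_map = col_map, chance_map = chance_map,
      agent_aggregation = agent_aggregation, gg = gg),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()]; a `sim` section
#' holds [sim_config()] fields, with profiles given either as preset names
#' (`profiles: {human: human_like, gpt4: llm_like}`) or as parameter maps.
#'
#' @param path Path to a YAML file.
#' @param out_dir Override for the output directory (optional).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file does not exist: ", path),
      class = "metasense_io_error")
  }
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$profiles)) {
      sim_args$profiles <- lapply(sim_args$profiles, function(p) {
        if (is.character(p)) make_profile(p) else do.call(agent_profile, p)
      })
    }
    if (!is.null(sim_args$chance_map)) {
      sim_args$chance_map <- unlist(sim_args$chance_map)
    }
    sim <- do.call(sim_config, sim_args)
  }
  cm <- if (is.null(raw$chance_map)) {
    default_chance_map()
  } else {
    unlist(raw$chance_map)
  }
  run_config(
    out_dir = if (is.null(out_dir)) raw$out_dir else out_dir,
    input = raw$input, sim = sim, seed = raw$seed,
    delim = if (is.null(raw$delim)) "," else raw$delim,
    col_map = if (is.null(raw$col_map)) NULL else unlist(raw$col_map),
    chance_map = cm,
    agent_aggregation = if (is.null(raw$agent_aggregation)) "pooled"
      else raw$agent_aggregation,
    gg = if (is.null(raw$gg)) "auto" else raw$gg
  )
}

stage_abort <- function(stage, parent) {
  rlang::abort(paste0("pipeline stage `", stage, "` failed: ",
    conditionMessage(parent)),
    class = "metasense_stage_error", parent = parent)
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the full metacognition analysis pipeline
#'
#' Executes, in order: ingest or simulate; per-agent and per-item
#' summaries; stimulus- and agent-level association analyses (correlation,
#' Fisher z comparison, slope difference); mixed ANOVAs on correct rate and
#' mean confidence with Bonferroni post hocs; the three-way
#' confidence-by-correctness ANOVA; per-agent Type-2 AUROC and
#' meta-J/meta-J2r with group summaries and their ANOVAs; and the folded
#' X-pattern table. Every intermediate is persisted as CSV in the output
#' directory, and a JSON manifest of content digests makes re-runs
#' verifiable: the same configuration and seed reproduce identical
#' digests.
#'
#' Statistical stages that the input cannot support (e.g. a toy table too
#' small for the factorial design) are skipped with a warning and recorded
#' in the manifest; failures in the data stages abort with the stage name.
#'
#' @param config A [run_config()].
#' @return Object of class `report_bundle`: list with `tables` (the
#'   in-memory results), `files` (named paths), `skipped` (named skip
#'   reasons), `manifest` (file digests) and `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  files <- character(0)
  skipped <- character(0)

  note_skip <- function(stage, msg) {
    rlang::warn(paste0("stage `", stage, "` skipped: ", msg),
      class = "metasense_stage_skipped")
    skipped[[stage]] <<- msg
  }
  try_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note_skip(stage, conditionMessage(e))
      NULL
    })
  }

  # -- ingest / simulate ----------------------------------------------------
  trials <- tryCatch({
    if (!is.null(config$input)) {
      read_trials(config$input, delim = config$delim,
        col_map = config$col_map, chance_map = config$chance_map)
    } else {
      generate_cohort(config$sim)
    }
  }, error = function(e) stage_abort("ingest", e))
  tables$trials <- trials
  files["trials"] <- write_stage_csv(tibble::as_tibble(trials),
    config$out_dir, "trials.csv")

  # -- summaries ------------------------------------------------------------
  tables$agent_summaries <- tryCatch(
    summarize_by_agent(trials, include_pooled = TRUE),
    error = function(e) stage_abort("summaries", e))
  tables$item_summaries <- summarize_by_item(trials)
  files["agent_summaries"] <- write_stage_csv(tables$agent_summaries,
    config$out_dir, "agent_summaries.csv")
  files["item_summaries"] <- write_stage_csv(tables$item_summaries,
    config$out_dir, "item_summaries.csv")

  # -- associations ---------------------------------------------------------
  assoc <- try_stage("associations", {
    stim <- level_means(trials, "stimulus")
    agent <- level_means(trials, "agent",
      agent_aggregation = config$agent_aggregation)
    cors <- dplyr::bind_rows(lapply(
      list(stimulus = stim, agent = agent), function(pts) {
        dplyr::bind_rows(lapply(split(pts, pts$group), function(sub) {
          pr <- pearson_r(sub$correct_rate, sub$mean_confidence)
          tibble::tibble(group = sub$group[1], r = pr$r, p = pr$p,
            n = pr$n)
        }))
      }), .id = "level")
    fz <- dplyr::bind_rows(lapply(split(cors, cors$level), function(cc) {
      if (nrow(cc) != 2 || anyNA(cc$r)) {
        return(NULL)
      }
      fzc <- fisher_z_compare(cc$r[1], cc$n[1], cc$r[2], cc$n[2])
      tibble::tibble(level = cc$level[1], group1 = cc$group[1],
        group2 = cc$group[2], r1 = fzc$r1, n1 = fzc$n1, r2 = fzc$r2,
        n2 = fzc$n2, z = fzc$z, p = fzc$p)
    }))
    slopes <- dplyr::bind_rows(lapply(
      list(stimulus = stim, agent = agent), function(pts) {
        sd_ <- slope_difference(pts)
        tibble::tibble(
          group1 = sd_$groups[1], group2 = sd_$groups[2],
          beta1 = sd_$beta_per_group[1], beta2 = sd_$beta_per_group[2],
          delta_beta = sd_$delta_beta, t = sd_$t, df = sd_$df, p = sd_$p,
          degenerate = sd_$degenerate)
      }), .id = "level")
    list(stim = stim, agent = agent, cors = cors, fisher_z = fz,
      slopes = slopes)
  })
  if (!is.null(assoc)) {
    tables$correlations <- assoc$cors
    tables$fisher_z <- assoc$fisher_z
    tables$slopes <- assoc$slopes
    files["fig1_stimulus_points"] <- write_stage_csv(
      tibble::as_tibble(assoc$stim), config$out_dir,
      "fig1_stimulus_points.csv")
    files["fig1_agent_points"] <- write_stage_csv(
      tibble::as_tibble(assoc$agent), config$out_dir,
      "fig1_agent_points.csv")
    files["correlations"] <- write_stage_csv(assoc$cors, config$out_dir,
      "correlations.csv")
    if (nrow(assoc$fisher_z) > 0) {
      files["fisher_z"] <- write_stage_csv(assoc$fisher_z, config$out_dir,
        "fisher_z.csv")
    }
    files["slopes"] <- write_stage_csv(assoc$slopes, config$out_dir,
      "slopes.csv")
  }

  # -- mixed ANOVAs on accuracy and confidence ------------------------------
  per_cond <- dplyr::filter(tables$agent_summaries, .data$condition != "All")
  for (dv in c("correct_rate", "mean_confidence")) {
    stage <- paste0("anova_", dv)
    res <- try_stage(stage, {
      an <- mixed_anova(per_cond, dv = dv, subject = "agent_id",
        between = "agent_group", within = "condition", gg = config$gg)
      ph_cond <- dplyr::bind_rows(lapply(
        split(per_cond, per_cond$agent_group), function(sub) {
          dplyr::mutate(
            bonferroni_pairwise(sub, dv, "condition",
              subject = "agent_id"),
            agent_group = sub$agent_group[1], .before = 1)
        }))
      ph_group <- dplyr::bind_rows(lapply(
        split(per_cond, per_cond$condition), function(sub) {
          dplyr::mutate(
            bonferroni_pairwise(sub, dv, "agent_group"),
            condition = sub$condition[1], .before = 1)
        }))
      list(anova = an, posthoc_condition = ph_cond,
        posthoc_agent = ph_group)
    })
    if (!is.null(res)) {
      tables[[stage]] <- res$anova
      files[stage] <- write_stage_csv(res$anova, config$out_dir,
        paste0(stage, ".csv"))
      files[paste0("posthoc_condition_", dv)] <- write_stage_csv(
        res$posthoc_condition, config$out_dir,
        paste0("posthoc_condition_", dv, ".csv"))
      files[paste0("posthoc_agent_", dv)] <- write_stage_csv(
        res$posthoc_agent, config$out_dir,
        paste0("posthoc_agent_", dv, ".csv"))
    }
  }

  # -- confidence by correctness x condition (three-way) --------------------
  res3 <- try_stage("anova_confidence_correctness", {
    cc <- tibble::as_tibble(trials) |>
      dplyr::group_by(.data$agent_id, .data$agent_group, .data$condition,
        .data$correct) |>
      dplyr::summarise(mean_confidence = mean(.data$confidence),
        .groups = "drop")
    n_cells <- length(unique(cc$condition)) * 2
    complete <- cc |>
      dplyr::count(.data$agent_id) |>
      dplyr::filter(.data$n == n_cells)
    cc_complete <- dplyr::semi_join(cc, complete, by = "agent_id")
    n_dropped <- length(unique(cc$agent_id)) - nrow(complete)
    an <- mixed_anova(cc_complete, dv = "mean_confidence",
      subject = "agent_id", between = "agent_group",
      within = c("correct", "condition"), gg = config$gg)
    list(anova = an, cells = cc, n_dropped = n_dropped)
  })
  if (!is.null(res3)) {
    tables$anova_confidence_correctness <- res3$anova
    tables$confidence_by_correctness <- res3$cells
    tables$n_agents_dropped_three_way <- res3$n_dropped
    files["confidence_by_correctness"] <- write_stage_csv(res3$cells,
      config$out_dir, "confidence_by_correctness.csv")
    files["anova_confidence_correctness"] <- write_stage_csv(res3$anova,
      config$out_dir, "anova_confidence_correctness.csv")
  }

  # -- metacognition metrics ------------------------------------------------
  metrics <- tryCatch(agent_metric_table(trials),
    error = function(e) stage_abort("metrics", e))
  tables$agent_metrics <- metrics
  tables$group_summary <- group_metric_summary(metrics)
  files["auroc_by_agent"] <- write_stage_csv(
    dplyr::select(metrics, "agent_id", "agent_group", "condition",
      "n_trials", "auroc"),
    config$out_dir, "auroc_by_agent.csv")
  files["meta_j_by_agent"] <- write_stage_csv(
    dplyr::select(metrics, "agent_id", "agent_group", "condition",
      "n_trials", "meta_j", "threshold", "accuracy_entropy", "meta_j2r"),
    config$out_dir, "meta_j_by_agent.csv")
  files["group_summary"] <- write_stage_csv(tables$group_summary,
    config$out_dir, "group_summary.csv")

  for (dv in c("auroc", "meta_j", "meta_j2r")) {
    stage <- paste0("anova_", dv)
    res <- try_stage(stage, {
      dat <- metrics |>
        dplyr::filter(.data$condition != "All") |>
        dplyr::select("agent_id", "agent_group", "condition",
          dplyr::all_of(dv))
      defined <- dat[!is.na(dat[[dv]]), ]
      n_cond <- length(unique(defined$condition))
      keep <- defined |>
        dplyr::count(.data$agent_id) |>
        dplyr::filter(.data$n == n_cond)
      dat_complete <- dplyr::semi_join(defined, keep, by = "agent_id")
      mixed_anova(dat_complete, dv = dv, subject = "agent_id",
        between = "agent_group", within = "condition", gg = config$gg)
    })
    if (!is.null(res)) {
      tables[[stage]] <- res
      files[stage] <- write_stage_csv(res, config$out_dir,
        paste0(stage, ".csv"))
    }
  }

  # -- folded X-pattern -----------------------------------------------------
  fx <- try_stage("folded_x", folded_x_table(trials))
  if (!is.null(fx)) {
    tables$folded_x <- fx
    files["folded_x"] <- write_stage_csv(fx, config$out_dir,
      "folded_x.csv")
  }

  # -- manifest -------------------------------------------------------------
  digests <- tools::md5sum(unname(files))
  manifest <- list(
    package = "metasense",
    version = as.character(utils::packageVersion("metasense")),
    seed = if (!is.null(config$sim)) config$sim$seed else config$seed,
    agent_aggregation = config$agent_aggregation,
    gg = config$gg,
    skipped = as.list(skipped),
    files = stats::setNames(as.list(unname(digests)),
      basename(unname(files)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  files["manifest"] <- manifest_path

  structure(
    list(tables = tables, files = files, skipped = skipped,
      manifest = manifest, config = config),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  output:", x$config$out_dir, "\n")
  cat("  files:", length(x$files), "\n")
  if (length(x$skipped) > 0) {
    cat("  skipped stages:", paste(names(x$skipped), collapse = ", "),
      "\n")
  }
  invisible(x)
}
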