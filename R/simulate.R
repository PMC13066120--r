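#' Generative parameters for one agent group
#'
#' The simulator couples accuracy and confidence through a latent
#' signal-detection-style discriminability `d`. An agent's confidence is a
#' linear readout of a metacognitive signal `r`: on correct trials
#' `r = d + noise`, on incorrect trials `r = error_offset - error_slope * d
#' + noise`, which builds the folded X-pattern in by construction (correct
#' confidence rises with `d`, error confidence falls with `d`).
#'
#' @param ability_mean,ability_sd Mean and SD of the Normal distribution of
#'   agent ability on the latent evidence scale (`ability_sd >= 0`).
#' @param conf_bias Confidence offset `B` on the 0-100 rating scale: the
#'   rating an agent with `r = 0` would give.
#' @param conf_scale Confidence gain `S >= 0`: rating points per unit of
#'   metacognitive signal.
#' @param meta_noise SD of the metacognitive readout noise (`>= 0`, latent
#'   units). Large values decouple confidence from accuracy.
#' @param error_slope Slope `gamma` of the incorrect-trial readout: how
#'   steeply error confidence falls as discriminability grows.
#' @param error_offset Intercept `d0` of the incorrect-trial readout.
#' @param round_to_integers Round ratings to whole percent? Default `TRUE`,
#'   matching 0-100 ratings as humans report them (and exercising
#'   tie-handling downstream).
#' @param conf_source `"readout"` (default) derives confidence from `r`;
#'   `"independent"` draws confidence from the bias/scale/noise parameters
#'   while ignoring `r` entirely, so confidence carries no information
#'   about accuracy.
#' @return An object of class `agent_profile`.
#' @seealso [make_profile()] for documented presets.
#' @export
agent_profile <- function(ability_mean = 1, ability_sd = 0.3,
                          conf_bias = 40, conf_scale = 30,
                          meta_noise = 0.4, error_slope = 0.6,
                          error_offset = 0.55, round_to_integers = TRUE,
                          conf_source = c("readout", "independent")) {
  conf_source <- match.arg(conf_source)
  if (ability_sd < 0 || conf_scale < 0 || meta_noise < 0) {
    rlang::abort("ability_sd, conf_scale and meta_noise must be >= 0",
      class = "metasense_parameter_error")
  }
  structure(
    list(
      ability_mean = ability_mean, ability_sd = ability_sd,
      conf_bias = conf_bias, conf_scale = conf_scale,
      meta_noise = meta_noise, error_slope = error_slope,
      error_offset = error_offset,
      round_to_integers = isTRUE(round_to_integers),
      conf_source = conf_source
    ),
    class = "agent_profile"
  )
}

#' Preset agent profiles
#'
#' Four documented parameter sets:
#' \describe{
#'   \item{`human_like`}{Graded, difficulty-tracking confidence: moderate
#'     bias, large gain, small metacognitive noise. Mean ratings sit in the
#'     60s-70s and spread widely.}
#'   \item{`llm_like`}{Compressed, weakly coupled confidence near the
#'     ceiling: high bias (about 90), small gain, large metacognitive
#'     noise, plus higher ability. Emulates an agent whose confidence stays
#'     uniformly high regardless of difficulty.}
#'   \item{`oracle`}{Zero metacognitive noise and an error readout strictly
#'     below the correct readout, so correct and incorrect confidences
#'     never overlap and Type-2 AUROC is exactly 1 whenever both response
#'     classes occur.}
#'   \item{`independent`}{Confidence drawn ignoring the metacognitive
#'     signal; accuracy and confidence are statistically independent.}
#' }
#'
#' @param name One of `"human_like"`, `"llm_like"`, `"oracle"`,
#'   `"independent"`.
#' @return An [agent_profile()].
#' @export
#' @examples
#' make_profile("human_like")
make_profile <- function(name) {
  switch(name,
    human_like = agent_profile(
      ability_mean = 0.9, ability_sd = 0.35,
      conf_bias = 40, conf_scale = 30,
      meta_noise = 0.35, error_slope = 0.6, error_offset = 0.55
    ),
    llm_like = agent_profile(
      ability_mean = 1.8, ability_sd = 0.25,
      conf_bias = 92, conf_scale = 6,
      meta_noise = 2, error_slope = 0.3, error_offset = 0.5
    ),
    oracle = agent_profile(
      ability_mean = 1, ability_sd = 0.3,
      conf_bias = 50, conf_scale = 35,
      meta_noise = 0, error_slope = 0.5, error_offset = -0.2
    ),
    independent = agent_profile(
      ability_mean = 1, ability_sd = 0.3,
      conf_bias = 50, conf_scale = 20,
      meta_noise = 1, error_slope = 0, error_offset = 0,
      conf_source = "independent"
    ),
    rlang::abort(paste0("unknown profile preset: ", name),
      class = "metasense_lookup_error")
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the study layout the package is designed around:
#' two agent groups of 87 agents each, 60 items split evenly over the
#' three answering conditions (2C, 4C, OP with chance levels 0.5, 0.25
#' and 0).
#'
#' @param n_agents_per_group Agents per group (>= 1). Default 87.
#' @param n_items_per_condition Items per condition (>= 1). Default 20.
#' @param chance_map Condition labels and chance levels; default
#'   [default_chance_map()].
#' @param difficulty_sd SD of item difficulty on the latent scale (>= 0).
#' @param trial_noise SD of trial-to-trial evidence noise (>= 0).
#' @param accuracy_rate Rate `lambda > 0` of the saturating mapping from
#'   discriminability to above-chance success probability,
#'   `P(correct) = g + (1 - g) * (1 - exp(-lambda * d))`.
#' @param profiles Named list of [agent_profile()] objects, one per agent
#'   group; the names become the `agent_group` labels.
#' @param seed Integer master seed; the per-agent substreams are derived
#'   from it deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents_per_group = 87, n_items_per_condition = 20,
                       chance_map = default_chance_map(),
                       difficulty_sd = 0.5, trial_noise = 0.3,
                       accuracy_rate = 1.1,
                       profiles = list(
                         human = make_profile("human_like"),
                         gpt4 = make_profile("llm_like")
                       ),
                       seed = 1L) {
  validate_chance_map(chance_map)
  if (n_agents_per_group < 1 || n_items_per_condition < 1) {
    rlang::abort("counts must be >= 1", class = "metasense_parameter_error")
  }
  if (difficulty_sd < 0 || trial_noise < 0) {
    rlang::abort("noise scales must be >= 0",
      class = "metasense_parameter_error")
  }
  if (accuracy_rate <= 0) {
    rlang::abort("accuracy_rate must be > 0",
      class = "metasense_parameter_error")
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    rlang::abort("profiles must be a named list",
      class = "metasense_parameter_error")
  }
  for (p in profiles) {
    if (!inherits(p, "agent_profile")) {
      rlang::abort("every profile must be an agent_profile",
        class = "metasense_parameter_error")
    }
  }
  structure(
    list(
      n_agents_per_group = as.integer(n_agents_per_group),
      n_items_per_condition = as.integer(n_items_per_condition),
      chance_map = chance_map,
      difficulty_sd = difficulty_sd,
      trial_noise = trial_noise,
      accuracy_rate = accuracy_rate,
      profiles = profiles,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

clamp01_100 <- function(x) pmin(100, pmax(0, x))

#' Generate a synthetic cohort of confidence-judgement trials
#'
#' Per trial (agent `i`, item `j`, condition with chance level `g`):
#' ability `a_i ~ N(ability_mean, ability_sd)`, difficulty
#' `b_j ~ N(0, difficulty_sd)`, effective discriminability
#' `d_ij = max(0, a_i - b_j + e1)` with `e1 ~ N(0, trial_noise)`;
#' `P(correct) = g + (1 - g) * (1 - exp(-lambda * d_ij))`; the
#' metacognitive readout is `r_ij = d_ij + e2` on correct trials and
#' `r_ij = error_offset - error_slope * d_ij + e2` on incorrect trials with
#' `e2 ~ N(0, meta_noise)`; confidence is `clamp(0, 100, B + S * r_ij)`,
#' optionally rounded to integers. Item difficulties are drawn once and
#' shared across groups (both groups answer the same questions).
#'
#' The output is deterministic given the config seed: a master stream seeds
#' the item difficulties and derives one substream per agent.
#'
#' @param config A [sim_config()].
#' @return A [trial_table()] with `n_groups * n_agents_per_group *
#'   n_conditions * n_items_per_condition` rows.
#' @export
#' @examples
#' cfg <- sim_config(n_agents_per_group = 3, n_items_per_condition = 4)
#' generate_cohort(cfg)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("config must be a sim_config",
      class = "metasense_parameter_error")
  }
  conds <- names(config$chance_map)
  m <- config$n_items_per_condition
  n <- config$n_agents_per_group
  groups <- names(config$profiles)

  set.seed(config$seed)
  items <- tibble::tibble(
    condition = rep(conds, each = m),
    item_id = paste0(rep(conds, each = m), "_item",
      sprintf("%02d", rep(seq_len(m), times = length(conds)))),
    difficulty = stats::rnorm(length(conds) * m, 0, config$difficulty_sd),
    chance = rep(unname(config$chance_map), each = m)
  )
  # one deterministic substream per agent, derived from the master stream
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n * length(groups))

  n_trial <- nrow(items)
  out <- vector("list", n * length(groups))
  k <- 0L
  for (gi in seq_along(groups)) {
    prof <- config$profiles[[gi]]
    for (i in seq_len(n)) {
      k <- k + 1L
      set.seed(agent_seeds[k])
      a <- stats::rnorm(1, prof$ability_mean, prof$ability_sd)
      e1 <- stats::rnorm(n_trial, 0, config$trial_noise)
      d <- pmax(0, a - items$difficulty + e1)
      p_corr <- items$chance +
        (1 - items$chance) * (1 - exp(-config$accuracy_rate * d))
      correct <- stats::rbinom(n_trial, 1L, p_corr)
      e2 <- stats::rnorm(n_trial, 0, prof$meta_noise)
      r <- ifelse(correct == 1L, d + e2,
        prof$error_offset - prof$error_slope * d + e2)
      raw <- if (prof$conf_source == "independent") {
        prof$conf_bias + prof$conf_scale * e2
      } else {
        prof$conf_bias + prof$conf_scale * r
      }
      conf <- clamp01_100(raw)
      if (prof$round_to_integers) conf <- round(conf)
      out[[k]] <- tibble::tibble(
        agent_id = sprintf("%s_%03d", groups[gi], i),
        agent_group = groups[gi],
        condition = items$condition,
        item_id = items$item_id,
        correct = correct,
        confidence = conf
      )
    }
  }
  trial_table(dplyr::bind_rows(out), chance_map = config$chance_map)
}
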