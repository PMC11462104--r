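#' Run the full cohort analytics pipeline
#'
#' Orchestrates the whole workflow on one cohort: read (or simulate) the
#' episode table, build Markov trajectories, count transitions, estimate the
#' jump-probability and generator matrices, compute descriptive statistics
#' (transition-time summaries, first-episode distribution, death
#' attribution), and evaluate the progression pattern for every
#' non-absorbing start state. Optionally writes every table to `out_dir`.
#'
#' @param config Either a path to a YAML configuration file or a named list
#'   with sections:
#' \describe{
#'   \item{input}{`episodes` (path to a delimited episode file) and
#'     optionally `delimiter`; \emph{or} `scenario` (path to a YAML
#'     simulation scenario, see [read_scenario()]).}
#'   \item{states}{`absorbing` (labels, default `"Death"`),
#'     `min_count` (pruning threshold, required), `prune_policy`.}
#'   \item{estimator}{`mode`: `"paper"` or `"mle"`.}
#'   \item{prediction}{`interval_days` (default 90), `horizon_days`
#'     (default 1800).}
#'   \item{output}{`scale` (`"fraction"`/`"percent"`), `layout`
#'     (`"wide"`/`"long"`).}
#' }
#' @param out_dir Optional output directory for exported tables.
#' @param seed Seed forwarded to a simulation scenario input.
#' @return An object of class `analysis_bundle`: list with `state_space`,
#'   `trajectories`, `counts`, `jump_probabilities`, `generator`,
#'   `transition_times`, `first_episodes`, `death_attribution`,
#'   `progression` (named list of `progression_pattern` per start state) and
#'   `provenance` (config snapshot, input digest, seed) — enough to re-run
#'   the analysis bit-identically.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- load_config(config)
  required_key(cfg, "states", "min_count")
  absorbing <- cfg$states$absorbing %||% "Death"
  mode <- cfg$estimator$mode %||% "paper"
  interval <- cfg$prediction$interval_days %||% 90
  horizon <- cfg$prediction$horizon_days %||% 1800

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  input <- cfg$input %||% abort("config section 'input' is missing")
  episodes <- stage("episode_io", {
    if (!is.null(input$episodes)) {
      read_episodes(input$episodes, delim = input$delimiter %||% ",")
    } else if (!is.null(input$scenario)) {
      sc <- read_scenario(input$scenario)
      if (!is.null(seed)) sc$seed <- as.integer(seed)
      roughen_episodes(simulate_cohort(sc), sc)
    } else {
      abort("config must name input$episodes or input$scenario")
    }
  })
  inform(sprintf("episode_io: %d records, %d patients",
                 nrow(episodes), dplyr::n_distinct(episodes$patient_id)))

  built <- stage("state_builder",
                 build_trajectories(episodes, naming = cfg_naming(cfg),
                                    min_count = cfg$states$min_count,
                                    absorbing_labels = absorbing,
                                    prune_policy = cfg$states$prune_policy %||% "drop_records"))
  traj <- built$trajectories
  sp <- built$state_space
  inform(sprintf("state_builder: %d visits, %d patients, %d states",
                 nrow(traj), dplyr::n_distinct(traj$patient_id), length(sp$states)))

  counts <- stage("ctmc_core", count_transitions(traj, sp))
  jp <- stage("ctmc_core", jump_probability_matrix(counts))
  gen <- stage("ctmc_core", estimate_generator(counts, mode = mode))
  tts <- stage("ctmc_core", transition_time_stats(counts))
  fed <- stage("ctmc_core", first_episode_distribution(traj))
  datt <- stage("ctmc_core", {
    if (length(absorbing) > 0 && absorbing[1] %in% sp$states &&
        any(counts$N[, absorbing[1]] > 0)) {
      death_attribution(counts, absorbing[1])
    } else NULL
  })
  inform(sprintf("ctmc_core: %d transitions observed", sum(counts$N)))

  starts <- setdiff(sp$states, sp$absorbing)
  progression <- stage("ctmc_predict", {
    out <- lapply(starts, function(s) progression_series(gen, s, interval, horizon))
    setNames(out, starts)
  })

  bundle <- structure(
    list(state_space = sp, trajectories = traj, counts = counts,
         jump_probabilities = jp, generator = gen,
         transition_times = tts, first_episodes = fed,
         death_attribution = datt, progression = progression,
         provenance = list(config = cfg, seed = seed,
                           input_digest = input_digest(input, episodes),
                           n_records = nrow(episodes))),
    class = "analysis_bundle")
  if (!is.null(out_dir)) {
    export_matrix_tables(bundle, out_dir = out_dir,
                         scale = cfg$output$scale %||% "fraction",
                         layout = cfg$output$layout %||% "long")
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("Analysis bundle: %d states, %d patients, %d transitions (%s-mode generator)\n",
              length(x$state_space$states),
              dplyr::n_distinct(x$trajectories$patient_id),
              sum(x$counts$N), x$generator$mode))
  invisible(x)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file path or a named list")
  config
}

required_key <- function(cfg, section, key) {
  if (is.null(cfg[[section]]) || is.null(cfg[[section]][[key]])) {
    abort(sprintf("config key '%s$%s' is required", section, key))
  }
}

cfg_naming <- function(cfg) {
  nm <- cfg$states$naming
  if (is.null(nm)) return(cvd_naming())
  naming_scheme(components = unlist(nm$components),
                singletons = if (!is.null(nm$singletons)) unlist(nm$singletons),
                special = nm$special %||% character(),
                state_order = nm$state_order)
}

input_digest <- function(input, episodes) {
  if (!is.null(input$episodes) && file.exists(input$episodes)) {
    unname(tools::md5sum(input$episodes))
  } else {
    f <- tempfile(); on.exit(unlink(f))
    write_episodes(episodes, f)
    unname(tools::md5sum(f))
  }
}

#' Read a simulation scenario file
#'
#' A scenario is a YAML file with the true generator and cohort settings:
#' `states` (labels), `absorbing`, `rates` (list of `from`, `to`,
#' `per_day`), `initial_distribution` (named), `n_patients`,
#' `max_followup_days`, `seed`, and the roughening flags
#' `decompose_composites` and `duplicate_rate`.
#'
#' @param path Scenario YAML path.
#' @return A [simulation_config()].
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  st <- unlist(sc$states)
  Q <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (r in sc$rates) Q[r$from, r$to] <- r$per_day
  diag(Q) <- -rowSums(Q)
  Q[unlist(sc$absorbing), ] <- 0
  gen <- new_generator_matrix(Q, state_space(st, unlist(sc$absorbing)))
  simulation_config(
    generator = gen,
    initial_distribution = unlist(sc$initial_distribution),
    n_patients = sc$n_patients,
    max_followup_days = sc$max_followup_days %||% 5800,
    seed = sc$seed %||% 1L,
    decompose_composites = isTRUE(sc$decompose_composites),
    duplicate_rate = sc$duplicate_rate %||% 0)
}

#' Read a labelled matrix from delimited text
#'
#' Companion to [export_matrix_tables()] and to packaged count fixtures: the
#' first column (`state`) holds row labels, remaining columns are states.
#'
#' @param path CSV path.
#' @return A numeric matrix with state dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}

#' Stratified cohort comparison
#'
#' Partitions the cohort by a patient-constant covariate (for example sex),
#' runs the full pipeline per stratum over a shared state space (the union
#' of the strata's states, so the matrices are comparable cell-for-cell),
#' and tabulates the difference in progression probabilities between the
#' first two strata at every grid time and destination state.
#'
#' @param config Pipeline config (file or list); the input must be an
#'   episode file whose records carry the covariate on every row.
#' @param stratum_covariate Covariate column name to partition on.
#' @return A list of class `stratified_comparison`: `bundles` (named list of
#'   `analysis_bundle` per stratum value), `difference` (tibble
#'   `start_state`, `time_days`, `to_state`, and one probability column per
#'   stratum plus `difference` = first - second; empty with fewer than two
#'   strata) and `strata` (tibble of per-stratum patient/record counts).
#' @export
stratified_compare <- function(config, stratum_covariate) {
  cfg <- load_config(config)
  required_key(cfg, "states", "min_count")
  if (is.null(cfg$input$episodes)) abort("stratified comparison needs input$episodes")
  episodes <- read_episodes(cfg$input$episodes, delim = cfg$input$delimiter %||% ",")
  if (!stratum_covariate %in% names(episodes)) {
    abort(sprintf("covariate '%s' not present in the episode table", stratum_covariate))
  }
  if (any(is.na(episodes[[stratum_covariate]]))) {
    abort(sprintf("covariate '%s' missing on some records", stratum_covariate))
  }
  per_patient <- as_tibble(episodes) |>
    group_by(.data$patient_id) |>
    summarise(n_values = dplyr::n_distinct(.data[[stratum_covariate]]), .groups = "drop")
  if (any(per_patient$n_values > 1L)) {
    abort(sprintf("covariate '%s' is not constant within every patient", stratum_covariate))
  }

  values <- sort(unique(episodes[[stratum_covariate]]))
  # shared state space: build over the whole cohort once
  naming <- cfg_naming(cfg)
  absorbing <- cfg$states$absorbing %||% "Death"
  full <- build_trajectories(episodes, naming, cfg$states$min_count, absorbing,
                             cfg$states$prune_policy %||% "drop_records")
  shared_sp <- full$state_space
  mode <- cfg$estimator$mode %||% "paper"
  interval <- cfg$prediction$interval_days %||% 90
  horizon <- cfg$prediction$horizon_days %||% 1800

  bundles <- lapply(values, function(v) {
    sub <- as_tibble(episodes)[episodes[[stratum_covariate]] == v, , drop = FALSE]
    sub <- new_episode_tbl(sub, covariates = episode_covariates(episodes))
    built <- build_trajectories(sub, naming, cfg$states$min_count, absorbing,
                                cfg$states$prune_policy %||% "drop_records")
    traj <- built$trajectories
    counts <- count_transitions(traj, shared_sp)
    gen <- estimate_generator(counts, mode)
    starts <- setdiff(shared_sp$states, shared_sp$absorbing)
    progression <- setNames(
      lapply(starts, function(s) progression_series(gen, s, interval, horizon)),
      starts)
    structure(list(state_space = shared_sp, trajectories = traj, counts = counts,
                   jump_probabilities = jump_probability_matrix(counts),
                   generator = gen,
                   transition_times = transition_time_stats(counts),
                   first_episodes = first_episode_distribution(traj),
                   death_attribution = NULL,
                   progression = progression,
                   provenance = list(config = cfg, stratum = v)),
              class = "analysis_bundle")
  })
  names(bundles) <- values

  strata <- tibble(
    stratum = values,
    n_patients = unname(map_int(bundles, ~ dplyr::n_distinct(.x$trajectories$patient_id))),
    n_records = map_int(values, ~ sum(episodes[[stratum_covariate]] == .x)))

  difference <- if (length(values) >= 2L) {
    a <- values[1]; b <- values[2]
    long <- function(bnd, nm) {
      bind_rows(imap(bnd$progression, function(pp, s) {
        mutate(as_tibble(pp), start_state = s)
      })) |> rename(!!nm := "probability")
    }
    dplyr::full_join(long(bundles[[a]], paste0("p_", a)),
                     long(bundles[[b]], paste0("p_", b)),
                     by = c("start_state", "time_days", "to_state")) |>
      mutate(difference = .data[[paste0("p_", a)]] - .data[[paste0("p_", b)]]) |>
      select("start_state", "time_days", "to_state", dplyr::everything())
  } else {
    tibble(start_state = character(), time_days = numeric(),
           to_state = character(), difference = numeric())
  }

  structure(list(bundles = bundles, difference = difference, strata = strata),
            class = "stratified_comparison")
}

#' @importFrom purrr map_int imap
#' @export
print.stratified_comparison <- function(x, ...) {
  cat("Stratified comparison\n")
  print(x$strata)
  invisible(x)
}

#' Export bundle matrices and tables to delimited text
#'
#' Writes every matrix and statistics table in an [run_pipeline()] bundle to
#' CSV files. On the percent scale values are multiplied by 100 and rounded
#' half-up to one decimal, the convention used in published transition
#' tables; the fraction scale writes full precision. Progression patterns
#' are written long (`start_state`, `time_days`, `to_state`, `probability`)
#' or wide (one states-by-states heat-map block per grid time).
#'
#' @param bundle An `analysis_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param scale `"fraction"` or `"percent"`.
#' @param layout `"wide"` or `"long"` for progression tables.
#' @return Invisibly, the character vector of files written.
#' @export
export_matrix_tables <- function(bundle, out_dir, scale = c("fraction", "percent"),
                                 layout = c("long", "wide")) {
  scale <- match.arg(scale)
  layout <- match.arg(layout)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fmt <- function(M) {
    if (scale == "percent") round_half_up(M * 100, 1) else M
  }
  put_matrix <- function(M, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    df <- as_tibble(as.data.frame(M), rownames = "state")
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  put_tbl <- function(tb, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tb, path)
    written <<- c(written, path)
  }

  put_matrix(bundle$counts$N, "jump_frequency")
  put_matrix(fmt(bundle$jump_probabilities), "jump_probability")
  put_matrix(bundle$generator$Q, "generator")
  put_tbl(bundle$transition_times, "transition_time_stats")
  put_tbl(bundle$first_episodes, "first_episode_distribution")
  if (!is.null(bundle$death_attribution)) {
    put_tbl(bundle$death_attribution$by_state, "death_attribution")
  }
  for (s in names(bundle$progression)) {
    pp <- as_tibble(bundle$progression[[s]])
    safe <- gsub("[^A-Za-z0-9]+", "_", s)
    if (layout == "long") {
      out <- mutate(pp, start_state = s,
                    probability = if (scale == "percent")
                      round_half_up(.data$probability * 100, 1) else .data$probability)
      put_tbl(out[, c("start_state", "time_days", "to_state", "probability")],
              paste0("progression_", safe))
    } else {
      wide <- tidyr::pivot_wider(pp, names_from = "to_state",
                                 values_from = "probability")
      num <- setdiff(names(wide), "time_days")
      if (scale == "percent") {
        wide[num] <- lapply(wide[num], function(v) round_half_up(v * 100, 1))
      }
      put_tbl(wide, paste0("progression_", safe))
    }
  }
  invisible(written)
}
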