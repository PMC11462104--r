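#' Simulation configuration for a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs to generate a reproducible
#' synthetic episodic cohort from a known generator matrix, and the realism
#' controls [roughen_episodes()] uses to re-introduce the raw-data
#' pathologies (same-day multimorbidity rows, consecutive duplicate
#' episodes) that trajectory preprocessing exists to handle.
#'
#' @param generator The true `generator_matrix` to simulate from.
#' @param initial_distribution Named or state-ordered probability vector over
#'   non-absorbing states (mass on an absorbing state is an error).
#' @param n_patients Number of patients (>= 1).
#' @param max_followup_days Follow-up span in days; transitions scheduled
#'   past it are not observed. Default 5800 days, a ~16-year cohort window.
#' @param seed Integer seed; the simulated table is a pure function of the
#'   config.
#' @param decompose_composites Should [roughen_episodes()] split composite
#'   states into their component episode rows on the same day?
#' @param duplicate_rate Per-visit probability that [roughen_episodes()]
#'   injects a duplicate same-state row inside the holding interval.
#' @param round_days Round entry times up to whole days (with a 1-day
#'   minimum hold), as registry data records whole days? Default `TRUE`.
#' @param naming The [naming_scheme()] whose composites
#'   [roughen_episodes()] may decompose.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(generator, initial_distribution, n_patients,
                              max_followup_days = 5800, seed = 1L,
                              decompose_composites = FALSE, duplicate_rate = 0,
                              round_days = TRUE, naming = cvd_naming()) {
  stopifnot(inherits(generator, "generator_matrix"))
  st <- generator$state_space$states
  if (!is.null(names(initial_distribution))) {
    full <- setNames(numeric(length(st)), st)
    full[names(initial_distribution)] <- initial_distribution
    initial_distribution <- full
  }
  if (length(initial_distribution) != length(st)) {
    abort("'initial_distribution' length must equal the number of states")
  }
  if (any(initial_distribution < 0) || abs(sum(initial_distribution) - 1) > 1e-9) {
    abort("'initial_distribution' must be nonnegative and sum to 1")
  }
  if (any(initial_distribution[st %in% generator$state_space$absorbing] > 0)) {
    abort("initial distribution places mass on an absorbing state")
  }
  if (n_patients < 1) abort("'n_patients' must be >= 1")
  if (duplicate_rate < 0 || duplicate_rate > 1) abort("'duplicate_rate' must be in [0, 1]")
  structure(list(generator = generator,
                 initial_distribution = setNames(initial_distribution, st),
                 n_patients = as.integer(n_patients),
                 max_followup_days = max_followup_days,
                 seed = as.integer(seed),
                 decompose_composites = isTRUE(decompose_composites),
                 duplicate_rate = duplicate_rate,
                 round_days = isTRUE(round_days),
                 naming = naming),
            class = "simulation_config")
}

#' Simulate an episodic cohort from a known generator
#'
#' Gillespie-style simulation of the continuous-time Markov chain: each
#' patient starts at day 0 in a state drawn from the initial distribution,
#' holds in state i for an Exponential(lambda_i) time with lambda_i = -q_ii,
#' then jumps to j with the embedded-chain probability q_ij / lambda_i, and
#' repeats until absorption or the end of follow-up. One episode row is
#' emitted per entered state at its (integer, when `round_days`) entry day;
#' entry days are forced strictly increasing with at least one day between
#' visits, so the output already satisfies the trajectory invariants.
#'
#' A non-absorbing state with zero exit rate freezes the patient there until
#' follow-up end (with a warning); this is a degenerate configuration, not
#' an error.
#'
#' @param config A [simulation_config()].
#' @return An `episode_tbl` (columns `patient_id`, `episode`, `day`), fully
#'   reproducible from the config's seed.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gen <- config$generator
  st <- gen$state_space$states
  Q <- gen$Q
  exit <- -diag(Q)
  absorbing <- st %in% gen$state_space$absorbing
  frozen <- which(!absorbing & exit <= 0)
  if (length(frozen) > 0L) {
    warn(paste0("non-absorbing state(s) with zero exit rate; patients freeze there: ",
                paste(st[frozen], collapse = ", ")))
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    code
  }
  id_width <- nchar(as.character(config$n_patients))
  rows <- withr_seed({
    lapply(seq_len(config$n_patients), function(p) {
      pid <- sprintf("S%0*d", id_width, p)
      i <- sample.int(length(st), 1L, prob = config$initial_distribution)
      t_now <- 0
      day_now <- 0L
      states <- st[i]; days <- 0L
      repeat {
        if (absorbing[i] || exit[i] <= 0) break
        wait <- rexp(1L, rate = exit[i])
        t_next <- t_now + wait
        if (t_next > config$max_followup_days) break
        p_jump <- Q[i, ] / exit[i]
        p_jump[i] <- 0
        j <- sample.int(length(st), 1L, prob = p_jump)
        day_next <- if (config$round_days) max(day_now + 1L, as.integer(ceiling(t_next))) else t_next
        states <- c(states, st[j]); days <- c(days, day_next)
        i <- j; t_now <- t_next; day_now <- day_next
      }
      tibble(patient_id = pid, episode = states, day = as.integer(days))
    })
  })
  new_episode_tbl(bind_rows(rows), source = "simulate_cohort", covariates = character())
}

#' Re-introduce raw-registry pathologies into a simulated cohort
#'
#' Simulated cohorts are "clean": one row per entered state. Real episodic
#' registries are not — simultaneous multimorbidity episodes appear as
#' several same-day rows, and the same ongoing condition is often reported
#' again a few days later. This transform re-creates both pathologies so the
#' preprocessing rules can be exercised end-to-end: with
#' `decompose_composites`, every composite-state row is replaced by its
#' component episode rows on the same day (which
#' [compose_same_day_states()] recomposes exactly); with positive
#' `duplicate_rate`, visits gain a duplicate same-state row strictly inside
#' the holding interval (which [merge_consecutive_runs()] removes exactly).
#' `build_trajectories()` applied to the roughened table therefore recovers
#' the pre-roughening trajectories.
#'
#' @param table An `episode_tbl` from [simulate_cohort()].
#' @param config The same [simulation_config()] (supplies the naming scheme,
#'   flags and seed).
#' @return A roughened `episode_tbl`.
#' @export
roughen_episodes <- function(table, config) {
  stopifnot(inherits(config, "simulation_config"))
  df <- as_tibble(table)
  naming <- config$naming

  if (config$decompose_composites) {
    # invert the composite naming: CHANMI -> CH, AN, MI component labels
    codes <- naming$components
    composite_members <- function(state) {
      if (state %in% naming$special || state %in% unname(naming$singletons)) return(NULL)
      remaining <- state; members <- character()
      for (lab in names(codes)) {   # codes listed in composition order
        code <- codes[[lab]]
        if (startsWith(remaining, code)) {
          members <- c(members, lab)
          remaining <- substring(remaining, nchar(code) + 1L)
        }
      }
      if (nchar(remaining) > 0L || length(members) < 2L) return(NULL)
      members
    }
    df <- df |>
      mutate(.row = dplyr::row_number()) |>
      group_by(.data$.row) |>
      dplyr::reframe(patient_id = .data$patient_id,
                     episode = composite_members(.data$episode) %||% .data$episode,
                     day = .data$day) |>
      select(-".row")
  }

  if (config$duplicate_rate > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed + 1L)
    extra <- as_tibble(table) |>
      group_by(.data$patient_id) |>
      arrange(.data$day, .by_group = TRUE) |>
      mutate(next_day = lead(.data$day)) |>
      ungroup() |>
      filter(!is.na(.data$next_day), .data$next_day - .data$day >= 2L) |>
      filter(runif(dplyr::n()) < config$duplicate_rate) |>
      mutate(day = .data$day + 1L +
               as.integer(floor(runif(dplyr::n()) * (.data$next_day - .data$day - 1L)))) |>
      select("patient_id", "episode", "day")
    if (nrow(extra) > 0L && config$decompose_composites) {
      # duplicates of composite visits must also appear decomposed
      cfg2 <- config; cfg2$duplicate_rate <- 0
      extra <- as_tibble(roughen_episodes(new_episode_tbl(extra), cfg2))
    }
    df <- bind_rows(df[, c("patient_id", "episode", "day")], extra)
  }
  new_episode_tbl(df[, c("patient_id", "episode", "day")],
                  source = attr(table, "source"), covariates = character())
}
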