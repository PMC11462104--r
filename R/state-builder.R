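#' Composite-state naming scheme
#'
#' Defines how same-day multimorbidity episodes are collapsed into single
#' composite Markov states. Each component episode label has a short code and
#' the composite name is the concatenation of the component codes in a fixed
#' component order, so the same label set always yields the same name
#' regardless of input order. Labels in `special` (typically the absorbing
#' death state) are never composed: when one co-occurs with other episodes on
#' a day, it dominates.
#'
#' @param components Named character vector mapping episode labels to short
#'   codes, in composition order (earlier = leftmost in composite names).
#' @param singletons Named character vector mapping episode labels to the
#'   state name used when the label occurs alone (defaults to the code).
#' @param special Character vector of labels never composed.
#' @param state_order Optional preferred display/ordering of state labels for
#'   the state space.
#' @return A list of class `naming_scheme`.
#' @seealso [cvd_naming()] for the cardiovascular default.
#' @export
naming_scheme <- function(components, singletons = NULL, special = character(),
                          state_order = NULL) {
  stopifnot(is.character(components), !is.null(names(components)))
  if (anyDuplicated(components)) abort("component codes must be unique")
  if (is.null(singletons)) singletons <- components
  structure(list(components = components, singletons = singletons,
                 special = special, state_order = state_order),
            class = "naming_scheme")
}

#' Cardiovascular-disease naming scheme
#'
#' The default scheme for CVD cohorts: congestive heart failure (CH), angina
#' (AN), myocardial infarction (MI) and stroke (ST) compose in the order
#' CH < AN < MI < ST, producing the composite multimorbidity states CHMI,
#' CHST, CHAN, ANMI and CHANMI; `Death` is special (absorbing, never
#' composed). Singleton occurrences keep their conventional short names
#' (CHF, Angina, MI, Stroke).
#'
#' @return A `naming_scheme`.
#' @export
cvd_naming <- function() {
  naming_scheme(
    components = c("Congestive heart failure" = "CH",
                   "Angina" = "AN",
                   "Myocardial infarction" = "MI",
                   "Stroke" = "ST"),
    singletons = c("Congestive heart failure" = "CHF",
                   "Angina" = "Angina",
                   "Myocardial infarction" = "MI",
                   "Stroke" = "Stroke"),
    special = "Death",
    state_order = c("MI", "Stroke", "Death", "CHF", "CHMI", "CHST",
                    "Angina", "CHANMI", "ANMI", "CHAN")
  )
}

# canonical state name for a set of distinct labels present on one day
compose_label_set <- function(labels, naming) {
  labels <- unique(labels)
  sp <- intersect(labels, naming$special)
  if (length(sp) > 0L) {
    if (length(labels) > length(sp)) {
      warn(sprintf("absorbing label '%s' co-occurs with other episodes on one day; absorbing label wins", sp[1]))
    }
    return(sp[1])
  }
  if (length(labels) == 1L) {
    lab <- labels
    if (lab %in% names(naming$singletons)) return(unname(naming$singletons[lab]))
    return(lab)  # unknown labels pass through unchanged
  }
  codes <- naming$components[labels]
  if (anyNA(codes)) {
    abort(sprintf("cannot compose same-day labels not in the naming scheme: %s",
                  paste(labels[is.na(codes)], collapse = ", ")))
  }
  paste(codes[order(match(codes, naming$components))], collapse = "")
}

#' Collapse same-day multimorbidity episodes into composite states
#'
#' For every (patient, day) cell, the set of distinct episode labels is
#' replaced by a single record carrying the canonical composite state name;
#' single labels map to their singleton state names and exact duplicate
#' labels on one day collapse to one record. This enforces the Markov rule
#' that a patient occupies exactly one state at a time while preserving
#' multimorbidity information as distinct composite states.
#'
#' @param table An `episode_tbl`.
#' @param naming A [naming_scheme()]; defaults to [cvd_naming()].
#' @return An `episode_tbl` with one record per (patient, day). Covariate
#'   values are taken from the first record of each cell.
#' @examples
#' tbl <- as_episode_tbl(data.frame(
#'   patient_id = "201195",
#'   episode = c("Angina", "Congestive heart failure", "Myocardial infarction"),
#'   day = 3086))
#' compose_same_day_states(tbl)$episode  # "CHANMI"
#' @export
compose_same_day_states <- function(table, naming = cvd_naming()) {
  df <- as_tibble(table)
  covars <- episode_covariates(table)
  out <- df |>
    group_by(.data$patient_id, .data$day) |>
    summarise(episode = compose_label_set(.data$episode, naming),
              across(all_of(covars), first),
              .groups = "drop")
  new_episode_tbl(out[, c("patient_id", "episode", "day", covars)],
                  source = attr(table, "source"), covariates = covars)
}

#' Merge consecutive duplicate visits into one continuous state
#'
#' A patient reporting the same state on consecutive visits (e.g. stroke at
#' day 100 and again at day 110 with nothing in between) is treated as
#' continuously occupying that state across the interim, not as leaving and
#' re-entering it: maximal runs of identical consecutive states collapse to a
#' single visit dated at the run's first day. Returning to a state after an
#' intervening different state is a genuine re-entry and is preserved.
#'
#' @param visits A data frame of one patient's day-sorted visits with columns
#'   `state` and `day` (extra columns are carried from the run's first row).
#' @return The merged visit tibble.
#' @examples
#' merge_consecutive_runs(data.frame(state = c("Stroke", "Stroke", "Angina"),
#'                                   day = c(100, 110, 115)))
#' @export
merge_consecutive_runs <- function(visits) {
  v <- as_tibble(visits)
  if (nrow(v) <= 1L) return(v)
  if (is.unsorted(v$day)) abort("visits must be day-sorted")
  keep <- c(TRUE, v$state[-1L] != v$state[-nrow(v)])
  v[keep, , drop = FALSE]
}

#' Drop rare states from a composed episode table
#'
#' States whose total record count falls below `min_count` are removed, as a
#' cohort analysis keeps only states with enough occurrences to estimate
#' transition rates. Two policies govern what removal means for the
#' surrounding sequence: `"drop_records"` (default) removes the records and
#' breaks the patient's sequence at each removal, so no transition is ever
#' counted across a dropped visit; `"splice"` removes the records but leaves
#' the surrounding visits adjacent, so the neighbours are treated as a direct
#' transition.
#'
#' @param table A composed `episode_tbl` (pruning operates on final state
#'   labels).
#' @param min_count Minimum record count for a state to survive.
#' @param policy `"drop_records"` or `"splice"`.
#' @return A list with `table` (pruned `episode_tbl`, plus a `.segment`
#'   column under `drop_records` marking sequence breaks) and
#'   `dropped_states` (tibble of `state`, `n` removed).
#' @export
prune_rare_states <- function(table, min_count,
                              policy = c("drop_records", "splice")) {
  policy <- match.arg(policy)
  if (!is.numeric(min_count) || length(min_count) != 1L || is.na(min_count)) {
    abort("'min_count' must be a single number (pruning threshold)")
  }
  df <- as_tibble(table)
  covars <- episode_covariates(table)
  tab <- count(df, state = .data$episode, name = "n")
  dropped <- filter(tab, .data$n < min_count)
  df <- arrange(df, .data$patient_id, .data$day, .data$episode)
  is_dropped <- df$episode %in% dropped$state
  if (all(is_dropped)) abort("pruning removed every record; lower 'min_count'")
  if (policy == "drop_records") {
    # breaks accumulate per patient: each removed visit starts a new segment
    df <- df |>
      group_by(.data$patient_id) |>
      mutate(.segment = cumsum(.data$episode %in% dropped$state)) |>
      ungroup()
    out <- df[!is_dropped, , drop = FALSE]
    covars2 <- c(covars, ".segment")
  } else {
    out <- df[!is_dropped, , drop = FALSE]
    covars2 <- covars
  }
  list(table = new_episode_tbl(out, source = attr(table, "source"),
                               covariates = covars2),
       dropped_states = as_tibble(dropped))
}

#' Construct the Markov state space
#'
#' @param states Ordered character vector of state labels.
#' @param absorbing Subset of `states` with no outgoing transitions.
#' @param dropped Tibble of pruned states (`state`, `n`), if any.
#' @return A list of class `state_space`.
#' @export
state_space <- function(states, absorbing = character(),
                        dropped = tibble(state = character(), n = integer())) {
  if (anyDuplicated(states)) abort("state labels must be unique")
  if (!all(absorbing %in% states)) abort("absorbing states must be a subset of states")
  structure(list(states = states, absorbing = absorbing, dropped = dropped),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State space: %d states (%s)\n", length(x$states),
              paste(x$states, collapse = ", ")))
  if (length(x$absorbing)) cat("  absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  if (nrow(x$dropped)) cat(sprintf("  pruned: %s\n",
                                   paste0(x$dropped$state, " (n=", x$dropped$n, ")", collapse = ", ")))
  invisible(x)
}

order_states <- function(labels, naming) {
  pref <- naming$state_order
  if (!is.null(pref)) {
    c(intersect(pref, labels), sort(setdiff(labels, pref)))
  } else {
    sort(labels)
  }
}

#' Build Markov-valid patient trajectories from raw episodes
#'
#' The full preprocessing stage: composes same-day multimorbidity episodes
#' into composite states, prunes rare states, sorts per patient, discards
#' episodes recorded after an absorbing (death) visit, and merges consecutive
#' duplicate states into single continuous holds. The result satisfies the
#' Markov-trajectory invariants: strictly increasing entry days, no
#' consecutive repeats, at most one absorbing visit and only as the last.
#'
#' @param table An `episode_tbl` of raw episode rows.
#' @param naming A [naming_scheme()].
#' @param min_count Pruning threshold (0 disables pruning). Required: there
#'   is no universal default for which states are "negligible".
#' @param absorbing_labels State labels treated as absorbing.
#' @param prune_policy Passed to [prune_rare_states()].
#' @return A list with `trajectories` — a tibble of `patient_id`, `segment`,
#'   `state`, `day` plus covariates, one row per visit — and `state_space`.
#' @examples
#' f <- system.file("extdata", "episodes_two_patients.csv", package = "ctmccohort")
#' build_trajectories(read_episodes(f), min_count = 0)$trajectories
#' @export
build_trajectories <- function(table, naming = cvd_naming(), min_count = 0,
                               absorbing_labels = "Death",
                               prune_policy = "drop_records") {
  composed <- compose_same_day_states(table, naming)
  pruned <- prune_rare_states(composed, min_count, prune_policy)
  df <- as_tibble(pruned$table)
  covars <- setdiff(episode_covariates(pruned$table), ".segment")
  if (!".segment" %in% names(df)) df$.segment <- 0L

  one_patient <- function(d) {
    d <- arrange(d, .data$day)
    # truncate after the first absorbing visit
    abs_idx <- which(d$episode %in% absorbing_labels)
    if (length(abs_idx) > 0L && abs_idx[1] < nrow(d)) {
      warn(sprintf("patient %s: discarding %d episode(s) after absorbing visit on day %d",
                   d$patient_id[1], nrow(d) - abs_idx[1], d$day[abs_idx[1]]))
      d <- d[seq_len(abs_idx[1]), , drop = FALSE]
    }
    d <- rename(d, state = "episode")
    bind_rows(lapply(split(d, d$.segment), merge_consecutive_runs))
  }
  traj <- as_tibble(df) |>
    (\(d) bind_rows(lapply(split(d, d$patient_id), one_patient)))() |>
    rename(segment = ".segment") |>
    select(all_of(c("patient_id", "segment", "state", "day", covars)))
  if (nrow(traj) == 0L) abort("preprocessing produced no visits")

  labels <- order_states(unique(traj$state), naming)
  absorbing <- intersect(absorbing_labels, labels)
  list(trajectories = traj,
       state_space = state_space(labels, absorbing, pruned$dropped_states))
}
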