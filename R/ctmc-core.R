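#' Count observed one-step transitions and holding times
#'
#' Walks every patient trajectory and, for each consecutive visit pair
#' (state i entered on day d, state j entered on day d'), accumulates one
#' jump into the frequency matrix `N[i, j]` and the holding time d' - d days
#' into the destination-specific wait total `R[i, j]`. Time after a patient's
#' last observed visit contributes nothing: right-censored exposure is
#' deliberately ignored, matching the destination-specific accounting the
#' generator estimator uses.
#'
#' @param trajectories Trajectory tibble from [build_trajectories()] (columns
#'   `patient_id`, `segment`, `state`, `day`).
#' @param state_space A [state_space()] covering every visited state.
#' @return An object of class `transition_counts`: list with the
#'   `state_space`, integer matrix `N` (zero diagonal, zero absorbing rows),
#'   numeric matrix `R` of total wait days, and `waits`, a tibble of
#'   `from`, `to`, `days` holding the individual wait samples.
#' @examples
#' traj <- tibble::tibble(patient_id = "p1", segment = 0L,
#'                        state = c("A", "B", "Death"), day = c(0L, 10L, 30L))
#' sp <- state_space(c("A", "B", "Death"), absorbing = "Death")
#' count_transitions(traj, sp)$N
#' @export
count_transitions <- function(trajectories, state_space) {
  st <- state_space$states
  unknown <- setdiff(unique(trajectories$state), st)
  if (length(unknown) > 0L) {
    abort(paste0("trajectory states not in state space: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!"segment" %in% names(trajectories)) trajectories$segment <- 0L
  d <- trajectories |>
    arrange(.data$patient_id, .data$segment, .data$day) |>
    group_by(.data$patient_id, .data$segment) |>
    mutate(to = lead(.data$state), days = lead(.data$day) - .data$day) |>
    ungroup() |>
    filter(!is.na(.data$to)) |>
    select(from = "state", "to", "days")

  k <- length(st)
  N <- matrix(0L, k, k, dimnames = list(st, st))
  R <- matrix(0, k, k, dimnames = list(st, st))
  if (nrow(d) > 0L) {
    idx <- cbind(match(d$from, st), match(d$to, st))
    for (r in seq_len(nrow(d))) {
      N[idx[r, 1], idx[r, 2]] <- N[idx[r, 1], idx[r, 2]] + 1L
      R[idx[r, 1], idx[r, 2]] <- R[idx[r, 1], idx[r, 2]] + d$days[r]
    }
  }
  if (any(N[state_space$absorbing, , drop = FALSE] > 0)) {
    abort("observed a transition out of an absorbing state")
  }
  structure(list(state_space = state_space, N = N, R = R, waits = d),
            class = "transition_counts")
}

#' Construct transition counts directly from matrices
#'
#' Builds a `transition_counts` object from a jump-frequency matrix and
#' (optionally) a matrix of total destination-specific wait days — useful for
#' working from published count tables when the underlying records are not
#' available. When `R` is omitted, individual wait samples are unknown and
#' only operations that need counts alone (jump probabilities, death
#' attribution) are meaningful.
#'
#' @param N Square integer matrix of one-step jump counts with state labels
#'   as dimnames.
#' @param R Optional matching matrix of total wait days.
#' @param absorbing Absorbing state labels (default: rows of `N` that are
#'   all zero).
#' @return A `transition_counts` object.
#' @export
transition_counts_from_matrices <- function(N, R = NULL, absorbing = NULL) {
  stopifnot(is.matrix(N), nrow(N) == ncol(N), !is.null(rownames(N)))
  st <- rownames(N)
  if (is.null(absorbing)) absorbing <- st[rowSums(N) == 0]
  if (is.null(R)) R <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
  stopifnot(all(dim(R) == dim(N)))
  structure(list(state_space = state_space(st, absorbing), N = N, R = R,
                 waits = NULL),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("Transition counts over %d states: %d jumps, %s total wait days\n",
              length(x$state_space$states), sum(x$N), format(sum(x$R))))
  invisible(x)
}

#' @describeIn count_transitions `tidy()` returns one row per ordered state
#'   pair with a positive count: `from`, `to`, `n`, `total_wait_days`.
#' @param x A `transition_counts` object.
#' @param ... Unused.
#' @method tidy transition_counts
#' @export
tidy.transition_counts <- function(x, ...) {
  idx <- which(x$N > 0, arr.ind = TRUE)
  st <- x$state_space$states
  tibble(from = st[idx[, 1]], to = st[idx[, 2]],
         n = x$N[idx], total_wait_days = x$R[idx]) |>
    arrange(.data$from, .data$to)
}

#' Embedded jump probability matrix
#'
#' Row-normalizes the jump frequency matrix: entry (i, j) is the probability
#' that the next state is j given a jump out of i, regardless of how long the
#' patient waited. Absorbing rows have no jumps; with
#' `absorbing_self_loop = TRUE` (default) they become identity rows (the
#' convention used when the matrix is read as "where is the patient next"),
#' otherwise they are all zero.
#'
#' @param counts A `transition_counts` object.
#' @param absorbing_self_loop Put probability 1 on staying for absorbing
#'   rows?
#' @return A square probability matrix; every row with observed jumps sums
#'   to 1. A non-absorbing state with no observed outgoing jumps yields an
#'   all-zero row with a warning (it cannot be normalized).
#' @export
jump_probability_matrix <- function(counts, absorbing_self_loop = TRUE) {
  N <- counts$N
  st <- counts$state_space$states
  P <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
  rs <- rowSums(N)
  pos <- rs > 0
  P[pos, ] <- N[pos, , drop = FALSE] / rs[pos]
  zero_nonabs <- st[!pos & !(st %in% counts$state_space$absorbing)]
  if (length(zero_nonabs) > 0L) {
    warn(paste0("non-absorbing state(s) with no outgoing transitions left as zero rows: ",
                paste(zero_nonabs, collapse = ", ")))
  }
  if (absorbing_self_loop) {
    for (s in counts$state_space$absorbing) P[s, s] <- 1
  }
  P
}

#' Estimate the infinitesimal generator matrix Q
#'
#' Two estimators of the transition rate matrix are provided. In
#' `mode = "paper"` (default) each off-diagonal rate is the
#' destination-specific ratio q_ij = n_ij / r_ij: the number of observed
#' i to j jumps divided by the total days those particular patients held in i
#' before jumping to j. In `mode = "mle"` the standard maximum-likelihood
#' estimator for a continuously observed Markov jump process is used,
#' q_ij = n_ij / T_i, dividing by the total observed holding time in i over
#' all destinations. Both set q_ii = -sum_{j != i} q_ij so rows sum to zero,
#' leave q_ij = 0 where no jump was observed (no smoothing), and zero the
#' absorbing rows.
#'
#' The two estimators answer different questions: under exponential holding
#' times the destination-specific ratio converges to the state's total exit
#' rate lambda_i = -q_ii for every realized destination (holding time is
#' independent of where the jump goes), while the MLE converges to the
#' per-destination rate q_ij itself. The MLE is therefore the estimator to
#' use for inference; the destination-specific mode reproduces the
#' worked-example accounting of the source analytics workflow.
#'
#' @param counts A `transition_counts` object.
#' @param mode `"paper"` (destination-specific ratio) or `"mle"`.
#' @return An object of class `generator_matrix`: list with `state_space`,
#'   the rate matrix `Q` (per day) and `mode`.
#' @examples
#' N <- matrix(0, 2, 2, dimnames = list(c("MI", "CHF"), c("MI", "CHF")))
#' R <- N; N["MI", "CHF"] <- 31; R["MI", "CHF"] <- 16633
#' cnt <- transition_counts_from_matrices(N, R, absorbing = "CHF")
#' estimate_generator(cnt)$Q["MI", "CHF"]  # 0.001864 at 6 dp
#' @export
estimate_generator <- function(counts, mode = c("paper", "mle")) {
  mode <- match.arg(mode)
  N <- counts$N
  R <- counts$R
  st <- counts$state_space$states
  k <- length(st)
  Q <- matrix(0, k, k, dimnames = list(st, st))
  if (mode == "paper") {
    pos <- N > 0
    Q[pos] <- N[pos] / R[pos]
  } else {
    Ti <- rowSums(R)
    pos_row <- Ti > 0
    Q[pos_row, ] <- N[pos_row, , drop = FALSE] / Ti[pos_row]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q[counts$state_space$absorbing, ] <- 0
  new_generator_matrix(Q, counts$state_space, mode)
}

new_generator_matrix <- function(Q, state_space, mode = "given") {
  validate_generator(Q, state_space)
  structure(list(state_space = state_space, Q = Q, mode = mode),
            class = "generator_matrix")
}

validate_generator <- function(Q, state_space) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  off <- Q; diag(off) <- 0
  if (any(off < 0)) abort("generator off-diagonal entries must be nonnegative")
  scale <- pmax(apply(abs(Q), 1, max), 1)
  if (any(abs(rowSums(Q)) > 1e-12 * scale)) abort("generator rows must sum to zero")
  if (length(state_space$absorbing) > 0 &&
      any(Q[state_space$absorbing, , drop = FALSE] != 0)) {
    abort("absorbing rows of the generator must be zero")
  }
  invisible(Q)
}

#' Build a generator object from a rate matrix
#'
#' @param Q Square rate matrix with state dimnames: nonnegative
#'   off-diagonals, zero row sums, zero absorbing rows.
#' @param absorbing Absorbing state labels (default: all-zero rows).
#' @return A `generator_matrix`.
#' @export
as_generator <- function(Q, absorbing = NULL) {
  stopifnot(!is.null(rownames(Q)))
  if (is.null(absorbing)) absorbing <- rownames(Q)[rowSums(Q != 0) == 0]
  new_generator_matrix(Q, state_space(rownames(Q), absorbing))
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat(sprintf("Generator matrix (%s mode), %d states, rates per day\n",
              x$mode, nrow(x$Q)))
  print(round(x$Q, 6))
  invisible(x)
}

#' @describeIn estimate_generator `tidy()` returns one row per nonzero
#'   off-diagonal rate: `from`, `to`, `rate` (per day).
#' @param x A `generator_matrix`.
#' @param ... Unused.
#' @method tidy generator_matrix
#' @export
tidy.generator_matrix <- function(x, ...) {
  Q <- x$Q
  idx <- which(Q > 0 & row(Q) != col(Q), arr.ind = TRUE)
  st <- x$state_space$states
  tibble(from = st[idx[, 1]], to = st[idx[, 2]], rate = Q[idx]) |>
    arrange(.data$from, .data$to)
}

#' @describeIn estimate_generator `glance()` returns a one-row summary:
#'   state count, absorbing count, estimator mode, largest exit rate and the
#'   corresponding shortest mean holding time in days.
#' @method glance generator_matrix
#' @export
glance.generator_matrix <- function(x, ...) {
  exit <- -diag(x$Q)
  tibble(n_states = nrow(x$Q),
         n_absorbing = length(x$state_space$absorbing),
         mode = x$mode,
         max_exit_rate = max(exit),
         min_mean_hold_days = if (any(exit > 0)) 1 / max(exit) else Inf)
}

#' Per-pair transition time statistics
#'
#' Mean and population standard deviation (divisor n, so SD = 0 when a
#' single patient made the transition) of the observed holding times for each
#' ordered state pair with at least one observed jump.
#'
#' @param counts A `transition_counts` built from trajectories (individual
#'   wait samples required).
#' @return Tibble of `from`, `to`, `n`, `mean_days`, `sd_days`, sorted by
#'   ascending mean (fastest transitions first).
#' @export
transition_time_stats <- function(counts) {
  if (is.null(counts$waits)) {
    abort("individual wait samples unavailable (counts built from matrices)")
  }
  counts$waits |>
    group_by(.data$from, .data$to) |>
    summarise(n = dplyr::n(),
              mean_days = mean(.data$days),
              sd_days = sqrt(mean((.data$days - mean(.data$days))^2)),
              .groups = "drop") |>
    arrange(.data$mean_days, .data$from, .data$to)
}

#' Distribution of first observed episodes
#'
#' Counts each patient's first visit state. With `restrict_to`, only
#' patients whose first state is in the subset enter the tally and fractions
#' are over that restricted denominator (useful when the analysis focuses on
#' a few dominant states).
#'
#' @param trajectories Trajectory tibble from [build_trajectories()].
#' @param restrict_to Optional character vector of states.
#' @return Tibble of `state`, `n`, `fraction`, descending by count;
#'   fractions sum to 1.
#' @export
first_episode_distribution <- function(trajectories, restrict_to = NULL) {
  if (nrow(trajectories) == 0L) abort("no trajectories")
  firsts <- trajectories |>
    group_by(.data$patient_id) |>
    summarise(state = .data$state[which.min(.data$day)], .groups = "drop")
  if (!is.null(restrict_to)) firsts <- filter(firsts, .data$state %in% restrict_to)
  if (nrow(firsts) == 0L) abort("no patients with a first episode in the requested subset")
  firsts |>
    count(.data$state, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$n))
}

#' Attribution of deaths to the preceding state
#'
#' Among all observed jumps into the absorbing state, the share contributed
#' by each source state, plus the collective share of an optional subset of
#' source states.
#'
#' @param counts A `transition_counts` object.
#' @param absorbing_state The absorbing state label (default `"Death"`).
#' @param subset Optional source-state subset whose collective share is also
#'   reported.
#' @return A list with `by_state` (tibble `state`, `n`, `share`, descending)
#'   and `subset_share` (`NA` when no subset given; 0 for an empty subset).
#' @export
death_attribution <- function(counts, absorbing_state = "Death", subset = NULL) {
  st <- counts$state_space$states
  if (!absorbing_state %in% st) abort(sprintf("'%s' is not in the state space", absorbing_state))
  col <- counts$N[, absorbing_state]
  total <- sum(col)
  if (total == 0) abort("no transitions into the absorbing state observed")
  by_state <- tibble(state = st, n = as.integer(col)) |>
    filter(.data$n > 0) |>
    mutate(share = .data$n / total) |>
    arrange(dplyr::desc(.data$n))
  subset_share <- if (is.null(subset)) NA_real_ else sum(by_state$share[by_state$state %in% subset])
  list(by_state = by_state, subset_share = subset_share, total_deaths = total)
}
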