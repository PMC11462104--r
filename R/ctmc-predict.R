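#' Time-variant transition probability matrix P(t) = e^(Qt)
#'
#' Computes the matrix exponential of Q t, the probability of occupying state
#' j at time t (in days) given occupation of state i at time 0. The
#' exponential is evaluated with a scaling-and-squaring Pade scheme
#' (`Matrix::expm`); rows are required to sum to 1 within 1e-9 and are never
#' renormalized — drift beyond that is an error, not something to paper over.
#'
#' @param generator A `generator_matrix` (see [estimate_generator()],
#'   [as_generator()]).
#' @param t Time in days, a single non-negative number.
#' @return An object of class `transition_probability`: list with
#'   `state_space`, `t` and the probability matrix `P`. Absorbing-state rows
#'   are unit vectors on themselves.
#' @examples
#' Q <- matrix(c(-1, 1, 1, -1), 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' transition_probability(as_generator(Q), log(2))$P[1, 1]  # 0.625
#' @export
transition_probability <- function(generator, t) {
  stopifnot(inherits(generator, "generator_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("'t' must be a single non-negative time in days")
  }
  Q <- generator$Q
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  dimnames(P) <- dimnames(Q)
  P[P < 0 & P > -1e-12] <- 0  # clip exponential-roundoff negatives only
  drift <- abs(rowSums(P) - 1)
  if (any(drift > 1e-9) || any(P < 0) || any(P > 1 + 1e-9)) {
    abort("matrix exponential lost stochasticity beyond tolerance")
  }
  structure(list(state_space = generator$state_space, t = t, P = P),
            class = "transition_probability")
}

#' @export
print.transition_probability <- function(x, ...) {
  cat(sprintf("Transition probabilities at t = %g days\n", x$t))
  print(round(x$P, 4))
  invisible(x)
}

#' @describeIn transition_probability `tidy()` returns the long form:
#'   `from`, `to`, `time_days`, `probability`.
#' @param x A `transition_probability`.
#' @param ... Unused.
#' @method tidy transition_probability
#' @export
tidy.transition_probability <- function(x, ...) {
  st <- x$state_space$states
  tibble(from = rep(st, each = length(st)),
         to = rep(st, times = length(st)),
         time_days = x$t,
         probability = as.vector(t(x$P)))
}

#' Progression pattern over a time grid
#'
#' Conditional on a starting state, evaluates the occupancy distribution at
#' every multiple of `interval_days` up to `horizon_days` — the data behind a
#' progression heat map and trend chart. The defaults, 90-day steps over
#' 1800 days, give the conventional quarterly review grid over five years
#' (20 time points).
#'
#' @param generator A `generator_matrix`.
#' @param start_state Starting state label.
#' @param interval_days Grid step in days (> 0).
#' @param horizon_days Last grid time in days (>= interval).
#' @return An object of class `progression_pattern`: tibble of `time_days`,
#'   `to_state`, `probability` with attributes `start_state` and
#'   `state_space`. Each time slice sums to 1.
#' @export
progression_series <- function(generator, start_state,
                               interval_days = 90, horizon_days = 1800) {
  st <- generator$state_space$states
  if (!start_state %in% st) {
    abort(sprintf("unknown start state '%s'; valid states: %s",
                  start_state, paste(st, collapse = ", ")))
  }
  if (interval_days <= 0 || horizon_days < interval_days) {
    abort("need 0 < interval_days <= horizon_days")
  }
  grid <- seq(interval_days, horizon_days, by = interval_days)
  rows <- map(grid, function(t) {
    P <- transition_probability(generator, t)$P
    tibble(time_days = t, to_state = st, probability = unname(P[start_state, ]))
  })
  out <- bind_rows(rows)
  attr(out, "start_state") <- start_state
  attr(out, "state_space") <- generator$state_space
  class(out) <- unique(c("progression_pattern", class(out)))
  out
}

#' Plot a progression pattern
#'
#' Trend lines of the probability of each destination state against time,
#' conditional on the pattern's starting state.
#'
#' @param object A `progression_pattern` from [progression_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot progression_pattern
#' @export
autoplot.progression_pattern <- function(object, ...) {
  start <- attr(object, "start_state")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_days, y = .data$probability,
                               colour = .data$to_state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time in current state (days)", y = "Transition probability",
                  colour = "Next state",
                  title = sprintf("Progression pattern from state %s", start)) +
    ggplot2::theme_minimal()
}

#' @export
plot.progression_pattern <- function(x, ...) print(autoplot(x, ...))

#' Forecast the cohort state mix at a future time
#'
#' Propagates an initial distribution over states forward by t days:
#' returns `initial_mix %*% P(t)`. Useful for predictive resource planning —
#' what fraction of the cohort will occupy each state at the next review.
#'
#' @param generator A `generator_matrix`.
#' @param initial_mix Named or state-ordered nonnegative vector summing to 1.
#' @param t Forecast time in days.
#' @return Tibble of `state`, `probability` (sums to 1).
#' @export
forecast_state_mix <- function(generator, initial_mix, t) {
  st <- generator$state_space$states
  if (!is.null(names(initial_mix))) {
    if (!setequal(names(initial_mix), st)) {
      abort("names of 'initial_mix' must match the state space")
    }
    initial_mix <- initial_mix[st]
  }
  if (length(initial_mix) != length(st)) abort("'initial_mix' length must equal number of states")
  if (any(initial_mix < 0) || abs(sum(initial_mix) - 1) > 1e-9) {
    abort("'initial_mix' must be nonnegative and sum to 1")
  }
  P <- transition_probability(generator, t)$P
  mix <- as.numeric(initial_mix %*% P)
  tibble(state = st, probability = mix)
}
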