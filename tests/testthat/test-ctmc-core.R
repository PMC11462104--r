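test_that("transition counting matches hand-tallied jumps and waits", {
  traj <- tibble::tibble(patient_id = "p1", segment = 0L,
                         state = c("A", "B", "Death"), day = c(0L, 10L, 30L))
  sp <- state_space(c("A", "B", "Death"), absorbing = "Death")
  cnt <- count_transitions(traj, sp)
  expect_equal(cnt$N["A", "B"], 1L)
  expect_equal(cnt$R["A", "B"], 10)
  expect_equal(cnt$N["B", "Death"], 1L)
  expect_equal(cnt$R["B", "Death"], 20)
  expect_equal(sum(cnt$N), 2L)
  expect_true(all(diag(cnt$N) == 0))
  expect_true(all(cnt$N["Death", ] == 0))
  # R[i,j] >= N[i,j] whenever N > 0 (waits are at least one day)
  expect_true(all(cnt$R[cnt$N > 0] >= cnt$N[cnt$N > 0]))
  # a length-1 trajectory contributes nothing
  solo <- tibble::tibble(patient_id = "p2", segment = 0L, state = "A", day = 3L)
  expect_equal(sum(count_transitions(solo, sp)$N), 0L)
  # unknown state is an error
  bad <- tibble::tibble(patient_id = "p", segment = 0L, state = "Z", day = 1L)
  expect_error(count_transitions(bad, sp), "state space")
})

test_that("jump probabilities row-normalize counts with sensible edge rows", {
  cnt <- cvd_jump_counts()
  P <- jump_probability_matrix(cnt)
  nonabs <- setdiff(rownames(P), "Death")
  expect_equal(unname(rowSums(P)[nonabs]), rep(1, length(nonabs)), tolerance = 1e-12)
  expect_equal(unname(P["Death", ]), c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(P["MI", "Death"], 44 / 86)
  expect_equal(P["Angina", "CHF"], 39 / 101)
  # absorbing row all zero when self-loop convention is off
  expect_equal(sum(jump_probability_matrix(cnt, absorbing_self_loop = FALSE)["Death", ]), 0)
  # a single observed transition gives a unit row
  N1 <- matrix(c(0L, 1L, 0L, 0L), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(jump_probability_matrix(
    transition_counts_from_matrices(N1, absorbing = "B"))["A", ]), c(0, 1))
  # non-absorbing zero row warns
  N2 <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  N2["A", "B"] <- 1L
  expect_warning(jump_probability_matrix(
    transition_counts_from_matrices(N2, absorbing = character())), "no outgoing")
})

test_that("the published frequency table reproduces the printed percent matrix cell-for-cell", {
  P <- jump_probability_matrix(cvd_jump_counts())
  expect_equal(round1(P * 100), cvd_jump_percent_expected())
})

test_that("generator estimation implements both accounting modes exactly", {
  # destination-specific worked example: 31 jumps over 16,633 waiting days
  N <- matrix(0, 2, 2, dimnames = list(c("MI", "CHF"), c("MI", "CHF")))
  R <- N; N["MI", "CHF"] <- 31; R["MI", "CHF"] <- 16633
  q <- estimate_generator(transition_counts_from_matrices(N, R, absorbing = "CHF"))
  expect_equal(round(q$Q["MI", "CHF"], 6), 0.001864)
  expect_equal(q$Q["MI", "MI"], -q$Q["MI", "CHF"])

  # single-pair toy
  N1 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  R1 <- N1; N1["A", "B"] <- 2; R1["A", "B"] <- 4
  Q1 <- estimate_generator(transition_counts_from_matrices(N1, R1, absorbing = "B"))$Q
  expect_equal(unname(Q1["A", ]), c(-0.5, 0.5))

  # three-state toy separating the two modes (hand-derived)
  st <- c("A", "B", "C")
  N3 <- matrix(0, 3, 3, dimnames = list(st, st))
  R3 <- N3
  N3["A", "B"] <- 1; R3["A", "B"] <- 2
  N3["A", "C"] <- 1; R3["A", "C"] <- 4
  cnt3 <- transition_counts_from_matrices(N3, R3, absorbing = c("B", "C"))
  Qp <- estimate_generator(cnt3, "paper")$Q
  expect_equal(unname(Qp["A", ]), c(-0.75, 0.5, 0.25))
  Qm <- estimate_generator(cnt3, "mle")$Q
  expect_equal(unname(Qm["A", ]), c(-1 / 3, 1 / 6, 1 / 6))
  # mle embedded-jump consistency: q_ij / (-q_ii) = N_ij / rowsum(N)
  expect_equal(Qm["A", "B"] / -Qm["A", "A"], 0.5)
})

test_that("generator validity holds for any counts in either mode", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    st <- paste0("S", 1:k)
    N <- matrix(rpois(k * k, 3), k, k, dimnames = list(st, st))
    diag(N) <- 0L
    N[k, ] <- 0L  # absorbing last state
    R <- N * (1 + matrix(round(runif(k * k, 0, 50)), k, k))
    cnt <- transition_counts_from_matrices(N, R, absorbing = st[k])
    for (mode in c("paper", "mle")) {
      Q <- estimate_generator(cnt, mode)$Q
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
      expect_true(all(abs(rowSums(Q)) <= 1e-12 * pmax(1, apply(abs(Q), 1, max))))
      expect_true(all(Q[k, ] == 0))
    }
  }
})

test_that("transition time statistics use population SD with n=1 giving SD 0", {
  traj <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c", "c"),
    segment = 0L,
    state = c("MI", "Stroke", "MI", "Angina", "MI", "Angina"),
    day = c(0L, 3L, 0L, 10L, 0L, 20L))
  sp <- state_space(c("MI", "Stroke", "Angina"))
  tts <- transition_time_stats(count_transitions(traj, sp))
  ms <- dplyr::filter(tts, from == "MI", to == "Stroke")
  expect_equal(ms$mean_days, 3)
  expect_equal(ms$sd_days, 0)
  expect_equal(ms$n, 1L)
  ma <- dplyr::filter(tts, from == "MI", to == "Angina")
  expect_equal(ma$mean_days, 15)
  expect_equal(ma$sd_days, 5)  # population SD of {10, 20}
  # fastest transition sorts first
  expect_equal(tts$to[1], "Stroke")
  expect_error(transition_time_stats(cvd_jump_counts()), "samples")
})

test_that("first-episode distribution counts patients and honours restriction", {
  mk <- function(states) {
    tibble::tibble(patient_id = paste0("p", seq_along(states)), segment = 0L,
                   state = states, day = 0L)
  }
  # printed first-episode counts: 371 CHF, 216 Stroke, 140 Angina, 113 MI
  states <- rep(c("CHF", "Stroke", "Angina", "MI"), c(371, 216, 140, 113))
  fed <- first_episode_distribution(mk(states))
  expect_equal(fed$state, c("CHF", "Stroke", "Angina", "MI"))
  expect_equal(fed$n, c(371L, 216L, 140L, 113L))
  expect_equal(round1(fed$fraction * 100), c(44.2, 25.7, 16.7, 13.5))
  expect_equal(sum(fed$fraction), 1)
  # single patient
  one <- first_episode_distribution(mk("MI"))
  expect_equal(one$fraction, 1)
  # restriction changes the denominator
  r <- first_episode_distribution(mk(c("A", "A", "B")), restrict_to = "A")
  expect_equal(r$n, 2L)
  expect_equal(r$fraction, 1)
  expect_error(first_episode_distribution(mk("A"), restrict_to = "Z"), "subset")
})

test_that("death attribution from the published counts gives the dominant-state share", {
  att <- death_attribution(cvd_jump_counts(), "Death",
                           subset = c("CHF", "Stroke", "MI", "Angina"))
  expect_equal(att$total_deaths, 262L)
  expect_equal(round1(att$subset_share * 100), 88.2)
  shares <- setNames(att$by_state$share, att$by_state$state)
  expect_equal(unname(shares[c("CHF", "Stroke", "MI", "Angina")]),
               c(101, 74, 44, 12) / 262)
  # single death
  N <- matrix(0, 2, 2, dimnames = list(c("A", "D"), c("A", "D")))
  N["A", "D"] <- 1
  one <- death_attribution(transition_counts_from_matrices(N, absorbing = "D"), "D")
  expect_equal(one$by_state$share, 1)
  # empty subset -> zero share; zero deaths -> error
  expect_equal(death_attribution(cvd_jump_counts(), "Death", character())$subset_share, 0)
  N0 <- matrix(0, 2, 2, dimnames = list(c("A", "D"), c("A", "D")))
  N0["A", "A"] <- 0
  expect_error(death_attribution(
    transition_counts_from_matrices(N0, absorbing = "D"), "D"), "no transitions")
})
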