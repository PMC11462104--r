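# Shared fixtures: generators and count tables built in code.

# Random valid generator on k states; draws from the current RNG stream.
random_generator <- function(k, rate_range = c(5e-4, 2e-2), n_absorbing = 0,
                             zero_fraction = 0.3) {
  st <- paste0("S", seq_len(k))
  Q <- matrix(runif(k * k, rate_range[1], rate_range[2]), k, k,
              dimnames = list(st, st))
  Q[matrix(runif(k * k) < zero_fraction, k, k)] <- 0
  diag(Q) <- 0
  for (i in seq_len(k - n_absorbing)) {
    if (all(Q[i, -i] == 0)) Q[i, (i %% k) + 1] <- rate_range[2]
  }
  if (n_absorbing > 0) Q[(k - n_absorbing + 1):k, ] <- 0
  diag(Q) <- -rowSums(Q)
  as_generator(Q, absorbing = if (n_absorbing > 0) st[(k - n_absorbing + 1):k] else character())
}

# Fixed 4-state CVD-like truth used for recovery studies: day-scale rates,
# absorbing death.
cvd4_generator <- function() {
  st <- c("CHF", "Stroke", "MI", "Death")
  Q <- matrix(0, 4, 4, dimnames = list(st, st))
  Q["CHF", "Stroke"] <- 0.002; Q["CHF", "MI"] <- 0.001; Q["CHF", "Death"] <- 0.003
  Q["Stroke", "CHF"] <- 0.0015; Q["Stroke", "Death"] <- 0.004
  Q["MI", "CHF"] <- 0.002; Q["MI", "Death"] <- 0.005
  diag(Q) <- -rowSums(Q)
  as_generator(Q, absorbing = "Death")
}

cvd4_initial <- function() c(CHF = 0.5, Stroke = 0.3, MI = 0.2)

# Published 10-state jump-frequency table shipped as a text fixture.
cvd_jump_counts <- function() {
  N <- read_matrix_csv(system.file("extdata", "jump_frequency_cvd.csv",
                                   package = "ctmccohort"))
  transition_counts_from_matrices(N, absorbing = "Death")
}

two_patient_file <- function() {
  system.file("extdata", "episodes_two_patients.csv", package = "ctmccohort")
}

# Expected jump probability matrix in printed percent (1 dp), row-normalized
# from the frequency fixture by an independent hand computation.
cvd_jump_percent_expected <- function() {
  st <- c("MI", "Stroke", "Death", "CHF", "CHMI", "CHST", "Angina",
          "CHANMI", "ANMI", "CHAN")
  vals <- rbind(
    c(0, 1.2, 51.2, 36, 0, 2.3, 8.1, 1.2, 0, 0),
    c(7.6, 0, 56.5, 13.7, 1.5, 6.9, 2.3, 4.6, 5.3, 1.5),
    c(0, 0, 100, 0, 0, 0, 0, 0, 0, 0),
    c(7.5, 13.4, 54, 0, 1.6, 0, 5.9, 7, 4.8, 5.9),
    c(0, 5.6, 44.4, 33.3, 0, 0, 11.1, 0, 0, 5.6),
    c(7.1, 42.9, 21.4, 28.6, 0, 0, 0, 0, 0, 0),
    c(8.9, 10.9, 11.9, 38.6, 1, 1, 0, 6.9, 6.9, 13.9),
    c(11.3, 6.5, 16.1, 30.6, 1.6, 0, 21, 0, 6.5, 6.5),
    c(5.9, 7.8, 7.8, 29.4, 0, 0, 31.4, 11.8, 0, 5.9),
    c(2.3, 4.5, 13.6, 43.2, 4.5, 0, 18.2, 11.4, 2.3, 0))
  dimnames(vals) <- list(st, st)
  vals
}

round1 <- function(x) ctmccohort:::round_half_up(x, 1)
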