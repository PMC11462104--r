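pipeline_cfg <- function(episodes_path, ...) {
  utils::modifyList(
    list(input = list(episodes = episodes_path),
         states = list(min_count = 0),
         estimator = list(mode = "paper"),
         prediction = list(interval_days = 90, horizon_days = 360)),
    list(...))
}

test_that("the pipeline bundles every stage for the two-patient snapshot", {
  b <- suppressMessages(run_pipeline(pipeline_cfg(two_patient_file())))
  expect_s3_class(b, "analysis_bundle")
  expect_equal(dplyr::n_distinct(b$trajectories$patient_id), 2L)
  expect_equal(sum(b$counts$N), 5L)  # 3 transitions for 200453 + 2 for 201195
  expect_equal(b$generator$mode, "paper")
  expect_equal(sort(names(b$progression)), sort(b$state_space$states))
  expect_equal(unique(b$progression[[1]]$time_days), c(90, 180, 270, 360))
  expect_false(is.null(b$provenance$input_digest))
  # missing pruning threshold is an error naming the key
  expect_error(run_pipeline(list(input = list(episodes = two_patient_file()))),
               "min_count")
  # stage errors carry the stage name
  expect_error(suppressMessages(run_pipeline(
    pipeline_cfg("/nonexistent/file.csv"))), "episode_io")
})

test_that("a simulator-scenario config replays identically under one seed", {
  scenario <- system.file("extdata", "cvd_demo_scenario.yaml",
                          package = "ctmccohort")
  sc <- read_scenario(scenario)
  expect_s3_class(sc, "simulation_config")
  expect_equal(sc$generator$state_space$absorbing, "Death")
  cfg <- list(input = list(scenario = scenario),
              states = list(min_count = 0),
              prediction = list(interval_days = 90, horizon_days = 180))
  b1 <- suppressMessages(run_pipeline(cfg, seed = 5))
  b2 <- suppressMessages(run_pipeline(cfg, seed = 5))
  expect_identical(b1$counts$N, b2$counts$N)
  expect_identical(b1$provenance$input_digest, b2$provenance$input_digest)
})

test_that("exports reproduce the printed percent table and honour layouts", {
  # percent export of the packaged frequency fixture reproduces the printed
  # jump probability table cell-for-cell
  cnt <- cvd_jump_counts()
  b <- suppressMessages(run_pipeline(pipeline_cfg(two_patient_file())))
  b$counts <- cnt
  b$jump_probabilities <- jump_probability_matrix(cnt)
  dir <- withr::local_tempdir()
  files <- export_matrix_tables(b, dir, scale = "percent", layout = "long")
  jp <- read_matrix_csv(file.path(dir, "jump_probability.csv"))
  expect_equal(jp, cvd_jump_percent_expected())
  # fraction-scale rows sum to 1
  dir2 <- withr::local_tempdir()
  export_matrix_tables(b, dir2, scale = "fraction", layout = "long")
  jp2 <- read_matrix_csv(file.path(dir2, "jump_probability.csv"))
  expect_equal(unname(rowSums(jp2)), rep(1, 10), tolerance = 1e-12)
  # long layout: one row per grid time and destination state
  prog <- readr::read_csv(file.path(dir2, list.files(dir2, "^progression_")[1]),
                          show_col_types = FALSE)
  expect_equal(nrow(prog), 4 * length(b$state_space$states))
  expect_equal(names(prog), c("start_state", "time_days", "to_state", "probability"))
  # wide layout: one states-wide row per grid time
  dir3 <- withr::local_tempdir()
  export_matrix_tables(b, dir3, scale = "fraction", layout = "wide")
  wide <- readr::read_csv(file.path(dir3, list.files(dir3, "^progression_")[1]),
                          show_col_types = FALSE)
  expect_equal(nrow(wide), 4L)
  expect_equal(ncol(wide), 1L + length(b$state_space$states))
})

test_that("stratified comparison partitions patients and pools back to the whole", {
  # two strata simulated from different generators, written to one file
  g_fast <- cvd4_generator()
  Q_slow <- g_fast$Q / 2
  g_slow <- as_generator(Q_slow, absorbing = "Death")
  mk <- function(g, seed, sex, prefix) {
    cfg <- simulation_config(g, cvd4_initial(), n_patients = 150, seed = seed)
    tbl <- tibble::as_tibble(simulate_cohort(cfg))
    tbl$patient_id <- paste0(prefix, tbl$patient_id)
    tbl$sex <- sex
    tbl
  }
  combined <- as_episode_tbl(rbind(mk(g_fast, 21, "M", "m"),
                                   mk(g_slow, 22, "F", "f")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_episodes(combined, f)
  cfg <- pipeline_cfg(f, prediction = list(interval_days = 180, horizon_days = 720))
  cmp <- suppressMessages(stratified_compare(cfg, "sex"))
  expect_named(cmp$bundles, c("F", "M"))
  expect_equal(cmp$strata$n_patients, c(150L, 150L))
  expect_equal(cmp$strata$n_records, c(sum(combined$sex == "F"),
                                       sum(combined$sex == "M")))
  # strata share one state space
  expect_identical(cmp$bundles$F$state_space$states,
                   cmp$bundles$M$state_space$states)
  # pooled per-stratum counts equal the unstratified counts
  full <- suppressMessages(run_pipeline(cfg))
  pooled <- cmp$bundles$F$counts$N + cmp$bundles$M$counts$N
  expect_equal(pooled[rownames(full$counts$N), colnames(full$counts$N)],
               full$counts$N)
  # the faster-male cohort should show higher death probability early on:
  # difference table is F - M, so death-column differences are negative
  ddeath <- dplyr::filter(cmp$difference, to_state == "Death",
                          start_state == "CHF", time_days == 180)
  expect_lt(ddeath$difference, 0)
  # covariate errors
  expect_error(suppressMessages(stratified_compare(cfg, "nope")), "not present")
  broken <- combined
  broken$sex[1] <- "X"
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_episodes(broken, f2)
  expect_error(suppressMessages(stratified_compare(pipeline_cfg(f2), "sex")),
               "constant")
})

test_that("single-stratum input yields one bundle and an empty difference table", {
  g <- cvd4_generator()
  cfg0 <- simulation_config(g, cvd4_initial(), n_patients = 40, seed = 30)
  tbl <- tibble::as_tibble(simulate_cohort(cfg0))
  tbl$sex <- "F"
  f <- withr::local_tempfile(fileext = ".csv")
  write_episodes(as_episode_tbl(tbl), f)
  cmp <- suppressMessages(stratified_compare(
    pipeline_cfg(f, prediction = list(interval_days = 180, horizon_days = 360)),
    "sex"))
  expect_length(cmp$bundles, 1L)
  expect_equal(nrow(cmp$difference), 0L)
})
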