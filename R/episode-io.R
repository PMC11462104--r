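#' Read an episodic cohort file
#'
#' Reads longitudinal episode records in the minimal three-column format a
#' cohort registry export provides: a patient identifier, an episode (disease
#' state) label, and the episode time in whole days since that patient's
#' baseline date. Any additional columns are kept as per-record covariates
#' (for example `sex`) and can later drive stratified comparisons.
#'
#' @param path Path to a delimited text file, or a connection.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param col_patient,col_episode,col_day Names (when the file has a header)
#'   or 1-based positions (when it does not) of the three required columns.
#' @param has_header Does the file carry a header row?
#'
#' @return A tibble of class `episode_tbl` with columns `patient_id`
#'   (character), `episode` (character), `day` (integer) and one column per
#'   covariate, in canonical `(patient_id, day, episode)` order. The source
#'   path is recorded in the `"source"` attribute and covariate column names
#'   in `"covariates"`.
#'
#' @details Days must be non-negative integers: the format is
#'   baseline-relative whole days, so fractional or negative values are a
#'   hard error naming the offending row. Exact duplicate rows are preserved;
#'   collapsing duplicates is a trajectory-building concern, not an I/O one.
#'
#' @examples
#' f <- system.file("extdata", "episodes_two_patients.csv", package = "ctmccohort")
#' read_episodes(f)
#' @export
read_episodes <- function(path, delim = ",",
                          col_patient = "patient_id", col_episode = "episode",
                          col_day = "day", has_header = TRUE) {
  raw <- readr::read_delim(path, delim = delim, col_names = has_header,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    abort("episode file is empty (no data rows)")
  }
  pick <- function(key, what) {
    if (is.numeric(key)) {
      if (key > ncol(raw)) abort(sprintf("column position %d for %s exceeds %d columns", key, what, ncol(raw)))
      return(as.integer(key))
    }
    idx <- match(key, names(raw))
    if (is.na(idx)) abort(sprintf("required column '%s' (%s) not found; columns are: %s",
                                  key, what, paste(names(raw), collapse = ", ")))
    idx
  }
  ip <- pick(col_patient, "patient identifier")
  ie <- pick(col_episode, "episode label")
  id <- pick(col_day, "episode day")

  day_chr <- raw[[id]]
  day_num <- suppressWarnings(as.numeric(day_chr))
  bad <- which(is.na(day_num) | day_num < 0 | day_num != floor(day_num))
  if (length(bad) > 0L) {
    abort(sprintf("row %d: day '%s' is not a non-negative whole number",
                  bad[1], day_chr[bad[1]]))
  }

  covar_idx <- setdiff(seq_len(ncol(raw)), c(ip, ie, id))
  out <- tibble(
    patient_id = as.character(raw[[ip]]),
    episode    = trimws(as.character(raw[[ie]])),
    day        = as.integer(day_num)
  )
  for (j in covar_idx) out[[names(raw)[j]]] <- raw[[j]]
  new_episode_tbl(out,
                  source = if (is.character(path)) path else "<connection>",
                  covariates = names(raw)[covar_idx])
}

new_episode_tbl <- function(df, source = NA_character_, covariates = character()) {
  df <- as_tibble(df)
  df <- arrange(df, .data$patient_id, .data$day, .data$episode)
  attr(df, "source") <- source
  attr(df, "covariates") <- covariates
  class(df) <- unique(c("episode_tbl", class(df)))
  df
}

#' Coerce a data frame to an episode table
#'
#' @param df A data frame with columns `patient_id`, `episode`, `day`; any
#'   other columns become covariates.
#' @return An `episode_tbl` in canonical order.
#' @export
as_episode_tbl <- function(df) {
  req <- c("patient_id", "episode", "day")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df$patient_id <- as.character(df$patient_id)
  df$episode <- trimws(as.character(df$episode))
  if (any(is.na(df$day)) || any(df$day < 0) || any(df$day != floor(df$day))) {
    abort("'day' must be non-negative whole numbers")
  }
  df$day <- as.integer(df$day)
  new_episode_tbl(df, covariates = setdiff(names(df), req))
}

episode_covariates <- function(table) attr(table, "covariates") %||% character()

#' Write an episodic cohort file
#'
#' Writes an episode table back to delimited text in the same three-column
#' (+ covariates) layout that [read_episodes()] consumes, so that simulated
#' cohorts round-trip through files byte-stably.
#'
#' @param table An `episode_tbl`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(table, path, delim = ",") {
  stopifnot(is.data.frame(table))
  cols <- c("patient_id", "episode", "day", episode_covariates(table))
  out <- as_tibble(table)[, intersect(cols, names(table)), drop = FALSE]
  out <- arrange(out, .data$patient_id, .data$day, .data$episode)
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Validate an episode table
#'
#' Report-based validation: counts records and patients and flags problems
#' without stopping. Negative or missing days and blank episode labels are
#' errors; an episode recorded after the same patient's absorbing (death)
#' episode is a warning, since downstream trajectory building discards such
#' records rather than failing (registry noise is common).
#'
#' @param table An `episode_tbl` or compatible data frame.
#' @param absorbing_labels Labels treated as absorbing when checking for
#'   post-death records.
#' @return A list of class `validation_report` with elements `n_records`,
#'   `n_patients`, `errors` and `warnings` (tibbles of `row`, `message`).
#'   The table is accepted iff `errors` is empty.
#' @export
validate_episodes <- function(table, absorbing_labels = "Death") {
  df <- as_tibble(table)
  errors <- list(); warnings <- list()
  note <- function(store, row, msg) c(store, list(tibble(row = row, message = msg)))

  if (!all(c("patient_id", "episode", "day") %in% names(df))) {
    errors <- note(errors, NA_integer_, "missing required column(s)")
    df <- tibble(patient_id = character(), episode = character(), day = integer())
  }
  blank <- which(is.na(df$episode) | trimws(df$episode) == "")
  for (r in blank) errors <- note(errors, r, "blank episode label")
  badday <- which(is.na(df$day) | df$day < 0)
  for (r in badday) errors <- note(errors, r, sprintf("invalid day '%s'", df$day[r]))

  # post-absorbing episodes: anything on a later day than the patient's first
  # absorbing episode
  if (nrow(df) > 0L) {
    idx <- seq_len(nrow(df))
    split_rows <- split(idx, df$patient_id)
    for (rows in split_rows) {
      dd <- df$day[rows]
      abs_rows <- rows[df$episode[rows] %in% absorbing_labels]
      if (length(abs_rows) > 0L) {
        d_abs <- min(df$day[abs_rows])
        late <- rows[dd > d_abs]
        for (r in late) {
          warnings <- note(warnings, r,
                           sprintf("episode '%s' on day %d after absorbing episode on day %d",
                                   df$episode[r], df$day[r], d_abs))
        }
      }
    }
  }
  empty <- tibble(row = integer(), message = character())
  structure(
    list(n_records = nrow(df),
         n_patients = dplyr::n_distinct(df$patient_id),
         errors = if (length(errors)) bind_rows(errors) else empty,
         warnings = if (length(warnings)) bind_rows(warnings) else empty),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Episode table: %d records, %d patients; %d error(s), %d warning(s)\n",
              x$n_records, x$n_patients, nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(x$errors)
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}
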