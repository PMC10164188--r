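# CSV dialects: training data (subject_id, session, level) and transfer
# panels (subject_id, task, session, score; empty score = missing).

#' Read a training CSV
#'
#' Reads long-format daily training performance: one row per observed
#' session, columns `subject_id` (string), `session` (integer >= 1) and
#' `level` (positive number). Rows are returned sorted by subject (order
#' of first appearance) and session.
#'
#' @param path Path to a UTF-8, comma-separated file with a header.
#' @return A tibble with columns `subject_id`, `session`, `level`
#'   (zero rows for a header-only file).
#' @export
read_training_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("subject_id", "session", "level")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("training CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  session <- suppressWarnings(as.numeric(df$session))
  level <- suppressWarnings(as.numeric(df$level))
  bad <- which(is.na(session) | is.na(level) |
                 session != as.integer(session) | session < 1)
  if (length(bad)) {
    abort(sprintf(
      "training CSV row %d (subject %s): non-numeric or invalid session/level.",
      bad[1] + 1L, df$subject_id[bad[1]]))
  }
  out <- tibble(subject_id = as.character(df$subject_id),
                session = as.integer(session), level = level)
  dup <- duplicated(out[c("subject_id", "session")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    abort(sprintf("duplicate row for subject %s, session %d.",
                  d$subject_id, d$session))
  }
  out %>% arrange(match(.data$subject_id, unique(.data$subject_id)),
                  .data$session)
}

#' Write a training CSV
#'
#' @param data Tibble with columns `subject_id`, `session`, `level`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_csv <- function(data, path) {
  readr::write_csv(data[c("subject_id", "session", "level")], path)
  invisible(path)
}

#' Read a transfer-panel CSV
#'
#' Columns: `subject_id`, `task` (Grid, OOO, FI or Math), `session`
#' (1..5) and `score` (number, empty for a missed test).
#'
#' @param path Path to the CSV file.
#' @return A long panel tibble; missing scores are `NA`, never zero.
#' @export
read_transfer_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("subject_id", "task", "session", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("transfer CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(!is.na(df$score) & df$score != "" & is.na(score))
  if (length(bad)) {
    abort(sprintf("transfer CSV row %d: non-numeric score '%s'.",
                  bad[1] + 1L, df$score[bad[1]]))
  }
  out <- tibble(subject_id = as.character(df$subject_id),
                task = as.character(df$task),
                session = as.integer(df$session),
                score = score)
  check_panel(out)
  out
}

#' Write a transfer-panel CSV
#'
#' @param panel Long panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(panel, path) {
  readr::write_csv(panel[c("subject_id", "task", "session", "score")],
                   path)
  invisible(path)
}
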