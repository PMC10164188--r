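# Preprocessing of transfer-test panels: subject exclusion, k-NN
# imputation of missing test scores, and standardization to baseline.
# A panel is a long tibble: subject_id, task (Grid/OOO/FI/Math),
# session (1..5), score (NA = missing).

check_panel <- function(panel) {
  need <- c("subject_id", "task", "session", "score")
  if (!all(need %in% names(panel))) {
    abort("panel must have columns subject_id, task, session, score.")
  }
  bad <- setdiff(unique(panel$task), panel_tasks)
  if (length(bad)) {
    abort(paste0("unknown task(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!panel$session %in% 1:5)) abort("sessions must be in 1..5.")
  if (anyDuplicated(panel[c("subject_id", "task", "session")])) {
    abort("duplicate (subject, task, session) rows in panel.")
  }
  invisible(panel)
}

#' Exclude subjects with too many missed tests
#'
#' Drops every subject whose number of missing test scores reaches
#' `max_missing`. Missingness is counted over the transfer tasks (OOO,
#' FI, Math; 15 cells per subject), so the default threshold of 6
#' corresponds to two full test sessions.
#'
#' @param panel Long transfer panel (`subject_id`, `task`, `session`,
#'   `score`; `NA` score = missing).
#' @param max_missing Subjects with this many or more missing cells are
#'   excluded (default 6).
#' @param tasks Tasks over which missing cells are counted.
#' @return The panel restricted to retained subjects (possibly empty).
#' @export
exclude_incomplete <- function(panel, max_missing = 6,
                               tasks = c("OOO", "FI", "Math")) {
  check_panel(panel)
  miss <- panel %>%
    filter(.data$task %in% tasks) %>%
    group_by(.data$subject_id) %>%
    summarise(n_missing = sum(is.na(.data$score)), .groups = "drop")
  keep <- miss$subject_id[miss$n_missing < max_missing]
  filter(panel, .data$subject_id %in% keep)
}

#' Impute missing test scores from the k nearest subjects
#'
#' Replaces each missing cell by the mean of that cell's value among the
#' `k` nearest subjects, where distance between two subjects is the
#' Euclidean distance over the cells observed in both, divided by the
#' number of co-observed cells. Only subjects with the target cell
#' observed are candidate neighbours; ties in distance are broken by
#' original subject order. Observed cells are never modified, and all
#' distances are computed on the original (pre-imputation) scores.
#'
#' @inheritParams exclude_incomplete
#' @param k Number of neighbours to average (default 35).
#' @return The panel with every `NA` score imputed.
#' @export
knn_impute <- function(panel, k = 35) {
  check_panel(panel)
  if (!any(is.na(panel$score))) return(panel)
  wide <- tidyr::pivot_wider(panel, id_cols = "subject_id",
                             names_from = c("task", "session"),
                             values_from = "score")
  ids <- wide$subject_id
  X <- as.matrix(wide[-1])
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0)) {
    abort(paste0("subject(s) with no observed cells: ",
                 paste(ids[rowSums(obs) == 0], collapse = ", ")))
  }
  Xf <- X
  for (i in which(rowSums(!obs) > 0)) {
    D <- sweep(X, 2, X[i, ])^2          # NA where either cell missing
    m <- rowSums(!is.na(D))
    d <- sqrt(rowSums(D, na.rm = TRUE)) / m
    d[m == 0] <- Inf
    d[i] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) < k) {
        abort(sprintf(
          "subject %s, cell %s: only %d candidate neighbours (< k = %d).",
          ids[i], colnames(X)[j], length(cand), k))
      }
      nn <- cand[order(d[cand], cand)][seq_len(k)]
      Xf[i, j] <- mean(X[nn, j])
    }
  }
  filled <- as_tibble(Xf) %>%
    mutate(subject_id = ids) %>%
    tidyr::pivot_longer(-"subject_id", names_to = c("task", "session"),
                        names_sep = "_", values_to = "score") %>%
    mutate(session = as.integer(.data$session))
  # restore the input row order
  panel %>%
    select(-"score") %>%
    left_join(filled, by = c("subject_id", "task", "session"))
}

#' Standardize panel scores to the first test session
#'
#' Per task, transforms every session's scores as
#' `(x - mean_T1) / sd_T1`, where the mean and standard deviation are
#' taken over the task's scores at session 1. After the transform each
#' task's session-1 column has mean 0 and standard deviation 1. The
#' transform is not idempotent on later sessions.
#'
#' @inheritParams exclude_incomplete
#' @return The standardized panel.
#' @export
standardize_to_T1 <- function(panel) {
  check_panel(panel)
  ref <- panel %>%
    filter(.data$session == 1L) %>%
    group_by(.data$task) %>%
    summarise(m1 = mean(.data$score, na.rm = TRUE),
              s1 = sd(.data$score, na.rm = TRUE), .groups = "drop")
  bad <- ref$task[!is.finite(ref$s1) | ref$s1 == 0]
  if (length(bad)) {
    abort(paste0("zero T1 variance for task(s): ",
                 paste(bad, collapse = ", ")))
  }
  panel %>%
    left_join(ref, by = "task") %>%
    mutate(score = (.data$score - .data$m1) / .data$s1) %>%
    select(-"m1", -"s1")
}
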