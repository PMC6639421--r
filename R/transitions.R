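#' Build first-order transition records from daily states
#'
#' Converts each subject's daily 0/1 series into one transition record per
#' observed day: the pair (previous state, current state), carrying along any
#' per-day covariate columns. The previous state of a subject's first day is
#' the configured initial state — 1 by default, reflecting the high overall
#' adherence of PrEP cohorts and prior evidence that the initial-state
#' assumption has limited impact.
#'
#' @param states Per-day tibble from [daily_states()] or
#'   [resolve_covariates()]; extra columns beyond `subject_id`, `date`, `day`,
#'   `state` are treated as covariates and retained.
#' @param initial_state Previous state assumed for each subject's first day
#'   (0 or 1, default 1).
#' @return A tibble `subject_id`, `day`, `prev_state`, `state`, covariates,
#'   plus a `transition` factor with levels `"01"`, `"11"`, `"10"`, `"00"`
#'   (prev then current).
#' @examples
#' s <- tibble::tibble(subject_id = "A", date = as.Date("2015-01-01") + 0:3,
#'                     day = 1:4, state = c(1L, 0L, 0L, 1L))
#' build_transitions(s)$transition
#' @export
build_transitions <- function(states, initial_state = 1L) {
  assert_that(initial_state %in% c(0L, 1L), "initial_state must be 0 or 1")
  assert_that(all(c("subject_id", "day", "state") %in% names(states)),
              "states must have subject_id, day and state columns")
  assert_that(all(states$state %in% c(0L, 1L)), "states must be 0/1")
  out <- states |>
    dplyr::arrange(.data$subject_id, .data$day) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(prev_state = dplyr::lag(.data$state, default = as.integer(initial_state))) |>
    dplyr::ungroup() |>
    dplyr::mutate(transition = transition_label(.data$prev_state, .data$state)) |>
    dplyr::relocate("prev_state", "state", "transition", .after = "day")
  out$date <- NULL
  out
}

transition_label <- function(prev, cur) {
  factor(paste0(prev, cur), levels = c("01", "11", "10", "00"))
}

#' Count the four transition types
#'
#' Tallies `[01]`, `[11]`, `[10]`, `[00]` transitions, optionally within groups
#' defined by covariate columns (e.g. per category of a covariate, mirroring a
#' per-covariate transition summary table).
#'
#' @param transitions Tibble from [build_transitions()].
#' @param by Optional character vector of grouping column names.
#' @return A tibble with one row per (group x) transition type, columns
#'   `transition`, `n`; counts sum to the number of records per group.
#' @export
count_transitions <- function(transitions, by = NULL) {
  if (!is.null(by)) {
    missing_cols <- setdiff(by, names(transitions))
    assert_that(length(missing_cols) == 0,
                paste0("unknown grouping column(s): ", paste(missing_cols, collapse = ", ")))
  }
  transitions |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "transition"))), .drop = FALSE) |>
    dplyr::rename(n = "n")
}

#' Screen covariates by transition sparsity
#'
#' Flags covariates whose categories are too sparse to support estimation of
#' all four transition types: a covariate is dropped when, within any one of
#' its categories, any of the four transition types accounts for strictly less
#' than `threshold` of that category's transitions. Exactly `threshold` is
#' retained. Optionally the rule can be applied to transitions pooled across
#' categories instead.
#'
#' @param transitions Tibble from [build_transitions()] including the covariate
#'   columns to screen.
#' @param covariates Character vector of covariate column names. Each column's
#'   distinct values define its categories (0/1 indicators or factors both
#'   work).
#' @param threshold Minimum share of transitions per type (default 0.05).
#' @param within `"category"` (default) applies the rule inside each category;
#'   `"pooled"` applies it to the covariate's pooled transitions.
#' @return A tibble `covariate`, `keep` (logical), `reason` (NA when kept,
#'   otherwise the offending category/type/share).
#' @export
screen_covariates <- function(transitions, covariates, threshold = 0.05,
                              within = c("category", "pooled")) {
  within <- match.arg(within)
  missing_cols <- setdiff(covariates, names(transitions))
  assert_that(length(missing_cols) == 0,
              paste0("unknown covariate column(s): ", paste(missing_cols, collapse = ", ")))
  purrr::map_dfr(covariates, function(cv) {
    groups <- if (within == "category") {
      split(transitions, transitions[[cv]], drop = TRUE)
    } else {
      list(pooled = transitions)
    }
    for (g in names(groups)) {
      cnt <- count_transitions(groups[[g]])
      total <- sum(cnt$n)
      if (total == 0) {
        return(tibble::tibble(covariate = cv, keep = FALSE,
                              reason = paste0("category ", g, " has no transitions")))
      }
      share <- cnt$n / total
      low <- which(share < threshold)
      if (length(low) > 0) {
        i <- low[which.min(share[low])]
        return(tibble::tibble(
          covariate = cv, keep = FALSE,
          reason = sprintf("category %s: [%s] is %.1f%% of %d transitions",
                           g, as.character(cnt$transition[i]), 100 * share[i], total)
        ))
      }
    }
    tibble::tibble(covariate = cv, keep = TRUE, reason = NA_character_)
  })
}
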