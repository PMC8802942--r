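#' Task data model: trial tables
#'
#' The package represents behaviour as a flat trial table (a tibble, one row
#' per trial). A *problem* is a block of trials sharing `problem_id`: four
#' objects are shown on every trial, one or two of them are rewarded targets,
#' and trials are organised into four *cycles*. Cycle 1 is the explore cycle
#' (the subject searches for the targets); each cycle ends once every target
#' has been selected. Reselecting a target already selected within a cycle is
#' not rewarded.
#'
#' Required columns:
#' \describe{
#'   \item{session_id, animal_id, problem_id, trial_id}{identifiers;
#'     `trial_id` is unique per row.}
#'   \item{n_targets}{1 or 2.}
#'   \item{object_set}{1 or 2 (which fixed 4-object set the problem used).}
#'   \item{cycle, trial_in_cycle}{cycle 1--4 and trial index within cycle.}
#'   \item{obj_loc_1 .. obj_loc_4}{display arrangement: location (1--4) of
#'     each object; a bijection of objects onto locations.}
#'   \item{target_1, target_2}{target object ids; `target_2` is `NA` on
#'     1-target problems.}
#'   \item{chosen_object, chosen_location}{the touched object/location, `NA`
#'     on no-response or aborted trials.}
#'   \item{correct, rewarded, aborted}{logicals.}
#'   \item{t_ch_on, t_go, t_touch, t_fb_on}{event times in seconds from trial
#'     start (choice-array onset, go cue, touch, feedback onset); later
#'     events are `NA` on aborted trials.}
#' }
#'
#' @name trial-table
NULL

#' Column names required in a trial table
#' @return character vector of column names.
#' @export
trial_table_columns <- function() {
  c("session_id", "animal_id", "problem_id", "trial_id",
    "n_targets", "object_set", "cycle", "trial_in_cycle",
    paste0("obj_loc_", 1:4), "target_1", "target_2",
    "chosen_object", "chosen_location",
    "correct", "rewarded", "aborted",
    "t_ch_on", "t_go", "t_touch", "t_fb_on")
}

#' Column names required in a long-format spike table
#' @return character vector of column names.
#' @export
spike_table_columns <- function() {
  c("cell_id", "trial_id", "spike_time_s")
}

#' Column names required in a cell table
#' @return character vector of column names.
#' @export
cell_table_columns <- function() {
  c("cell_id", "session_id", "region")
}

target_set <- function(trial) {
  stats::na.omit(c(trial$target_1, trial$target_2))
}

#' Classify one response against its within-cycle history
#'
#' Response types: `T` (target not yet selected this cycle), `T_revisit`
#' (target already selected this cycle; only possible with 2 targets),
#' `NT_novel` (nontarget not yet sampled this cycle), `NT_revisit`
#' (nontarget already sampled), `no_response` (no touch recorded).
#'
#' @param trial a one-row trial table (list or tibble row).
#' @param cycle_history trial table of *earlier* trials from the same problem
#'   and cycle (may have zero rows).
#' @return a single string, one of
#'   `c("T", "T_revisit", "NT_novel", "NT_revisit", "no_response")`.
#' @export
classify_response <- function(trial, cycle_history) {
  trial <- as.list(trial[1, , drop = FALSE])
  chosen <- trial$chosen_object
  if (is.null(chosen) || is.na(chosen)) return("no_response")
  targets <- target_set(trial)
  if (!chosen %in% 1:4) {
    stop("chosen_object ", chosen, " is not consistent with a 4-object set",
         call. = FALSE)
  }
  prior <- cycle_history$chosen_object
  prior <- prior[!is.na(prior)]
  if (chosen %in% targets) {
    if (chosen %in% prior) "T_revisit" else "T"
  } else {
    if (chosen %in% prior) "NT_revisit" else "NT_novel"
  }
}

#' Add a `response_type` column to a trial table
#'
#' Applies [classify_response()] within each problem and cycle, in
#' `trial_in_cycle` order.
#'
#' @param trials a trial table.
#' @return `trials` with a `response_type` character column.
#' @export
add_response_types <- function(trials) {
  trials <- dplyr::arrange(trials, .data$problem_id, .data$cycle,
                           .data$trial_in_cycle)
  grp <- interaction(trials$problem_id, trials$cycle, drop = TRUE)
  out <- character(nrow(trials))
  for (g in split(seq_len(nrow(trials)), grp)) {
    prior_objects <- integer(0)
    for (i in g) {
      chosen <- trials$chosen_object[i]
      if (is.na(chosen)) {
        out[i] <- "no_response"
        next
      }
      targets <- stats::na.omit(c(trials$target_1[i], trials$target_2[i]))
      revisit <- chosen %in% prior_objects
      out[i] <- if (chosen %in% targets) {
        if (revisit) "T_revisit" else "T"
      } else {
        if (revisit) "NT_revisit" else "NT_novel"
      }
      prior_objects <- c(prior_objects, chosen)
    }
  }
  trials$response_type <- out
  trials
}

#' Exclude problems with too many failures in one cycle
#'
#' A problem is dropped when the subject failed to respond (no touch, or an
#' aborted trial: key release / fixation break) on 6 or more trials within a
#' single cycle, indicating poor task focus. Aborted trials count toward the
#' threshold; the exclusion log flags how many of each kind contributed.
#'
#' @param trials a trial table.
#' @param max_failures threshold; a cycle with `>= max_failures` failed
#'   trials excludes its whole problem (default 6).
#' @return list with `trials` (filtered table) and `log` (tibble of excluded
#'   `problem_id`, worst-cycle failure count, and its split into no-response
#'   and aborted trials).
#' @export
apply_problem_exclusion <- function(trials, max_failures = 6L) {
  if (nrow(trials) == 0L) {
    return(list(trials = trials,
                log = tibble::tibble(problem_id = character(),
                                     cycle = integer(),
                                     n_failed = integer(),
                                     n_no_response = integer(),
                                     n_aborted = integer())))
  }
  failed <- is.na(trials$chosen_object) | trials$aborted
  per_cycle <- dplyr::summarise(
    dplyr::group_by(trials, .data$problem_id, .data$cycle),
    n_failed = sum(failed[dplyr::cur_group_rows()]),
    n_aborted = sum(.data$aborted),
    n_no_response = sum(is.na(.data$chosen_object) & !.data$aborted),
    .groups = "drop")
  bad <- dplyr::filter(per_cycle, .data$n_failed >= max_failures)
  excl_log <- dplyr::select(bad, "problem_id", "cycle", "n_failed",
                            "n_no_response", "n_aborted")
  list(trials = dplyr::filter(trials,
                              !.data$problem_id %in% bad$problem_id),
       log = excl_log)
}

#' Expected number of search trials for an optimal random searcher
#'
#' For a searcher sampling objects uniformly at random without revisits, the
#' number of trials needed to have selected all targets equals the maximum of
#' the targets' positions in a uniformly random permutation of the objects,
#' with expectation `n_targets * (n_objects + 1) / (n_targets + 1)`.
#' With 4 objects this gives 2.50 for one target and 10/3 for two.
#'
#' @param n_objects number of objects in the display.
#' @param n_targets number of rewarded targets.
#' @return expected trial count (double).
#' @export
expected_search_trials <- function(n_objects, n_targets) {
  stopifnot(length(n_objects) == 1L, length(n_targets) == 1L)
  if (!(n_targets >= 1 && n_targets <= n_objects)) {
    stop("require 1 <= n_targets <= n_objects", call. = FALSE)
  }
  n_targets * (n_objects + 1) / (n_targets + 1)
}

#' Revisit probability of a memoryless uniform chooser
#'
#' @param n_already_sampled number of distinct objects already sampled this
#'   cycle (0 to `n_objects - 1`).
#' @param n_objects number of objects in the display.
#' @return probability `n_already_sampled / n_objects`.
#' @export
chance_revisit_probability <- function(n_already_sampled, n_objects = 4L) {
  if (any(n_already_sampled < 0 | n_already_sampled >= n_objects)) {
    stop("require 0 <= n_already_sampled < n_objects", call. = FALSE)
  }
  n_already_sampled / n_objects
}

#' Probability that the first object sampled is a target
#'
#' @inheritParams expected_search_trials
#' @return probability `n_targets / n_objects`.
#' @export
first_target_probability <- function(n_objects, n_targets) {
  if (!(n_targets >= 1 && n_targets <= n_objects)) {
    stop("require 1 <= n_targets <= n_objects", call. = FALSE)
  }
  n_targets / n_objects
}
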