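#' Analysis window specification
#'
#' A window is aligned to a trial event (`CH` = choice-array onset, `FB` =
#' feedback onset) and spans the half-open interval
#' `[event + start, event + start + width)` so that adjacent windows
#' partition time.
#'
#' @param alignment `"CH"` or `"FB"`.
#' @param start window start in seconds relative to the alignment event.
#' @param width window width in seconds (> 0).
#' @return a `window_spec` list.
#' @export
window_spec <- function(alignment = c("CH", "FB"), start = 0, width = 0.4) {
  alignment <- match.arg(alignment)
  stopifnot(is.numeric(start), is.numeric(width), width > 0)
  structure(list(alignment = alignment, start = start, width = width),
            class = "window_spec")
}

#' @export
format.window_spec <- function(x, ...) {
  sprintf("%s [%+.3f, %+.3f) s", x$alignment, x$start, x$start + x$width)
}

#' @export
print.window_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

alignment_column <- function(alignment) {
  switch(alignment, CH = "t_ch_on", FB = "t_fb_on",
         stop("unknown alignment ", alignment, call. = FALSE))
}

#' The standard 400 ms selection windows
#'
#' Two windows beginning at CH onset and FB onset, used for cell selection,
#' validation t tests and discriminant analyses.
#' @return named list of two [window_spec()]s.
#' @export
selection_windows <- function() {
  list(CH = window_spec("CH", 0, 0.4), FB = window_spec("FB", 0, 0.4))
}

#' The 4 x 100 ms windows per phase for cross-temporal generalization
#' @return named list of eight [window_spec()]s (4 CH then 4 FB).
#' @export
crossgen_windows <- function() {
  starts <- seq(0, 0.3, by = 0.1)
  w <- c(lapply(starts, function(s) window_spec("CH", s, 0.1)),
         lapply(starts, function(s) window_spec("FB", s, 0.1)))
  names(w) <- c(sprintf("CH_%03d", round(starts * 1000)),
                sprintf("FB_%03d", round(starts * 1000)))
  w
}

#' PSTH window centres
#'
#' 100 ms windows centred from -200 ms to +475 ms in 25 ms steps (28
#' overlapping windows).
#' @return numeric vector of 28 window centres (seconds).
#' @export
psth_centers <- function() seq(-0.200, 0.475, by = 0.025)

#' Windowed firing rate of one spike train on one trial
#'
#' Counts spikes in the half-open window and divides by its width. A spike
#' exactly at the window end is excluded.
#'
#' @param spike_times numeric vector of spike times (s from trial start).
#' @param trial one-row trial table carrying the alignment event time.
#' @param window a [window_spec()].
#' @return rate in spikes/s, or `NA` if the alignment event is missing.
#' @export
window_rate <- function(spike_times, trial, window) {
  ev <- trial[[alignment_column(window$alignment)]][1]
  if (is.na(ev)) return(NA_real_)
  lo <- ev + window$start
  sum(spike_times >= lo & spike_times < lo + window$width) / window$width
}

#' Windowed firing rates for all cells and trials
#'
#' Vectorised version of [window_rate()]: returns one rate per cell x trial
#' combination, zero-filled for trials without spikes in the window. Trials
#' missing the alignment event are dropped. Each cell contributes only trials
#' from its own session.
#'
#' @param spikes spike table (`cell_id`, `trial_id`, `spike_time_s`).
#' @param trials a trial table.
#' @param cells cell table (`cell_id`, `session_id`, `region`).
#' @param window a [window_spec()].
#' @return tibble with `cell_id`, `trial_id`, `rate` (spikes/s).
#' @export
window_rates <- function(spikes, trials, cells, window) {
  ev_col <- alignment_column(window$alignment)
  tr <- trials[!is.na(trials[[ev_col]]),
               c("trial_id", "session_id", ev_col)]
  grid <- dplyr::inner_join(cells[, c("cell_id", "session_id")], tr,
                            by = "session_id",
                            relationship = "many-to-many")
  ev <- tr[[ev_col]][match(spikes$trial_id, tr$trial_id)]
  lo <- ev + window$start
  keep <- !is.na(ev) & spikes$spike_time_s >= lo &
    spikes$spike_time_s < lo + window$width &
    spikes$cell_id %in% cells$cell_id
  counts <- dplyr::count(spikes[keep, c("cell_id", "trial_id")],
                         .data$cell_id, .data$trial_id)
  out <- dplyr::left_join(grid[, c("cell_id", "trial_id")], counts,
                          by = c("cell_id", "trial_id"))
  out$rate <- dplyr::coalesce(out$n, 0L) / window$width
  out$n <- NULL
  tibble::as_tibble(out)
}

#' Unweighted mean over task-condition cells
#'
#' Mean of per-condition means over the non-empty cells of the condition
#' grid, removing the influence of unequal trial counts per condition.
#'
#' @param df tibble with a `rate` column and the condition columns.
#' @param by condition column names.
#' @return scalar unweighted mean (NA if no data).
#' @export
unweighted_mean <- function(df, by = c("n_targets", "object_set",
                                       "chosen_location")) {
  if (nrow(df) == 0L) return(NA_real_)
  cond_means <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(by))),
    m = mean(.data$rate), .groups = "drop")
  mean(cond_means$m)
}
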