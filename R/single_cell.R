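#' Flag regular exploit cycles
#'
#' A Cycle 2--4 cycle is *regular* when its first completed response was
#' correct; cycles whose first response was an error are excluded from the
#' one-shot analyses.
#'
#' @param trials a trial table.
#' @return tibble with `problem_id`, `cycle`, `regular` for cycles 2--4.
#' @keywords internal
#' @export
regular_cycle_flags <- function(trials) {
  t24 <- dplyr::filter(trials, .data$cycle >= 2L, !is.na(.data$chosen_object))
  t24 <- dplyr::arrange(t24, .data$problem_id, .data$cycle,
                        .data$trial_in_cycle)
  firsts <- dplyr::slice_head(
    dplyr::group_by(t24, .data$problem_id, .data$cycle), n = 1L)
  dplyr::transmute(dplyr::ungroup(firsts), problem_id = .data$problem_id,
                   cycle = .data$cycle, regular = .data$correct)
}

#' Identify failed-learning trials
#'
#' Failed-learning trials are correct Cycle-2 trials preceded by at least one
#' completed Cycle-2 error in the same problem, indicating that learning did
#' not complete in Cycle 1.
#'
#' @param trials a trial table (typically restricted to 1-target problems).
#' @return character vector of `trial_id`s.
#' @export
failed_learning_trials <- function(trials) {
  c2 <- dplyr::filter(trials, .data$cycle == 2L, !is.na(.data$chosen_object))
  c2 <- dplyr::arrange(c2, .data$problem_id, .data$trial_in_cycle)
  ids <- character(0)
  for (g in split(seq_len(nrow(c2)),
                  factor(c2$problem_id, levels = unique(c2$problem_id)))) {
    err_seen <- FALSE
    for (i in g) {
      if (c2$correct[i] && err_seen) ids <- c(ids, c2$trial_id[i])
      if (!c2$correct[i]) err_seen <- TRUE
    }
  }
  ids
}

#' Sampling position of each Cycle-1 trial
#'
#' Position = number of distinct objects already sampled this cycle + 1, so
#' the first object sampled has position 1 and a target found after three
#' other objects has position 4. Revisits keep the position implied by the
#' distinct count.
#'
#' @param trials a trial table.
#' @return integer vector along rows of `trials` (`NA` off Cycle 1 or on
#'   trials without a choice).
#' @export
sampling_positions <- function(trials) {
  pos <- rep(NA_integer_, nrow(trials))
  c1 <- which(trials$cycle == 1L & !is.na(trials$chosen_object))
  ord <- c1[order(trials$problem_id[c1], trials$trial_in_cycle[c1])]
  for (g in split(ord, factor(trials$problem_id[ord],
                              levels = unique(trials$problem_id[ord])))) {
    sampled <- integer(0)
    for (i in g) {
      pos[i] <- length(sampled) + 1L
      sampled <- union(sampled, trials$chosen_object[i])
    }
  }
  pos
}

#' Favoured first-choice location per animal
#'
#' The modal touched location on the first trial of Cycle 1. Ties resolve to
#' the lowest location index and are flagged.
#'
#' @param trials a trial table.
#' @return tibble with `animal_id`, `favored_location`, `tie`, `n_trials`.
#' @export
favored_location <- function(trials) {
  firsts <- dplyr::filter(trials, .data$cycle == 1L,
                          .data$trial_in_cycle == 1L,
                          !is.na(.data$chosen_location))
  if (nrow(firsts) == 0L) stop("no completed first Cycle-1 trials",
                               call. = FALSE)
  out <- lapply(split(firsts, firsts$animal_id), function(d) {
    m <- modal_value(d$chosen_location)
    if (m$tie) {
      message("favored_location: tie for animal ", d$animal_id[1],
              "; lowest location index used")
    }
    tibble::tibble(animal_id = d$animal_id[1],
                   favored_location = m$value, tie = m$tie,
                   n_trials = nrow(d))
  })
  dplyr::bind_rows(out)
}

# -- shared machinery for group-level condition means ------------------------

# tibble(cell_id, trial_id) pairing every cell with a trial subset from its
# own session
all_cells_trials <- function(cells, trials_subset) {
  dplyr::inner_join(cells[, c("cell_id", "session_id")],
                    trials_subset[, c("trial_id", "session_id")],
                    by = "session_id",
                    relationship = "many-to-many")[, c("cell_id", "trial_id")]
}

# per-cell normalised mean rate per condition, for labelled cells.
# cond_trials: tibble(cell_id, trial_id, condition); rates computed in each
# cell's own phase window.
group_condition_means <- function(labelled, trials, spikes, cells, norms,
                                  cond_trials,
                                  windows = selection_windows()) {
  out <- list()
  for (ph in unique(labelled$phase)) {
    rates <- window_rates(spikes, trials, cells, windows[[ph]])
    ids <- labelled$cell_id[labelled$phase == ph]
    dat <- dplyr::inner_join(
      rates, cond_trials[cond_trials$cell_id %in% ids, ],
      by = c("cell_id", "trial_id"))
    if (nrow(dat) == 0L) next
    m <- dplyr::summarise(
      dplyr::group_by(dat, .data$cell_id, .data$condition),
      value = mean(.data$rate), n_trials = dplyr::n(), .groups = "drop")
    m$phase <- ph
    out[[ph]] <- m
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) return(out)
  out$value <- out$value / norms$norm_constant[match(out$cell_id,
                                                     norms$cell_id)]
  out <- out[!is.na(out$value) &
               out$cell_id %in% norms$cell_id[norms$usable], ]
  key <- paste(labelled$cell_id, labelled$phase)
  out$label <- labelled$label[match(paste(out$cell_id, out$phase), key)]
  out
}

# paired t between two conditions, across cells with both defined
paired_condition_t <- function(m, cond_a, cond_b) {
  wide <- tidyr::pivot_wider(m[m$condition %in% c(cond_a, cond_b),
                               c("cell_id", "condition", "value")],
                             names_from = "condition",
                             values_from = "value")
  if (!all(c(cond_a, cond_b) %in% names(wide))) {
    return(tibble::tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                          n_cells = 0L))
  }
  ok <- stats::complete.cases(wide[, c(cond_a, cond_b)])
  if (sum(ok) < 2L) {
    return(tibble::tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                          n_cells = sum(ok)))
  }
  tt <- t.test(wide[[cond_a]][ok], wide[[cond_b]][ok], paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_cells = sum(ok))
}

# one-way repeated-measures F across conditions, cell as the repeated unit
# (two-way ANOVA value ~ condition + cell, one observation per cell x
# condition, complete cases only)
repeated_measures_f <- function(m) {
  wide <- tidyr::pivot_wider(m[, c("cell_id", "condition", "value")],
                             names_from = "condition",
                             values_from = "value")
  conds <- setdiff(names(wide), "cell_id")
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2L || length(conds) < 2L) {
    return(tibble::tibble(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                          p_value = NA_real_, n_cells = nrow(wide)))
  }
  long <- tidyr::pivot_longer(wide, -"cell_id", names_to = "condition",
                              values_to = "value")
  fit <- aov(value ~ factor(condition) + factor(cell_id), data = long)
  tab <- summary(fit)[[1]]
  i <- grep("condition", rownames(tab))
  tibble::tibble(F = tab[i, "F value"], df1 = tab[i, "Df"],
                 df2 = tab[nrow(tab), "Df"], p_value = tab[i, "Pr(>F)"],
                 n_cells = nrow(wide))
}

# -- analyses ---------------------------------------------------------------

#' One-shot transition of group activity across cycles
#'
#' For 1-target problems, compares mean normalised activity of each
#' explore/exploit group across Cycles 1--4 in the group's 0--400 ms phase
#' window. Cycles 1 and 4 use each cell's validation half; Cycles 2 and 3
#' use all trials. For Cycles 2--4, cycles whose first response was an error
#' are excluded ([regular_cycle_flags()]). Tests per group: paired t between
#' Cycles 1 and 2, and a repeated-measures F across Cycles 2--4.
#'
#' @param selection labelled output of [run_selection()].
#' @param trials,spikes,cells the dataset tables.
#' @param split the selection/validation [split_trials()] assignment.
#' @param norms output of [cell_norm_constants()].
#' @param windows phase windows, default [selection_windows()].
#' @return list with `cell_means` (per cell x cycle), `group_means`, and
#'   `tests` (per phase x label).
#' @export
one_shot_cycle_analysis <- function(selection, trials, spikes, cells, split,
                                    norms, windows = selection_windows()) {
  labelled <- selection[selection$label != "none", ]
  base <- dplyr::filter(trials, .data$n_targets == 1L, .data$correct)
  reg <- regular_cycle_flags(trials)
  base24 <- dplyr::inner_join(
    dplyr::filter(base, .data$cycle %in% 2:4),
    dplyr::filter(reg, .data$regular)[, c("problem_id", "cycle")],
    by = c("problem_id", "cycle"))
  val_half <- split[split$half == "validation", c("cell_id", "trial_id")]
  ct14 <- dplyr::inner_join(
    val_half,
    dplyr::filter(base, .data$cycle %in% c(1L, 4L))[, c("trial_id", "cycle")],
    by = "trial_id")
  ct23 <- dplyr::inner_join(
    all_cells_trials(cells, dplyr::filter(base24, .data$cycle %in% 2:3)),
    base24[, c("trial_id", "cycle")], by = "trial_id")
  cond_trials <- dplyr::bind_rows(ct14, ct23)
  cond_trials$condition <- paste0("C", cond_trials$cycle)
  cond_trials$cycle <- NULL
  m <- group_condition_means(labelled, trials, spikes, cells, norms,
                             cond_trials, windows)
  groups <- dplyr::group_split(dplyr::group_by(m, .data$phase, .data$label))
  tests <- lapply(groups, function(g) {
    dplyr::bind_cols(
      tibble::tibble(phase = g$phase[1], label = g$label[1]),
      dplyr::rename_with(paired_condition_t(g, "C1", "C2"),
                         ~ paste0("c1_vs_c2_", .x)),
      dplyr::rename_with(repeated_measures_f(
        g[g$condition %in% c("C2", "C3", "C4"), ]),
        ~ paste0("c2_c4_", .x)))
  })
  group_means <- dplyr::summarise(
    dplyr::group_by(m, .data$phase, .data$label, .data$condition),
    value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  list(cell_means = m, group_means = group_means,
       tests = dplyr::bind_rows(tests))
}

#' Activity on failed-learning trials
#'
#' Compares group activity on Cycle-2 failed-learning trials
#' ([failed_learning_trials()]) with regular Cycle-2 trials and with Cycle-1
#' (validation half), in 1-target problems. Paired t tests across cells.
#'
#' @inheritParams one_shot_cycle_analysis
#' @param min_cells minimum cells with failed-learning data per group.
#' @return list with `cell_means`, `group_means` and `tests`; groups with
#'   too few failed-learning observations are reported with `NA` tests.
#' @export
failed_learning_analysis <- function(selection, trials, spikes, cells, split,
                                     norms, windows = selection_windows(),
                                     min_cells = 2L) {
  labelled <- selection[selection$label != "none", ]
  base <- dplyr::filter(trials, .data$n_targets == 1L)
  failed_ids <- failed_learning_trials(base)
  reg <- regular_cycle_flags(trials)
  regular_c2 <- dplyr::inner_join(
    dplyr::filter(base, .data$cycle == 2L, .data$correct),
    dplyr::filter(reg, .data$cycle == 2L, .data$regular)["problem_id"],
    by = "problem_id")
  val_half <- split[split$half == "validation", c("cell_id", "trial_id")]
  c1 <- dplyr::filter(base, .data$cycle == 1L, .data$correct)
  cond_trials <- dplyr::bind_rows(
    dplyr::mutate(dplyr::inner_join(val_half, c1["trial_id"],
                                    by = "trial_id"),
                  condition = "C1"),
    dplyr::mutate(all_cells_trials(cells, regular_c2),
                  condition = "C2_regular"),
    dplyr::mutate(all_cells_trials(
      cells, base[base$trial_id %in% failed_ids, ]),
      condition = "C2_failed"))
  m <- group_condition_means(labelled, trials, spikes, cells, norms,
                             cond_trials, windows)
  groups <- dplyr::group_split(dplyr::group_by(m, .data$phase, .data$label))
  tests <- lapply(groups, function(g) {
    n_failed <- sum(g$condition == "C2_failed")
    base_row <- tibble::tibble(phase = g$phase[1], label = g$label[1],
                               n_cells_failed = n_failed)
    if (n_failed < min_cells) {
      return(dplyr::bind_cols(base_row, tibble::tibble(
        failed_vs_regular_t = NA_real_, failed_vs_regular_p = NA_real_,
        failed_vs_c1_t = NA_real_, failed_vs_c1_p = NA_real_)))
    }
    t1 <- paired_condition_t(g, "C2_failed", "C2_regular")
    t2 <- paired_condition_t(g, "C2_failed", "C1")
    dplyr::bind_cols(base_row, tibble::tibble(
      failed_vs_regular_t = t1$t, failed_vs_regular_p = t1$p_value,
      failed_vs_c1_t = t2$t, failed_vs_c1_p = t2$p_value))
  })
  group_means <- dplyr::summarise(
    dplyr::group_by(m, .data$phase, .data$label, .data$condition),
    value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  list(cell_means = m, group_means = group_means,
       tests = dplyr::bind_rows(tests))
}

#' Group activity by Cycle-1 sampling position
#'
#' For 1-target problems, correct Cycle-1 trials on which the target was
#' found in the animal's favoured location are binned by sampling position
#' (target was the 1st--4th different object sampled). Selection-half trials
#' are removed. Repeated-measures F across positions per group; a flat
#' profile argues against graded reward-expectancy coding.
#'
#' @inheritParams one_shot_cycle_analysis
#' @return list with `cell_means`, `group_means`, `tests`.
#' @export
sampling_order_analysis <- function(selection, trials, spikes, cells, split,
                                    norms, windows = selection_windows()) {
  labelled <- selection[selection$label != "none", ]
  fav <- favored_location(trials)
  trials$sampling_position <- sampling_positions(trials)
  base <- dplyr::filter(
    trials, .data$n_targets == 1L, .data$cycle == 1L, .data$correct,
    .data$chosen_location ==
      fav$favored_location[match(.data$animal_id, fav$animal_id)])
  val_half <- split[split$half == "validation", c("cell_id", "trial_id")]
  cond_trials <- dplyr::inner_join(
    val_half, base[, c("trial_id", "sampling_position")], by = "trial_id")
  cond_trials$condition <- paste0("pos", cond_trials$sampling_position)
  cond_trials$sampling_position <- NULL
  m <- group_condition_means(labelled, trials, spikes, cells, norms,
                             cond_trials, windows)
  groups <- dplyr::group_split(dplyr::group_by(m, .data$phase, .data$label))
  tests <- lapply(groups, function(g) {
    dplyr::bind_cols(tibble::tibble(phase = g$phase[1], label = g$label[1]),
                     repeated_measures_f(g))
  })
  group_means <- dplyr::summarise(
    dplyr::group_by(m, .data$phase, .data$label, .data$condition),
    value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  list(cell_means = m, group_means = group_means,
       tests = dplyr::bind_rows(tests))
}

#' Group activity on correct versus error trials
#'
#' Cycle-1, 1-target trials at the favoured location, revisits excluded;
#' correct (target) and incorrect (nontarget) means are computed separately
#' per sampling position 1--3 and averaged unweighted across positions
#' (an error is impossible on position 4). Selection-half trials are removed;
#' this analysis requires error trials, overriding the correct-only filter
#' used elsewhere. Paired t per group.
#'
#' @inheritParams one_shot_cycle_analysis
#' @return list with `cell_means` (per cell: `correct_mean`,
#'   `incorrect_mean`), `tests`.
#' @export
correct_error_analysis <- function(selection, trials, spikes, cells, split,
                                   norms, windows = selection_windows()) {
  labelled <- selection[selection$label != "none", ]
  if (!"response_type" %in% names(trials)) {
    trials <- add_response_types(trials)
  }
  fav <- favored_location(trials)
  trials$sampling_position <- sampling_positions(trials)
  base <- dplyr::filter(
    trials, .data$n_targets == 1L, .data$cycle == 1L,
    .data$response_type %in% c("T", "NT_novel"),
    .data$sampling_position <= 3L,
    .data$chosen_location ==
      fav$favored_location[match(.data$animal_id, fav$animal_id)])
  val_half <- split[split$half == "validation", c("cell_id", "trial_id")]
  cond_trials <- dplyr::inner_join(
    val_half,
    base[, c("trial_id", "response_type", "sampling_position")],
    by = "trial_id")
  cond_trials$condition <- paste0(
    ifelse(cond_trials$response_type == "T", "correct", "incorrect"),
    "_pos", cond_trials$sampling_position)
  cond_trials <- cond_trials[, c("cell_id", "trial_id", "condition")]
  m <- group_condition_means(labelled, trials, spikes, cells, norms,
                             cond_trials, windows)
  if (nrow(m) == 0L) {
    return(list(cell_means = m, tests = tibble::tibble()))
  }
  m$outcome <- sub("_pos[0-9]$", "", m$condition)
  cellwise <- dplyr::summarise(
    dplyr::group_by(m, .data$cell_id, .data$phase, .data$label,
                    .data$outcome),
    value = mean(.data$value), .groups = "drop")  # unweighted over positions
  cellwise$condition <- cellwise$outcome
  groups <- dplyr::group_split(dplyr::group_by(cellwise, .data$phase,
                                               .data$label))
  tests <- lapply(groups, function(g) {
    dplyr::bind_cols(tibble::tibble(phase = g$phase[1], label = g$label[1]),
                     paired_condition_t(g, "correct", "incorrect"))
  })
  list(cell_means = cellwise[, c("cell_id", "phase", "label", "outcome",
                                 "value")],
       tests = dplyr::bind_rows(tests))
}

#' Group activity by target-discovery type
#'
#' Compares Cycle-1 target-discovery trials of three types: the single
#' discovery in 1-target problems, and the first and second discoveries in
#' 2-target problems (which carry different reward probabilities).
#' Selection-half trials are removed. Repeated-measures F per group.
#'
#' @inheritParams one_shot_cycle_analysis
#' @return list with `cell_means`, `group_means`, `tests`.
#' @export
discovery_type_analysis <- function(selection, trials, spikes, cells, split,
                                    norms, windows = selection_windows()) {
  labelled <- selection[selection$label != "none", ]
  if (!"response_type" %in% names(trials)) {
    trials <- add_response_types(trials)
  }
  disc <- dplyr::filter(trials, .data$cycle == 1L, .data$response_type == "T")
  disc <- dplyr::arrange(disc, .data$problem_id, .data$trial_in_cycle)
  disc <- dplyr::mutate(
    dplyr::group_by(disc, .data$problem_id),
    discovery_index = dplyr::row_number())
  disc <- dplyr::ungroup(disc)
  disc$condition <- dplyr::case_when(
    disc$n_targets == 1L ~ "one_target",
    disc$discovery_index == 1L ~ "first_of_two",
    TRUE ~ "second_of_two")
  val_half <- split[split$half == "validation", c("cell_id", "trial_id")]
  cond_trials <- dplyr::inner_join(val_half,
                                   disc[, c("trial_id", "condition")],
                                   by = "trial_id")
  m <- group_condition_means(labelled, trials, spikes, cells, norms,
                             cond_trials, windows)
  groups <- dplyr::group_split(dplyr::group_by(m, .data$phase, .data$label))
  tests <- lapply(groups, function(g) {
    dplyr::bind_cols(tibble::tibble(phase = g$phase[1], label = g$label[1]),
                     repeated_measures_f(g))
  })
  group_means <- dplyr::summarise(
    dplyr::group_by(m, .data$phase, .data$label, .data$condition),
    value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  list(cell_means = m, group_means = group_means,
       tests = dplyr::bind_rows(tests))
}

#' Outcome (correct/error) coding across the whole sample
#'
#' Per cell, an ANOVA of the FB-window rate on correct/error x object set x
#' touched location over all completed trials, selection and validation
#' halves combined. Reports cells with a significant outcome main effect,
#' split by preferred direction, and the overlap with FB explore/exploit
#' labels when a selection table is supplied.
#'
#' @param trials,spikes,cells the dataset tables.
#' @param window the FB analysis window (default FB 0--400 ms).
#' @param alpha significance level.
#' @param selection optional labelled output of [run_selection()] for the
#'   overlap report.
#' @return list with `cells` (per-cell p and direction), `counts`, and
#'   `overlap` (NULL without `selection`).
#' @export
outcome_coding_anova <- function(trials, spikes, cells,
                                 window = window_spec("FB", 0, 0.4),
                                 alpha = 0.05, selection = NULL) {
  tr <- dplyr::filter(trials, !is.na(.data$chosen_object))
  rates <- window_rates(spikes, tr, cells, window)
  dat <- dplyr::inner_join(
    rates,
    tr[, c("trial_id", "correct", "object_set", "chosen_location")],
    by = "trial_id")
  dat$outcome <- ifelse(dat$correct, "correct", "error")
  per_cell <- lapply(split(dat, dat$cell_id), function(d) {
    an <- selection_anova(d, factors = c("outcome", "object_set",
                                         "chosen_location"))
    p <- an$p_value[an$term == "outcome"]
    tibble::tibble(
      cell_id = d$cell_id[1],
      p_outcome = if (length(p)) p else NA_real_,
      mean_correct = mean(d$rate[d$outcome == "correct"]),
      mean_error = mean(d$rate[d$outcome == "error"]))
  })
  per_cell <- dplyr::bind_rows(per_cell)
  per_cell$significant <- !is.na(per_cell$p_outcome) &
    per_cell$p_outcome < alpha
  per_cell$direction <- ifelse(
    per_cell$significant,
    ifelse(per_cell$mean_correct > per_cell$mean_error, "correct", "error"),
    NA_character_)
  counts <- tibble::tibble(
    n_cells = nrow(per_cell),
    n_significant = sum(per_cell$significant),
    n_prefer_correct = sum(per_cell$direction == "correct", na.rm = TRUE),
    n_prefer_error = sum(per_cell$direction == "error", na.rm = TRUE),
    fraction_significant = mean(per_cell$significant))
  overlap <- NULL
  if (!is.null(selection)) {
    fb_labelled <- selection$cell_id[selection$phase == "FB" &
                                       selection$label != "none"]
    if (length(fb_labelled) > 0L) {
      both <- sum(per_cell$significant &
                    per_cell$cell_id %in% fb_labelled)
      overlap <- tibble::tibble(
        n_fb_labelled = length(fb_labelled),
        n_also_outcome = both,
        fraction = both / length(fb_labelled))
    }
  }
  list(cells = per_cell, counts = counts, overlap = overlap)
}
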