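#' Agent configuration for the behavioural simulator
#'
#' The simulated agent searches a 4-object display for one or two rewarded
#' targets over problems of four cycles, emulating the behavioural regularities
#' of trained macaques on this task: near-optimal sampling without revisits in
#' Cycle 1, one-shot learning on most problems, occasional lapses.
#'
#' @param p_learn_one_shot probability that the target set is acquired after
#'   the Cycle-1 rewards, so Cycles 2--4 are exploit cycles. With probability
#'   `1 - p_learn_one_shot` learning fails: Cycle 2 begins with at least one
#'   error before the (re)discovered target is selected, after which learning
#'   completes.
#' @param p_revisit_lapse per-object forgetting probability in explore
#'   sampling: on each trial, every already-sampled object is independently
#'   forgotten with this probability and the choice is uniform over objects
#'   not currently remembered as sampled. `0` gives a perfect-memory searcher
#'   (no revisits); `1` a memoryless uniform chooser whose revisit rates at
#'   1/2/3 objects already sampled are exactly 25/50/75%.
#' @param p_exploit_error_by_cycle named numeric, probability per trial of a
#'   lapse (nontarget choice) in exploit Cycles 2--4; non-increasing in cycle.
#' @param favored_location_bias probability that the very first choice of
#'   Cycle 1 is the object at the agent's favoured display location.
#' @param favored_location the favoured location id (1--4).
#' @param p_abort per-trial probability of an aborted trial (fixation break or
#'   key release before go).
#' @param p_no_response per-trial probability of failing to touch after go.
#' @return an `agent_config` list.
#' @export
agent_config <- function(p_learn_one_shot = 0.85,
                         p_revisit_lapse = 0.35,
                         p_exploit_error_by_cycle = c("2" = 0.10, "3" = 0.06,
                                                      "4" = 0.04),
                         favored_location_bias = 0.7,
                         favored_location = 1L,
                         p_abort = 0.01,
                         p_no_response = 0.01) {
  probs <- c(p_learn_one_shot, p_revisit_lapse, p_exploit_error_by_cycle,
             favored_location_bias, p_abort, p_no_response)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c("2", "3", "4") %in% names(p_exploit_error_by_cycle)),
            !is.unsorted(rev(p_exploit_error_by_cycle[c("2", "3", "4")])),
            favored_location %in% 1:4)
  structure(list(p_learn_one_shot = p_learn_one_shot,
                 p_revisit_lapse = p_revisit_lapse,
                 p_exploit_error_by_cycle = p_exploit_error_by_cycle,
                 favored_location_bias = favored_location_bias,
                 favored_location = as.integer(favored_location),
                 p_abort = p_abort,
                 p_no_response = p_no_response),
            class = "agent_config")
}

# Event timestamps (s from trial start) following the task's timing ranges:
# wait 0.8-1.2 s to choice-array onset, delay 1.2-2.0 s to go, touch within
# 1.8 s of go, hold 0.35-0.45 s to feedback onset, feedback 0.3 s.
draw_trial_events <- function(outcome = c("choice", "aborted", "no_response")) {
  outcome <- match.arg(outcome)
  t_ch_on <- runif(1, 0.8, 1.2)
  if (outcome == "aborted") {
    return(list(t_ch_on = t_ch_on, t_go = NA_real_, t_touch = NA_real_,
                t_fb_on = NA_real_))
  }
  t_go <- t_ch_on + runif(1, 1.2, 2.0)
  if (outcome == "no_response") {
    return(list(t_ch_on = t_ch_on, t_go = t_go, t_touch = NA_real_,
                t_fb_on = NA_real_))
  }
  t_touch <- t_go + runif(1, 0.25, 0.9)
  list(t_ch_on = t_ch_on, t_go = t_go, t_touch = t_touch,
       t_fb_on = t_touch + runif(1, 0.35, 0.45))
}

explore_choice <- function(sampled, p_forget) {
  remembered <- sampled[runif(length(sampled)) >= p_forget]
  candidates <- setdiff(1:4, remembered)
  if (length(candidates) == 0L) candidates <- 1:4
  candidates[sample.int(length(candidates), 1L)]
}

#' Simulate behaviour on the object-search task
#'
#' Generates a trial table for one session: alternating 1- and 2-target
#' problems of four cycles each, four objects per display with uniformly
#' random arrangement, targets drawn uniformly per problem, and an agent
#' defined by [agent_config()]. Cycle 1 is explore sampling; if one-shot
#' learning succeeds the remaining cycles select targets directly up to
#' lapses, otherwise Cycle 2 begins with at least one error before learning
#' completes.
#'
#' @param n_problems_1target,n_problems_2target numbers of problems of each
#'   type (interleaved).
#' @param agent an [agent_config()].
#' @param session_id,animal_id identifiers.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return a trial table (see [trial-table]) with columns
#'   [trial_table_columns()].
#' @export
simulate_behavior <- function(n_problems_1target = 30L,
                              n_problems_2target = 30L,
                              agent = agent_config(),
                              session_id = "S01",
                              animal_id = "A",
                              seed = 1L) {
  with_seed(seed, {
    schedule <- c(rep(1L, n_problems_1target), rep(2L, n_problems_2target))
    # interleave problem types as in blocked alternation
    ord <- order(c(seq_len(n_problems_1target),
                   seq_len(n_problems_2target) + 0.5))
    schedule <- schedule[ord]
    rows <- vector("list", 4096L)
    n_rows <- 0L
    for (pi in seq_along(schedule)) {
      nt <- schedule[pi]
      problem_id <- sprintf("%s_P%03d", session_id, pi)
      object_set <- if (pi %% 2L == 1L) 1L else 2L
      targets <- sort(sample.int(4L, nt))
      target_1 <- targets[1]
      target_2 <- if (nt == 2L) targets[2] else NA_integer_
      learned <- FALSE
      for (cycle in 1:4) {
        sampled <- integer(0)       # objects sampled this cycle
        selected <- integer(0)      # targets already selected this cycle
        exploit_remaining <- targets[sample.int(length(targets))]
        trial_no <- 0L
        first_choice_made <- FALSE
        forced_error_pending <- (cycle == 2L && !learned)
        while (length(selected) < nt && trial_no < 50L) {
          trial_no <- trial_no + 1L
          arrangement <- sample.int(4L)  # location of object i
          u <- runif(1)
          outcome_kind <- if (u < agent$p_abort) "aborted"
            else if (u < agent$p_abort + agent$p_no_response) "no_response"
            else "choice"
          ev <- draw_trial_events(outcome_kind)
          chosen <- NA_integer_
          if (outcome_kind == "choice") {
            explore_mode <- (cycle == 1L) || (cycle == 2L && !learned)
            if (explore_mode) {
              if (forced_error_pending) {
                nontargets <- setdiff(1:4, targets)
                chosen <- nontargets[sample.int(length(nontargets), 1L)]
                forced_error_pending <- FALSE
              } else if (cycle == 1L && !first_choice_made &&
                         runif(1) < agent$favored_location_bias) {
                chosen <- which(arrangement == agent$favored_location)
              } else {
                chosen <- explore_choice(sampled, agent$p_revisit_lapse)
              }
            } else {
              p_err <- agent$p_exploit_error_by_cycle[[as.character(cycle)]]
              if (runif(1) < p_err) {
                novel_nt <- setdiff(setdiff(1:4, targets), sampled)
                pool <- if (length(novel_nt)) novel_nt else setdiff(1:4, targets)
                chosen <- pool[sample.int(length(pool), 1L)]
              } else {
                exploit_remaining <- setdiff(exploit_remaining, selected)
                chosen <- exploit_remaining[1]
              }
            }
            first_choice_made <- TRUE
          }
          correct <- !is.na(chosen) && chosen %in% targets &&
            !(chosen %in% selected)
          if (!is.na(chosen)) sampled <- union(sampled, chosen)
          if (correct) selected <- c(selected, chosen)
          n_rows <- n_rows + 1L
          if (n_rows > length(rows)) rows <- c(rows, vector("list", n_rows))
          rows[[n_rows]] <- list(
            session_id = session_id, animal_id = animal_id,
            problem_id = problem_id,
            trial_id = sprintf("%s_C%d_T%02d", problem_id, cycle, trial_no),
            n_targets = nt, object_set = object_set,
            cycle = cycle, trial_in_cycle = trial_no,
            obj_loc_1 = arrangement[1], obj_loc_2 = arrangement[2],
            obj_loc_3 = arrangement[3], obj_loc_4 = arrangement[4],
            target_1 = target_1, target_2 = target_2,
            chosen_object = chosen,
            chosen_location = if (is.na(chosen)) NA_integer_
                              else arrangement[chosen],
            correct = correct, rewarded = correct,
            aborted = outcome_kind == "aborted",
            t_ch_on = ev$t_ch_on, t_go = ev$t_go,
            t_touch = ev$t_touch, t_fb_on = ev$t_fb_on)
        }
        if (cycle == 1L) learned <- runif(1) < agent$p_learn_one_shot
        if (cycle == 2L) learned <- TRUE  # learning completes in Cycle 2
      }
    }
    dplyr::bind_rows(rows[seq_len(n_rows)])
  })
}

#' Monte-Carlo search lengths of an optimal random searcher
#'
#' Directly simulates the explore cycle of a perfect-memory agent: objects are
#' sampled uniformly at random without revisits until all targets have been
#' selected. Vectorised; used as a Monte-Carlo check of
#' [expected_search_trials()].
#'
#' @inheritParams expected_search_trials
#' @param n_reps number of simulated cycles.
#' @param seed integer seed.
#' @return integer vector of cycle lengths (trials to find all targets).
#' @export
simulate_search_lengths <- function(n_objects, n_targets, n_reps = 1e5,
                                    seed = 1L) {
  stopifnot(n_targets >= 1, n_targets <= n_objects)
  with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      perm <- sample.int(n_objects)
      max(match(seq_len(n_targets), perm))
    }, integer(1))
  })
}

#' Population configuration for the spiking simulator
#'
#' Defines a population containing explore- and exploit-preferring cells whose
#' cycle preference is conjunctive with trial phase (choice CH vs feedback
#' FB), outcome-tuned cells, multiplicative object/location tuning, and
#' untuned cells, all with Poisson spiking.
#'
#' @param n_cells population size.
#' @param fraction_explore_ch,fraction_exploit_ch,fraction_explore_fb,fraction_exploit_fb
#'   fractions of cells with a cycle preference at each phase; the four
#'   classes are disjoint (a cell carries at most one phase x preference).
#' @param state_gain multiplicative firing-rate gain in the cell's preferred
#'   state, applied within its phase window.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   rates (spikes/s).
#' @param object_tuning_sd,location_tuning_sd SD of log-normal multiplicative
#'   tuning to the chosen object / location.
#' @param fraction_outcome_cells fraction of cells modulated by correct vs
#'   error at FB (drawn independently of cycle preference, so overlap occurs
#'   at the product of the marginal fractions).
#' @param outcome_gain multiplicative gain for the preferred outcome.
#' @param trial_noise_sd SD of optional per-trial log-normal rate jitter;
#'   0 (default) gives pure Poisson variability.
#' @param phase_leakage exponent in `[0, 1]` applied to the state gain in the
#'   cell's non-preferred phase window: 0 (default) makes phase conjunction
#'   absolute, 1 makes the preference phase-general.
#' @param region region label for all cells.
#' @return a `population_config` list.
#' @export
population_config <- function(n_cells = 60L,
                              fraction_explore_ch = 0.07,
                              fraction_exploit_ch = 0.10,
                              fraction_explore_fb = 0.07,
                              fraction_exploit_fb = 0.10,
                              state_gain = 1.5,
                              baseline_meanlog = log(5),
                              baseline_sdlog = 0.5,
                              object_tuning_sd = 0.1,
                              location_tuning_sd = 0.1,
                              fraction_outcome_cells = 0.15,
                              outcome_gain = 1.5,
                              trial_noise_sd = 0,
                              phase_leakage = 0,
                              region = "PFC") {
  fr <- c(fraction_explore_ch, fraction_exploit_ch,
          fraction_explore_fb, fraction_exploit_fb)
  stopifnot(all(fr >= 0), sum(fr) <= 1, state_gain >= 0, outcome_gain >= 0,
            phase_leakage >= 0, phase_leakage <= 1,
            fraction_outcome_cells >= 0, fraction_outcome_cells <= 1)
  structure(list(n_cells = as.integer(n_cells),
                 fraction_explore_ch = fraction_explore_ch,
                 fraction_exploit_ch = fraction_exploit_ch,
                 fraction_explore_fb = fraction_explore_fb,
                 fraction_exploit_fb = fraction_exploit_fb,
                 state_gain = state_gain,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 object_tuning_sd = object_tuning_sd,
                 location_tuning_sd = location_tuning_sd,
                 fraction_outcome_cells = fraction_outcome_cells,
                 outcome_gain = outcome_gain,
                 trial_noise_sd = trial_noise_sd,
                 phase_leakage = phase_leakage,
                 region = region),
            class = "population_config")
}

#' Per-trial explore/exploit state implied by a trial table
#'
#' Cycle-1 trials are explore-state. On problems where one-shot learning
#' failed (first completed Cycle-2 response incorrect), Cycle-2 trials before
#' the first correct selection remain explore-state and the first correct
#' Cycle-2 trial is `"mixed"`: the explore subpopulation still holds the
#' explore state while the exploit subpopulation has already switched,
#' yielding the partial preservation of the explore state seen after failed
#' learning. All other trials are exploit-state.
#'
#' @param trials a trial table.
#' @return character vector along rows of `trials`:
#'   `"explore"`, `"exploit"` or `"mixed"`.
#' @export
trial_states <- function(trials) {
  trials <- dplyr::arrange(trials, .data$problem_id, .data$cycle,
                           .data$trial_in_cycle)
  state <- ifelse(trials$cycle == 1L, "explore", "exploit")
  for (g in split(seq_len(nrow(trials)),
                  factor(trials$problem_id,
                         levels = unique(trials$problem_id)))) {
    c2 <- g[trials$cycle[g] == 2L]
    completed <- c2[!is.na(trials$chosen_object[c2])]
    if (length(completed) == 0L) next
    if (!trials$correct[completed[1]]) {  # learning failed on this problem
      first_correct <- completed[which(trials$correct[completed])[1]]
      if (is.na(first_correct)) first_correct <- Inf
      state[c2[c2 < first_correct]] <- "explore"
      if (is.finite(first_correct)) state[first_correct] <- "mixed"
    }
  }
  state
}

#' Per-problem learned flag implied by a trial table
#'
#' `FALSE` when the first completed Cycle-2 response was an error (failed
#' one-shot learning).
#' @param trials a trial table.
#' @return tibble with `problem_id`, `learned`.
#' @export
problem_learned_flags <- function(trials) {
  trials <- dplyr::arrange(trials, .data$problem_id, .data$cycle,
                           .data$trial_in_cycle)
  c2 <- dplyr::filter(trials, .data$cycle == 2L, !is.na(.data$chosen_object))
  first_c2 <- dplyr::slice_head(dplyr::group_by(c2, .data$problem_id), n = 1L)
  dplyr::left_join(
    tibble::tibble(problem_id = unique(trials$problem_id)),
    dplyr::transmute(first_c2, problem_id = .data$problem_id,
                     learned = .data$correct),
    by = "problem_id")
}

# Draw Poisson spikes on [start, end) at constant rate, vectorised over trials.
segment_spikes <- function(trial_id, start, end, rate) {
  n_seg <- length(trial_id)
  start <- rep_len(start, n_seg)
  end <- rep_len(end, n_seg)
  rate <- rep_len(rate, n_seg)
  ok <- !is.na(start) & !is.na(end) & !is.na(rate) & end > start & rate > 0
  if (!any(ok)) {
    return(tibble::tibble(trial_id = character(), spike_time_s = double()))
  }
  start <- start[ok]; end <- end[ok]; rate <- rate[ok]
  trial_id <- trial_id[ok]
  n <- rpois(length(start), rate * (end - start))
  tot <- sum(n)
  if (tot == 0L) {
    return(tibble::tibble(trial_id = character(), spike_time_s = double()))
  }
  tibble::tibble(
    trial_id = rep(trial_id, n),
    spike_time_s = rep(start, n) + runif(tot) * rep(end - start, n))
}

#' Simulate a spiking population over a trial table
#'
#' Each cell's rate is piecewise-constant over trial epochs:
#' `baseline x state gain x phase gate x object/location/outcome tuning`,
#' with the state gain acting only within the cell's phase window, extending
#' from 200 ms before event onset to 500 ms after (cycle preferences are
#' sustained and begin before event onset). Spikes are an inhomogeneous
#' Poisson draw. Cells are assigned round-robin to the sessions present in
#' `trials`; a cell has spikes only on its own session's trials.
#'
#' @param trials a trial table (with event timestamps).
#' @param pop a [population_config()].
#' @param seed integer seed.
#' @return list with `spikes` (tibble `cell_id`, `trial_id`, `spike_time_s`),
#'   `cells` (tibble `cell_id`, `session_id`, `region`), and `ground_truth`
#'   (list: `cells` tibble with `label`/`phase`/`outcome_cell`/`baseline`,
#'   `problems` tibble with learned flags, `config`).
#' @export
simulate_population <- function(trials, pop = population_config(), seed = 1L) {
  stopifnot(inherits(pop, "population_config"))
  if (any(is.na(trials$t_ch_on))) {
    stop("trials must carry a choice-array onset timestamp", call. = FALSE)
  }
  with_seed(seed, {
    n <- pop$n_cells
    counts <- round(n * c(pop$fraction_explore_ch, pop$fraction_exploit_ch,
                          pop$fraction_explore_fb, pop$fraction_exploit_fb))
    classes <- c(rep("explore_CH", counts[1]), rep("exploit_CH", counts[2]),
                 rep("explore_FB", counts[3]), rep("exploit_FB", counts[4]),
                 rep("none", n - sum(counts)))
    classes <- sample(classes)
    label <- sub("_.*", "", classes)
    phase <- ifelse(classes == "none", NA_character_, sub(".*_", "", classes))
    label[classes == "none"] <- "none"
    outcome_cell <- runif(n) < pop$fraction_outcome_cells
    outcome_pref <- ifelse(outcome_cell,
                           ifelse(runif(n) < 0.5, "correct", "error"),
                           NA_character_)
    baseline <- rlnorm(n, pop$baseline_meanlog, pop$baseline_sdlog)
    obj_gain <- matrix(exp(rnorm(n * 4, 0, pop$object_tuning_sd)), n, 4)
    loc_gain <- matrix(exp(rnorm(n * 4, 0, pop$location_tuning_sd)), n, 4)
    sessions <- unique(trials$session_id)
    cell_session <- sessions[(seq_len(n) - 1L) %% length(sessions) + 1L]
    cell_ids <- sprintf("cell_%03d", seq_len(n))

    state <- trial_states(trials)
    spikes_per_cell <- vector("list", n)
    for (ci in seq_len(n)) {
      tr <- trials[trials$session_id == cell_session[ci], ]
      st <- state[trials$session_id == cell_session[ci]]
      b <- baseline[ci]
      jit <- if (pop$trial_noise_sd > 0) {
        exp(rnorm(nrow(tr), 0, pop$trial_noise_sd))
      } else rep(1, nrow(tr))
      tune <- rep(1, nrow(tr))
      has_choice <- !is.na(tr$chosen_object)
      tune[has_choice] <- obj_gain[ci, tr$chosen_object[has_choice]] *
        loc_gain[ci, tr$chosen_location[has_choice]]
      # state match per trial for this cell
      match_state <- if (label[ci] == "none") rep(FALSE, nrow(tr)) else {
        st == label[ci] | st == "mixed"
      }
      # mixed trials: explore cells stay explore, exploit cells have switched,
      # so both classes are in their preferred state on mixed trials.
      gain_pref <- ifelse(match_state, pop$state_gain, 1)
      gain_nonpref <- ifelse(match_state, pop$state_gain^pop$phase_leakage, 1)
      ch_state_gain <- if (is.na(phase[ci])) rep(1, nrow(tr)) else {
        if (phase[ci] == "CH") gain_pref else gain_nonpref
      }
      fb_state_gain <- if (is.na(phase[ci])) rep(1, nrow(tr)) else {
        if (phase[ci] == "FB") gain_pref else gain_nonpref
      }
      out_gain <- rep(1, nrow(tr))
      if (outcome_cell[ci]) {
        match_out <- has_choice &
          ((tr$correct & outcome_pref[ci] == "correct") |
           (!tr$correct & outcome_pref[ci] == "error"))
        out_gain[match_out] <- pop$outcome_gain
      }
      base_r <- b * jit
      ch0 <- tr$t_ch_on - 0.2
      ch1 <- tr$t_ch_on + 0.5
      fb0 <- tr$t_fb_on - 0.2
      fb1 <- tr$t_fb_on + 0.5
      t_end <- ifelse(is.na(tr$t_fb_on), tr$t_ch_on + 0.8, tr$t_fb_on + 0.8)
      segs <- dplyr::bind_rows(
        segment_spikes(tr$trial_id, 0, ch0, base_r),
        segment_spikes(tr$trial_id, ch0, ch1,
                       base_r * tune * ch_state_gain),
        segment_spikes(tr$trial_id, ch1, ifelse(is.na(fb0), t_end, fb0),
                       base_r),
        segment_spikes(tr$trial_id, fb0, fb1,
                       base_r * tune * fb_state_gain * out_gain),
        segment_spikes(tr$trial_id, fb1, t_end, base_r))
      segs$cell_id <- rep(cell_ids[ci], nrow(segs))
      spikes_per_cell[[ci]] <- segs
    }
    spikes <- dplyr::arrange(dplyr::bind_rows(spikes_per_cell),
                             .data$cell_id, .data$trial_id,
                             .data$spike_time_s)
    cells <- tibble::tibble(cell_id = cell_ids, session_id = cell_session,
                            region = pop$region)
    gt_cells <- tibble::tibble(cell_id = cell_ids, label = label,
                               phase = phase, outcome_cell = outcome_cell,
                               outcome_pref = outcome_pref,
                               baseline = baseline)
    list(spikes = spikes[, c("cell_id", "trial_id", "spike_time_s")],
         cells = cells,
         ground_truth = list(cells = gt_cells,
                             problems = problem_learned_flags(trials),
                             config = unclass(pop)))
  })
}

#' Write a synthetic dataset fixture to disk
#'
#' Writes `trials.csv`, `spikes.csv`, `cells.csv` and `ground_truth.json`
#' (all plain text) for a simulated dataset. `tiny` completes in seconds
#' (2 sessions, 12 problems and 6 cells each); `paper_like` matches the scale
#' of the recorded dataset (60 sessions, about 69 1-target and 67 2-target
#' problems per session, 254 cells) and takes correspondingly longer.
#'
#' @param dir output directory (created if needed).
#' @param scale `"tiny"` or `"paper_like"`.
#' @param seed integer seed; output is deterministic given it.
#' @return (invisibly) named character vector of the written file paths.
#' @export
make_fixture <- function(dir, scale = c("tiny", "paper_like"), seed = 1L) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    tiny = list(n_sessions = 2L, n1 = 6L, n2 = 6L, n_cells = 12L),
    paper_like = list(n_sessions = 60L, n1 = 69L, n2 = 67L, n_cells = 254L))
  trials <- dplyr::bind_rows(lapply(seq_len(dims$n_sessions), function(s) {
    simulate_behavior(dims$n1, dims$n2, agent_config(),
                      session_id = sprintf("S%02d", s),
                      animal_id = if (s %% 2L == 1L) "A" else "B",
                      seed = child_seed(seed, paste0("behavior", s)))
  }))
  sim <- simulate_population(trials,
                             population_config(n_cells = dims$n_cells),
                             seed = child_seed(seed, "population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             spikes = file.path(dir, "spikes.csv"),
             cells = file.path(dir, "cells.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  readr::write_csv(trials, paths[["trials"]])
  spikes_long <- dplyr::left_join(
    sim$spikes,
    dplyr::select(trials, "trial_id", "session_id", "problem_id", "cycle",
                  "trial_in_cycle"),
    by = "trial_id")
  readr::write_csv(spikes_long, paths[["spikes"]])
  readr::write_csv(sim$cells, paths[["cells"]])
  jsonlite::write_json(
    list(cells = sim$ground_truth$cells,
         problems = sim$ground_truth$problems,
         config = sim$ground_truth$config,
         seed = seed, scale = scale),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
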