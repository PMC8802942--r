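# Shared fixtures, generated in code and cached across test files.
.ee_cache <- new.env(parent = emptyenv())

ee_cached <- function(key, expr) {
  if (!exists(key, envir = .ee_cache)) {
    assign(key, force(expr), envir = .ee_cache)
  }
  get(key, envir = .ee_cache)
}

# one paper-scale session with a strongly tuned labelled population,
# reused by selection / single-cell / population tests
ee_labeled_sim <- function() {
  ee_cached("labeled_sim", {
    trials <- simulate_behavior(69, 67, seed = 501)
    pop <- population_config(n_cells = 50,
                            fraction_explore_ch = 0.15,
                            fraction_exploit_ch = 0.15,
                            fraction_explore_fb = 0.15,
                            fraction_exploit_fb = 0.15,
                            state_gain = 1.8,
                            object_tuning_sd = 0,
                            fraction_outcome_cells = 0)
    sim <- simulate_population(trials, pop, seed = 502)
    split_sel <- split_trials(trials, sim$cells, seed = 503)
    selection <- run_selection(trials, sim$spikes, sim$cells, split_sel)
    norms <- cell_norm_constants(trials, sim$spikes, sim$cells, split_sel)
    list(trials = trials, spikes = sim$spikes, cells = sim$cells,
         gt = sim$ground_truth, split_sel = split_sel,
         selection = selection, norms = norms)
  })
}

# a minimal valid trial table built by hand; override any column via `...`
manual_trials <- function(n = 1L, ...) {
  base <- tibble::tibble(
    session_id = "S1", animal_id = "A", problem_id = "S1_P001",
    trial_id = sprintf("tr%02d", seq_len(n)),
    n_targets = 1L, object_set = 1L, cycle = 1L,
    trial_in_cycle = seq_len(n),
    obj_loc_1 = 1L, obj_loc_2 = 2L, obj_loc_3 = 3L, obj_loc_4 = 4L,
    target_1 = 1L, target_2 = NA_integer_,
    chosen_object = 1L, chosen_location = 1L,
    correct = TRUE, rewarded = TRUE, aborted = FALSE,
    t_ch_on = 1.0, t_go = 2.5, t_touch = 3.0, t_fb_on = 3.4)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$chosen_location <- ifelse(
    is.na(base$chosen_object), NA_integer_,
    as.integer(as.matrix(base[, paste0("obj_loc_", 1:4)])[
      cbind(seq_len(n), pmin(pmax(base$chosen_object, 1L), 4L))]))
  base
}

manual_cells <- function(ids = "c1", session = "S1") {
  tibble::tibble(cell_id = ids, session_id = session, region = "PFC")
}

# deterministic spike table: one row per supplied time; trial_id is either
# scalar or parallel to times
manual_spikes <- function(cell_id, trial_id, times) {
  tibble::tibble(cell_id = cell_id, trial_id = trial_id,
                 spike_time_s = times)
}

# k spikes evenly spread in [lo, hi)
spread_spikes <- function(k, lo, hi) {
  if (k == 0L) return(numeric(0))
  lo + (seq_len(k) - 0.5) / k * (hi - lo)
}
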