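test_that("simulation is deterministic given the seed", {
  a <- simulate_behavior(5, 5, seed = 9)
  b <- simulate_behavior(5, 5, seed = 9)
  expect_identical(a, b)
  pa <- simulate_population(a, population_config(n_cells = 4), seed = 2)
  pb <- simulate_population(b, population_config(n_cells = 4), seed = 2)
  expect_identical(pa$spikes, pb$spikes)
  expect_identical(pa$ground_truth$cells, pb$ground_truth$cells)
})

test_that("an optimal agent produces minimal exploit cycles, all T", {
  agent <- agent_config(p_learn_one_shot = 1, p_revisit_lapse = 0,
                        p_exploit_error_by_cycle = c("2" = 0, "3" = 0,
                                                     "4" = 0),
                        p_abort = 0, p_no_response = 0)
  trials <- add_response_types(simulate_behavior(40, 40, agent = agent,
                                                 seed = 41))
  exploit <- dplyr::filter(trials, .data$cycle > 1L)
  expect_true(all(exploit$response_type == "T"))
  n_per_cycle <- dplyr::count(exploit, .data$problem_id, .data$cycle,
                              .data$n_targets)
  expect_true(all(n_per_cycle$n == n_per_cycle$n_targets))
  # Cycle 1 contains no revisits with perfect memory
  expect_false(any(trials$response_type %in% c("NT_revisit", "T_revisit")))
})

test_that("failed-learning state runs until the first correct Cycle-2 trial", {
  agent <- agent_config(p_learn_one_shot = 0, p_abort = 0,
                        p_no_response = 0)
  trials <- simulate_behavior(10, 0, agent = agent, seed = 77)
  st <- trial_states(trials)
  trials <- dplyr::arrange(trials, .data$problem_id, .data$cycle,
                           .data$trial_in_cycle)
  expect_true(all(st[trials$cycle == 1L] == "explore"))
  expect_true(all(st[trials$cycle >= 3L] == "exploit"))
  for (pid in unique(trials$problem_id)) {
    i2 <- which(trials$problem_id == pid & trials$cycle == 2L)
    first_ok <- i2[which(trials$correct[i2])[1]]
    expect_identical(st[first_ok], "mixed")
    expect_true(all(st[i2[i2 < first_ok]] == "explore"))
    expect_true(all(st[i2[i2 > first_ok]] == "exploit"))
    # the simulator guarantees at least one Cycle-2 error when learning fails
    expect_false(trials$correct[i2[1]])
  }
  expect_true(all(!problem_learned_flags(trials)$learned))
})

test_that("spike counts are Poisson (Fano factor near 1 within conditions)", {
  agent <- agent_config(p_abort = 0, p_no_response = 0)
  trials <- simulate_behavior(50, 0, agent = agent, seed = 51)
  pop <- population_config(n_cells = 6, fraction_explore_ch = 0,
                           fraction_exploit_ch = 0, fraction_explore_fb = 0,
                           fraction_exploit_fb = 0, object_tuning_sd = 0,
                           location_tuning_sd = 0,
                           fraction_outcome_cells = 0)
  sim <- simulate_population(trials, pop, seed = 52)
  w <- window_spec("CH", 0, 0.4)
  rates <- window_rates(sim$spikes, trials, sim$cells, w)
  counts <- dplyr::mutate(rates, count = .data$rate * 0.4)
  # untuned constant-rate cells: all trials are one condition per cell
  for (d in split(counts, counts$cell_id)) {
    n <- nrow(d)
    disp <- (n - 1) * var(d$count) / mean(d$count)  # ~ chisq(n - 1)
    expect_gt(disp, qchisq(0.0005, df = n - 1))
    expect_lt(disp, qchisq(0.9995, df = n - 1))
  }
})

test_that("state gain scales the preferred-phase window rate as specified", {
  # one explore-CH cell, gain 2: mean CH-window rate in Cycle 1 should be
  # twice that in Cycle 4 (closed-form Poisson mean check)
  agent <- agent_config(p_learn_one_shot = 1, p_abort = 0, p_no_response = 0)
  trials <- simulate_behavior(200, 0, agent = agent, seed = 61)
  pop <- population_config(n_cells = 1, fraction_explore_ch = 1,
                           fraction_exploit_ch = 0, fraction_explore_fb = 0,
                           fraction_exploit_fb = 0, state_gain = 2.0,
                           object_tuning_sd = 0, location_tuning_sd = 0,
                           fraction_outcome_cells = 0,
                           baseline_meanlog = log(8), baseline_sdlog = 0)
  sim <- simulate_population(trials, pop, seed = 62)
  expect_identical(sim$ground_truth$cells$label, "explore")
  expect_identical(sim$ground_truth$cells$phase, "CH")
  rates <- window_rates(sim$spikes, trials, sim$cells,
                        window_spec("CH", 0, 0.4))
  dat <- dplyr::inner_join(rates, trials[, c("trial_id", "cycle")],
                           by = "trial_id")
  m1 <- mean(dat$rate[dat$cycle == 1L])
  m4 <- mean(dat$rate[dat$cycle == 4L])
  # Poisson SE of the ratio at these counts is well under 10%
  expect_gt(m1 / m4, 1.75)
  expect_lt(m1 / m4, 2.25)
  # no preference leaks into the FB window (phase conjunction is absolute)
  rfb <- window_rates(sim$spikes, trials, sim$cells,
                      window_spec("FB", 0, 0.4))
  dfb <- dplyr::inner_join(rfb, trials[, c("trial_id", "cycle")],
                           by = "trial_id")
  expect_lt(abs(mean(dfb$rate[dfb$cycle == 1L]) /
                  mean(dfb$rate[dfb$cycle == 4L]) - 1), 0.15)
})

test_that("ground-truth explore/exploit cells order their cycle means", {
  sim <- ee_labeled_sim()
  w <- selection_windows()
  gt <- sim$gt$cells
  for (ph in c("CH", "FB")) {
    rates <- window_rates(sim$spikes, sim$trials, sim$cells, w[[ph]])
    dat <- dplyr::inner_join(rates, sim$trials[, c("trial_id", "cycle")],
                             by = "trial_id")
    m <- dplyr::summarise(
      dplyr::group_by(dat, .data$cell_id),
      d41 = mean(.data$rate[.data$cycle == 4L]) -
        mean(.data$rate[.data$cycle == 1L]), .groups = "drop")
    m <- dplyr::inner_join(m, gt, by = "cell_id")
    expect_true(all(m$d41[m$label == "explore" & m$phase == ph] < 0))
    expect_true(all(m$d41[m$label == "exploit" & m$phase == ph] > 0))
  }
})

test_that("fixtures are deterministic and pass schema validation", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture(d1, "tiny", seed = 4)
  make_fixture(d2, "tiny", seed = 4)
  for (f in c("trials.csv", "spikes.csv", "cells.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ds <- read_dataset(d1)
  v <- validate_dataset(ds$trials, ds$spikes, ds$cells)
  expect_true(v$ok)
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_length(gt$cells, nrow(ds$cells))
})
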