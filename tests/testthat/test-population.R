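# deterministic mini-dataset: cells with exactly known rates per cycle.
# rates_by_cell: named list cell_id -> c(C1 = rate, C4 = rate); spikes are
# placed evenly so every trial's window rate is exactly the nominal rate.
make_deterministic_pop <- function(rates_by_cell, n_trials_per_cycle = 8L) {
  n <- 2L * n_trials_per_cycle
  trials <- manual_trials(
    n,
    problem_id = sprintf("S1_P%03d", rep(seq_len(n_trials_per_cycle), 2)),
    trial_id = sprintf("t%02d", seq_len(n)),
    cycle = rep(c(1L, 4L), each = n_trials_per_cycle),
    trial_in_cycle = 1L,
    n_targets = rep(c(1L, 2L), length.out = n),
    chosen_object = rep(c(1L, 2L), length.out = n),
    correct = TRUE, rewarded = TRUE)
  trials$target_2 <- ifelse(trials$n_targets == 2L, 2L, NA_integer_)
  cells <- manual_cells(names(rates_by_cell))
  spikes <- dplyr::bind_rows(lapply(names(rates_by_cell), function(cid) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      r <- rates_by_cell[[cid]][ifelse(trials$cycle[i] == 1L, "C1", "C4")]
      k <- round(r * 0.4)
      manual_spikes(cid, trials$trial_id[i],
                    spread_spikes(k, trials$t_ch_on[i],
                                  trials$t_ch_on[i] + 0.4))
    }))
  }))
  # alternate halves deterministically within cycle for a noiseless split
  split <- dplyr::bind_rows(lapply(names(rates_by_cell), function(cid) {
    tibble::tibble(cell_id = cid, trial_id = trials$trial_id,
                   half = rep(c("A", "B"), n_trials_per_cycle))
  }))
  list(trials = trials, cells = cells, spikes = spikes, split = split)
}

test_that("preference vectors equal Cycle-4 minus Cycle-1 constant rates", {
  pop <- make_deterministic_pop(list(c1 = c(C1 = 5, C4 = 10),
                                     c2 = c(C1 = 10, C4 = 5),
                                     c3 = c(C1 = 5, C4 = 7.5)))
  w <- list(W1 = window_spec("CH", 0, 0.4))
  for (h in c("A", "B")) {
    v <- cycle_preference_vectors(pop$trials, pop$spikes, pop$cells,
                                  pop$split, h, windows = w)
    expect_equal(v$preference[match(c("c1", "c2", "c3"), v$cell_id)],
                 c(5, -5, 2.5))
  }
})

test_that("unweighted preference matches a hand-computed unbalanced oracle", {
  # unbalanced: location 1 has 3 trials at rate 10, location 2 has 1 at 20
  tr <- manual_trials(8, trial_id = sprintf("u%02d", 1:8),
                      problem_id = sprintf("S1_P%03d", 1:8),
                      trial_in_cycle = 1L,
                      cycle = rep(c(1L, 4L), each = 4),
                      chosen_object = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
                      correct = TRUE, rewarded = TRUE)
  cells <- manual_cells("c1")
  rate_for <- function(i) if (tr$chosen_object[i] == 1L) 10 else 20
  spikes <- dplyr::bind_rows(lapply(1:8, function(i) {
    manual_spikes("c1", tr$trial_id[i],
                  spread_spikes(round(rate_for(i) * 0.4), tr$t_ch_on[i],
                                tr$t_ch_on[i] + 0.4))
  }))
  split <- tibble::tibble(cell_id = "c1", trial_id = tr$trial_id, half = "A")
  v <- cycle_preference_vectors(tr, spikes, cells, split, "A",
                                windows = list(W = window_spec("CH", 0, 0.4)))
  # unweighted over locations: mean(10, 20) = 15 in both cycles -> 0;
  # a trial-weighted mean would also be equal here, but the per-condition
  # means are 10 and 20, not the pooled 12.5
  expect_equal(v$preference, 0)
})

test_that("cross-generalization is block-diagonal for phase-conjunctive coding", {
  sim <- ee_labeled_sim()
  split_cg <- split_trials(sim$trials, sim$cells, seed = 171,
                           halves = c("A", "B"))
  cg <- cross_generalization_matrix(sim$trials, sim$spikes, sim$cells,
                                    split_cg)
  expect_identical(dim(cg), c(8L, 8L))
  expect_true(all(abs(cg) <= 1, na.rm = TRUE))
  ch <- grep("^CH", rownames(cg))
  fb <- grep("^FB", rownames(cg))
  expect_gt(mean(cg[ch, ch]), 0.5)
  expect_gt(mean(cg[fb, fb]), 0.5)
  expect_lt(abs(mean(cg[ch, fb])), 0.3)
  expect_gt(crossgen_phase_contrast(cg), 0.4)
})

test_that("phase-general coding removes the cross-generalization contrast", {
  trials <- simulate_behavior(40, 40, seed = 181)
  pop <- population_config(n_cells = 40, fraction_explore_ch = 0.15,
                           fraction_exploit_ch = 0.15,
                           fraction_explore_fb = 0.15,
                           fraction_exploit_fb = 0.15,
                           state_gain = 1.8, phase_leakage = 1)
  sim <- simulate_population(trials, pop, seed = 182)
  split_cg <- split_trials(trials, sim$cells, seed = 183,
                           halves = c("A", "B"))
  cg <- cross_generalization_matrix(trials, sim$spikes, sim$cells, split_cg)
  ch <- grep("^CH", rownames(cg))
  fb <- grep("^FB", rownames(cg))
  # preferences now generalize across phases
  expect_gt(mean(cg[ch, fb]), 0.3)
  expect_lt(abs(crossgen_phase_contrast(cg)), 0.2)
})

test_that("discriminant weights match a brute-force oracle", {
  set.seed(33)
  rates_by_cell <- setNames(lapply(1:5, function(i) {
    c(C1 = 2.5 * sample(1:6, 1), C4 = 2.5 * sample(1:6, 1))
  }), paste0("c", 1:5))
  pop <- make_deterministic_pop(rates_by_cell, n_trials_per_cycle = 10L)
  # add per-trial variation: plant extra spikes on half the trials
  extra <- manual_spikes("c1", pop$trials$trial_id[seq(1, 20, 2)],
                         rep(1.2, 10))
  spikes <- dplyr::bind_rows(pop$spikes, extra)
  split <- pop$split
  split$half <- ifelse(split$half == "A", "train", "test")
  model <- fit_discriminant(pop$trials, spikes, pop$cells, split,
                            window_spec("CH", 0, 0.4))
  # independent oracle, written from first principles
  w_or <- ctr_or <- sc_or <- numeric(5)
  for (i in 1:5) {
    cid <- paste0("c", i)
    get_rates <- function(cy) {
      ids <- pop$trials$trial_id[pop$trials$cycle == cy]
      ids <- ids[ids %in% split$trial_id[split$half == "train" &
                                           split$cell_id == cid]]
      vapply(ids, function(tid) {
        ev <- pop$trials$t_ch_on[pop$trials$trial_id == tid]
        sum(spikes$cell_id == cid & spikes$trial_id == tid &
              spikes$spike_time_s >= ev & spikes$spike_time_s < ev + 0.4) /
          0.4
      }, 0.0)
    }
    r1 <- get_rates(1L); r4 <- get_rates(4L)
    ctr_or[i] <- (mean(r1) + mean(r4)) / 2
    sc_or[i] <- (sd(r1) + sd(r4)) / 2
    if (is.na(sc_or[i]) || sc_or[i] == 0) {
      sc_or[i] <- 1; w_or[i] <- 0
    } else {
      w_or[i] <- (mean(r4) - mean(r1)) / sc_or[i]
    }
  }
  ord <- match(paste0("c", 1:5), model$cell_id)
  expect_equal(model$weights[ord], w_or, tolerance = 1e-10)
  expect_equal(model$center[ord], ctr_or, tolerance = 1e-10)
  expect_equal(model$scale[ord], sc_or, tolerance = 1e-10)
})

test_that("discriminant projections are antisymmetric in the cycle labels", {
  sim <- ee_labeled_sim()
  split_d <- split_trials(sim$trials, sim$cells, seed = 191,
                          halves = c("train", "test"))
  w <- selection_windows()$CH
  m1 <- fit_discriminant(sim$trials, sim$spikes, sim$cells, split_d, w)
  swapped <- sim$trials
  swapped$cycle[sim$trials$cycle == 1L] <- 4L
  swapped$cycle[sim$trials$cycle == 4L] <- 1L
  m2 <- fit_discriminant(swapped, sim$spikes, sim$cells, split_d, w)
  expect_equal(m2$weights, -m1$weights, tolerance = 1e-10)
  expect_equal(m2$center, m1$center, tolerance = 1e-10)
  # train-data projections: C4 positive, C1 negative with equal magnitude
  tr_train <- dplyr::semi_join(
    dplyr::filter(sim$trials, .data$correct, .data$cycle %in% c(1L, 4L)),
    split_d[split_d$half == "train" &
              split_d$cell_id == sim$cells$cell_id[1], ],
    by = "trial_id")
  cm4 <- explorexploit:::condition_cell_means(
    m1, sim$trials, sim$spikes, sim$cells,
    explorexploit:::all_cells_trials(sim$cells, dplyr::filter(tr_train, .data$cycle == 4L)))
  cm1 <- explorexploit:::condition_cell_means(
    m1, sim$trials, sim$spikes, sim$cells,
    explorexploit:::all_cells_trials(sim$cells, dplyr::filter(tr_train, .data$cycle == 1L)))
  p4 <- project_discriminant(m1, cm4)
  p1 <- project_discriminant(m1, cm1)
  expect_gt(p4, 0)
  expect_lt(p1, 0)
  expect_equal(as.numeric(p4), -as.numeric(p1), tolerance = 0.2)
})

test_that("projection of a 50/50 cycle mixture lands midway", {
  sim <- ee_labeled_sim()
  split_d <- split_trials(sim$trials, sim$cells, seed = 201,
                          halves = c("train", "test"))
  w <- selection_windows()$CH
  model <- fit_discriminant(sim$trials, sim$spikes, sim$cells, split_d, w)
  test_half <- split_d[split_d$half == "test", c("cell_id", "trial_id")]
  ct <- function(cy) {
    dplyr::inner_join(
      test_half,
      dplyr::filter(sim$trials, .data$correct,
                    .data$cycle == cy)["trial_id"],
      by = "trial_id")
  }
  c1 <- ct(1L); c4 <- ct(4L)
  mix <- dplyr::bind_rows(dplyr::slice_head(dplyr::group_by(c1, .data$cell_id), n = 5),
                          dplyr::slice_head(dplyr::group_by(c4, .data$cell_id), n = 5))
  pm <- project_discriminant(
    model, explorexploit:::condition_cell_means(model, sim$trials,
                                                sim$spikes, sim$cells, mix))
  p1 <- project_discriminant(
    model, explorexploit:::condition_cell_means(
      model, sim$trials, sim$spikes, sim$cells,
      dplyr::slice_head(dplyr::group_by(c1, .data$cell_id), n = 5)))
  p4 <- project_discriminant(
    model, explorexploit:::condition_cell_means(
      model, sim$trials, sim$spikes, sim$cells,
      dplyr::slice_head(dplyr::group_by(c4, .data$cell_id), n = 5)))
  expect_equal(as.numeric(pm), (as.numeric(p1) + as.numeric(p4)) / 2,
               tolerance = 1e-8)
})

test_that("permutation p values follow the add-one rule and its bounds", {
  pop <- make_deterministic_pop(list(c1 = c(C1 = 5, C4 = 15),
                                     c2 = c(C1 = 15, C4 = 5),
                                     c3 = c(C1 = 10, C4 = 10)),
                                n_trials_per_cycle = 10L)
  split <- pop$split
  split$half <- ifelse(split$half == "A", "train", "test")
  # add noise so scales are nonzero
  set.seed(44)
  noise <- manual_spikes("c1", sample(pop$trials$trial_id, 10), rep(1.3, 10))
  noise2 <- manual_spikes("c2", sample(pop$trials$trial_id, 10), rep(1.3, 10))
  noise3 <- manual_spikes("c3", sample(pop$trials$trial_id, 10), rep(1.3, 10))
  spikes <- dplyr::bind_rows(pop$spikes, noise, noise2, noise3)
  model <- fit_discriminant(pop$trials, spikes, pop$cells, split,
                            window_spec("CH", 0, 0.4))
  rates <- window_rates(spikes, pop$trials, pop$cells,
                        window_spec("CH", 0, 0.4))
  r1 <- dplyr::semi_join(rates, dplyr::filter(pop$trials, .data$cycle == 1L),
                         by = "trial_id")
  r4 <- dplyr::semi_join(rates, dplyr::filter(pop$trials, .data$cycle == 4L),
                         by = "trial_id")
  # strongly separated conditions reach the attainable minimum 1/(n+1)
  pt <- permutation_test(model, r1, r4, n = 200, seed = 7)
  expect_equal(pt$p_value, 1 / 201)
  # identical data: p = 1
  pt_same <- permutation_test(model, r1, r1, n = 200, seed = 7)
  expect_equal(pt_same$p_value, 1)
  # p never 0, and a warning below 100 permutations
  expect_warning(pt_small <- permutation_test(model, r1, r4, n = 50,
                                              seed = 8), "n < 100")
  expect_gt(pt_small$p_value, 0)
  expect_error(permutation_test(model, r1[0, ], r4), "empty")
})

test_that("one-shot population signature holds end to end", {
  sim <- ee_labeled_sim()
  split_d <- split_trials(sim$trials, sim$cells, seed = 211,
                          halves = c("train", "test"))
  da <- discriminant_analysis(sim$trials, sim$spikes, sim$cells, split_d,
                              selection_windows()$CH, n_permutations = 300,
                              seed = 212)
  pr <- da$projections
  expect_lt(pr[["C1_test"]], 0)
  expect_gt(pr[["C4_test"]], 0)
  # Cycles 2-3 cluster with Cycle 4; failed learning falls between C1 and C2
  expect_gt(pr[["C2_failed"]], pr[["C1_test"]])
  expect_lt(pr[["C2_failed"]], pr[["C2"]])
  pm <- da$permutation
  get_p <- function(a, b) pm$p_value[pm$condition_a == a & pm$condition_b == b]
  expect_equal(get_p("C1_test", "C2"), 1 / 301)
  expect_equal(get_p("C1_test", "C4_test"), 1 / 301)
  expect_gt(get_p("C2", "C4_test"), 0.05)
  expect_gt(get_p("C3", "C4_test"), 0.05)
  expect_lt(get_p("C2_failed", "C1_test"), 0.05)
  expect_lt(get_p("C2_failed", "C2"), 0.05)
})
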