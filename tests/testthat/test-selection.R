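test_that("trial splits are balanced, stratified and reproducible", {
  trials <- simulate_behavior(30, 30, seed = 111)
  cells <- manual_cells(c("c1", "c2"), session = "S01")
  s1 <- split_trials(trials, cells, seed = 5)
  s2 <- split_trials(trials, cells, seed = 5)
  expect_identical(s1, s2)
  s3 <- split_trials(trials, cells, seed = 6)
  expect_false(identical(s1$half, s3$half))
  # 50/50 within one trial overall and within every stratum
  for (cid in cells$cell_id) {
    h <- s1[s1$cell_id == cid, ]
    expect_lte(abs(sum(h$half == "selection") - sum(h$half == "validation")),
               nlevels(interaction(trials$cycle, trials$n_targets,
                                   trials$object_set,
                                   trials$chosen_location, drop = TRUE)))
    d <- dplyr::inner_join(h, trials, by = "trial_id")
    per_stratum <- dplyr::count(
      d, .data$cycle, .data$n_targets, .data$object_set,
      .data$chosen_location, .data$half)
    wide <- tidyr::pivot_wider(per_stratum, names_from = "half",
                               values_from = "n", values_fill = 0L)
    expect_true(all(abs(wide$selection - wide$validation) <= 1L))
  }
})

test_that("selection ANOVA matches a model-comparison oracle and guards degeneracy", {
  set.seed(9)
  d <- tibble::tibble(
    cycle = rep(c(1L, 4L), each = 40),
    n_targets = rep(c(1L, 2L), 40),
    object_set = rep(c(1L, 1L, 2L, 2L), 20),
    chosen_location = sample(1:4, 80, replace = TRUE),
    rate = rnorm(80, 10) + rep(c(0, 2), each = 40))
  res <- selection_anova(d)
  # independent oracle: Type II = comparison of the main-effects model with
  # the model dropping the factor
  oracle_p <- function(dd, fac) {
    full <- lm(rate ~ factor(cycle) + factor(n_targets) +
                 factor(object_set) + factor(chosen_location), data = dd)
    red_terms <- setdiff(c("cycle", "n_targets", "object_set",
                           "chosen_location"), fac)
    red <- lm(stats::reformulate(paste0("factor(", red_terms, ")"),
                                 response = "rate"), data = dd)
    stats::anova(red, full)[2, "Pr(>F)"]
  }
  for (fac in c("cycle", "n_targets", "object_set", "chosen_location")) {
    expect_equal(res$p_value[res$term == fac], oracle_p(d, fac),
                 tolerance = 1e-10)
  }
  # single-level factor is dropped and logged
  d1 <- d
  d1$object_set <- 1L
  res1 <- selection_anova(d1)
  expect_false("object_set" %in% res1$term)
  expect_identical(attr(res1, "dropped"), "object_set")
  # zero variance: never selected
  d0 <- d
  d0$rate <- 5
  expect_true(all(is.na(selection_anova(d0)$p_value)))
})

test_that("cells are labelled by significance and direction", {
  res <- tibble::tibble(cell_id = c("a", "b", "c"), phase = "CH",
                        p_cycle = c(0.01, 0.01, 0.2),
                        mean_c1 = c(5, 2, 9), mean_c4 = c(2, 5, 1))
  lab <- classify_cells(res)
  expect_identical(lab$label, c("explore", "exploit", "none"))
})

test_that("ground-truth cells are recovered with correct sign and phase", {
  sim <- ee_labeled_sim()
  gt <- sim$gt$cells[sim$gt$cells$label != "none", ]
  key_est <- paste(sim$selection$cell_id, sim$selection$phase,
                   sim$selection$label)
  hit <- paste(gt$cell_id, gt$phase, gt$label) %in% key_est
  expect_gte(mean(hit), 0.8)
  # untuned cells are rarely labelled
  null_ids <- sim$gt$cells$cell_id[sim$gt$cells$label == "none"]
  fp <- sim$selection$label[sim$selection$cell_id %in% null_ids] != "none"
  expect_lt(mean(fp), 0.25)
})

test_that("validation t tests preserve group direction on held-out data", {
  sim <- ee_labeled_sim()
  val <- validate_selection(sim$selection, sim$trials, sim$spikes,
                            sim$cells, sim$split_sel)
  g <- val$groups
  expect_true(all(g$mean_diff[g$label == "explore"] < 0))
  expect_true(all(g$mean_diff[g$label == "exploit"] > 0))
  expect_true(all(g$p_value < 0.05))
})

test_that("CH-selected cells show no cycle preference at FB (phase conjunction)", {
  sim <- ee_labeled_sim()
  # validate each phase's labels in the *other* phase's window
  swapped <- list(CH = selection_windows()$FB, FB = selection_windows()$CH)
  val <- validate_selection(sim$selection, sim$trials, sim$spikes,
                            sim$cells, sim$split_sel, windows = swapped)
  g <- val$groups
  expect_true(all(g$p_value > 0.05))
  labelled <- val$cells[val$cells$label != "none", ]
  expect_lt(mean(abs(labelled$validation_t) > 2, na.rm = TRUE), 0.3)
})

test_that("normalised PSTHs are flat at 1 for a homogeneous Poisson cell", {
  agent <- agent_config(p_abort = 0, p_no_response = 0)
  trials <- simulate_behavior(60, 60, agent = agent, seed = 121)
  pop <- population_config(n_cells = 2, fraction_explore_ch = 0,
                           fraction_exploit_ch = 0, fraction_explore_fb = 0,
                           fraction_exploit_fb = 0, object_tuning_sd = 0,
                           location_tuning_sd = 0,
                           fraction_outcome_cells = 0,
                           baseline_meanlog = log(10), baseline_sdlog = 0)
  sim <- simulate_population(trials, pop, seed = 122)
  split <- split_trials(trials, sim$cells, seed = 123)
  norms <- cell_norm_constants(trials, sim$spikes, sim$cells, split)
  expect_true(all(norms$usable))
  expect_equal(norms$norm_constant, rep(10, 2), tolerance = 0.1)
  val_trials <- dplyr::semi_join(
    dplyr::filter(trials, .data$correct),
    split[split$half == "validation" & split$cell_id == "cell_001", ],
    by = "trial_id")
  psth <- build_psth(val_trials, sim$spikes, sim$cells, "CH", norms)
  expect_length(unique(psth$center), 28)
  g <- group_psth(psth)
  expect_true(all(abs(g$value - 1) < 0.15))
})

test_that("PSTHs are invariant to trial order and uniform time translation", {
  trials <- simulate_behavior(20, 0, agent_config(p_abort = 0,
                                                  p_no_response = 0),
                              seed = 131)
  pop <- population_config(n_cells = 1, fraction_explore_ch = 0,
                           fraction_exploit_ch = 0, fraction_explore_fb = 0,
                           fraction_exploit_fb = 0,
                           fraction_outcome_cells = 0)
  sim <- simulate_population(trials, pop, seed = 132)
  split <- split_trials(trials, sim$cells, seed = 133)
  norms <- cell_norm_constants(trials, sim$spikes, sim$cells, split)
  correct <- dplyr::filter(trials, .data$correct)
  p0 <- build_psth(correct, sim$spikes, sim$cells, "CH", norms)
  # shuffled trial order
  p1 <- build_psth(correct[sample(nrow(correct)), ], sim$spikes, sim$cells,
                   "CH", norms)
  expect_equal(p0, p1)
  # shift all events and spikes by the same constant
  shift <- 2.5
  tr_s <- dplyr::mutate(correct,
                        t_ch_on = .data$t_ch_on + shift,
                        t_go = .data$t_go + shift,
                        t_touch = .data$t_touch + shift,
                        t_fb_on = .data$t_fb_on + shift)
  sp_s <- dplyr::mutate(sim$spikes,
                        spike_time_s = .data$spike_time_s + shift)
  p2 <- build_psth(tr_s, sp_s, sim$cells, "CH", norms)
  expect_equal(p0$value, p2$value)
})

test_that("object-interaction screen stays near alpha without object-specific gain", {
  sim <- ee_labeled_sim()
  scr <- object_interaction_screen(sim$selection, sim$trials, sim$spikes,
                                   sim$cells, sim$split_sel)
  expect_true(all(scr$fraction$fraction < 0.25))
  expect_true(all(scr$details$p_interaction >= 0 |
                    is.na(scr$details$p_interaction)))
})
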