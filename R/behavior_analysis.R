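#' Summarise trials per cycle and response-type breakdown
#'
#' For each animal, problem type (1- vs 2-target) and cycle: the mean number
#' of trials per cycle and the mean count of each response type per cycle
#' (correct target selections `T`, novel nontarget selections `NT_novel`,
#' nontarget revisits `NT_revisit`, target revisits `T_revisit`, and
#' `no_response`). Counts are computed per problem and averaged over
#' problems, so per completed cycle the `T` count equals `n_targets`.
#'
#' @param trials a trial table (should already have passed
#'   [apply_problem_exclusion()]).
#' @return tibble with one row per animal x n_targets x cycle.
#' @export
summarize_cycles <- function(trials) {
  if (!"response_type" %in% names(trials)) {
    trials <- add_response_types(trials)
  }
  per_problem <- dplyr::summarise(
    dplyr::group_by(trials, .data$animal_id, .data$n_targets,
                    .data$problem_id, .data$cycle),
    n_trials = dplyr::n(),
    T = sum(.data$response_type == "T"),
    NT_novel = sum(.data$response_type == "NT_novel"),
    NT_revisit = sum(.data$response_type == "NT_revisit"),
    T_revisit = sum(.data$response_type == "T_revisit"),
    no_response = sum(.data$response_type == "no_response"),
    .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_problem, .data$animal_id, .data$n_targets,
                    .data$cycle),
    n_problems = dplyr::n(),
    mean_trials = mean(.data$n_trials),
    mean_T = mean(.data$T),
    mean_NT_novel = mean(.data$NT_novel),
    mean_NT_revisit = mean(.data$NT_revisit),
    mean_T_revisit = mean(.data$T_revisit),
    mean_no_response = mean(.data$no_response),
    .groups = "drop")
}

# chi-square goodness of fit of k revisits out of n against chance p
revisit_chisq <- function(k, n, p) {
  if (n == 0L || p <= 0 || p >= 1) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  obs <- c(k, n - k)
  expd <- n * c(p, 1 - p)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cycle-1 revisit rates against chance
#'
#' Breaks Cycle-1 choice trials down by the number of distinct objects
#' already sampled in the cycle (0--3) and compares the observed proportion
#' of revisits in each bin against the memoryless chance expectation
#' `n_already_sampled / 4` ([chance_revisit_probability()]), with a per-bin
#' chi-square goodness-of-fit test. Empty bins are reported with `NA`
#' statistics.
#'
#' @param trials a trial table.
#' @param by grouping columns in addition to the already-sampled bin
#'   (default animal and problem type, as in the published table).
#' @return tibble with observed/expected revisit percentages, trial counts
#'   and chi-square statistics per group x bin.
#' @export
revisit_vs_chance <- function(trials, by = c("animal_id", "n_targets")) {
  c1 <- dplyr::filter(trials, .data$cycle == 1L, !is.na(.data$chosen_object))
  c1 <- dplyr::arrange(c1, .data$problem_id, .data$trial_in_cycle)
  n_sampled <- integer(nrow(c1))
  revisit <- logical(nrow(c1))
  for (g in split(seq_len(nrow(c1)),
                  factor(c1$problem_id, levels = unique(c1$problem_id)))) {
    sampled <- integer(0)
    for (i in g) {
      n_sampled[i] <- length(sampled)
      revisit[i] <- c1$chosen_object[i] %in% sampled
      sampled <- union(sampled, c1$chosen_object[i])
    }
  }
  c1$n_already_sampled <- n_sampled
  c1$revisit <- revisit
  grid <- tidyr::crossing(dplyr::distinct(c1,
                                          dplyr::across(dplyr::all_of(by))),
                          n_already_sampled = 0:3)
  obs <- dplyr::summarise(
    dplyr::group_by(c1, dplyr::across(dplyr::all_of(by)),
                    .data$n_already_sampled),
    n_trials = dplyr::n(), n_revisits = sum(.data$revisit),
    .groups = "drop")
  out <- dplyr::left_join(grid, obs, by = c(by, "n_already_sampled"))
  out$n_trials <- dplyr::coalesce(out$n_trials, 0L)
  out$n_revisits <- dplyr::coalesce(out$n_revisits, 0L)
  out$expected_pct <- 100 * chance_revisit_probability(out$n_already_sampled)
  out$observed_pct <- ifelse(out$n_trials > 0,
                             100 * out$n_revisits / out$n_trials, NA_real_)
  tests <- Map(revisit_chisq, out$n_revisits, out$n_trials,
               out$expected_pct / 100)
  out$chisq <- vapply(tests, `[[`, 0.0, "statistic")
  out$p_value <- vapply(tests, `[[`, 0.0, "p_value")
  out
}

#' Decline of nontarget selections across cycles
#'
#' One mean novel-nontarget count per session per cycle enters a one-way
#' repeated-factor ANOVA on cycle (session as the repeated unit), followed by
#' Tukey HSD tests on cycle pairs, separately per animal and problem type.
#'
#' @param trials a trial table spanning at least two sessions.
#' @return tibble with one row per animal x n_targets: F, df, p, and a
#'   list-column `tukey` of pairwise cycle comparisons.
#' @export
nontarget_decline_test <- function(trials) {
  if (!"response_type" %in% names(trials)) {
    trials <- add_response_types(trials)
  }
  per_session <- dplyr::summarise(
    dplyr::group_by(trials, .data$animal_id, .data$n_targets,
                    .data$session_id, .data$problem_id, .data$cycle),
    nt = sum(.data$response_type == "NT_novel"), .groups = "drop")
  per_session <- dplyr::summarise(
    dplyr::group_by(per_session, .data$animal_id, .data$n_targets,
                    .data$session_id, .data$cycle),
    mean_nt = mean(.data$nt), .groups = "drop")
  groups <- dplyr::group_split(dplyr::group_by(per_session, .data$animal_id,
                                               .data$n_targets))
  out <- lapply(groups, function(d) {
    if (length(unique(d$session_id)) < 2L) {
      stop("nontarget_decline_test needs >= 2 sessions per animal x type",
           call. = FALSE)
    }
    d$cycle_f <- factor(d$cycle)
    d$session_f <- factor(d$session_id)
    fit <- aov(mean_nt ~ cycle_f + session_f, data = d)
    tab <- summary(fit)[[1]]
    i <- grep("^cycle_f", rownames(tab))
    tukey <- TukeyHSD(fit, which = "cycle_f")$cycle_f
    tibble::tibble(
      animal_id = d$animal_id[1], n_targets = d$n_targets[1],
      F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p_value = tab[i, "Pr(>F)"],
      tukey = list(tibble::tibble(pair = rownames(tukey),
                                  diff = tukey[, "diff"],
                                  p_adj = tukey[, "p adj"])))
  })
  dplyr::bind_rows(out)
}
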