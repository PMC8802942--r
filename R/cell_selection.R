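#' Split trials into two halves per cell
#'
#' Random 50/50 split of each cell's trials, stratified within the cells of
#' the condition grid (by default cycle x n_targets x object_set x chosen
#' location) so both halves cover every condition where possible. Cells of
#' the grid with an odd trial count place their remainder at random.
#'
#' @param trials a trial table.
#' @param cells cell table; each cell is split over its own session's trials.
#' @param seed integer seed; the assignment is reproducible from it.
#' @param halves length-2 character, names of the halves.
#' @param stratify_by condition columns for stratification.
#' @return tibble with `cell_id`, `trial_id`, `half`.
#' @export
split_trials <- function(trials, cells, seed,
                         halves = c("selection", "validation"),
                         stratify_by = c("cycle", "n_targets", "object_set",
                                         "chosen_location")) {
  stopifnot(length(halves) == 2L)
  with_seed(seed, {
    strata <- interaction(lapply(stratify_by, function(cn) {
      x <- trials[[cn]]
      x[is.na(x)] <- -1L
      x
    }), drop = TRUE)
    out <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      in_sess <- which(trials$session_id == cells$session_id[ci])
      half <- character(length(in_sess))
      for (g in split(seq_along(in_sess), droplevels(strata[in_sess]))) {
        n <- length(g)
        lab <- c(rep(halves, n %/% 2L),
                 if (n %% 2L) sample(halves, 1L))
        half[g] <- sample(lab)
      }
      out[[ci]] <- tibble::tibble(cell_id = cells$cell_id[ci],
                                  trial_id = trials$trial_id[in_sess],
                                  half = half)
    }
    dplyr::bind_rows(out)
  })
}

# restrict a rates table to one half of a split for each cell
rates_in_half <- function(rates, split, which_half) {
  dplyr::inner_join(rates,
                    split[split$half == which_half,
                          c("cell_id", "trial_id")],
                    by = c("cell_id", "trial_id"))
}

#' Factorial ANOVA on windowed rates for one cell
#'
#' Fits a main-effects linear model of per-trial rate on the supplied task
#' factors and returns Type II tests per factor. Factors observed at a single
#' level are dropped (and listed in the `dropped` attribute); with zero rate
#' variance or too few residual degrees of freedom all p values are `NA`, so
#' such cells are never selected.
#'
#' @param data tibble with a `rate` column and the factor columns.
#' @param factors factor column names; the first is the effect of interest.
#' @param interactions optional character vector of interaction terms, e.g.
#'   `"cycle:chosen_object"`.
#' @return tibble with `term`, `df`, `F`, `p_value`; attribute `dropped`
#'   lists dropped factors.
#' @export
selection_anova <- function(data,
                            factors = c("cycle", "n_targets", "object_set",
                                        "chosen_location"),
                            interactions = character(0)) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  keep <- vapply(factors, function(f) nlevels(droplevels(data[[f]])) > 1L,
                 logical(1))
  dropped <- factors[!keep]
  factors <- factors[keep]
  interactions <- interactions[
    vapply(interactions, function(tm) {
      all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% factors)
    }, logical(1))]
  empty <- tibble::tibble(term = character(), df = double(), F = double(),
                          p_value = double())
  if (length(factors) == 0L || nrow(data) < length(factors) + 2L ||
      var(data$rate) == 0) {
    out <- tibble::tibble(term = factors, df = NA_real_, F = NA_real_,
                          p_value = NA_real_)
    attr(out, "dropped") <- dropped
    return(out)
  }
  rhs <- paste(c(factors, interactions), collapse = " + ")
  fit <- lm(stats::as.formula(paste("rate ~", rhs)), data = data)
  tab <- tryCatch(suppressMessages(car::Anova(fit, type = 2)),
                  error = function(e) NULL)
  if (is.null(tab)) {
    out <- tibble::tibble(term = factors, df = NA_real_, F = NA_real_,
                          p_value = NA_real_)
    attr(out, "dropped") <- dropped
    return(out)
  }
  tab <- as.data.frame(tab)
  terms_kept <- setdiff(rownames(tab), "Residuals")
  out <- tibble::tibble(term = terms_kept,
                        df = tab[terms_kept, "Df"],
                        F = tab[terms_kept, "F value"],
                        p_value = tab[terms_kept, "Pr(>F)"])
  attr(out, "dropped") <- dropped
  out
}

#' Classify cells as explore, exploit or none
#'
#' A cell is labelled when its cycle main effect is significant at `alpha`:
#' `explore` if its Cycle-1 mean exceeds its Cycle-4 mean on the selection
#' data, `exploit` for the reverse.
#'
#' @param results tibble with columns `cell_id`, `phase`, `p_cycle`,
#'   `mean_c1`, `mean_c4` (one row per cell x phase).
#' @param alpha selection level (default 0.05, uncorrected across cells; the
#'   held-out validation half guards against selection bias).
#' @return `results` with a `label` column.
#' @export
classify_cells <- function(results, alpha = 0.05) {
  results$label <- ifelse(
    !is.na(results$p_cycle) & results$p_cycle < alpha,
    ifelse(results$mean_c1 > results$mean_c4, "explore", "exploit"),
    "none")
  results
}

# per-cell selection data: selection half, cycles 1 and 4, correct trials
selection_data <- function(trials, spikes, cells, split, window) {
  rates <- window_rates(spikes, trials, cells, window)
  rates <- rates_in_half(rates, split, "selection")
  tr <- trials[trials$cycle %in% c(1L, 4L) & trials$correct,
               c("trial_id", "cycle", "n_targets", "object_set",
                 "chosen_location", "chosen_object")]
  dplyr::inner_join(rates, tr, by = "trial_id")
}

#' Cross-validated selection of explore/exploit cells
#'
#' For each phase (CH, FB) runs, per cell, a factorial ANOVA of the 400 ms
#' window rate on cycle (1, 4) x number of targets x object set x touched
#' location, on correct trials of the selection half only (Cycles 2 and 3
#' are never used for selection). Cells with a significant cycle main effect
#' are labelled explore (Cycle 1 > 4) or exploit (Cycle 4 > 1) via
#' [classify_cells()].
#'
#' @param trials,spikes,cells the dataset tables.
#' @param split a [split_trials()] assignment with halves
#'   `selection`/`validation`.
#' @param alpha selection level.
#' @param windows named list of [window_spec()]s per phase
#'   (default [selection_windows()]).
#' @return tibble with one row per cell x phase: `p_cycle`, selection-half
#'   cycle means, `label`, plus ANOVA diagnostics in the `anova` list-column.
#' @export
run_selection <- function(trials, spikes, cells, split, alpha = 0.05,
                          windows = selection_windows()) {
  out <- lapply(names(windows), function(ph) {
    dat <- selection_data(trials, spikes, cells, split, windows[[ph]])
    per_cell <- lapply(split(dat, dat$cell_id), function(d) {
      an <- selection_anova(d)
      pc <- an$p_value[an$term == "cycle"]
      tibble::tibble(
        cell_id = d$cell_id[1], phase = ph,
        p_cycle = if (length(pc)) pc else NA_real_,
        mean_c1 = mean(d$rate[d$cycle == 1L]),
        mean_c4 = mean(d$rate[d$cycle == 4L]),
        n_sel_trials = nrow(d),
        anova = list(an))
    })
    dplyr::bind_rows(per_cell)
  })
  classify_cells(dplyr::bind_rows(out), alpha = alpha)
}

#' Validate selected cells on the held-out half
#'
#' Per labelled cell, a two-sample t test of validation-half rates (0--400 ms
#' phase window, correct trials) between Cycles 1 and 4; and per group
#' (phase x label), an across-cells one-sample t test of the per-cell
#' Cycle-4 minus Cycle-1 validation mean differences.
#'
#' @param selection output of [run_selection()].
#' @inheritParams run_selection
#' @return list with `cells` (selection table plus `validation_t`,
#'   `validation_p`, `validation_diff`) and `groups` (per phase x label:
#'   across-cells t, df, p, mean difference, n).
#' @export
validate_selection <- function(selection, trials, spikes, cells, split,
                               windows = selection_windows()) {
  tr <- trials[trials$cycle %in% c(1L, 4L) & trials$correct,
               c("trial_id", "cycle")]
  per_phase <- lapply(unique(selection$phase), function(ph) {
    rates <- window_rates(spikes, trials, cells, windows[[ph]])
    rates <- rates_in_half(rates, split, "validation")
    dat <- dplyr::inner_join(rates, tr, by = "trial_id")
    sel_ph <- selection[selection$phase == ph, ]
    res <- lapply(seq_len(nrow(sel_ph)), function(i) {
      d <- dat[dat$cell_id == sel_ph$cell_id[i], ]
      x1 <- d$rate[d$cycle == 1L]
      x4 <- d$rate[d$cycle == 4L]
      if (length(x1) < 2L || length(x4) < 2L ||
          (var(x1) == 0 && var(x4) == 0)) {
        return(tibble::tibble(validation_t = NA_real_,
                              validation_p = NA_real_,
                              validation_diff = mean(x4) - mean(x1)))
      }
      tt <- t.test(x4, x1)
      tibble::tibble(validation_t = unname(tt$statistic),
                     validation_p = tt$p.value,
                     validation_diff = mean(x4) - mean(x1))
    })
    dplyr::bind_cols(sel_ph, dplyr::bind_rows(res))
  })
  cells_out <- dplyr::bind_rows(per_phase)
  labelled <- cells_out[cells_out$label != "none", ]
  groups <- dplyr::group_split(dplyr::group_by(labelled, .data$phase,
                                               .data$label))
  group_tests <- lapply(groups, function(g) {
    base <- tibble::tibble(phase = g$phase[1], label = g$label[1],
                           n_cells = nrow(g),
                           mean_diff = mean(g$validation_diff, na.rm = TRUE))
    d <- g$validation_diff[!is.na(g$validation_diff)]
    if (length(d) < 2L) {
      warning("validation group ", g$phase[1], "/", g$label[1],
              " has < 2 cells; skipped", call. = FALSE)
      return(dplyr::bind_cols(base, tibble::tibble(
        t = NA_real_, df = NA_real_, p_value = NA_real_)))
    }
    tt <- t.test(d)
    dplyr::bind_cols(base, tibble::tibble(
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value))
  })
  list(cells = cells_out, groups = dplyr::bind_rows(group_tests))
}

#' Per-cell normalisation constants
#'
#' A cell's mean activity is the unweighted mean over all condition cells of
#' the selection ANOVAs (cycle x n_targets x object_set x location), averaged
#' over the CH and FB 400 ms windows. Cells with a constant below
#' `min_rate` are flagged for exclusion from normalised group PSTHs.
#'
#' @inheritParams run_selection
#' @param min_rate minimum usable constant in spikes/s.
#' @return tibble with `cell_id`, `norm_constant`, `usable`.
#' @export
cell_norm_constants <- function(trials, spikes, cells, split,
                                windows = selection_windows(),
                                min_rate = 0.1) {
  by <- c("cycle", "n_targets", "object_set", "chosen_location")
  per_window <- lapply(windows, function(w) {
    dat <- selection_data(trials, spikes, cells, split, w)
    dplyr::summarise(dplyr::group_by(dat, .data$cell_id),
                     m = unweighted_mean(dplyr::pick(dplyr::everything()),
                                         by = by),
                     .groups = "drop")
  })
  both <- dplyr::bind_rows(per_window)
  out <- dplyr::summarise(dplyr::group_by(both, .data$cell_id),
                          norm_constant = mean(.data$m, na.rm = TRUE),
                          .groups = "drop")
  out$usable <- !is.na(out$norm_constant) & out$norm_constant >= min_rate
  out
}

#' Normalised PSTH for cells over a trial subset
#'
#' Counts spikes in 28 overlapping 100 ms windows (centres -200 to +475 ms
#' in 25 ms steps from the alignment event), takes per window the unweighted
#' mean rate over n_targets x object_set x touched location, and divides by
#' the cell's mean activity ([cell_norm_constants()]).
#'
#' @param trials a trial table already restricted to the trials of interest
#'   (e.g. validation-half correct trials of one cycle).
#' @param spikes,cells the dataset tables.
#' @param alignment `"CH"` or `"FB"`.
#' @param norms output of [cell_norm_constants()]; cells flagged unusable are
#'   dropped.
#' @return tibble with `cell_id`, `center` (s), `value` (normalised rate).
#' @export
build_psth <- function(trials, spikes, cells, alignment, norms) {
  usable <- norms[norms$usable, ]
  cells <- cells[cells$cell_id %in% usable$cell_id, ]
  by <- c("n_targets", "object_set", "chosen_location")
  cond <- trials[, c("trial_id", by)]
  out <- lapply(psth_centers(), function(ctr) {
    w <- window_spec(alignment, ctr - 0.05, 0.1)
    rates <- window_rates(spikes, trials, cells, w)
    dat <- dplyr::inner_join(rates, cond, by = "trial_id")
    m <- dplyr::summarise(dplyr::group_by(dat, .data$cell_id),
                          value = unweighted_mean(
                            dplyr::pick(dplyr::everything()), by = by),
                          .groups = "drop")
    m$center <- ctr
    m
  })
  out <- dplyr::bind_rows(out)
  out$value <- out$value /
    usable$norm_constant[match(out$cell_id, usable$cell_id)]
  dplyr::arrange(out[, c("cell_id", "center", "value")],
                 .data$cell_id, .data$center)
}

#' Average per-cell PSTHs into a group PSTH
#' @param psth output of [build_psth()].
#' @return tibble with `center`, `value` (mean over cells), `n_cells`.
#' @export
group_psth <- function(psth) {
  dplyr::summarise(dplyr::group_by(psth, .data$center),
                   value = mean(.data$value, na.rm = TRUE),
                   n_cells = sum(!is.na(.data$value)), .groups = "drop")
}

#' Screen labelled cells for cycle x object interactions
#'
#' Repeats the selection ANOVA separately per object set with an added
#' object factor and a cycle:object interaction, and reports the fraction of
#' labelled cells with a significant interaction, averaged over the two
#' object sets.
#'
#' @param selection output of [run_selection()] (labelled cells are used).
#' @inheritParams run_selection
#' @return list with `fraction` (per phase, averaged over object sets) and
#'   `details` (per cell x phase x object set interaction p values).
#' @export
object_interaction_screen <- function(selection, trials, spikes, cells,
                                      split, alpha = 0.05,
                                      windows = selection_windows()) {
  labelled <- selection[selection$label != "none", ]
  details <- list()
  for (ph in unique(labelled$phase)) {
    dat_all <- selection_data(trials, spikes, cells, split, windows[[ph]])
    ids <- labelled$cell_id[labelled$phase == ph]
    for (os in sort(unique(trials$object_set))) {
      dat <- dat_all[dat_all$object_set == os & dat_all$cell_id %in% ids, ]
      for (d in split(dat, dat$cell_id)) {
        an <- selection_anova(
          d, factors = c("cycle", "n_targets", "chosen_object",
                         "chosen_location"),
          interactions = "cycle:chosen_object")
        pi_ <- an$p_value[an$term == "cycle:chosen_object"]
        details[[length(details) + 1L]] <- tibble::tibble(
          cell_id = d$cell_id[1], phase = ph, object_set = os,
          p_interaction = if (length(pi_)) pi_ else NA_real_)
      }
    }
  }
  details <- dplyr::bind_rows(details)
  frac <- dplyr::summarise(
    dplyr::group_by(details, .data$phase, .data$object_set),
    fraction = mean(.data$p_interaction < alpha, na.rm = TRUE),
    .groups = "drop")
  frac <- dplyr::summarise(dplyr::group_by(frac, .data$phase),
                           fraction = mean(.data$fraction),
                           .groups = "drop")
  list(fraction = frac, details = details)
}
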