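#' Cycle-preference vectors per time window
#'
#' For each cell and window, the Cycle-4 minus Cycle-1 mean rate computed on
#' correct trials of one half of a fresh random split, using unweighted means
#' over touched location x number of targets to remove those factors. Cells
#' with empty Cycle-1 or Cycle-4 data in the half get `NA` and are excluded
#' pairwise from correlations.
#'
#' @param trials,spikes,cells the dataset tables.
#' @param split a [split_trials()] assignment with halves `A`/`B`,
#'   independent of the selection/validation split.
#' @param half `"A"` or `"B"`.
#' @param windows named list of [window_spec()]s (default
#'   [crossgen_windows()]).
#' @return tibble with `cell_id`, `window`, `preference`.
#' @export
cycle_preference_vectors <- function(trials, spikes, cells, split, half,
                                     windows = crossgen_windows()) {
  by <- c("n_targets", "chosen_location")
  tr <- trials[trials$cycle %in% c(1L, 4L) & trials$correct,
               c("trial_id", "cycle", by)]
  out <- lapply(names(windows), function(wn) {
    rates <- window_rates(spikes, trials, cells, windows[[wn]])
    rates <- rates_in_half(rates, split, half)
    dat <- dplyr::inner_join(rates, tr, by = "trial_id")
    pref <- dplyr::bind_rows(lapply(split(dat, dat$cell_id), function(d) {
      tibble::tibble(cell_id = d$cell_id[1],
                     m1 = unweighted_mean(d[d$cycle == 1L, ], by = by),
                     m4 = unweighted_mean(d[d$cycle == 4L, ], by = by))
    }))
    tibble::tibble(cell_id = pref$cell_id, window = wn,
                   preference = pref$m4 - pref$m1)
  })
  dplyr::bind_rows(out)
}

#' Temporal cross-generalization matrix of cycle preference
#'
#' Pearson correlation (Spearman optional) between the half-A preference
#' vector of window i and the half-B vector of window j, for all pairs of the
#' 4 CH + 4 FB windows. Strong within-phase blocks with near-zero cross-phase
#' blocks indicate cycle preferences that are stable within a trial phase but
#' unrelated between phases.
#'
#' @inheritParams cycle_preference_vectors
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return an 8 x 8 matrix (rows: half-A windows; columns: half-B windows);
#'   attribute `n_cells` gives the pairwise-complete cell counts.
#' @export
cross_generalization_matrix <- function(trials, spikes, cells, split,
                                        windows = crossgen_windows(),
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pa <- cycle_preference_vectors(trials, spikes, cells, split, "A", windows)
  pb <- cycle_preference_vectors(trials, spikes, cells, split, "B", windows)
  wn <- names(windows)
  ids <- sort(unique(c(pa$cell_id, pb$cell_id)))
  if (length(ids) < 3L) stop("need >= 3 cells with data", call. = FALSE)
  vec <- function(p, w) {
    v <- p$preference[p$window == w][match(ids, p$cell_id[p$window == w])]
    v
  }
  mat <- matrix(NA_real_, length(wn), length(wn), dimnames = list(wn, wn))
  n_mat <- mat
  for (i in wn) {
    vi <- vec(pa, i)
    for (j in wn) {
      vj <- vec(pb, j)
      ok <- !is.na(vi) & !is.na(vj)
      n_mat[i, j] <- sum(ok)
      if (sum(ok) >= 3L && sd(vi[ok]) > 0 && sd(vj[ok]) > 0) {
        mat[i, j] <- cor(vi[ok], vj[ok], method = method)
      }
    }
  }
  attr(mat, "n_cells") <- n_mat
  mat
}

#' Within- minus cross-phase correlation contrast
#'
#' Mean of the two within-phase 4 x 4 blocks minus mean of the two
#' cross-phase blocks of a cross-generalization matrix. Positive values
#' indicate phase-conjunctive cycle preference.
#'
#' @param mat output of [cross_generalization_matrix()].
#' @return scalar contrast.
#' @export
crossgen_phase_contrast <- function(mat) {
  ch <- grep("^CH", rownames(mat))
  fb <- grep("^FB", rownames(mat))
  within <- c(mat[ch, ch], mat[fb, fb])
  cross <- c(mat[ch, fb], mat[fb, ch])
  mean(within, na.rm = TRUE) - mean(cross, na.rm = TRUE)
}

#' Fit the Cycle-1 vs Cycle-4 population discriminant
#'
#' From the train half (correct trials of Cycles 1 and 4): per cell, the
#' centre is the unweighted mean of the two cycle means, the scale the
#' unweighted mean of the two across-trial SDs, and the discriminant weight
#' the scaled Cycle-4 minus scaled Cycle-1 mean, in the full cell-dimensional
#' space. Cells with zero or undefined scale get scale 1 and weight 0
#' (masked) and are listed in `flagged`.
#'
#' @param trials,spikes,cells the dataset tables.
#' @param split a [split_trials()] assignment with halves `train`/`test`.
#' @param window analysis window (e.g. `selection_windows()$CH`).
#' @return a `discriminant_model` list: `cell_id`, `center`, `scale`,
#'   `weights`, `flagged`, `window`.
#' @export
fit_discriminant <- function(trials, spikes, cells, split, window) {
  rates <- window_rates(spikes, trials, cells, window)
  rates <- rates_in_half(rates, split, "train")
  tr <- trials[trials$cycle %in% c(1L, 4L) & trials$correct,
               c("trial_id", "cycle")]
  dat <- dplyr::inner_join(rates, tr, by = "trial_id")
  st <- dplyr::summarise(
    dplyr::group_by(dat, .data$cell_id),
    m1 = mean(.data$rate[.data$cycle == 1L]),
    m4 = mean(.data$rate[.data$cycle == 4L]),
    s1 = sd(.data$rate[.data$cycle == 1L]),
    s4 = sd(.data$rate[.data$cycle == 4L]),
    .groups = "drop")
  st <- dplyr::left_join(tibble::tibble(cell_id = cells$cell_id), st,
                         by = "cell_id")
  center <- (st$m1 + st$m4) / 2
  scale <- (st$s1 + st$s4) / 2
  bad <- is.na(scale) | scale == 0 | is.na(center)
  scale[bad] <- 1
  center[is.na(center)] <- 0
  w <- (st$m4 - st$m1) / scale
  w[bad | is.na(w)] <- 0
  structure(list(cell_id = st$cell_id, center = center, scale = scale,
                 weights = w, flagged = st$cell_id[bad], window = window),
            class = "discriminant_model")
}

# per-cell mean rates for a set of (cell_id, trial_id) pairs in the model's
# window; returns vector aligned with model$cell_id (NA where no trials)
condition_cell_means <- function(model, trials, spikes, cells, cond_trials) {
  rates <- window_rates(spikes, trials, cells, model$window)
  dat <- dplyr::inner_join(rates, cond_trials[, c("cell_id", "trial_id")],
                           by = c("cell_id", "trial_id"))
  m <- dplyr::summarise(dplyr::group_by(dat, .data$cell_id),
                        m = mean(.data$rate), .groups = "drop")
  m$m[match(model$cell_id, m$cell_id)]
}

#' Project condition means onto the discriminant
#'
#' Condition mean rates per cell are centred and scaled with the train
#' statistics and projected by dot product with the discriminant weights.
#' Cells with no data for the condition contribute zero (their weight is
#' masked); the count is reported in the `coverage` attribute.
#'
#' @param model a [fit_discriminant()] result.
#' @param cell_means numeric vector of per-cell condition means aligned with
#'   `model$cell_id` (`NA` allowed).
#' @return scalar projection with attribute `coverage` (fraction of cells
#'   with data).
#' @export
project_discriminant <- function(model, cell_means) {
  z <- (cell_means - model$center) / model$scale
  masked <- is.na(z)
  z[masked] <- 0
  out <- sum(model$weights * z)
  attr(out, "coverage") <- 1 - mean(masked)
  out
}

#' Permutation test for a projection difference
#'
#' Tests whether two conditions differ in their discriminant projections.
#' Per replicate and per cell, the pooled trials of both conditions have
#' their condition labels shuffled, condition means are recomputed,
#' re-projected onto the *fixed* discriminant (train centre/scale reused
#' unchanged), and the absolute projection difference recorded. The p value
#' uses the add-one rule `(k + 1) / (n + 1)` and therefore never equals 0.
#'
#' @param model a [fit_discriminant()] result.
#' @param rates_a,rates_b tibbles (`cell_id`, `trial_id`, `rate`) of
#'   per-trial rates in the model window for the two conditions.
#' @param n number of permutations (default 1000; below 100 a warning is
#'   issued).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` (projection difference a - b),
#'   `null_abs` (vector of permuted absolute differences), `n`.
#' @export
permutation_test <- function(model, rates_a, rates_b, n = 1000L, seed = 1L) {
  if (nrow(rates_a) == 0L || nrow(rates_b) == 0L) {
    stop("permutation_test: empty condition", call. = FALSE)
  }
  if (n < 100L) warning("permutation_test: n < 100 permutations",
                        call. = FALSE)
  w_over_s <- model$weights / model$scale
  names(w_over_s) <- model$cell_id
  obs_a <- dplyr::summarise(dplyr::group_by(rates_a, .data$cell_id),
                            m = mean(.data$rate), .groups = "drop")
  obs_b <- dplyr::summarise(dplyr::group_by(rates_b, .data$cell_id),
                            m = mean(.data$rate), .groups = "drop")
  ma <- obs_a$m[match(model$cell_id, obs_a$cell_id)]
  mb <- obs_b$m[match(model$cell_id, obs_b$cell_id)]
  # centring cancels in the difference; masked cells contribute 0
  contrib <- w_over_s * (ma - mb)
  observed <- sum(contrib, na.rm = TRUE)
  null_abs <- with_seed(seed, {
    acc <- numeric(n)
    both <- dplyr::bind_rows(
      dplyr::mutate(rates_a[, c("cell_id", "rate")], cond = "a"),
      dplyr::mutate(rates_b[, c("cell_id", "rate")], cond = "b"))
    for (d in split(both, both$cell_id)) {
      ws <- w_over_s[[d$cell_id[1]]]
      if (is.na(ws) || ws == 0) next
      x <- d$rate
      n_a <- sum(d$cond == "a")
      n_b <- length(x) - n_a
      if (n_a == 0L || n_b == 0L) next
      tot <- sum(x)
      perm <- vapply(seq_len(n), function(i) {
        sa <- sum(x[sample.int(length(x), n_a)])
        sa / n_a - (tot - sa) / n_b
      }, 0.0)
      acc <- acc + ws * perm
    }
    abs(acc)
  })
  k <- sum(null_abs >= abs(observed))
  list(p_value = (k + 1) / (n + 1), observed = observed,
       null_abs = null_abs, n = n)
}

#' One-shot population analysis: projections and permutation inference
#'
#' Fits the Cycle-1 vs Cycle-4 discriminant on the train half, projects test
#' data from Cycles 1 and 4, regular trials of Cycles 2 and 3, and Cycle-2
#' failed-learning trials, and runs permutation tests on the standard
#' condition pairs.
#'
#' @param trials,spikes,cells the dataset tables (1-target restriction is
#'   applied internally for the cycle conditions as in the one-shot
#'   analyses).
#' @param split a [split_trials()] assignment with halves `train`/`test`.
#' @param window analysis window.
#' @param n_permutations permutations per condition pair.
#' @param seed integer seed for the permutation draws.
#' @param one_target_only restrict conditions to 1-target problems
#'   (default TRUE).
#' @return list with `model`, `projections` (named numeric), `coverage`,
#'   `permutation` (tibble of pairwise p values) and `n_trials` per
#'   condition.
#' @export
discriminant_analysis <- function(trials, spikes, cells, split, window,
                                  n_permutations = 1000L, seed = 1L,
                                  one_target_only = TRUE) {
  model <- fit_discriminant(trials, spikes, cells, split, window)
  base <- if (one_target_only) {
    dplyr::filter(trials, .data$n_targets == 1L)
  } else trials
  reg <- regular_cycle_flags(trials)
  regular_ok <- function(d) {
    dplyr::inner_join(d, dplyr::filter(reg, .data$regular)[
      , c("problem_id", "cycle")], by = c("problem_id", "cycle"))
  }
  test_half <- split[split$half == "test", c("cell_id", "trial_id")]
  cond_defs <- list(
    C1_test = dplyr::inner_join(
      test_half,
      dplyr::filter(base, .data$cycle == 1L, .data$correct)["trial_id"],
      by = "trial_id"),
    C2 = all_cells_trials(cells, regular_ok(
      dplyr::filter(base, .data$cycle == 2L, .data$correct))),
    C3 = all_cells_trials(cells, regular_ok(
      dplyr::filter(base, .data$cycle == 3L, .data$correct))),
    C4_test = dplyr::inner_join(
      test_half,
      dplyr::filter(base, .data$cycle == 4L, .data$correct)["trial_id"],
      by = "trial_id"),
    C2_failed = all_cells_trials(
      cells, base[base$trial_id %in% failed_learning_trials(base), ]))
  rates_all <- window_rates(spikes, trials, cells, window)
  cond_rates <- lapply(cond_defs, function(ct) {
    dplyr::inner_join(rates_all, ct, by = c("cell_id", "trial_id"))
  })
  n_trials <- vapply(cond_defs, function(ct) {
    length(unique(ct$trial_id))
  }, integer(1))
  projections <- vapply(names(cond_rates), function(cn) {
    cm <- condition_cell_means(model, trials, spikes, cells, cond_defs[[cn]])
    as.numeric(project_discriminant(model, cm))
  }, 0.0)
  coverage <- vapply(names(cond_rates), function(cn) {
    cm <- condition_cell_means(model, trials, spikes, cells, cond_defs[[cn]])
    attr(project_discriminant(model, cm), "coverage")
  }, 0.0)
  pairs <- list(c("C1_test", "C2"), c("C1_test", "C3"),
                c("C2", "C4_test"), c("C3", "C4_test"),
                c("C1_test", "C4_test"),
                c("C2_failed", "C1_test"), c("C2_failed", "C2"))
  perm <- lapply(pairs, function(pr) {
    ra <- cond_rates[[pr[1]]]
    rb <- cond_rates[[pr[2]]]
    if (nrow(ra) == 0L || nrow(rb) == 0L) {
      return(tibble::tibble(condition_a = pr[1], condition_b = pr[2],
                            observed = NA_real_, p_value = NA_real_))
    }
    pt <- permutation_test(model, ra, rb, n = n_permutations,
                           seed = child_seed(seed, paste(pr, collapse = "_")))
    tibble::tibble(condition_a = pr[1], condition_b = pr[2],
                   observed = pt$observed, p_value = pt$p_value)
  })
  list(model = model, projections = projections, coverage = coverage,
       permutation = dplyr::bind_rows(perm), n_trials = n_trials,
       n_permutations = n_permutations, seed = seed)
}
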