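#' Pipeline configuration
#'
#' One configuration object drives the full pipeline; every analysis constant
#' is explicit (no hidden defaults) and all randomness flows from the named
#' seeds, so identical configuration yields identical numeric output. The
#' object round-trips through YAML unchanged ([read_config()],
#' [write_config()]).
#'
#' @param input_dir directory with `trials.csv`, `spikes.csv`, `cells.csv`
#'   (as written by [make_fixture()]); `NULL` to analyse in-memory tables
#'   passed to [run_pipeline()].
#' @param output_dir directory for result files; `NULL` to skip writing.
#' @param region region label to analyse (`"PFC"`, `"parietal"`, ...); the
#'   same code path runs for any region.
#' @param alpha selection significance level (0.05).
#' @param window_width selection/validation window width in seconds (0.4,
#'   beginning at CH and FB onset).
#' @param max_failures_per_cycle problem-exclusion threshold (6 failed trials
#'   in one cycle).
#' @param n_permutations permutations for discriminant inference (1000).
#' @param seed_split_selection,seed_split_crossgen,seed_split_discriminant,seed_permutation
#'   integer seeds for the three independent trial splits and the permutation
#'   draws.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            output_dir = NULL,
                            region = "PFC",
                            alpha = 0.05,
                            window_width = 0.4,
                            max_failures_per_cycle = 6L,
                            n_permutations = 1000L,
                            seed_split_selection = 11L,
                            seed_split_crossgen = 22L,
                            seed_split_discriminant = 33L,
                            seed_permutation = 44L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 region = region, alpha = alpha,
                 window_width = window_width,
                 max_failures_per_cycle = as.integer(max_failures_per_cycle),
                 n_permutations = as.integer(n_permutations),
                 seed_split_selection = as.integer(seed_split_selection),
                 seed_split_crossgen = as.integer(seed_split_crossgen),
                 seed_split_discriminant = as.integer(seed_split_discriminant),
                 seed_permutation = as.integer(seed_permutation)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @param config a [pipeline_config()].
#' @return `read_config` returns a `pipeline_config`; `write_config` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[intersect(names(x),
                                       names(formals(pipeline_config)))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a dataset from disk
#'
#' Reads the three CSV tables written by [make_fixture()] (or any dataset in
#' the same schema).
#'
#' @param dir directory containing `trials.csv`, `spikes.csv`, `cells.csv`.
#' @return list with `trials`, `spikes`, `cells` tibbles.
#' @export
read_dataset <- function(dir) {
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE)
  spikes <- readr::read_csv(file.path(dir, "spikes.csv"),
                            show_col_types = FALSE)
  cells <- readr::read_csv(file.path(dir, "cells.csv"),
                           show_col_types = FALSE)
  list(trials = trials, spikes = spikes[, spike_table_columns()],
       cells = cells[, cell_table_columns()])
}

#' Validate a dataset against the schema
#'
#' Checks column presence, arrangement bijectivity, event ordering
#' (`t_ch_on < t_go < t_touch < t_fb_on` where present), target/choice
#' consistency, identifier integrity and spike-time sanity. Returns all
#' issues found rather than stopping at the first.
#'
#' @param trials,spikes,cells the dataset tables.
#' @return list with `ok` (logical) and `issues` (tibble: `check`,
#'   `detail`, `n_rows`).
#' @export
validate_dataset <- function(trials, spikes, cells) {
  issues <- list()
  add <- function(check, detail, n_rows) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      check = check, detail = detail, n_rows = as.integer(n_rows))
  }
  missing_tr <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_tr)) {
    add("columns", paste("trials missing:",
                         paste(missing_tr, collapse = ", ")), NA)
  }
  missing_sp <- setdiff(spike_table_columns(), names(spikes))
  if (length(missing_sp)) {
    add("columns", paste("spikes missing:",
                         paste(missing_sp, collapse = ", ")), NA)
  }
  missing_ce <- setdiff(cell_table_columns(), names(cells))
  if (length(missing_ce)) {
    add("columns", paste("cells missing:",
                         paste(missing_ce, collapse = ", ")), NA)
  }
  if (length(issues)) {  # cannot check content without the columns
    return(list(ok = FALSE, issues = dplyr::bind_rows(issues)))
  }
  if (anyDuplicated(trials$trial_id)) {
    add("identifiers", "duplicated trial_id", sum(duplicated(trials$trial_id)))
  }
  arr <- as.matrix(trials[, paste0("obj_loc_", 1:4)])
  bad_arr <- apply(arr, 1L, function(r) {
    any(is.na(r)) || !setequal(r, 1:4)
  })
  if (any(bad_arr)) {
    add("arrangement", "object->location map is not a bijection of 1:4",
        sum(bad_arr))
  }
  ev <- trials[, c("t_ch_on", "t_go", "t_touch", "t_fb_on")]
  bad_order <- apply(as.matrix(ev), 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1L && is.unsorted(r, strictly = TRUE)
  })
  if (any(bad_order)) {
    add("event_order", "trial events not strictly increasing",
        sum(bad_order))
  }
  has_choice <- !is.na(trials$chosen_object)
  idx <- which(has_choice)
  loc_mismatch <- vapply(idx, function(i) {
    trials$chosen_location[i] != arr[i, trials$chosen_object[i]]
  }, logical(1))
  if (any(loc_mismatch, na.rm = TRUE)) {
    add("choice", "chosen_location inconsistent with arrangement",
        sum(loc_mismatch, na.rm = TRUE))
  }
  is_target <- has_choice &
    (trials$chosen_object == trials$target_1 |
       (!is.na(trials$target_2) & trials$chosen_object == trials$target_2))
  if (any(trials$correct & !is_target)) {
    add("choice", "correct = TRUE on a nontarget selection",
        sum(trials$correct & !is_target))
  }
  if (any(trials$rewarded & !trials$correct)) {
    add("choice", "rewarded = TRUE on an incorrect trial",
        sum(trials$rewarded & !trials$correct))
  }
  orphan <- !spikes$trial_id %in% trials$trial_id
  if (any(orphan)) add("spikes", "spike rows with unknown trial_id",
                       sum(orphan))
  if (any(spikes$spike_time_s < 0, na.rm = TRUE)) {
    add("spikes", "negative spike times", sum(spikes$spike_time_s < 0))
  }
  orphan_cells <- !spikes$cell_id %in% cells$cell_id
  if (any(orphan_cells)) {
    add("spikes", "spike rows with unknown cell_id", sum(orphan_cells))
  }
  if (!all(cells$session_id %in% trials$session_id)) {
    add("cells", "cell session_id not present in trials",
        sum(!cells$session_id %in% trials$session_id))
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(check = character(), detail = character(),
                   n_rows = integer())
  }
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: schema validation, problem exclusion, behavioural
#' summaries, cross-validated explore/exploit cell selection and validation,
#' one-shot and expectancy analyses, temporal cross-generalization, and the
#' population discriminant with permutation inference. Stage-level counts of
#' trials and cells after every filter are collected in the manifest. With an
#' `output_dir`, tidy CSV/JSON result files and a manifest are written.
#' Identical configuration and input give identical numeric output.
#'
#' @param config a [pipeline_config()].
#' @param trials,spikes,cells in-memory dataset tables (used when
#'   `config$input_dir` is `NULL`).
#' @return a report list keyed by stage (`behavior`, `selection`,
#'   `validation`, `psth`, `one_shot`, `failed_learning`, `expectancy`,
#'   `crossgen`, `discriminant`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         spikes = NULL, cells = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_dir)) {
    ds <- read_dataset(config$input_dir)
    trials <- ds$trials; spikes <- ds$spikes; cells <- ds$cells
  }
  stopifnot(!is.null(trials), !is.null(spikes), !is.null(cells))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(stage = stage, ...)
  }

  val <- validate_dataset(trials, spikes, cells)
  if (!val$ok) {
    stop("validate: dataset failed schema validation (",
         nrow(val$issues), " issue(s)); see validate_dataset()",
         call. = FALSE)
  }
  note("validate", n_trials = nrow(trials), n_cells = nrow(cells))

  cells <- cells[cells$region == config$region, ]
  if (nrow(cells) == 0L) {
    stop("region filter: no cells with region '", config$region, "'",
         call. = FALSE)
  }
  note("region_filter", region = config$region, n_cells = nrow(cells))

  excl <- apply_problem_exclusion(trials, config$max_failures_per_cycle)
  trials <- add_response_types(excl$trials)
  spikes <- spikes[spikes$trial_id %in% trials$trial_id, ]
  note("exclusion", n_excluded_problems = nrow(excl$log),
       n_trials = nrow(trials))

  windows <- list(CH = window_spec("CH", 0, config$window_width),
                  FB = window_spec("FB", 0, config$window_width))

  behavior <- list(cycles = summarize_cycles(trials),
                   revisits = revisit_vs_chance(trials),
                   exclusion_log = excl$log)
  behavior$nontarget_decline <- tryCatch(
    nontarget_decline_test(trials), error = function(e) e$message)
  note("behavior", n_problems = length(unique(trials$problem_id)))

  split_sel <- split_trials(trials, cells, config$seed_split_selection)
  selection <- run_selection(trials, spikes, cells, split_sel,
                             alpha = config$alpha, windows = windows)
  validation <- validate_selection(selection, trials, spikes, cells,
                                   split_sel, windows = windows)
  selection <- validation$cells
  norms <- cell_norm_constants(trials, spikes, cells, split_sel,
                               windows = windows)
  note("selection",
       n_labelled_ch = sum(selection$label != "none" &
                             selection$phase == "CH"),
       n_labelled_fb = sum(selection$label != "none" &
                             selection$phase == "FB"),
       n_norm_usable = sum(norms$usable))

  labelled <- selection[selection$label != "none", ]
  val_half <- split_sel[split_sel$half == "validation", ]
  psth <- list()
  for (ph in c("CH", "FB")) {
    for (lab in c("explore", "exploit")) {
      ids <- labelled$cell_id[labelled$phase == ph & labelled$label == lab]
      if (length(ids) == 0L) next
      for (cy in c(1L, 4L)) {
        sub <- dplyr::semi_join(
          dplyr::filter(trials, .data$cycle == cy, .data$correct),
          val_half[val_half$cell_id %in% ids, ], by = "trial_id")
        p <- build_psth(sub, spikes, cells[cells$cell_id %in% ids, ],
                        ph, norms)
        psth[[paste(ph, lab, paste0("C", cy), sep = "_")]] <- group_psth(p)
      }
    }
  }

  one_shot <- one_shot_cycle_analysis(selection, trials, spikes, cells,
                                      split_sel, norms, windows)
  failed <- failed_learning_analysis(selection, trials, spikes, cells,
                                     split_sel, norms, windows)
  expectancy <- list(
    favored = favored_location(trials),
    sampling_order = sampling_order_analysis(selection, trials, spikes,
                                             cells, split_sel, norms,
                                             windows),
    correct_error = correct_error_analysis(selection, trials, spikes, cells,
                                           split_sel, norms, windows),
    discovery_type = discovery_type_analysis(selection, trials, spikes,
                                             cells, split_sel, norms,
                                             windows),
    outcome_coding = outcome_coding_anova(trials, spikes, cells,
                                          window = windows$FB,
                                          alpha = config$alpha,
                                          selection = selection))
  note("single_cell", n_groups = nrow(one_shot$tests))

  split_cg <- split_trials(trials, cells, config$seed_split_crossgen,
                           halves = c("A", "B"))
  crossgen <- cross_generalization_matrix(trials, spikes, cells, split_cg)
  note("crossgen", phase_contrast = crossgen_phase_contrast(crossgen))

  split_disc <- split_trials(trials, cells, config$seed_split_discriminant,
                             halves = c("train", "test"))
  discriminant <- lapply(windows, function(w) {
    discriminant_analysis(trials, spikes, cells, split_disc, w,
                          n_permutations = config$n_permutations,
                          seed = config$seed_permutation)
  })
  note("discriminant", n_permutations = config$n_permutations)

  manifest <- list(
    config = unclass(config),
    stages = lapply(log, as.list),
    n_trials = nrow(trials), n_cells = nrow(cells),
    package_version = as.character(utils::packageVersion("explorexploit")))
  report <- list(behavior = behavior, selection = selection,
                 validation = validation$groups, psth = psth,
                 one_shot = one_shot, failed_learning = failed,
                 expectancy = expectancy, crossgen = crossgen,
                 discriminant = discriminant, manifest = manifest)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Tidy CSVs for the behavioural tables, selection results and PSTHs, an 8x8
#' cross-generalization matrix CSV, a JSON of projections and permutation p
#' values, and a JSON manifest (configuration, seeds, stage log, versions).
#'
#' @param report output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$behavior$cycles,
                   file.path(dir, "behavior_cycles.csv"))
  readr::write_csv(report$behavior$revisits,
                   file.path(dir, "behavior_revisits.csv"))
  sel <- report$selection
  sel$anova <- NULL
  readr::write_csv(sel, file.path(dir, "selection_results.csv"))
  if (length(report$psth)) {
    psth_df <- dplyr::bind_rows(report$psth, .id = "group")
    readr::write_csv(psth_df, file.path(dir, "psth_groups.csv"))
  }
  cg <- as.data.frame(report$crossgen)
  cg <- cbind(window_half_a = rownames(cg), cg)
  readr::write_csv(cg, file.path(dir, "crossgen_matrix.csv"))
  fig_results <- list(
    fig3 = list(validation = report$validation),
    fig4 = list(matrix = report$crossgen,
                phase_contrast = crossgen_phase_contrast(report$crossgen)),
    fig5 = list(one_shot = report$one_shot$tests,
                failed_learning = report$failed_learning$tests),
    fig6 = lapply(report$discriminant, function(d) {
      list(projections = as.list(d$projections),
           permutation = d$permutation, coverage = as.list(d$coverage),
           n_permutations = d$n_permutations, seed = d$seed)
    }),
    fig7 = list(sampling_order = report$expectancy$sampling_order$tests,
                correct_error = report$expectancy$correct_error$tests,
                discovery_type = report$expectancy$discovery_type$tests,
                outcome_counts = report$expectancy$outcome_coding$counts,
                outcome_overlap = report$expectancy$outcome_coding$overlap))
  jsonlite::write_json(fig_results, file.path(dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
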