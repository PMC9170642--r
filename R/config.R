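#' Battery configuration
#'
#' Aggregates the per-task configurations and the cohort design into one
#' object whose defaults equal the published task parameters. This is the
#' in-memory form of the JSON config files consumed by [load_config()]
#' and the CLI.
#'
#' @param moa a [moa_config()].
#' @param mot a [mot_config()].
#' @param dsst a list with `form_length`, `duration`, `rate`,
#'   `error_prob` for the DSST simulation.
#' @param cohort a [cohort_spec()].
#' @param master_seed integer battery seed, propagated into the task
#'   configs when they are built from a file.
#' @return an object of class `battery_config`.
#' @export
battery_config <- function(moa = moa_config(),
                           mot = mot_config(),
                           dsst = list(form_length = 93L, duration = 60,
                                       rate = 0.8, error_prob = 0.02),
                           cohort = cohort_spec(),
                           master_seed = 1L) {
  stopifnot(inherits(moa, "moa_config"), inherits(mot, "mot_config"),
            inherits(cohort, "cohort_spec"))
  if (!(dsst$rate > 0) || dsst$error_prob < 0 || dsst$error_prob > 1 ||
      !(dsst$duration > 0) || !(dsst$form_length >= 1)) {
    stop("invalid dsst settings")
  }
  structure(list(moa = moa, mot = mot, dsst = dsst, cohort = cohort,
                 master_seed = as.integer(master_seed)),
            class = "battery_config")
}

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  strip(cfg)
}

#' Hash a configuration
#'
#' 32-bit FNV-1a hash over the canonical JSON serialization of a config
#' object; reproducibly identifies the full configuration in session-log
#' headers.
#'
#' @param cfg any config object ([battery_config()], [moa_config()], ...).
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(config_to_list(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

apply_section <- function(defaults, given, path, builder = NULL) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ",
         paste(paste0(path, ".", unknown), collapse = ", "))
  }
  modifyList(defaults, given)
}

#' Load a battery configuration from JSON
#'
#' Reads a JSON file whose top-level sections are `master_seed`, `moa`,
#' `mot`, `dsst`, `cohort` (all optional; absent fields take the
#' published defaults). Window sizes are given as two-element arrays.
#' Unknown keys are rejected with their field path; invariant violations
#' (negative intervals etc.) are reported naming the offending field.
#'
#' @param path path to a JSON config file; an empty object (`{}`) yields
#'   the full default configuration.
#' @return a [battery_config()].
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  top_known <- c("master_seed", "moa", "mot", "dsst", "cohort")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  master_seed <- as.integer(raw$master_seed %||% 1L)

  moa_def <- config_to_list(moa_config(master_seed = master_seed))
  moa_lst <- apply_section(moa_def, raw$moa %||% list(), "moa")
  moa <- tryCatch(
    moa_config(window = playfield(moa_lst$window$width, moa_lst$window$height),
               disc_diameter = moa_lst$disc_diameter,
               n_initial_hazards = moa_lst$n_initial_hazards,
               spawn_interval = moa_lst$spawn_interval,
               grace_duration = moa_lst$grace_duration,
               speed_min = moa_lst$speed_min, speed_max = moa_lst$speed_max,
               tick = moa_lst$tick,
               n_practice_trials = moa_lst$n_practice_trials,
               n_recorded_trials = moa_lst$n_recorded_trials,
               max_trial_duration = moa_lst$max_trial_duration,
               master_seed = moa_lst$master_seed),
    error = function(e) stop("moa: ", conditionMessage(e), call. = FALSE))

  mot_def <- config_to_list(mot_config(master_seed = master_seed))
  mot_lst <- apply_section(mot_def, raw$mot %||% list(), "mot")
  mot <- tryCatch(
    mot_config(window = playfield(mot_lst$window$width, mot_lst$window$height),
               square_side = mot_lst$square_side,
               n_squares = mot_lst$n_squares, n_targets = mot_lst$n_targets,
               direction_set = mot_lst$direction_set,
               speed_set = mot_lst$speed_set,
               flash_duration = mot_lst$flash_duration,
               move_duration = mot_lst$move_duration,
               n_trials = mot_lst$n_trials, tick = mot_lst$tick,
               master_seed = mot_lst$master_seed),
    error = function(e) stop("mot: ", conditionMessage(e), call. = FALSE))

  dsst_def <- list(form_length = 93L, duration = 60, rate = 0.8,
                   error_prob = 0.02)
  dsst <- apply_section(dsst_def, raw$dsst %||% list(), "dsst")

  coh_def <- config_to_list(cohort_spec(master_seed = master_seed))
  coh_lst <- apply_section(coh_def, raw$cohort %||% list(), "cohort")
  build_group <- function(lst, path) {
    lst <- apply_section(config_to_list(cohort_spec()$group_a), lst, path)
    do.call(group_params, lst)
  }
  cohort <- cohort_spec(
    group_a = build_group(coh_lst$group_a, "cohort.group_a"),
    group_b = build_group(coh_lst$group_b, "cohort.group_b"),
    group_effect = coh_lst$group_effect,
    master_seed = coh_lst$master_seed)

  battery_config(moa = moa, mot = mot, dsst = dsst, cohort = cohort,
                 master_seed = master_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
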