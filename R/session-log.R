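#' Build a session log
#'
#' Pairs the per-trial rows of a completed session with a reproducibility
#' header (schema version, task id, config hash, master seed, timestamp).
#' The timestamp defaults to a fixed epoch placeholder so that identical
#' sessions serialize to byte-identical files; pass `Sys.time()` output
#' explicitly if wall-clock provenance matters more than reproducibility.
#'
#' @param task task id: `"MOA"`, `"MOT"`, `"DSST"` or `"COHORT"`.
#' @param config the config object the session ran with.
#' @param master_seed integer master seed of the session.
#' @param rows data.frame of per-trial (or per-participant) rows.
#' @param session_id identifier string; defaults to `task-master_seed`.
#' @param timestamp ISO-8601 string recorded in the header.
#' @return an object of class `session_log`.
#' @export
session_log <- function(task, config, master_seed, rows,
                        session_id = paste0(task, "-", master_seed),
                        timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(task %in% c("MOA", "MOT", "DSST", "COHORT"), is.data.frame(rows))
  structure(list(schema_version = 1L, task = task,
                 session_id = session_id,
                 config_hash = config_hash(config),
                 master_seed = as.integer(master_seed),
                 timestamp = timestamp, rows = rows),
            class = "session_log")
}

#' Write a session log to CSV
#'
#' Comma-separated UTF-8 with '.' decimals; the header block is written
#' as '#'-prefixed comment lines before the column header. Output is
#' byte-stable for identical inputs.
#'
#' @param log a [session_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    paste0("# schema_version: ", log$schema_version),
    paste0("# task: ", log$task),
    paste0("# session_id: ", log$session_id),
    paste0("# config_hash: ", log$config_hash),
    paste0("# master_seed: ", log$master_seed),
    paste0("# timestamp: ", log$timestamp))
  writeLines(hdr, con)
  rows <- log$rows
  for (nm in names(rows)) {
    if (is.logical(rows[[nm]])) rows[[nm]] <- as.integer(rows[[nm]])
    if (is.numeric(rows[[nm]]) && !is.integer(rows[[nm]])) {
      rows[[nm]] <- formatC(rows[[nm]], digits = 15, format = "g")
    }
  }
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session log written by [write_session()]
#'
#' @param path CSV path.
#' @return a list with `header` (named character) and `rows` (data.frame).
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- sub("^# ", "", lines[is_hdr])
  header <- setNames(sub("^[^:]+: ?", "", kv), sub(":.*$", "", kv))
  rows <- read.csv(text = paste(lines[!is_hdr], collapse = "\n"))
  list(header = header, rows = rows)
}

#' Session log rows for an MOA session
#' @param session an `moa_session`.
#' @param session_id identifier string.
#' @return data.frame in the MOA log schema.
#' @export
moa_log_rows <- function(session, session_id) {
  r <- session$records
  data.frame(session_id = session_id, task = "MOA",
             trial_index = r$trial_index, practice = as.integer(r$practice),
             seed = r$seed, survival_time_s = r$survival_time,
             censored = as.integer(r$censored))
}

#' Session log rows for an MOT session
#' @param session a `mot_session`.
#' @param session_id identifier string.
#' @return data.frame in the MOT log schema.
#' @export
mot_log_rows <- function(session, session_id) {
  t <- session$trials
  data.frame(session_id = session_id, task = "MOT",
             trial_index = t$trial_index, seed = t$seed,
             n_correct = t$n_correct, accuracy = t$accuracy)
}
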