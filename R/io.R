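trial_table_header <- c("time_s", "x_target_m", "x_hand_m", "x_cursor_m",
                        "grip_force_n")

#' Write a trial as a plain-text columnar table
#'
#' Columns `time_s x_target_m x_hand_m x_cursor_m grip_force_n`
#' (tab-separated, header line, `NA` grip force when absent). Condition and
#' schedule metadata are stored in `#key=value` comment lines so the file
#' round-trips through [read_trial_table()].
#'
#' @param trial a `trial_record`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trial_table <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$schedule
  meta <- c(sprintf("#condition=%s", trial$condition),
            sprintf("#schedule=%g,%g,%g,%g,%g,%g", s$aligned_head, s$ramp_up,
                    s$plateau, s$ramp_down, s$aligned_tail, s$plateau_value))
  df <- data.frame(time_s = trial$t, x_target_m = trial$x_target,
                   x_hand_m = trial$x_hand, x_cursor_m = trial$x_cursor,
                   grip_force_n = if (is.null(trial$grip_force)) NA
                                  else trial$grip_force)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table
#'
#' Validates the header, the monotone uniform time base (naming the first
#' offending row otherwise), and reconstructs the `trial_record` with its
#' condition and schedule metadata.
#'
#' @param path file written by [write_trial_table()] (or any table with the
#'   same header).
#' @return a `trial_record`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 20L)
  meta <- grep("^#", lines, value = TRUE)
  condition <- "N"
  schedule <- delay_schedule()
  m <- sub("^#condition=", "", grep("^#condition=", meta, value = TRUE))
  if (length(m) == 1L) condition <- m
  m <- sub("^#schedule=", "", grep("^#schedule=", meta, value = TRUE))
  if (length(m) == 1L) {
    v <- as.numeric(strsplit(m, ",")[[1]])
    if (length(v) == 6L && !any(is.na(v))) {
      schedule <- delay_schedule(v[1], v[2], v[3], v[4], v[5], v[6])
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  if (!identical(names(df), trial_table_header)) {
    stop("malformed header: expected ",
         paste(trial_table_header, collapse = ", "))
  }
  tt <- df$time_s
  dts <- diff(tt)
  if (any(dts <= 0)) {
    stop("time column not monotone at row ", which(dts <= 0)[1] + 1L)
  }
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1])) {
    stop("non-uniform sampling at row ",
         which(abs(dts - dts[1]) > 1e-6 * dts[1])[1] + 1L)
  }
  gf <- if (all(is.na(df$grip_force_n))) NULL else df$grip_force_n
  trial_record(tt, df$x_target_m, df$x_hand_m, df$x_cursor_m,
               grip_force = gf, condition = condition, schedule = schedule)
}

#' Write an experiment as one trial table per trial
#'
#' @param trials list of `trial_record`s (or a `synthetic_experiment`).
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths.
#' @export
write_experiment <- function(trials, dir) {
  if (inherits(trials, "synthetic_experiment")) trials <- trials$trials
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(trials), function(k) {
    p <- file.path(dir, sprintf("trial_%02d.tsv", k))
    write_trial_table(trials[[k]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read all trial tables from a directory
#'
#' @param dir directory of `trial_*.tsv` files.
#' @return list of `trial_record`s in file order.
#' @export
read_experiment <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^trial_.*\\.tsv$",
                           full.names = TRUE))
  if (!length(paths)) stop("no trial tables found in ", dir)
  lapply(paths, read_trial_table)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `motion` (amplitude, omega), `schedule`
#' (the five durations and plateau value), `protocol` (group or explicit
#' conditions, catch positions), `analysis` (mass, K, segments, max_lag) and
#' `subject` (any `subject_params` field). Missing fields fall back to the
#' package defaults, every one of which traces to an experiment value or a
#' documented design choice. Unknown fields are an error.
#'
#' @param path YAML file path.
#' @return a validated list of configuration objects: `motion`, `schedule`,
#'   `protocol`, `analysis`, `subject`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("motion", "schedule", "protocol", "analysis", "subject", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config sections: ",
                          paste(extra, collapse = ", "))
  motion <- do.call(target_motion, as.list(cfg$motion))
  schedule <- do.call(delay_schedule, as.list(cfg$schedule))
  prot_args <- as.list(cfg$protocol)
  protocol <- if (length(prot_args)) do.call(protocol_spec, prot_args)
              else protocol_spec(group = 1)
  analysis <- utils::modifyList(
    list(mass = 0.1, K = 27, segments = 4:19, max_lag = 0.9,
         gf_max_lag = 0.4),
    as.list(cfg$analysis))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  subj_args <- as.list(cfg$subject)
  subj_args$seed <- seed
  subject <- do.call(subject_params, subj_args)
  list(motion = motion, schedule = schedule, protocol = protocol,
       analysis = analysis, subject = subject, seed = seed)
}
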