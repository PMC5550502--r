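#' Full kinematic and grip analysis of one trial
#'
#' @param trial a `trial_record`.
#' @param mass handle mass (kg); `K` virtual spring constant (N/m).
#' @param max_lag kinematic cross-correlation half-window (s).
#' @param gf_max_lag grip-force cross-correlation half-window (s).
#' @return list with `rmse`, `lags` (a `segment_lags`), `after_effect`,
#'   `amplitude`, and `grip` (a `grip_metrics` or NULL without grip force).
#' @export
analyze_trial <- function(trial, mass = 0.1, K = 27, max_lag = 0.9,
                          gf_max_lag = 0.4) {
  stopifnot(inherits(trial, "trial_record"))
  lags <- trial_lag_profile(trial, "cursor_vs_target", max_lag = max_lag)
  list(rmse = plateau_rmse(trial),
       lags = lags,
       after_effect = if (length(lags$lags) == 22L) after_effect(lags)
                      else NA_real_,
       amplitude = movement_amplitude(trial_signal(trial, "x_hand")),
       grip = if (!is.null(trial$grip_force)) {
         grip_metrics(trial, mass = mass, K = K, max_lag = gf_max_lag)
       } else NULL)
}

#' Analyze a list of trials into summary tables
#'
#' @param trials list of `trial_record`s (or a `synthetic_experiment`).
#' @inheritParams analyze_trial
#' @return list of data.frames: `trials` (one row per trial: rmse,
#'   after-effect, amplitude, grip metrics) and `lags` (one row per trial x
#'   segment).
#' @export
analyze_experiment <- function(trials, mass = 0.1, K = 27, max_lag = 0.9,
                               gf_max_lag = 0.4) {
  if (inherits(trials, "synthetic_experiment")) trials <- trials$trials
  res <- lapply(trials, analyze_trial, mass = mass, K = K,
                max_lag = max_lag, gf_max_lag = gf_max_lag)
  per_trial <- do.call(rbind, lapply(seq_along(res), function(k) {
    r <- res[[k]]
    data.frame(trial = k, condition = trials[[k]]$condition,
               rmse = r$rmse, after_effect = r$after_effect,
               amplitude = r$amplitude,
               gf_phase_s = if (is.null(r$grip)) NA else r$grip$phase_s,
               gf_ratio = if (is.null(r$grip)) NA else r$grip$ratio,
               gf_corrected_phase_s = if (is.null(r$grip)) NA
                                      else r$grip$corrected_phase_s,
               gf_corrected_ratio = if (is.null(r$grip)) NA
                                    else r$grip$corrected_ratio)
  }))
  lag_tab <- do.call(rbind, lapply(seq_along(res), function(k) {
    l <- res[[k]]$lags
    data.frame(trial = k, segment = seq_along(l$lags), lag_s = l$lags)
  }))
  list(trials = per_trial, lags = lag_tab)
}

write_summary_tables <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(analysis$trials, file.path(dir, "trial_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(analysis$lags, file.path(dir, "segment_lags.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

run_log <- function(dir, cfg_path, seed) {
  lines <- c(sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("config: %s", cfg_path),
             sprintf("config_sha: %s",
                     if (file.exists(cfg_path)) {
                       paste(tools::md5sum(cfg_path), collapse = "")
                     } else "none"),
             sprintf("seed: %d", seed),
             sprintf("mechdelay_version: %s",
                     as.character(utils::packageVersion("mechdelay"))),
             sprintf("r_version: %s", R.version.string))
  writeLines(lines, file.path(dir, "run_log.txt"))
  invisible(NULL)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands used by the `inst/cli/mechdelay.R`
#' script: `simulate` (internal-model protocol simulation), `generate`
#' (synthetic experiment), `analyze` (kinematic and grip metrics over a
#' directory of trial tables), `fit-schedule`, `bode` (frequency-response
#' export) and `reproduce` (recompute the headline operator phases and
#' check them).
#'
#' @param args character vector, `c(command, --config path, --out dir, ...)`.
#' @return integer exit status (0 = success), invisibly.
#' @export
mechdelay_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mechdelay <simulate|generate|analyze|fit-schedule|bode|reproduce>",
    "[--config cfg.yaml] [--in dir] [--out dir] [--rep kind] [--tau x]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, `in` = NULL, out = "mechdelay_out",
               rep = "mechanical", tau = 0.25)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("bad option: ", args[i], "\n", usage); return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config) else {
    list(motion = target_motion(), schedule = delay_schedule(),
         protocol = protocol_spec(group = 1),
         analysis = list(mass = 0.1, K = 27, segments = 4:19, max_lag = 0.9,
                         gf_max_lag = 0.4),
         subject = subject_params(), seed = 1L)
  }
  out <- opts$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  status <- 0L
  if (cmd == "simulate") {
    kind <- match.arg(opts$rep, c("mechanical", "delayed_state"))
    sim <- run_protocol(cfg$protocol, kind, cfg$subject$adaptation,
                        fixed_params = list(B_est = cfg$subject$B_est,
                                            M_est = cfg$subject$M_est),
                        motion = cfg$motion, delay_sched = cfg$schedule)
    utils::write.table(sim$summary, file.path(out, "simulated_rmse.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (cmd == "generate") {
    exp <- generate_experiment(cfg$subject, cfg$protocol, cfg$motion,
                               cfg$schedule)
    write_experiment(exp, out)
    utils::write.table(exp$summary, file.path(out, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (cmd == "analyze") {
    if (is.null(opts$`in`)) { message("analyze needs --in"); return(invisible(1L)) }
    trials <- read_experiment(opts$`in`)
    a <- analyze_experiment(trials, mass = cfg$analysis$mass,
                            K = cfg$analysis$K,
                            max_lag = cfg$analysis$max_lag,
                            gf_max_lag = cfg$analysis$gf_max_lag)
    write_summary_tables(a, out)
  } else if (cmd == "fit-schedule") {
    if (is.null(opts$`in`)) { message("fit-schedule needs --in (trial_summary.tsv)"); return(invisible(1L)) }
    tab <- utils::read.table(opts$`in`, header = TRUE, sep = "\t")
    kind <- match.arg(opts$rep, c("mechanical", "delayed_state"))
    fit <- fit_schedule(tab$rmse, cfg$protocol, kind, cfg$motion,
                        cfg$schedule, seed = cfg$seed)
    out_tab <- data.frame(trial = seq_along(fit$predicted),
                          predicted_rmse = fit$predicted)
    utils::write.table(out_tab, file.path(out, "fitted_rmse.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(utils::capture.output(print(fit)),
               file.path(out, "fit_params.txt"))
  } else if (cmd == "bode") {
    tau <- as.numeric(opts$tau)
    grid <- 2 * pi * exp(seq(log(0.05), log(5), length.out = 200))
    grid <- sort(unique(c(grid, cfg$motion$omega)))
    write_freq_response(bode_data(tau, grid), out)
  } else if (cmd == "reproduce") {
    tau <- as.numeric(opts$tau)
    w <- cfg$motion$omega
    checks <- reproduce_checks(tau, w, cfg$motion, cfg$schedule)
    utils::write.table(checks, file.path(out, "reproduce.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    print(checks)
    if (!all(checks$pass)) status <- 1L
  } else {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  run_log(out, if (is.null(opts$config)) "defaults" else opts$config,
          cfg$seed)
  invisible(status)
}

reproduce_checks <- function(tau, w, motion, schedule) {
  mech <- mechanical_transfer(tau, w)
  del <- delay_transfer(tau, w)
  # measured lag on a simulated plateau
  t <- trial_time_grid(schedule)
  hand <- sampled_signal(target_position(motion, t), dt = t[2] - t[1], t0 = 0)
  cursor_d <- condition_cursor(hand, "D", schedule)
  win <- plateau_window(schedule)
  idx <- t >= win[1] & t < win[2]
  lag_d <- xcorr_lag(sampled_signal(hand$values[idx], hand$dt),
                     sampled_signal(cursor_d$values[idx], hand$dt), 0.9)
  cursor_m <- condition_cursor(hand, "M", schedule)
  lag_m <- xcorr_lag(sampled_signal(hand$values[idx], hand$dt),
                     sampled_signal(cursor_m$values[idx], hand$dt), 0.9)
  data.frame(
    quantity = c("delay_phase_sec_analytic", "delay_lag_sec_simulated",
                 "mechanical_phase_sec_analytic",
                 "mechanical_lag_sec_simulated"),
    value = c(del$phase_sec, lag_d, mech$phase_sec, lag_m),
    expected = c(tau, tau, 0.27, 0.27),
    tol = c(1e-9, 1e-9, 0.005, 0.005),
    pass = c(abs(del$phase_sec - tau) < 1e-9,
             abs(lag_d - tau) < 1e-9,
             abs(round(mech$phase_sec, 2) - 0.27) < 1e-9,
             abs(lag_m - 0.27) <= 0.005))
}
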