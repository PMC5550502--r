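#' Group protocol specification
#'
#' Each experiment is 19 trials: 3 Normal familiarization trials followed by
#' 16 manipulation trials. Groups 1 and 2 train on one condition (Delay and
#' Mechanical respectively) with sporadic catch trials of the other; groups 3
#' and 4 run two contiguous 8-trial blocks (trials 4-11 and 12-19) in the two
#' orders.
#'
#' Catch-trial positions for groups 1-2 default to manipulation trials 7, 11
#' and 15 (evenly spaced sporadic catches); they are configurable.
#'
#' @param group group id, 1-4, or `NULL` when `conditions` is given.
#' @param conditions optional explicit character vector of 19 condition
#'   labels in `c("N","D","M")`, overriding the group defaults.
#' @param catch_positions manipulation-trial indices (1-16) of the catch
#'   trials for groups 1-2.
#' @return an object of class `protocol_spec` with fields `group`,
#'   `conditions` (length 19), `dominant`, `catch_trials` (protocol trial
#'   indices), `manip_index` (NA for familiarization, 1..16 otherwise).
#' @export
protocol_spec <- function(group = NULL, conditions = NULL,
                          catch_positions = c(7, 11, 15)) {
  if (is.null(conditions)) {
    if (is.null(group) || !group %in% 1:4) {
      stop("group must be 1, 2, 3 or 4 (or give explicit conditions)")
    }
    manip <- switch(as.character(group),
      "1" = { x <- rep("D", 16); x[catch_positions] <- "M"; x },
      "2" = { x <- rep("M", 16); x[catch_positions] <- "D"; x },
      "3" = c(rep("D", 8), rep("M", 8)),
      "4" = c(rep("M", 8), rep("D", 8)))
    conditions <- c(rep("N", 3), manip)
  } else {
    if (length(conditions) != 19L || !all(conditions %in% c("N", "D", "M"))) {
      stop("conditions must be 19 labels in N/D/M")
    }
    if (!all(conditions[1:3] == "N")) {
      stop("trials 1-3 must be Normal familiarization trials")
    }
  }
  manip_cond <- conditions[4:19]
  dominant <- names(which.max(table(factor(manip_cond, c("D", "M")))))
  catch <- which(conditions != "N" & conditions != dominant)
  manip_index <- c(rep(NA_integer_, 3L), seq_len(16L))
  structure(list(group = group, conditions = conditions, dominant = dominant,
                 catch_trials = catch, manip_index = manip_index),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> group %s: %s\n",
              if (is.null(x$group)) "custom" else x$group,
              paste(x$conditions, collapse = " ")))
  cat(sprintf("  dominant %s, catch trials: %s\n", x$dominant,
              if (length(x$catch_trials)) paste(x$catch_trials, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Dominant-condition manipulation trials of a protocol
#'
#' Protocol trial indices (1-19) of the manipulation trials in the dominant
#' condition, i.e. excluding familiarization and catch trials. These are the
#' trials entering schedule fits.
#'
#' @param protocol a `protocol_spec`.
#' @return integer vector of trial indices.
#' @export
dominant_trials <- function(protocol) {
  which(protocol$conditions == protocol$dominant)
}
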