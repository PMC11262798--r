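# Experimental-design state machine: block-wise trial-type assignment,
# coherence-contingent triggering, yoked delay replay, timeout
# substitution, and session inclusion screens.

#' Behavioral protocol specification
#'
#' Delayed alternation (DA): 10-trial blocks with 1 high-coherence, 1
#' low-coherence, 1 yoked-high, 1 yoked-low and 6 random-delay trials
#' (20% experimental / 20% yoked / 60% random), random delays uniform on
#' 5--30 s, detector timeout 30 s. Conditional discrimination (CD):
#' 10-trial blocks with 4 high, 4 yoked-high and 2 random trials
#' (40/40/20), detector timeout 20 s, and a minimum delay-zone wait drawn
#' uniformly from 3.5--5 s applied to every trial.
#'
#' @param name `"delayed_alternation"` or `"conditional_discrimination"`.
#' @return An object of class `protocol_spec` with fields name,
#'   block_size, composition (named counts), random_delay_range, timeout,
#'   cd_min_wait.
#' @export
protocol_spec <- function(name = c("delayed_alternation",
                                   "conditional_discrimination")) {
  name <- match.arg(name)
  if (name == "delayed_alternation") {
    comp <- c(high = 1L, low = 1L, yoked_high = 1L, yoked_low = 1L,
              random = 6L)
    out <- list(name = name, block_size = 10L, composition = comp,
                random_delay_range = c(5, 30), timeout = 30,
                cd_min_wait = NULL)
  } else {
    comp <- c(high = 4L, yoked_high = 4L, random = 2L)
    out <- list(name = name, block_size = 10L, composition = comp,
                random_delay_range = c(5, 30), timeout = 20,
                cd_min_wait = c(3.5, 5))
  }
  stopifnot(sum(out$composition) == out$block_size)
  structure(out, class = "protocol_spec")
}

# Pair the j-th yoked trial of each flavor with the j-th experimental
# trial of the matching flavor, by position in the block.
yoked_partner_type <- c(yoked_high = "high", yoked_low = "low")

block_admissible <- function(types) {
  for (yk in intersect(names(yoked_partner_type), types)) {
    ex <- yoked_partner_type[[yk]]
    pos_y <- which(types == yk)
    pos_e <- which(types == ex)
    if (length(pos_y) > length(pos_e)) return(FALSE)
    if (any(pos_y <= pos_e[seq_along(pos_y)])) return(FALSE)
  }
  TRUE
}

#' Plan one pseudo-random trial block
#'
#' Draws a uniformly random permutation of the block composition,
#' rejecting orderings in which any yoked trial precedes its experimental
#' partner (the j-th yoked trial of a flavor is paired with the j-th
#' experimental trial of that flavor). The accepted ordering is uniform
#' over all admissible orderings. Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param protocol A `protocol_spec`.
#' @return Character vector of trial types, length `block_size`.
#' @export
plan_block <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  pool <- rep(names(protocol$composition), protocol$composition)
  repeat {
    types <- sample(pool)
    if (block_admissible(types)) return(types)
  }
}

#' Run one trial of the protocol state machine
#'
#' High/low entries run the coherence detector (in the matching mode, with
#' the protocol timeout); on a detector timeout the trial is recorded with
#' `trigger_cause = "timeout"` and the block's pending yoked partner is
#' mutated to a random-delay trial (keeping a `was_yoked` provenance
#' flag). Yoked entries replay their partner's delay exactly
#' (`trigger_cause = "clock"`); random entries wait a uniform draw from
#' the protocol's delay range. Under CD, every trial additionally enforces
#' a minimum wait drawn uniformly from `cd_min_wait`, so the realized
#' delay is the maximum of the scheduled delay and that minimum.
#'
#' This is the internal engine behind [run_session()]; the session state
#' is a mutable environment holding pending yoked pairings.
#'
#' @param type Trial type for this entry.
#' @param protocol A `protocol_spec`.
#' @param detector Function `(mode, timeout) -> list(trigger_time, cause)`
#'   (e.g. a closure over [stream_detect()]).
#' @param state Environment created by [run_session()].
#' @return A one-row data.frame (TrialRecord fields).
#' @keywords internal
run_trial <- function(type, protocol, detector, state) {
  cause <- "clock"
  was_yoked <- FALSE
  if (type %in% c("high", "low")) {
    res <- detector(mode = type, timeout = protocol$timeout)
    delay <- res$trigger_time
    cause <- res$cause
    if (cause == "timeout") {
      # mark the pending partner slot for substitution
      state$timeout_pending[[type]] <- c(state$timeout_pending[[type]],
                                         state$index)
    } else {
      state$logged_delays[[type]] <- c(state$logged_delays[[type]], delay)
      state$logged_index[[type]] <- c(state$logged_index[[type]],
                                      state$index)
    }
  } else if (type %in% names(yoked_partner_type)) {
    ex <- yoked_partner_type[[type]]
    if (length(state$timeout_pending[[ex]]) > 0L) {
      # partner timed out: substitute a random delay
      state$timeout_pending[[ex]] <- state$timeout_pending[[ex]][-1L]
      was_yoked <- TRUE
      type <- "random"
      delay <- stats::runif(1, protocol$random_delay_range[1],
                            protocol$random_delay_range[2])
    } else {
      if (length(state$logged_delays[[ex]]) == 0L) {
        stop("yoked entry with no logged partner")
      }
      delay <- state$logged_delays[[ex]][1L]
      paired <- state$logged_index[[ex]][1L]
      state$logged_delays[[ex]] <- state$logged_delays[[ex]][-1L]
      state$logged_index[[ex]] <- state$logged_index[[ex]][-1L]
      state$paired_with <- paired
    }
  } else {
    delay <- stats::runif(1, protocol$random_delay_range[1],
                          protocol$random_delay_range[2])
  }
  if (!is.null(protocol$cd_min_wait)) {
    min_wait <- stats::runif(1, protocol$cd_min_wait[1],
                             protocol$cd_min_wait[2])
    delay <- max(delay, min_wait)
  }
  paired <- if (type %in% names(yoked_partner_type)) state$paired_with
            else NA_integer_
  state$paired_with <- NA_integer_
  data.frame(index = state$index, block = state$block, type = type,
             delay = delay, trigger_cause = cause,
             was_yoked = was_yoked, paired_with = paired,
             stringsAsFactors = FALSE)
}

#' Run a full coherence-contingent session
#'
#' Plans `n_blocks` pseudo-random blocks and runs the trial state machine
#' over them, producing a trial table with realized delays, trigger
#' causes, yoked pairings and (optionally) simulated choice outcomes.
#'
#' @param protocol A `protocol_spec`.
#' @param n_blocks Number of 10-trial blocks.
#' @param detector Function `(mode, timeout) -> list(trigger_time, cause)`
#'   standing in for the real-time coherence detector. The default never
#'   triggers (always times out); supply a closure over [stream_detect()]
#'   or a simulator for meaningful sessions.
#' @param outcome_model Optional named vector of P(correct) per trial
#'   type; when supplied, a `correct` outcome is drawn per trial.
#' @param seed Optional integer seed (uses the current RNG state when
#'   NULL).
#' @return A data.frame of trial records: index, block, type, delay,
#'   trigger_cause, was_yoked, paired_with, outcome, turn.
#' @export
run_session <- function(protocol, n_blocks = 4, detector = NULL,
                        outcome_model = NULL, seed = NULL) {
  run <- function() {
    if (is.null(detector)) {
      detector <- function(mode, timeout) {
        list(trigger_time = timeout, cause = "timeout")
      }
    }
    state <- new.env(parent = emptyenv())
    state$logged_delays <- list(high = numeric(), low = numeric())
    state$logged_index <- list(high = integer(), low = integer())
    state$timeout_pending <- list(high = integer(), low = integer())
    state$paired_with <- NA_integer_
    recs <- vector("list", n_blocks * protocol$block_size)
    i <- 0L
    for (b in seq_len(n_blocks)) {
      types <- plan_block(protocol)
      state$block <- b
      for (type in types) {
        i <- i + 1L
        state$index <- i
        recs[[i]] <- run_trial(type, protocol, detector, state)
      }
      # pending substitutions never cross a block boundary
      state$timeout_pending <- list(high = integer(), low = integer())
      state$logged_delays <- list(high = numeric(), low = numeric())
      state$logged_index <- list(high = integer(), low = integer())
    }
    out <- do.call(rbind, recs)
    out$turn <- sample(c("L", "R"), nrow(out), replace = TRUE)
    if (!is.null(outcome_model)) {
      p <- outcome_model[out$type]
      p[is.na(p)] <- 0.5
      out$outcome <- ifelse(stats::runif(nrow(out)) < p, "correct", "error")
    } else {
      out$outcome <- NA_character_
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Session inclusion screen
#'
#' CD sessions are included iff performance exceeds 70% (strict), the
#' alternation fraction is below 70% (strict), and at least three
#' experimental (high/low) trials contributed. DA sessions are screened on
#' performance at or above 70%.
#'
#' @param records Trial records from [run_session()] with populated
#'   outcomes; alternation uses the `turn` column.
#' @param protocol A `protocol_spec`.
#' @return A list: performance, alternation, n_experimental, include.
#' @export
screen_session <- function(records, protocol) {
  if (nrow(records) == 0L) stop("empty record list")
  ok <- records$outcome %in% c("correct", "error")
  perf <- mean(records$outcome[ok] == "correct")
  turns <- records$turn[ok]
  altern <- if (length(turns) > 1L) {
    mean(turns[-1L] != turns[-length(turns)])
  } else NA_real_
  n_exp <- sum(records$type %in% c("high", "low"))
  include <- if (protocol$name == "conditional_discrimination") {
    perf > 0.70 && !is.na(altern) && altern < 0.70 && n_exp >= 3L
  } else {
    perf >= 0.70
  }
  list(performance = perf, alternation = altern,
       n_experimental = n_exp, include = include)
}

#' Choice accuracy by trial type, with paired difference scores
#'
#' Accuracy per type over non-excluded trials, plus the high-minus-yoked
#' and low-minus-yoked paired differences for the session.
#'
#' @param records Trial records with outcomes in
#'   correct/error/excluded.
#' @return A list with `accuracy` (named vector per type present) and
#'   `paired_diff` (named vector: high_vs_yoked_high, low_vs_yoked_low;
#'   NA when a member type is absent).
#' @export
summarize_choice_accuracy <- function(records) {
  keep <- records$outcome %in% c("correct", "error")
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L) stop("no non-excluded trials")
  acc <- tapply(r$outcome == "correct", r$type, mean)
  acc <- stats::setNames(as.numeric(acc), names(acc))
  pd <- c(high_vs_yoked_high = unname(acc["high"] - acc["yoked_high"]),
          low_vs_yoked_low = unname(acc["low"] - acc["yoked_low"]))
  list(accuracy = acc, paired_diff = pd)
}

#' Write trial records as delimited text
#' @param records Trial record data.frame.
#' @param path File path.
#' @export
write_trials <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
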