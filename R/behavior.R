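# Behavioral quantification: IdPhi head-movement complexity, distance
# traveled, and time-to-choice from event logs.

#' Gaussian-weighted smoothing of a position track
#'
#' Gaussian moving average applied to x and y independently; near the
#' track ends the truncated kernel is renormalized so constants (and, in
#' the interior, linear ramps) pass through unchanged.
#'
#' @param track A `behavior_track`.
#' @param kernel_width Smoothing window length in seconds (default 0.2);
#'   the Gaussian SD is a fifth of the window.
#' @return A smoothed `behavior_track`.
#' @export
smooth_track <- function(track, kernel_width = 0.2) {
  stopifnot(kernel_width > 0)
  dt <- stats::median(diff(track$t))
  if (kernel_width >= diff(range(track$t))) {
    stop("kernel wider than track duration")
  }
  half <- max(1L, as.integer(round(kernel_width / dt / 2)))
  sdk <- max(kernel_width / dt / 5, 0.5)
  kern <- exp(-((-half:half)^2) / (2 * sdk^2))
  n <- length(track$t)
  sm <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      a <- max(1L, i - half); b <- min(n, i + half)
      w <- kern[(a - i + half + 1L):(b - i + half + 1L)]
      out[i] <- sum(w * v[a:b]) / sum(w)
    }
    out
  }
  behavior_track(sm(track$x), sm(track$y), track$t, scale = track$scale)
}

# straight-line fit slope over indices a..b of (t, v); returns slope and
# max abs residual
line_fit <- function(t, v, a, b) {
  tt <- t[a:b]; vv <- v[a:b]
  tm <- mean(tt); vm <- mean(vv)
  den <- sum((tt - tm)^2)
  slope <- if (den > 0) sum((tt - tm) * (vv - vm)) / den else 0
  err <- max(abs(vv - (vm + slope * (tt - tm))))
  c(slope = slope, err = err)
}

#' Discrete time-adaptive windowed velocity
#'
#' Per-point derivative from the largest symmetric window over which a
#' straight-line fit to the positions stays within `tolerance` (the
#' adaptive-windowing criterion), capped at `max_window` samples. Wide
#' windows during stationary dwell keep differentiated noise from being
#' amplified; the window shrinks where the motion genuinely curves.
#'
#' @param track A `behavior_track`.
#' @param tolerance Maximum allowed fit residual, in position units
#'   (default 1).
#' @param min_window,max_window Window extents in samples (total window =
#'   2*half+1 grows from `min_window` to `max_window`).
#' @return A list of class `velocity_estimate`: `dx`, `dy` (units/s),
#'   `window_sizes` (samples per point), `t`.
#' @export
adaptive_velocity <- function(track, tolerance = 1, min_window = 3,
                              max_window = 15) {
  stopifnot(max_window >= min_window, min_window >= 2)
  n <- length(track$t)
  if (n < min_window) stop("track shorter than min_window")
  dx <- dy <- numeric(n)
  wsz <- integer(n)
  half_min <- max(1L, as.integer(floor(min_window / 2)))
  half_max <- max(half_min, as.integer(floor(max_window / 2)))
  for (i in seq_len(n)) {
    best <- NULL
    for (h in half_min:half_max) {
      a <- max(1L, i - h); b <- min(n, i + h)
      if (b - a + 1L < min_window) next
      fx <- line_fit(track$t, track$x, a, b)
      fy <- line_fit(track$t, track$y, a, b)
      if (max(fx["err"], fy["err"]) <= tolerance) {
        best <- list(fx = fx, fy = fy, w = b - a + 1L)
      } else if (!is.null(best)) break
      if (is.null(best) && h == half_min) {
        # even the smallest window violates tolerance: use it anyway
        best <- list(fx = fx, fy = fy, w = b - a + 1L)
        if (max(fx["err"], fy["err"]) > tolerance) break
      }
    }
    dx[i] <- best$fx[["slope"]]
    dy[i] <- best$fy[["slope"]]
    wsz[i] <- best$w
  }
  structure(list(dx = dx, dy = dy, window_sizes = wsz, t = track$t),
            class = "velocity_estimate")
}

#' IdPhi: integrated absolute angular velocity of the heading
#'
#' Phi is the four-quadrant angle of the velocity vector (dX, dY),
#' unwrapped; dPhi is obtained by the same adaptive windowing applied to
#' the unwrapped Phi; IdPhi is the time integral of |dPhi| over the trial
#' (radians). One IdPhi score summarizes the head-movement complexity of
#' one trial: 0 for a straight constant-heading run, about 2*pi for one
#' full smooth loop, large for tortuous paths.
#'
#' @param track A `behavior_track`.
#' @param tolerance,min_window,max_window Passed to
#'   [adaptive_velocity()]; `phi_tolerance` (radians) is used for the
#'   dPhi windowing.
#' @param phi_tolerance Fit tolerance on unwrapped Phi, radians.
#' @return A list of class `idphi_result`: `phi`, `dphi`, `idphi`.
#' @export
idphi <- function(track, tolerance = 1, min_window = 3, max_window = 15,
                  phi_tolerance = 0.1) {
  v <- adaptive_velocity(track, tolerance, min_window, max_window)
  speed <- sqrt(v$dx^2 + v$dy^2)
  if (all(speed < 1e-12)) {
    warning("degenerate all-zero velocity: Phi undefined, IdPhi = 0")
    return(structure(list(phi = rep(NA_real_, length(speed)),
                          dphi = rep(0, length(speed)), idphi = 0),
                     class = "idphi_result"))
  }
  phi <- signal::unwrap(atan2(v$dy, v$dx))
  ptrack <- behavior_track(phi, numeric(length(phi)), track$t)
  pv <- adaptive_velocity(ptrack, phi_tolerance, min_window, max_window)
  dphi <- pv$dx
  id <- pracma::trapz(track$t, abs(dphi))
  structure(list(phi = phi, dphi = dphi, idphi = id),
            class = "idphi_result")
}

#' Distance traveled along a track
#'
#' Sum of successive Euclidean steps, optionally restricted to the final
#' `window` seconds of the track (the pre-trigger interval).
#'
#' @param track A `behavior_track` (>= 2 points in the window).
#' @param window Optional length (s) of the terminal interval to use
#'   (e.g. 1.25 for the pre-door interval); NULL uses the whole track.
#' @return Distance in track units.
#' @export
distance_traveled <- function(track, window = NULL) {
  x <- track$x; y <- track$y; t <- track$t
  if (!is.null(window)) {
    keep <- t >= max(t) - window
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2L) stop("need at least 2 points in the window")
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Session-wise min-max normalization of per-trial distances
#'
#' Maps the session extremes to exactly 0 and 1. If all trials are equal
#' (max = min) the normalization is undefined; all values are reported as
#' 0 with a warning rather than propagating NaN.
#'
#' @param d Numeric vector of per-trial distances.
#' @return Values in [0, 1].
#' @export
normalize_distances <- function(d) {
  rng <- range(d)
  if (diff(rng) == 0) {
    warning("degenerate normalization: all distances equal; returning 0")
    return(rep(0, length(d)))
  }
  (d - rng[1]) / diff(rng)
}

#' Time to choice from the event log
#'
#' Per-trial latency from the central door opening to choice-point exit.
#' Events are paired within trial (by a `trial=` payload when present,
#' otherwise sequentially); trials with a missing exit, or an exit
#' preceding its door opening, are flagged and excluded from the returned
#' latencies.
#'
#' @param events An `event_log`.
#' @param exit_kind Event kind marking the choice exit (default
#'   `"choice_exit"`).
#' @return A list: `latency` (named by trial where known), `flagged`
#'   (data.frame of unmatched or ordering-violating trials).
#' @export
time_to_choice <- function(events, exit_kind = "choice_exit") {
  doors <- events[events$kind == "door_open", , drop = FALSE]
  exits <- events[events$kind == exit_kind, , drop = FALSE]
  trial_of <- function(p) {
    m <- regmatches(p, regexpr("trial=([0-9]+)", p))
    ifelse(nchar(m) > 0, sub("trial=", "", m), NA)
  }
  dt <- trial_of(doors$payload); et <- trial_of(exits$payload)
  lat <- numeric(0); flagged <- list()
  if (all(!is.na(dt)) && all(!is.na(et))) {
    for (i in seq_len(nrow(doors))) {
      j <- match(dt[i], et)
      if (is.na(j)) {
        flagged[[length(flagged) + 1L]] <-
          data.frame(trial = dt[i], reason = "missing exit")
      } else if (exits$time[j] < doors$time[i]) {
        flagged[[length(flagged) + 1L]] <-
          data.frame(trial = dt[i], reason = "exit before door")
      } else {
        lat[dt[i]] <- exits$time[j] - doors$time[i]
      }
    }
  } else {
    # sequential pairing: each door matches the next exit before the next
    # door
    k <- 1L
    for (i in seq_len(nrow(doors))) {
      nxt_door <- if (i < nrow(doors)) doors$time[i + 1L] else Inf
      j <- which(exits$time >= doors$time[i] & exits$time < nxt_door)
      if (length(j) == 0L) {
        flagged[[length(flagged) + 1L]] <-
          data.frame(trial = as.character(i), reason = "missing exit")
      } else {
        lat[as.character(k)] <- exits$time[j[1L]] - doors$time[i]
        k <- k + 1L
      }
    }
  }
  list(latency = lat,
       flagged = if (length(flagged)) do.call(rbind, flagged)
                 else data.frame(trial = character(), reason = character()))
}
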