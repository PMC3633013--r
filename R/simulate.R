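#' Initialize the phase of a cell within its pause/run cycle
#'
#' A cell's "phase" is how far into the current pause+run cycle it is at
#' observation start. \code{synchronized} starts every cell at the
#' beginning of a pause (phase offset 0), which exposes the pulsed
#' single-particle square-displacement profile. \code{stationary} draws
#' the offset uniformly over the cycle \code{[0, t_run)}, emulating an
#' asynchronously migrating population and yielding the smooth ensemble
#' mean square displacement.
#'
#' @param params a \code{\link{model_params}} object.
#' @param mode \code{"synchronized"} or \code{"stationary"}.
#' @return An object of class \code{phase_state} with fields \code{mode}
#'   and \code{tau0} (minutes into the cycle; \code{tau0 < t_pause} means
#'   the cell is pausing, otherwise it is mid-run).
#' @examples
#' init_phase(model_params(0.5, 2, 18.8), "synchronized")$tau0  # 0
#' @export
init_phase <- function(params, mode = c("synchronized", "stationary")) {
  params <- as_model_params(params)
  mode <- match.arg(mode)
  tau0 <- if (mode == "synchronized") 0 else stats::runif(1, 0, params$t_run)
  structure(list(mode = mode, tau0 = tau0), class = "phase_state")
}

# Draw run directions for a taxis mode (topotaxis skews the distribution).
draw_run_dirs <- function(k, taxis) {
  if (taxis$mode == "topotaxis" && taxis$p > 0)
    draw_topotaxis_direction(k, taxis$p, taxis$b)
  else
    draw_unit_direction(k)
}

#' Simulate one cell track of the Beauchemin model
#'
#' Event-driven simulation of the pause/turn/free-run cycle, optionally
#' under one of the four taxis modes. The underlying continuous path is
#' piecewise linear: stationary during pauses (drifting at
#' \code{\link{pause_drift}} in simple mode), straight at
#' \code{\link{run_speed}} during runs whose directions come from
#' \code{\link{draw_unit_direction}} (or the topotaxis distribution) and
#' whose lengths come from \code{\link{run_duration}}. Observations at
#' \code{t = 0, sample_dt, 2 sample_dt, ...} are evaluated exactly on
#' this path; cycle events need not align with sample times.
#'
#' For klinotaxis with stationary phase the cycle durations vary with the
#' run direction, so the initial (direction, phase) pair is drawn from
#' the renewal-stationary law, in which a cycle is intersected with
#' probability proportional to its duration. For all other modes the
#' cycle length is constant and the phase offset is simply uniform on the
#' cycle.
#'
#' @param params a \code{\link{model_params}} object.
#' @param taxis a \code{\link{taxis_spec}} object (default: unbiased).
#' @param duration total observation time in minutes (> 0).
#' @param sample_dt observation interval in minutes (0 < sample_dt <=
#'   duration).
#' @param phase \code{"synchronized"}, \code{"stationary"}, or a
#'   \code{phase_state} from \code{\link{init_phase}}.
#' @param max_events guard against runaway event loops (degenerate
#'   zero-length cycles); exceeded -> error.
#' @return A data frame of class \code{track} with columns \code{t},
#'   \code{x}, \code{y}, \code{z} (minutes / micrometres), starting at
#'   the origin at time 0.
#' @examples
#' set.seed(7)
#' tr <- simulate_track(model_params(0.5, 2, 18.8), duration = 30,
#'                      sample_dt = 0.5)
#' head(tr)
#' @export
simulate_track <- function(params, taxis = taxis_spec(), duration, sample_dt,
                           phase = c("synchronized", "stationary"),
                           max_events = 1e9) {
  params <- as_model_params(params)
  taxis <- as_taxis_spec(taxis)
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be a positive number of minutes")
  stopifnot(is.numeric(sample_dt), length(sample_dt) == 1L)
  if (!is.finite(sample_dt) || sample_dt <= 0 || sample_dt > duration)
    stop("'sample_dt' must satisfy 0 < sample_dt <= duration")

  tp <- params$t_pause; tf <- params$t_free; v <- params$v_free
  mode <- taxis$mode; p <- taxis$p; b <- taxis$b
  drift <- pause_drift(mode, p, b, v)
  pause_disp <- drift * tp

  if (inherits(phase, "phase_state")) {
    phase_mode <- phase$mode
    tau0 <- phase$tau0
  } else {
    phase_mode <- match.arg(phase)
    tau0 <- NULL
  }

  # --- initial partial cycle -------------------------------------------
  seg_dt <- numeric(0)
  seg_disp <- matrix(numeric(0), 0, 3)
  if (phase_mode == "stationary") {
    if (mode == "klinotaxis" && p > 0 && is.null(tau0)) {
      # renewal-stationary (length-biased) draw of the intersected cycle
      cmax <- tp + tf * (1 + p)
      repeat {
        d0 <- drop(draw_run_dirs(1L, taxis))
        dur0 <- run_duration(mode, p, sum(b * d0), tf)
        u <- stats::runif(1, 0, cmax)
        if (u < tp + dur0) break
      }
      tau0 <- u
      if (tau0 < tp) {
        seg_dt <- c(tp - tau0, dur0)
        seg_disp <- rbind(drift * (tp - tau0),
                          d0 * run_speed(mode, p, sum(b * d0), v) * dur0)
      } else {
        rem <- dur0 - (tau0 - tp)
        seg_dt <- rem
        seg_disp <- rbind(d0 * run_speed(mode, p, sum(b * d0), v) * rem)
      }
    } else {
      if (is.null(tau0)) tau0 <- stats::runif(1, 0, params$t_run)
      if (tau0 < tp) {
        # rest of the current cycle: remaining pause, then its full run
        d0 <- drop(draw_run_dirs(1L, taxis))
        dot0 <- sum(b * d0)
        dur0 <- run_duration(mode, p, dot0, tf)
        seg_dt <- c(tp - tau0, dur0)
        seg_disp <- rbind(drift * (tp - tau0),
                          d0 * run_speed(mode, p, dot0, v) * dur0)
      } else {
        d0 <- drop(draw_run_dirs(1L, taxis))
        dot0 <- sum(b * d0)
        rem <- max(run_duration(mode, p, dot0, tf) - (tau0 - tp), 0)
        seg_dt <- rem
        seg_disp <- rbind(d0 * run_speed(mode, p, dot0, v) * rem)
      }
    }
  }
  # synchronized: tau0 = 0, cycle begins with the pause; nothing partial

  # --- full cycles until the observation window is covered -------------
  covered <- sum(seg_dt)
  n_events <- length(seg_dt)
  parts <- list(list(dt = seg_dt, disp = seg_disp))
  while (covered < duration) {
    k <- max(16L, ceiling((duration - covered) / params$t_run) + 4L)
    dirs <- draw_run_dirs(k, taxis)
    dots <- as.vector(dirs %*% b)
    durs <- run_duration(mode, p, dots, tf)
    spds <- run_speed(mode, p, dots, v)
    run_disp <- dirs * (spds * durs)
    # interleave pause, run, pause, run, ...
    dt2 <- rbind(rep(tp, k), durs)
    dx2 <- rbind(rep(pause_disp[1], k), run_disp[, 1])
    dy2 <- rbind(rep(pause_disp[2], k), run_disp[, 2])
    dz2 <- rbind(rep(pause_disp[3], k), run_disp[, 3])
    parts[[length(parts) + 1L]] <-
      list(dt = as.vector(dt2),
           disp = cbind(as.vector(dx2), as.vector(dy2), as.vector(dz2)))
    covered <- covered + sum(dt2)
    n_events <- n_events + 2L * k
    if (n_events > max_events)
      stop("event budget exceeded (max_events = ", max_events,
           "); degenerate parameters?")
  }
  seg_dt <- unlist(lapply(parts, `[[`, "dt"), use.names = FALSE)
  seg_disp <- do.call(rbind, lapply(parts, `[[`, "disp"))

  times <- c(0, cumsum(seg_dt))
  pos <- rbind(c(0, 0, 0),
               cbind(cumsum(seg_disp[, 1]), cumsum(seg_disp[, 2]),
                     cumsum(seg_disp[, 3])))
  # drop breakpoints past the window (keep the first one at/after it)
  cut <- which(times >= duration)[1]
  if (!is.na(cut) && cut < length(times)) {
    times <- times[seq_len(cut)]
    pos <- pos[seq_len(cut), , drop = FALSE]
  }
  # duplicate times from zero-length events carry equal positions; keep last
  keep <- !duplicated(times, fromLast = TRUE)
  times <- times[keep]
  pos <- pos[keep, , drop = FALSE]

  ts <- sample_dt * (0:floor(duration / sample_dt + 1e-9))
  out <- data.frame(
    t = ts,
    x = stats::approx(times, pos[, 1], xout = ts)$y,
    y = stats::approx(times, pos[, 2], xout = ts)$y,
    z = stats::approx(times, pos[, 3], xout = ts)$y)
  class(out) <- c("track", "data.frame")
  out
}

#' Simulate an ensemble of independent cell tracks
#'
#' Runs \code{n} independent tracks on a common observation grid. Each
#' track uses its own random substream derived deterministically from the
#' master seed (L'Ecuyer-CMRG streams), so an ensemble is exactly
#' reproducible and track \code{i} is the same regardless of how many
#' tracks are simulated or in what order.
#'
#' @inheritParams simulate_track
#' @param n number of tracks (>= 1).
#' @param seed master seed (non-negative integer).
#' @return A \code{\link{trackset}}: a long-format data frame with
#'   columns \code{track_id}, \code{t}, \code{x}, \code{y}, \code{z},
#'   zero-aligned by construction, carrying the generating parameters as
#'   provenance attributes.
#' @examples
#' ts <- simulate_ensemble(5, model_params(0.5, 2, 18.8), duration = 10,
#'                         sample_dt = 1, seed = 42)
#' ts
#' @export
simulate_ensemble <- function(n, params, taxis = taxis_spec(), duration,
                              sample_dt,
                              phase = c("stationary", "synchronized"),
                              seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  params <- as_model_params(params)
  taxis <- as_taxis_spec(taxis)
  phase <- match.arg(phase)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)

  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })

  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    assign(".Random.seed", s, envir = globalenv())
    tracks[[i]] <- simulate_track(params, taxis, duration, sample_dt, phase)
    s <- parallel::nextRNGStream(s)
  }
  npt <- nrow(tracks[[1]])
  df <- do.call(rbind, tracks)
  df <- cbind(track_id = rep(seq_len(n), each = npt), df)
  rownames(df) <- NULL
  trackset(df, aligned = TRUE, sample_dt = sample_dt,
           provenance = list(params = unclass(params)[c("t_pause", "t_free",
                                                        "v_free")],
                             taxis = unclass(taxis),
                             n = n, duration = duration,
                             sample_dt = sample_dt, phase = phase,
                             seed = as.integer(seed)))
}

#' Track set container
#'
#' A long-format table of discrete-time 3-D cell observations: one row
#' per (cell, time point), columns \code{track_id}, \code{t} (min),
#' \code{x}, \code{y}, \code{z} (um). Within each track, times must be
#' strictly increasing.
#'
#' @param df a data frame with columns \code{track_id, t, x, y, z}.
#' @param aligned logical: do all tracks start at the origin at t = 0?
#' @param sample_dt common observation interval (min), or NA if unknown.
#' @param provenance named list recording how the tracks were produced.
#' @return The data frame with class \code{trackset} and the metadata
#'   stored as attributes.
#' @export
trackset <- function(df, aligned = FALSE, sample_dt = NA_real_,
                     provenance = list()) {
  req <- c("track_id", "t", "x", "y", "z")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("a trackset needs columns track_id, t, x, y, z")
  df <- df[req]
  for (cl in c("t", "x", "y", "z")) {
    if (!is.numeric(df[[cl]])) stop("column '", cl, "' must be numeric")
    if (any(!is.finite(df[[cl]]))) stop("non-finite values in column '", cl, "'")
  }
  bad <- unlist(lapply(split(df$t, df$track_id),
                       function(t) any(diff(t) <= 0)))
  if (any(bad))
    stop("times not strictly increasing in track(s): ",
         paste(names(bad)[bad], collapse = ", "))
  structure(df, class = c("trackset", "data.frame"),
            aligned = isTRUE(aligned), sample_dt = sample_dt,
            provenance = provenance)
}

#' @export
print.trackset <- function(x, ...) {
  ids <- unique(x$track_id)
  cat(sprintf("Track set: %d track(s), %d observations%s\n",
              length(ids), nrow(x),
              if (isTRUE(attr(x, "aligned"))) ", zero-aligned" else ""))
  pr <- attr(x, "provenance")
  if (length(pr) && !is.null(pr$params))
    cat(sprintf("  simulated: t_pause=%g t_free=%g v_free=%g, taxis %s, seed %s\n",
                pr$params$t_pause, pr$params$t_free, pr$params$v_free,
                if (is.null(pr$taxis)) "none" else pr$taxis$mode,
                if (is.null(pr$seed)) "?" else pr$seed))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Number of tracks in a track set
#' @param x a \code{\link{trackset}}.
#' @return integer count of distinct tracks.
#' @export
n_tracks <- function(x) length(unique(x$track_id))
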