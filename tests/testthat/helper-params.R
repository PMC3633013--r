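# Shared fixtures: the published best-fit triplet and friends.

best_fit <- function() model_params(t_pause = 0.5, t_free = 2.0, v_free = 18.8)

# (t_pause, v_free) chosen to leave M and t_free unchanged -> identical MSD
degenerate_twin <- function() model_params(9.32, 2.0, 40)

# deterministic straight 3-D mover at speed v, as a trackset
straight_mover <- function(v = 10, duration = 10, dt = 1, n = 3,
                           dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  tt <- seq(0, duration, by = dt)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(track_id = i, t = tt, x = v * tt * dir[1],
               y = v * tt * dir[2], z = v * tt * dir[3])))
  trackset(df, aligned = TRUE, sample_dt = dt)
}

stationary_tracks <- function(n = 3, duration = 5, dt = 1) {
  tt <- seq(0, duration, by = dt)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(track_id = i, t = tt, x = 0, y = 0, z = 0)))
  trackset(df, aligned = TRUE, sample_dt = dt)
}

# exact theory MSD packaged as a stat_curve (1-D view)
theory_msd_curve <- function(params, t_max = 30, dt = 0.5) {
  tt <- seq(dt, t_max, by = dt)
  stat_curve(tt, msd_ensemble(tt, params), rep(0, length(tt)),
             rep(1L, length(tt)), "msd", "x")
}
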