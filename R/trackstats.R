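#' Time-indexed statistic curve
#'
#' Container for an estimated track statistic: one row per time point
#' with the estimate, its standard error and the number of contributing
#' tracks. Produced by \code{\link{mean_displacement}},
#' \code{\link{mean_square_displacement}} and
#' \code{\link{empirical_confinement}}.
#'
#' @param t time grid (min).
#' @param estimate point estimates.
#' @param se per-point standard errors (sample SD / sqrt(n)).
#' @param n contributing tracks per point.
#' @param statistic tag: one of \code{"mean_displacement"}, \code{"msd"},
#'   \code{"sq_confinement"}, \code{"norm_sq_confinement"},
#'   \code{"classic_confinement"}.
#' @param dims coordinate subset the statistic was computed on.
#' @return A data frame of class \code{stat_curve}.
#' @export
stat_curve <- function(t, estimate, se, n, statistic, dims = c("x", "y", "z")) {
  stopifnot(length(t) == length(estimate), length(t) == length(se),
            length(t) == length(n))
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  structure(data.frame(t = as.numeric(t), estimate = as.numeric(estimate),
                       se = as.numeric(se), n = as.integer(n)),
            class = c("stat_curve", "data.frame"),
            statistic = statistic, dims = dims)
}

#' @export
print.stat_curve <- function(x, ...) {
  cat(sprintf("Statistic curve: %s on (%s), %d time points\n",
              attr(x, "statistic"), paste(attr(x, "dims"), collapse = ","),
              nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Zero-align a track set
#'
#' Translates every track so that it starts at the origin at time 0 by
#' subtracting its first observation from all observations (time
#' included). Within-track displacement differences are unchanged; the
#' operation is idempotent.
#'
#' @param tracks a \code{\link{trackset}} (or data frame with columns
#'   \code{track_id, t, x, y, z}).
#' @return The aligned \code{trackset}.
#' @export
zero_align <- function(tracks) {
  tracks <- as_trackset(tracks)
  if (isTRUE(attr(tracks, "aligned"))) return(tracks)
  o <- order(match(tracks$track_id, unique(tracks$track_id)), tracks$t)
  df <- as.data.frame(tracks)[o, ]
  first <- !duplicated(df$track_id)
  idx <- cumsum(first)          # track index per row
  for (cl in c("t", "x", "y", "z"))
    df[[cl]] <- df[[cl]] - df[[cl]][first][idx]
  rownames(df) <- NULL
  trackset(df, aligned = TRUE, sample_dt = attr(tracks, "sample_dt"),
           provenance = attr(tracks, "provenance"))
}

as_trackset <- function(x) {
  if (inherits(x, "trackset")) return(x)
  trackset(x)
}

# Reshape a shared-grid trackset into per-coordinate matrices
# (time points x tracks). Errors if tracks do not share one grid.
track_matrices <- function(tracks) {
  ids <- unique(tracks$track_id)
  n <- length(ids)
  o <- order(match(tracks$track_id, ids), tracks$t)
  df <- as.data.frame(tracks)[o, ]
  npt <- nrow(df) / n
  if (npt != floor(npt))
    stop("tracks do not share a common observation grid")
  npt <- as.integer(npt)
  tg <- matrix(df$t, npt, n)
  if (any(abs(tg - tg[, 1]) > 1e-8))
    stop("tracks do not share a common observation grid")
  list(t = tg[, 1], n = n,
       x = matrix(df$x, npt, n),
       y = matrix(df$y, npt, n),
       z = matrix(df$z, npt, n))
}

require_aligned <- function(tracks) {
  tracks <- as_trackset(tracks)
  if (!isTRUE(attr(tracks, "aligned"))) {
    o <- order(match(tracks$track_id, unique(tracks$track_id)), tracks$t)
    first <- !duplicated(tracks$track_id[o])
    f <- as.data.frame(tracks)[o, ][first, ]
    if (any(abs(f$t) > 1e-12) || any(abs(as.matrix(f[c("x", "y", "z")])) >
                                     1e-12))
      stop("tracks must be zero-aligned; call zero_align() first")
    attr(tracks, "aligned") <- TRUE
  }
  tracks
}

row_mean_se <- function(m) {
  n <- ncol(m)
  est <- rowMeans(m)
  sd <- if (n > 1) sqrt(pmax(rowSums((m - est)^2), 0) / (n - 1)) else rep(0, nrow(m))
  list(est = est, se = sd / sqrt(n), n = n)
}

sel_sqnorm <- function(mats, dims) {
  dims <- match.arg(dims, c("x", "y", "z"), several.ok = TRUE)
  sq <- 0
  for (d in dims) sq <- sq + mats[[d]]^2
  sq
}

#' Mean displacement curve
#'
#' At each shared time point, the average Euclidean distance of the
#' zero-aligned tracks from their origin,
#' \code{D(t) = mean_i ||x_i(t)||}, over the selected coordinate subset.
#' Unlike the mean \emph{square} displacement, this statistic couples
#' the dimensions and retains information about the pause time: triplets
#' with identical motility coefficient and run time can still differ in
#' mean displacement.
#'
#' @param tracks a zero-aligned \code{\link{trackset}} on a shared grid.
#' @param dims coordinate subset, e.g. \code{"x"} or
#'   \code{c("x", "y", "z")}.
#' @return A \code{\link{stat_curve}} (tag \code{"mean_displacement"}).
#' @export
mean_displacement <- function(tracks, dims = c("x", "y", "z")) {
  tracks <- require_aligned(tracks)
  mats <- track_matrices(tracks)
  r <- row_mean_se(sqrt(sel_sqnorm(mats, dims)))
  stat_curve(mats$t, r$est, r$se, rep(r$n, length(mats$t)),
             "mean_displacement", dims)
}

#' Mean square displacement curve
#'
#' At each shared time point, the average squared distance of the
#' zero-aligned tracks from their origin,
#' \code{D^2(t) = mean_i ||x_i(t)||^2}, over the selected coordinate
#' subset. For the Beauchemin model with stationary phase this estimates
#' \code{\link{msd_ensemble}} times the number of selected dimensions;
#' the 3-D curve is the exact per-track sum of the three 1-D curves.
#'
#' @inheritParams mean_displacement
#' @return A \code{\link{stat_curve}} (tag \code{"msd"}).
#' @export
mean_square_displacement <- function(tracks, dims = c("x", "y", "z")) {
  tracks <- require_aligned(tracks)
  mats <- track_matrices(tracks)
  r <- row_mean_se(sel_sqnorm(mats, dims))
  stat_curve(mats$t, r$est, r$se, rep(r$n, length(mats$t)), "msd", dims)
}

#' Empirical confinement ratio curves
#'
#' Two variants of track-straightness over time:
#' \describe{
#'   \item{\code{"squared"}}{the model's squared confinement ratio:
#'     per-track \code{||x_i(t)||^2 / (t^2 v_free^2)} on the selected
#'     (default one-dimensional) view, averaged over tracks. Needs the
#'     model run speed \code{v_free} (taken from simulation provenance
#'     when not supplied). Its small-t limit is 1/3 for a 1-D view.}
#'   \item{\code{"classic"}}{the meandering (chemotactic) index:
#'     per-track 3-D displacement divided by the 3-D path length up to
#'     \code{t}, averaged over tracks; always in [0, 1], and exactly 1
#'     for straight directed motion.}
#' }
#' The \code{t = 0} point is 0/0 and is omitted from the curve.
#'
#' @inheritParams mean_displacement
#' @param variant \code{"squared"} or \code{"classic"}.
#' @param v_free run speed (um/min) for the squared variant.
#' @param dims coordinate view for the squared variant (default
#'   \code{"x"}; the classic variant is always 3-D).
#' @return A \code{\link{stat_curve}} (tag \code{"sq_confinement"} or
#'   \code{"classic_confinement"}).
#' @export
empirical_confinement <- function(tracks, variant = c("squared", "classic"),
                                  v_free = NULL, dims = "x") {
  variant <- match.arg(variant)
  tracks <- require_aligned(tracks)
  mats <- track_matrices(tracks)
  keep <- mats$t > 0
  if (!any(keep)) stop("need at least one time point with t > 0")
  if (variant == "squared") {
    if (is.null(v_free)) {
      pr <- attr(tracks, "provenance")
      v_free <- if (!is.null(pr$params)) pr$params$v_free else
        stop("supply 'v_free' (no simulation provenance available)")
    }
    sq <- sel_sqnorm(mats, dims)[keep, , drop = FALSE]
    ratios <- sq / (mats$t[keep]^2 * v_free^2)
    r <- row_mean_se(ratios)
    stat_curve(mats$t[keep], r$est, r$se, rep(r$n, sum(keep)),
               "sq_confinement", dims)
  } else {
    disp <- sqrt(mats$x^2 + mats$y^2 + mats$z^2)
    steps <- sqrt(diff(mats$x)^2 + diff(mats$y)^2 + diff(mats$z)^2)
    plen <- rbind(0, apply(steps, 2, cumsum))
    ratios <- (disp / plen)[keep, , drop = FALSE]  # NaN where path length 0
    est <- se <- nn <- numeric(sum(keep))
    for (i in seq_len(sum(keep))) {
      v <- ratios[i, ]
      v <- v[is.finite(v)]
      nn[i] <- length(v)
      est[i] <- if (nn[i]) mean(v) else NA_real_
      se[i] <- if (nn[i] > 1) stats::sd(v) / sqrt(nn[i]) else 0
    }
    stat_curve(mats$t[keep], est, se, nn, "classic_confinement",
               c("x", "y", "z"))
  }
}

#' Displacement covariance matrix at a fixed time
#'
#' Sample covariance of the (x, y, z) displacements of zero-aligned
#' tracks at grid time \code{t}, with leave-one-out jackknife standard
#' errors. For the unbiased model this is isotropic, \code{2Mt} on the
#' diagonal and 0 off it; taxis modes other than the simple one distort
#' it anisotropically.
#'
#' @inheritParams mean_displacement
#' @param t a time on the shared grid.
#' @return A list with \code{cov} (3x3), \code{se} (3x3 jackknife SEs),
#'   \code{t} and \code{n}.
#' @export
displacement_covariance <- function(tracks, t) {
  tracks <- require_aligned(tracks)
  mats <- track_matrices(tracks)
  i <- which(abs(mats$t - t) < 1e-8)[1]
  if (is.na(i)) stop("'t' is not on the shared observation grid")
  X <- cbind(mats$x[i, ], mats$y[i, ], mats$z[i, ])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 tracks for a covariance estimate")
  C <- stats::cov(X)
  # vectorized leave-one-out covariances
  S1 <- colSums(X)
  S2 <- crossprod(X)
  SE <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    ci <- (S2[a, b] - X[, a] * X[, b] -
             (S1[a] - X[, a]) * (S1[b] - X[, b]) / (n - 1)) / (n - 2)
    SE[a, b] <- SE[b, a] <- sqrt((n - 1) / n * sum((ci - mean(ci))^2))
  }
  dimnames(C) <- dimnames(SE) <- list(c("x", "y", "z"), c("x", "y", "z"))
  list(cov = C, se = SE, t = mats$t[i], n = n)
}
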