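#' Fit result container
#' @keywords internal
fit_result <- function(estimates, ssr, n, method) {
  structure(list(estimates = estimates, ssr = ssr, n = n, method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s), %d points, SSR = %.6g\n", x$method, x$n, x$ssr))
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.6g\n", nm, x$estimates[[nm]]))
  invisible(x)
}

#' Fit the linear MSD regime
#'
#' Beyond \code{t = t_free} the ensemble MSD of the model is exactly the
#' line \code{alpha t + beta}, so a weighted least-squares line fitted
#' over that regime identifies the motility coefficient
#' \code{M = alpha/2} and the run time \code{t_free = -3 beta / alpha}.
#' Weights are \code{1/SE^2} where per-point standard errors are
#' available (and positive), otherwise uniform.
#'
#' The default fit range enforces the linear regime without knowing
#' \code{t_free}: a first fit over the whole positive grid produces a
#' \code{t_free} guess, and the fit is repeated once over
#' \code{t >= max(grid start, 2 * guess)}.
#'
#' @param curve an MSD \code{\link{stat_curve}} (or data frame with
#'   columns \code{t}, \code{estimate} and optionally \code{se}).
#' @param range optional numeric \code{c(lo, hi)} fit window in minutes;
#'   overrides the automatic choice.
#' @param dims number of observed dimensions the curve was computed on
#'   (the estimates are per-dimension quantities after division).
#' @return A \code{fit_result} with estimates \code{M} (um^2/min),
#'   \code{t_free} (min), \code{alpha}, \code{beta}. A positive fitted
#'   intercept yields \code{t_free = 0} with a warning.
#' @examples
#' p <- model_params(0.5, 2, 18.8)
#' tt <- seq(0.5, 30, by = 0.5)
#' cv <- stat_curve(tt, msd_ensemble(tt, p), rep(0, length(tt)),
#'                  rep(1, length(tt)), "msd", "x")
#' fit_linear_msd(cv, range = c(2, 30))$estimates
#' @export
fit_linear_msd <- function(curve, range = NULL, dims = 1L) {
  stopifnot(is.data.frame(curve), all(c("t", "estimate") %in% names(curve)))
  stopifnot(dims %in% 1:3)
  se <- if ("se" %in% names(curve)) curve$se else rep(0, nrow(curve))
  wls <- function(keep) {
    if (sum(keep) < 3) stop("fewer than 3 points in the fit range")
    w <- if (all(is.finite(se[keep])) && all(se[keep] > 0)) 1 / se[keep]^2
         else rep(1, sum(keep))
    stats::lm(estimate ~ t, data = curve[keep, ], weights = w)
  }
  if (is.null(range)) {
    f0 <- wls(curve$t > 0)
    a0 <- stats::coef(f0)[["t"]]; b0 <- stats::coef(f0)[["(Intercept)"]]
    guess <- if (a0 > 0) max(-3 * b0 / a0, 0) else 0
    range <- c(max(min(curve$t), 2 * guess), max(curve$t))
  }
  keep <- curve$t >= range[1] & curve$t <= range[2]
  fit <- wls(keep)
  alpha <- stats::coef(fit)[["t"]] / dims
  beta <- stats::coef(fit)[["(Intercept)"]] / dims
  if (alpha <= 0) stop("fitted MSD slope is not positive")
  if (beta > 0) {
    warning("positive fitted intercept; reporting t_free = 0")
    t_free <- 0
  } else {
    t_free <- -3 * beta / alpha
  }
  fit_result(list(M = alpha / 2, t_free = t_free, alpha = alpha, beta = beta),
             ssr = sum(stats::residuals(fit)^2), n = sum(keep),
             method = "linear_msd")
}

#' Fit Fuerth's equation to an MSD curve
#'
#' Nonlinear least squares of \code{dims * 2M (t - P (1 - e^{-t/P}))}
#' with positivity constraints, via Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}) from multiple starting values (M from a
#' preliminary line fit; P over a coarse grid of time scales). The best
#' converged start by SSR wins.
#'
#' @inheritParams fit_linear_msd
#' @return A \code{fit_result} with estimates \code{M} and \code{P}.
#' @export
fit_furth <- function(curve, dims = 1L) {
  stopifnot(is.data.frame(curve), all(c("t", "estimate") %in% names(curve)))
  if (nrow(curve) < 5) stop("need at least 5 points to fit Fuerth's equation")
  stopifnot(dims %in% 1:3)
  d <- curve[curve$t >= 0, c("t", "estimate")]
  tmax <- max(d$t)
  # slope-based M start
  lf <- stats::lm(estimate ~ 0 + t, data = d[d$t >= tmax / 2, , drop = FALSE])
  M0 <- max(stats::coef(lf)[["t"]] / (2 * dims), .Machine$double.eps)
  starts <- expand.grid(M = M0 * c(0.5, 1, 2),
                        P = tmax * c(0.005, 0.02, 0.1, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        estimate ~ dims * 2 * M * (t - P * (1 - exp(-t / P))),
        data = d, start = list(M = starts$M[i], P = starts$P[i]),
        lower = c(M = 0, P = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ssr < best$ssr)
        best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best))
    stop("Fuerth fit failed to converge from all starting values (",
         nrow(starts), " starts tried)")
  co <- stats::coef(best$fit)
  fit_result(list(M = unname(co["M"]), P = unname(co["P"])),
             ssr = best$ssr, n = nrow(d), method = "furth")
}

#' Rank a grid of parameter triplets against a reference curve
#'
#' Reproduces the simulation-grid ranking workflow used to calibrate the
#' model: for each candidate triplet, simulate \code{n} stationary-phase
#' unbiased tracks on the reference grid, compute the same statistic as
#' the reference (mean displacement or MSD, same coordinate view), and
#' score it by the sum of squared residuals (uniform weights) against
#' the reference estimates. Triplets are returned sorted by SSR, with
#' SSR normalized to the best fit (best = 1.00) and each triplet's
#' motility coefficient attached.
#'
#' MSD references cannot separate triplets that share M and t_free (the
#' curve has two degrees of freedom); mean-displacement references can.
#'
#' @param reference a \code{\link{stat_curve}} with statistic tag
#'   \code{"mean_displacement"} or \code{"msd"}, on a regular grid.
#' @param grid list of \code{\link{model_params}} (or length-3 vectors
#'   \code{c(t_pause, t_free, v_free)}).
#' @param n tracks simulated per triplet.
#' @param seed master seed; triplet \code{i} uses \code{seed + i}.
#' @return A data frame with columns \code{rank, t_pause, t_free,
#'   v_free, M, SSR, SSR_rel}, sorted by SSR.
#' @export
rank_parameter_grid <- function(reference, grid, n = 1e4, seed = 1L) {
  stopifnot(is.data.frame(reference),
            all(c("t", "estimate") %in% names(reference)))
  statistic <- attr(reference, "statistic")
  if (is.null(statistic) || !statistic %in% c("mean_displacement", "msd"))
    stop("reference must be a mean-displacement or MSD stat_curve")
  dims <- attr(reference, "dims")
  if (is.null(dims)) dims <- c("x", "y", "z")
  if (!length(grid)) stop("empty parameter grid")
  tt <- reference$t[reference$t > 0]
  dt <- unique(round(diff(sort(tt)), 9))
  if (length(dt) != 1)
    stop("reference grid must be regular for simulation on the same grid")
  duration <- max(reference$t)

  rows <- lapply(seq_along(grid), function(i) {
    pp <- grid[[i]]
    if (!inherits(pp, "model_params")) pp <- model_params(pp[1], pp[2], pp[3])
    sim <- simulate_ensemble(n, pp, taxis_spec(), duration = duration,
                             sample_dt = dt, phase = "stationary",
                             seed = seed + i)
    cv <- if (statistic == "msd") mean_square_displacement(sim, dims)
          else mean_displacement(sim, dims)
    m <- merge(as.data.frame(reference)[c("t", "estimate")],
               as.data.frame(cv)[c("t", "estimate")], by = "t",
               suffixes = c("_ref", "_sim"))
    if (!nrow(m)) stop("reference grid and simulation grid do not overlap")
    data.frame(t_pause = pp$t_pause, t_free = pp$t_free, v_free = pp$v_free,
               M = motility_coefficient(pp),
               SSR = sum((m$estimate_sim - m$estimate_ref)^2))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$SSR), ]
  out$SSR_rel <- out$SSR / out$SSR[1]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
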