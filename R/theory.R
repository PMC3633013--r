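#' Motility coefficient of the Beauchemin model
#'
#' In the Brownian scaling limit the model diffuses with motility
#' (diffusion) coefficient
#' \deqn{M = (v_{free} t_{free})^2 / (6 (t_{free} + t_{pause}))}
#' per observed dimension: one full cycle displaces the cell by a vector
#' uniform on the sphere of radius \code{r = v_free t_free}, whose
#' per-component variance is \code{r^2/3}, over a cycle time
#' \code{t_free + t_pause}, and \code{M = variance rate / 2}.
#'
#' @param params a \code{\link{model_params}} object.
#' @return M in um^2/min.
#' @examples
#' motility_coefficient(model_params(0.5, 2.0, 18.8))  # 94.25
#' @export
motility_coefficient <- function(params) {
  params <- as_model_params(params)
  (params$v_free * params$t_free)^2 / (6 * (params$t_free + params$t_pause))
}

#' Expected square displacement of a single synchronized particle
#'
#' For a particle that starts a cycle (pause first) at time 0, observed
#' in one dimension at time \code{t + tau} with \code{t} an integer
#' multiple of the cycle length \code{t_run} and \code{0 <= tau < t_run}:
#' \deqn{E[D^2](t+\tau) = 2 M t + (v_{free}^2/3) \max(\tau - t_{pause}, 0)^2}
#' The profile is flat during pauses and rises quadratically during runs,
#' producing the pulsed single-particle curve that the phase-averaged
#' ensemble curve smooths out.
#'
#' @param t elapsed whole cycles' time (min); must be a multiple of
#'   \code{t_run} (within 1e-9 relative).
#' @param tau offset into the current cycle, in \code{[0, t_run)}.
#' @param params a \code{\link{model_params}} object.
#' @param dims number of observed dimensions (1-3); per-dimension values
#'   are simply multiplied by \code{dims}.
#' @return Expected square displacement in um^2.
#' @export
msd_single <- function(t, tau, params, dims = 1L) {
  params <- as_model_params(params)
  stopifnot(dims %in% 1:3)
  if (any(t < 0)) stop("'t' must be >= 0")
  k <- t / params$t_run
  if (any(abs(k - round(k)) > 1e-9 * pmax(1, k)))
    stop("'t' must be an integer multiple of t_run = ", params$t_run)
  if (any(tau < 0 | tau >= params$t_run))
    stop("'tau' must lie in [0, t_run)")
  M <- motility_coefficient(params)
  dims * (2 * M * t +
            (params$v_free^2 / 3) * pmax(tau - params$t_pause, 0)^2)
}

#' Ensemble (phase-averaged) mean square displacement
#'
#' Expected MSD of a zero-aligned population observed from a uniformly
#' random phase within the pause/run cycle. Per observed dimension:
#' \deqn{E[D^2](t) = 2Mt - 2Mt_{free} g(t/t_{free})}
#' with \eqn{g(u) = 1/3} for \eqn{u \ge 1} and
#' \eqn{g(u) = u^3/3 - u^2 + u} for \eqn{u < 1}. From \code{t = t_free}
#' onward the curve is exactly the line \code{alpha t + beta} of
#' \code{\link{msd_linear_coeffs}}; at 0 it has value 0 and slope 0.
#'
#' @param t time(s) in minutes, >= 0 (vectorized).
#' @inheritParams msd_single
#' @return Expected MSD in um^2.
#' @examples
#' msd_ensemble(60, model_params(0.5, 2, 18.8))  # ~ 11184.4
#' @export
msd_ensemble <- function(t, params, dims = 1L) {
  params <- as_model_params(params)
  stopifnot(dims %in% 1:3)
  if (any(t < 0)) stop("'t' must be >= 0")
  M <- motility_coefficient(params)
  u <- t / params$t_free
  g <- ifelse(u >= 1, 1 / 3, u^3 / 3 - u^2 + u)
  dims * (2 * M * t - 2 * M * params$t_free * g)
}

#' Slope and intercept of the asymptotic linear MSD
#'
#' For \code{t >= t_free} the ensemble MSD per dimension is exactly
#' \code{alpha t + beta} with \code{alpha = 2M} and
#' \code{beta = -2 M t_free / 3}; note \code{beta/alpha = -t_free/3}, so
#' a fitted line identifies both the motility coefficient and the run
#' time. The pair (alpha, beta) has only two degrees of freedom: distinct
#' (t_pause, v_free) with the same M and t_free give identical lines.
#'
#' @param params a \code{\link{model_params}} object.
#' @return Named vector \code{c(alpha = 2M, beta = -2M t_free/3)}
#'   (um^2/min, um^2), per observed dimension.
#' @export
msd_linear_coeffs <- function(params) {
  params <- as_model_params(params)
  M <- motility_coefficient(params)
  c(alpha = 2 * M, beta = -2 * M * params$t_free / 3)
}

#' Expected squared confinement ratio
#'
#' The squared confinement ratio relates the one-dimensional squared
#' displacement to the squared three-dimensional path length:
#' \code{C^2(t) = D^2(t) / (t^2 v_free^2)}. For \code{t_pause = 0} (the
#' ideal-chain case, where path length is exactly \code{t v_free}) its
#' expectation has the closed form
#' \deqn{E[C^2](t) = (3\max(t,t_{free}) - \min(t,t_{free}))
#'   \, t_{free} / (3\max(t,t_{free}))^2,}
#' equal to 1/3 at \code{t = 0} (the 1-D projection of a 3-D path) and
#' monotonically decreasing to 0. Implemented as
#' \code{msd_ensemble(t)/(t^2 v^2)}, which reduces to the closed form.
#'
#' With \code{t_pause != 0} the ratio no longer measures path
#' straightness exactly (the cell is idle part of the time, so
#' \code{t v_free} overstates the path length); the same expression can
#' still be evaluated as an extrapolation by setting
#' \code{allow_pause = TRUE}, otherwise a nonzero pause is an error.
#'
#' @param t time(s) in minutes, >= 0 (vectorized); \code{t = 0} returns
#'   the limit 1/3.
#' @param params a \code{\link{model_params}} object.
#' @param allow_pause evaluate anyway when \code{t_pause != 0}.
#' @return Dimensionless expected squared confinement ratio.
#' @export
sq_confinement <- function(t, params, allow_pause = FALSE) {
  params <- as_model_params(params)
  if (params$t_pause != 0 && !allow_pause)
    stop("the squared confinement closed form assumes t_pause = 0; ",
         "set allow_pause = TRUE to evaluate it as an extrapolation")
  if (any(t < 0)) stop("'t' must be >= 0")
  tf <- params$t_free
  base <- ifelse(t <= tf, (3 * tf - t) / (9 * tf),
                 tf * (3 * t - tf) / (9 * t^2))
  # E[D^2]/(t^2 v^2) with the general M is the t_pause = 0 form scaled by
  # the fraction of time spent running
  base * tf / (tf + params$t_pause)
}

#' Time-normalized squared confinement ratio
#'
#' The confinement ratio decays with observation time, which makes it
#' hard to compare across experiments of different length; multiplying
#' by time stabilizes it. For \code{t >= t_free},
#' \deqn{t\,E[C^2](t) = t_{free}(3t - t_{free})/(9t),}
#' which increases monotonically and converges to \code{t_free/3} - a
#' quick rule of thumb for reading the persistence time off long
#' experiments.
#'
#' @inheritParams sq_confinement
#' @param t time(s) in minutes, > 0 (vectorized).
#' @return Normalized squared confinement ratio, units of minutes.
#' @export
normalized_sq_confinement <- function(t, params, allow_pause = FALSE) {
  if (any(t <= 0)) stop("'t' must be > 0")
  t * sq_confinement(t, params, allow_pause = allow_pause)
}

#' Convection speed of the biased-migration modes
#'
#' Length of the convection coefficient (drift velocity of the scaling
#' limit) as a function of the bias strength \code{p}:
#' \describe{
#'   \item{simple}{\code{p v_free t_pause / (t_free + t_pause)} - the
#'     pause-phase drift distance per cycle divided by the cycle time.}
#'   \item{orthotaxis, topotaxis, klinotaxis}{all three give exactly
#'     \code{v_free p t_free / (3 (t_free + t_pause))}: each run advances
#'     the cell along the bias by \code{v_free t_free p/3} on average.}
#'   \item{none}{0.}
#' }
#' Inverting these formulas lets a simulation be parameterized directly
#' by a target bias speed instead of \code{p}.
#'
#' @param mode taxis mode name (as in \code{\link{taxis_spec}}).
#' @param p bias strength in \code{[0, 1]}.
#' @param params a \code{\link{model_params}} object.
#' @return \code{||C||} in um/min.
#' @examples
#' convection_speed("orthotaxis", 1, model_params(0.5, 2, 18.8))  # 5.013
#' @export
convection_speed <- function(mode, p, params) {
  params <- as_model_params(params)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  mode <- switch(mode, ortho = "orthotaxis", topo = "topotaxis",
                 klino = "klinotaxis", mode)
  if (!mode %in% c("none", "simple", "orthotaxis", "topotaxis", "klinotaxis"))
    stop("unknown taxis mode: ", mode)
  switch(mode,
         none = 0,
         simple = p * params$v_free * params$t_pause /
           (params$t_free + params$t_pause),
         # orthotaxis, topotaxis and klinotaxis share one bias speed
         params$v_free * p * params$t_free /
           (3 * (params$t_free + params$t_pause)))
}

#' Fuerth's mean square displacement equation
#'
#' The classical persistent-random-walk MSD,
#' \deqn{E[D^2](t) = 2M (t - P (1 - e^{-t/P})),}
#' where persistence decays exponentially with persistence parameter
#' \code{P} - in contrast to the Beauchemin model, whose persistence is
#' lost completely after each cycle, making its MSD exactly linear beyond
#' \code{t_free}. Provided as the standard comparison model for fitting.
#'
#' @param t time(s) in minutes, >= 0.
#' @param M motility coefficient (um^2/min), >= 0.
#' @param P persistence parameter (min), >= 0; \code{P = 0} is the
#'   memoryless limit \code{2Mt}.
#' @return Expected MSD in um^2 (per observed dimension).
#' @export
furth_msd <- function(t, M, P) {
  stopifnot(M >= 0, P >= 0)
  if (any(t < 0)) stop("'t' must be >= 0")
  if (P == 0) return(2 * M * t)
  2 * M * (t - P * (1 - exp(-t / P)))
}

#' Gaussian solution of the convection-diffusion equation
#'
#' On long time scales the (possibly biased) walk converges to Brownian
#' motion with drift: the position density is Gaussian with mean
#' \code{C t} and variance \code{2 M t}, and solves
#' \deqn{\partial_t \phi = -C \partial_x \phi + M \partial_x^2 \phi.}
#'
#' @param x position(s) in um.
#' @param t time in minutes, > 0.
#' @param C convection coefficient (um/min).
#' @param M motility coefficient (um^2/min), > 0.
#' @return Density values (1/um).
#' @export
gaussian_density <- function(x, t, C, M) {
  stopifnot(is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("'t' must be > 0")
  if (M <= 0) stop("'M' must be > 0")
  stats::dnorm(x, mean = C * t, sd = sqrt(2 * M * t))
}
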