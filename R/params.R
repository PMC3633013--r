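#' Microscopic motility parameters of the Beauchemin model
#'
#' The Beauchemin model describes a cell as a massless particle that
#' alternates between a stationary turning pause of fixed length
#' \code{t_pause} and a straight "free run" of fixed length \code{t_free}
#' at speed \code{v_free}, each run in a fresh direction drawn uniformly
#' from the unit sphere. All times are in minutes, all lengths in
#' micrometres.
#'
#' @param t_pause pause (turning) time in minutes; must be >= 0.
#' @param t_free free-run time in minutes; must be > 0.
#' @param v_free free-run speed in micrometres per minute; must be >= 0.
#'
#' @return An object of class \code{model_params}: a list with the three
#'   parameters plus the derived cycle length \code{t_run = t_free +
#'   t_pause} (min) and step radius \code{r = v_free * t_free} (um), the
#'   distance covered by one full run.
#'
#' @examples
#' p <- model_params(t_pause = 0.5, t_free = 2.0, v_free = 18.8)
#' p$t_run   # 2.5 min
#' p$r       # 37.6 um
#' @export
model_params <- function(t_pause, t_free, v_free) {
  stopifnot(is.numeric(t_pause), length(t_pause) == 1L, is.finite(t_pause),
            is.numeric(t_free), length(t_free) == 1L, is.finite(t_free),
            is.numeric(v_free), length(v_free) == 1L, is.finite(v_free))
  if (t_pause < 0) stop("'t_pause' must be >= 0")
  if (t_free <= 0) stop("'t_free' must be > 0")
  if (v_free < 0) stop("'v_free' must be >= 0")
  structure(
    list(t_pause = as.numeric(t_pause),
         t_free  = as.numeric(t_free),
         v_free  = as.numeric(v_free),
         t_run   = as.numeric(t_free + t_pause),
         r       = as.numeric(v_free * t_free)),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Beauchemin model parameters\n")
  cat(sprintf("  t_pause: %g min   t_free: %g min   v_free: %g um/min\n",
              x$t_pause, x$t_free, x$v_free))
  cat(sprintf("  cycle t_run: %g min   step radius r: %g um   M: %g um^2/min\n",
              x$t_run, x$r, motility_coefficient(x)))
  invisible(x)
}

#' Taxis (biased migration) specification
#'
#' Four mechanisms of spatially uniform directional bias are supported:
#' \describe{
#'   \item{\code{none}}{unbiased random migration (forces \code{p = 0}).}
#'   \item{\code{simple}}{during pauses the cell drifts with velocity
#'     \code{p * v_free * b} instead of standing still; the only mode that
#'     leaves the random motility component untouched.}
#'   \item{\code{orthotaxis}}{run speed becomes
#'     \code{v_free * (1 + p * <b, d>)} for run direction \code{d}.}
#'   \item{\code{topotaxis}}{the component of the run direction along
#'     \code{b} is drawn from the skewed density \code{(1 + p x)/2} on
#'     \code{[-1, 1]} instead of the uniform density.}
#'   \item{\code{klinotaxis}}{run duration becomes
#'     \code{t_free * (1 + p * <b, d>)} (run-and-tumble-like bias).}
#' }
#'
#' @param mode one of \code{"none"}, \code{"simple"}, \code{"orthotaxis"},
#'   \code{"topotaxis"}, \code{"klinotaxis"} (the short forms
#'   \code{"ortho"}, \code{"topo"}, \code{"klino"} are accepted).
#' @param p dimensionless bias strength in \code{[0, 1]}; \code{p = 0} is
#'   unbiased, \code{p = 1} maximally biased.
#' @param b bias direction, a numeric 3-vector; normalized to unit length
#'   on construction (must be non-zero when \code{p > 0}).
#'
#' @return An object of class \code{taxis_spec}.
#' @examples
#' taxis_spec("orthotaxis", p = 0.5, b = c(1, 0, 0))
#' @export
taxis_spec <- function(mode = c("none", "simple", "orthotaxis", "topotaxis",
                                "klinotaxis"),
                       p = 0, b = c(1, 0, 0)) {
  if (length(mode) == 1L) {
    mode <- switch(mode, ortho = "orthotaxis", topo = "topotaxis",
                   klino = "klinotaxis", mode)
  }
  mode <- match.arg(mode)
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0 || p > 1) stop("taxis strength 'p' must lie in [0, 1]")
  if (mode == "none" && p != 0) stop("mode 'none' requires p = 0")
  stopifnot(is.numeric(b), length(b) == 3L, all(is.finite(b)))
  nb <- sqrt(sum(b^2))
  if (nb < 1e-9) stop("bias direction 'b' must be a non-zero vector")
  structure(list(mode = mode, p = as.numeric(p), b = as.numeric(b) / nb),
            class = "taxis_spec")
}

#' @export
print.taxis_spec <- function(x, ...) {
  if (x$mode == "none") {
    cat("Taxis: none (unbiased)\n")
  } else {
    cat(sprintf("Taxis: %s, p = %g, b = (%.4g, %.4g, %.4g)\n",
                x$mode, x$p, x$b[1], x$b[2], x$b[3]))
  }
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x) && all(c("t_pause", "t_free", "v_free") %in% names(x)))
    return(model_params(x$t_pause, x$t_free, x$v_free))
  stop("expected a 'model_params' object")
}

as_taxis_spec <- function(x) {
  if (is.null(x)) return(taxis_spec())
  if (inherits(x, "taxis_spec")) return(x)
  if (is.list(x) && "mode" %in% names(x))
    return(taxis_spec(x$mode, if (is.null(x$p)) 0 else x$p,
                      if (is.null(x$b)) c(1, 0, 0) else x$b))
  stop("expected a 'taxis_spec' object")
}
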