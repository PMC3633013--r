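#' Draw directions uniformly from the unit sphere
#'
#' Uses the normalized Gaussian triple (Marsaglia-style) construction: a
#' standard trivariate normal vector divided by its norm is exactly
#' uniform on the sphere. Each Cartesian component of such a direction is
#' marginally uniform on \code{[-1, 1]} (Archimedes' hat-box property)
#' with variance 1/3, and the components are pairwise uncorrelated.
#'
#' Randomness is taken from R's global random number stream; call
#' \code{set.seed()} (or use \code{\link{simulate_ensemble}}, which
#' manages per-track substreams) for reproducibility.
#'
#' @param n number of directions to draw.
#' @return An \code{n x 3} numeric matrix whose rows are unit vectors.
#' @examples
#' set.seed(1)
#' d <- draw_unit_direction(5)
#' rowSums(d^2)  # all 1
#' @export
draw_unit_direction <- function(n = 1L) {
  stopifnot(n >= 1)
  m <- matrix(stats::rnorm(3L * n), nrow = n, ncol = 3L)
  nrm <- sqrt(rowSums(m^2))
  # a zero norm has probability 0; guard against the pathological draw
  bad <- nrm < 1e-300
  if (any(bad)) {
    m[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
    nrm[bad] <- 1
  }
  m / nrm
}

#' Draw directions from the topotaxis (skewed-turning) distribution
#'
#' The component \code{x = <b, d>} of the returned direction along the
#' bias direction \code{b} has the linear density \code{(1 + p x)/2} on
#' \code{[-1, 1]}; conditional on \code{x}, the perpendicular part is
#' uniform on the circle of radius \code{sqrt(1 - x^2)} in the plane
#' normal to \code{b}. At \code{p = 0} this is exactly the uniform sphere
#' distribution. Sampling of \code{x} is by inverse transform: the CDF
#' \code{F(x) = (x + 1)/2 + p (x^2 - 1)/4} is quadratic, so its inverse
#' is a closed-form root, keeping the draw stream-reproducible.
#'
#' @param n number of directions to draw.
#' @param p bias strength in \code{[0, 1]}.
#' @param b unit bias direction (3-vector; normalized internally).
#' @return An \code{n x 3} numeric matrix whose rows are unit vectors.
#' @export
draw_topotaxis_direction <- function(n = 1L, p, b = c(1, 0, 0)) {
  stopifnot(n >= 1, is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0 || p > 1) stop("taxis strength 'p' must lie in [0, 1]")
  stopifnot(is.numeric(b), length(b) == 3L, all(is.finite(b)))
  nb <- sqrt(sum(b^2))
  if (abs(nb - 1) > 1e-9) {
    if (nb < 1e-9) stop("'b' must be a non-zero vector")
    b <- b / nb
  } else {
    b <- b / nb
  }
  u <- stats::runif(n)
  if (p == 0) {
    x <- 2 * u - 1
  } else {
    # root of (p/4) x^2 + x/2 + (1/2 - p/4 - u) = 0 in [-1, 1]
    disc <- 0.25 - p * (0.5 - p / 4 - u)
    x <- (-0.5 + sqrt(pmax(disc, 0))) / (p / 2)
    x <- pmin(pmax(x, -1), 1)
  }
  # orthonormal basis of the plane normal to b
  a <- if (abs(b[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(b[2] * a[3] - b[3] * a[2],
          b[3] * a[1] - b[1] * a[3],
          b[1] * a[2] - b[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(b[2] * e1[3] - b[3] * e1[2],
          b[3] * e1[1] - b[1] * e1[3],
          b[1] * e1[2] - b[2] * e1[1])
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - x^2, 0))
  outer(x, b) + outer(s * cos(phi), e1) + outer(s * sin(phi), e2)
}

#' Run speed under a taxis mode
#'
#' Only orthotaxis modifies the run speed: \code{v_free (1 + p <b, d>)},
#' so movement perpendicular to the bias is unaffected, movement against
#' it slower, movement along it faster. All other modes run at
#' \code{v_free}.
#'
#' @param mode taxis mode name.
#' @param p bias strength.
#' @param dot scalar product \code{<b, d>} of bias and run direction
#'   (vectorized; values in \code{[-1, 1]}).
#' @param v_free unbiased run speed (um/min).
#' @return Speed(s) in um/min, always >= 0 for \code{p <= 1}.
#' @export
run_speed <- function(mode, p, dot, v_free) {
  if (identical(mode, "orthotaxis")) v_free * (1 + p * dot)
  else rep_len(v_free, length(dot))
}

#' Run duration under a taxis mode
#'
#' Only klinotaxis modifies the run duration:
#' \code{t_free (1 + p <b, d>)}; runs along the bias last longer, runs
#' against it are cut short (down to zero-length at \code{p = 1},
#' \code{dot = -1}, a valid degenerate run). Mean duration over uniform
#' directions stays \code{t_free}.
#'
#' @inheritParams run_speed
#' @param t_free unbiased run duration (min).
#' @return Duration(s) in minutes, always >= 0 for \code{p <= 1}.
#' @export
run_duration <- function(mode, p, dot, t_free) {
  if (identical(mode, "klinotaxis")) t_free * (1 + p * dot)
  else rep_len(t_free, length(dot))
}

#' Pause-phase drift velocity
#'
#' In the simple phenomenological taxis mode the cell is not stationary
#' during pauses but drifts with velocity \code{p * v_free * b}. All
#' other modes pause in place.
#'
#' @inheritParams run_speed
#' @param b unit bias direction.
#' @return A velocity 3-vector in um/min.
#' @export
pause_drift <- function(mode, p, b, v_free) {
  if (identical(mode, "simple")) p * v_free * b else c(0, 0, 0)
}
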