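#' Parameter set for the simple diffusion decision model
#'
#' Bundles one condition's DDM parameters: drift rate `v` (evidence units
#' per second, signed toward the upper boundary), boundary separation `a`
#' (> 0), relative starting point `z` in (0, 1) (fraction of `a` measured
#' from the lower boundary), non-decision time `t0` (seconds, >= 0) and
#' the diffusion coefficient `s`, a scaling constant conventionally fixed
#' at 1 when response times are in seconds (the legacy 0.1 convention is
#' available by setting `s`).
#'
#' @param v drift rate.
#' @param a boundary separation, > 0.
#' @param z relative starting point, strictly inside (0, 1).
#' @param t0 non-decision time in seconds, >= 0.
#' @param s diffusion coefficient, > 0.
#' @return an object of class `ddm_params`.
#' @examples
#' ddm_params(v = 2, a = 1.2, z = 0.5, t0 = 0.3)
#' @export
ddm_params <- function(v, a, z = 0.5, t0 = 0.3, s = 1) {
  for (nm in c("v", "a", "z", "t0", "s")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (a <= 0) stop("boundary separation `a` must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("relative starting point `z` must lie in (0, 1)",
                             call. = FALSE)
  if (t0 < 0) stop("non-decision time `t0` must be >= 0", call. = FALSE)
  if (s <= 0) stop("diffusion coefficient `s` must be > 0", call. = FALSE)
  structure(list(v = v, a = a, z = z, t0 = t0, s = s), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("<ddm_params> v = %.3f, a = %.3f, z = %.3f, t0 = %.3f s, s = %g\n",
              x$v, x$a, x$z, x$t0, x$s))
  invisible(x)
}

check_boundary <- function(boundary) {
  boundary <- match.arg(boundary, c("upper", "lower"))
  boundary
}

#' Defective first-passage-time density of the simple DDM
#'
#' Density (1/seconds) of absorption at one boundary at response time `t`,
#' i.e. at decision time `t - t0`. The density is defective: it integrates
#' over (t0, Inf) to that boundary's absorption probability. Zero for
#' `t <= t0`. Evaluated by an adaptive choice between the small-time and
#' large-time series expansions with truncation error below 1e-9.
#'
#' @param t response times in seconds (vectorised).
#' @param boundary `"upper"` or `"lower"`.
#' @param p a [ddm_params()] object.
#' @return numeric vector of densities.
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), p) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  wfpt_density_cpp(t, as.integer(boundary == "upper"), p$v, p$a, p$z, p$t0, p$s)
}

#' Defective cumulative distribution of the simple DDM
#'
#' P(absorbed at `boundary` at or before response time `t`), computed by
#' quadrature of [wfpt_density()]. For long input vectors the CDF is
#' evaluated on a dense grid and interpolated.
#'
#' @inheritParams wfpt_density
#' @param rel.tol quadrature tolerance passed to [stats::integrate()].
#' @return numeric vector of probabilities.
#' @export
wfpt_cdf <- function(t, boundary = c("upper", "lower"), p, rel.tol = 1e-8) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  f <- function(u) wfpt_density(u, boundary, p)
  one <- function(ti) {
    if (ti <= p$t0) return(0)
    integrate(f, lower = p$t0, upper = ti, rel.tol = rel.tol,
              subdivisions = 500L)$value
  }
  if (length(t) <= 50L) return(vapply(t, one, numeric(1)))
  # dense-grid cumulative trapezoid, then interpolate
  hi <- max(t, p$t0 + 1e-3)
  grid <- seq(p$t0, hi, length.out = 20000L)
  dens <- f(grid)
  dt <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dt))
  out <- approx(grid, cdf, xout = pmax(t, p$t0), rule = 2)$y
  out[t <= p$t0] <- 0
  out
}

#' Absorption probabilities of the simple DDM
#'
#' Closed-form probability that the accumulator is absorbed at `boundary`:
#' P(upper) = (1 - exp(-2 v a z / s^2)) / (1 - exp(-2 v a / s^2)), with the
#' v -> 0 limit equal to `z`. The two boundary probabilities sum to 1.
#'
#' @inheritParams wfpt_density
#' @return a probability in `[0, 1]`.
#' @export
absorption_probability <- function(boundary = c("upper", "lower"), p) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  k <- 2 * p$v * p$a / p$s^2
  p_up <- if (abs(k) < 1e-9) p$z else expm1(-k * p$z) / expm1(-k)
  p_up <- min(max(p_up, 0), 1)
  if (boundary == "upper") p_up else 1 - p_up
}

#' Simulate trials from the simple DDM
#'
#' Euler-Maruyama forward simulation. The step `dt` should be small
#' relative to the decision-time scale `(a/s)^2` (the default 1e-4 s gives
#' step SDs two orders of magnitude below typical boundary separations).
#'
#' @param p a [ddm_params()] object.
#' @param n number of trials, >= 1.
#' @param dt Euler step in seconds, > 0.
#' @param seed integer seed; identical seed and arguments give identical
#'   output.
#' @return a data.frame with columns `rt` (seconds, always > t0) and
#'   `boundary` (factor, `upper`/`lower`).
#' @export
simulate_ddm <- function(p, n, dt = 1e-4, seed = NULL) {
  stopifnot(inherits(p, "ddm_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_ddm_cpp(as.integer(n), p$v, p$a, p$z, p$t0, p$s, dt)
  data.frame(rt = sim$rt,
             boundary = factor(ifelse(sim$upper == 1L, "upper", "lower"),
                               levels = c("upper", "lower")))
}

#' Floored log first-passage density
#'
#' `log(wfpt_density(...))` clamped below at `floor`, so out-of-support
#' response times (e.g. rt <= t0) contribute a large negative constant to
#' likelihood sums instead of -Inf.
#'
#' @inheritParams wfpt_density
#' @param rt response times in seconds, > 0.
#' @param floor lower clamp for the log density.
#' @return numeric vector of log densities, never below `floor`.
#' @export
trial_log_density <- function(rt, boundary = c("upper", "lower"), p,
                              floor = -700) {
  boundary <- match.arg(boundary)
  if (any(rt <= 0)) stop("`rt` must be > 0", call. = FALSE)
  pmax(log(pmax(wfpt_density(rt, boundary, p), 0)), floor)
}
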