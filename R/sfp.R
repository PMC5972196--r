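#' Stochastic fixed-point parameters
#'
#' Parameters of the closed-form response distribution of the depressing
#' synapse under Poisson stimulation.  When the calcium decay time is much
#' shorter than typical intervals, calcium relaxes between pulses, the
#' release probability sits at `Pmax`, and the pool fixed point depends on
#' the preceding interval `T` only through the baseline recovery rate
#' (see [rbar_of_isi()]).  Feeding an exponential interval through that
#' fixed-point curve yields the "stochastic fixed point", whose density is
#' available in closed form ([dsfp_rbar()], [dsfp_pr()]).
#'
#' @param lam Poisson rate in 1/ms (mean ISI is `1/lam` ms). Supply either
#'   `lam` or `rate_hz`.
#' @param rate_hz alternatively, the rate in Hz (converted to 1/ms).
#' @param Pmax maximum release probability in (0, 1].
#' @param kmin baseline recovery rate (1/ms).
#' @return list of class `sfp_params` with fields `lam`, `Pmax`, `kmin` and
#'   the derived `c = 1 - Pmax`.
#' @export
#' @examples
#' sfp_params(rate_hz = 3, Pmax = 0.85, kmin = 0.0017)
sfp_params <- function(lam = NULL, rate_hz = NULL, Pmax = 0.85,
                       kmin = 0.0017) {
  if (is.null(lam) == is.null(rate_hz))
    stop("supply exactly one of 'lam' (1/ms) or 'rate_hz'", call. = FALSE)
  if (!is.null(rate_hz)) lam <- rate_hz / 1000
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("the Poisson rate must be a single positive number", call. = FALSE)
  if (!is.numeric(Pmax) || length(Pmax) != 1L || Pmax <= 0 || Pmax > 1)
    stop("'Pmax' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(kmin) || length(kmin) != 1L || kmin <= 0)
    stop("'kmin' must be positive", call. = FALSE)
  structure(list(lam = lam, Pmax = Pmax, kmin = kmin, c = 1 - Pmax),
            class = "sfp_params")
}

#' Pool fixed point as a function of the interval
#'
#' The small-`tau_ca` fixed point of the releasable pool under periodic
#' stimulation at interval `T`:
#' \deqn{\bar R(T) = \frac{1 - e^{-k_{min} T}}{1 - (1 - P_{max}) e^{-k_{min} T}}.}
#'
#' @param T_ms interval(s) in ms.
#' @param p an [sfp_params()] object.
#' @return values in `[0, 1]`, vectorized over `T_ms`.
#' @export
rbar_of_isi <- function(T_ms, p) {
  stopifnot(inherits(p, "sfp_params"))
  if (any(T_ms <= 0)) stop("'T_ms' must be positive", call. = FALSE)
  e <- exp(-p$kmin * T_ms)
  (1 - e) / (1 - p$c * e)
}

#' Density of the pool stochastic fixed point
#'
#' Closed-form probability density of `X = Rbar(T)` when `T` is exponential
#' with rate `lam`:
#' \deqn{f(x) = \frac{\lambda (1-c)}{k_{min}} (1-x)^{-(1-\lambda/k_{min})}
#'        (1-cx)^{-(1+\lambda/k_{min})}, \qquad x \in (0, 1),}
#' with `c = 1 - Pmax`.  For `c = 0` this reduces to the Beta(1,
#' `lam/kmin`) density.
#'
#' @param x evaluation points; density is 0 outside (0, 1).
#' @param p an [sfp_params()] object.
#' @return non-negative densities, vectorized over `x`.
#' @export
dsfp_rbar <- function(x, p) {
  stopifnot(inherits(p, "sfp_params"))
  if (p$c >= 1) stop("Pmax = 0 is not a valid release probability",
                     call. = FALSE)
  r <- p$lam / p$kmin
  out <- numeric(length(x))
  ok <- is.finite(x) & x > 0 & x < 1
  xx <- x[ok]
  out[ok] <- p$lam * (1 - p$c) / p$kmin *
    (1 - xx)^(-(1 - r)) * (1 - p$c * xx)^(-(1 + r))
  out
}

#' Density of the normalized response stochastic fixed point
#'
#' Closed-form density of `Y = Pmax * Rbar(T)`, the per-pulse response proxy
#' at the stochastic fixed point, supported on `(0, Pmax)`:
#' \deqn{f(y) = \frac{\lambda P_{max} (1-c)}{k_{min}}
#'   (P_{max}-y)^{-(1-\lambda/k_{min})} (P_{max}-cy)^{-(1+\lambda/k_{min})}.}
#' Equivalently `dsfp_pr(y) = dsfp_rbar(y / Pmax) / Pmax`.
#'
#' @inheritParams dsfp_rbar
#' @param y evaluation points; density is 0 outside (0, Pmax).
#' @return non-negative densities, vectorized over `y`.
#' @export
#' @examples
#' p <- sfp_params(lam = 1/100, Pmax = 0.85, kmin = 0.0017)
#' stats::integrate(dsfp_pr, 0, 0.85, p = p) # integrates to 1
dsfp_pr <- function(y, p) {
  stopifnot(inherits(p, "sfp_params"))
  if (p$c >= 1) stop("Pmax = 0 is not a valid release probability",
                     call. = FALSE)
  r <- p$lam / p$kmin
  out <- numeric(length(y))
  ok <- is.finite(y) & y > 0 & y < p$Pmax
  yy <- y[ok]
  out[ok] <- p$lam * p$Pmax * (1 - p$c) / p$kmin *
    (p$Pmax - yy)^(-(1 - r)) * (p$Pmax - p$c * yy)^(-(1 + r))
  out
}

#' Distribution function of the response stochastic fixed point
#'
#' Exact CDF of [dsfp_pr()], obtained by inverting the monotone map from
#' interval to fixed point: `P(Y <= y) = 1 - u^{lam/kmin}` with
#' `u = (Pmax - y) / (Pmax - c y)`.
#'
#' @inheritParams dsfp_pr
#' @param q quantiles.
#' @return probabilities, vectorized over `q`.
#' @export
psfp_pr <- function(q, p) {
  stopifnot(inherits(p, "sfp_params"))
  r <- p$lam / p$kmin
  out <- numeric(length(q))
  out[q >= p$Pmax] <- 1
  ok <- is.finite(q) & q > 0 & q < p$Pmax
  qq <- q[ok]
  u <- (p$Pmax - qq) / (p$Pmax - p$c * qq)
  out[ok] <- 1 - u^r
  out
}

#' Sample the response stochastic fixed point
#'
#' Inverse-transform sampler: draws exponential intervals `T` with rate
#' `lam` and maps them through `Pmax * rbar_of_isi(T)`, producing i.i.d.
#' draws with density [dsfp_pr()].
#'
#' @param n number of draws.
#' @param p an [sfp_params()] object.
#' @param seed optional integer for reproducible draws.
#' @return numeric vector in `[0, Pmax]`.
#' @export
rsfp_pr <- function(n, p, seed = NULL) {
  stopifnot(inherits(p, "sfp_params"))
  if (n < 1) stop("'n' must be a positive integer", call. = FALSE)
  Ts <- with_seed(seed, stats::rexp(n, rate = p$lam))
  p$Pmax * rbar_of_isi(Ts, p)
}

#' Tabulate an analytic response density on a grid
#'
#' Convenience export for density-family plots: evaluates [dsfp_pr()] on an
#' even grid over `[0, Pmax]`.
#'
#' @param p an [sfp_params()] object.
#' @param n_points grid resolution.
#' @return data frame with columns `y` and `density`.
#' @export
sfp_density_table <- function(p, n_points = 512) {
  y <- seq(0, p$Pmax, length.out = n_points)
  data.frame(y = y, density = dsfp_pr(y, p))
}
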