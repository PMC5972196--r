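#' Poisson stimulus trains
#'
#' Draws inter-spike intervals (ISIs) of a homogeneous Poisson spike train:
#' independent exponential intervals with mean `1000 / rate_hz` milliseconds.
#'
#' @param rate_hz mean firing rate in Hz.
#' @param n number of intervals to draw.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of `n` ISIs in ms.
#' @export
#' @examples
#' isis <- poisson_isis(5, 1000, seed = 1)
#' mean(isis) # close to 200 ms
poisson_isis <- function(rate_hz, n, seed = NULL) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    stop("'rate_hz' must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  with_seed(seed, stats::rexp(n, rate = rate_hz / 1000))
}

# Evaluate `expr` under a private RNG stream when `seed` is non-NULL,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Resting state of the FD map
#'
#' The pre-stimulation state: baseline calcium (rescaled `C = 0`), a full
#' releasable pool (`R = 1`) and the corresponding release probability
#' `P = P(C = 0) = 0`.
#'
#' @return A named list with entries `C`, `R`, `P`.
#' @export
fd_rest_state <- function() list(C = 0, R = 1, P = 0)

check_state <- function(state) {
  if (!is.list(state) || !all(c("C", "R", "P") %in% names(state)))
    stop("'state' must be a list with fields C, R, P", call. = FALSE)
  v <- c(state$C, state$R, state$P)
  if (!all(is.finite(v))) stop("non-finite map state", call. = FALSE)
  if (state$C < 0 || state$R < 0 || state$R > 1 || state$P < 0 ||
      state$P > 1)
    stop("map state out of range: need C >= 0, R and P in [0,1]",
         call. = FALSE)
  invisible(state)
}

#' One step of the FD map
#'
#' Advances the discrete facilitation-depression map across one inter-spike
#' interval and applies the next pulse.  Writing `C`, `R`, `P` for the
#' post-pulse state carried in `state` and `T` for the interval:
#'
#' \deqn{C' = C e^{-T/\tau_{ca}} + \Delta}
#' \deqn{P' = P_{max} C'^4 / (C'^4 + K^4)}
#' \deqn{R' = 1 - (1 - (1-P)R)\,\gamma(T), \quad
#'       \gamma(T) = \Big(\frac{C e^{-T/\tau_{ca}} + K_r}{K_r + C}\Big)^{\Delta k}
#'                   e^{-k_{min} T}}
#'
#' Calcium decays exponentially with time constant `tau_ca` and jumps by
#' `delta` at the pulse; the release probability follows calcium through a
#' Hill function of coefficient 4; the pool recovers toward 1 at a
#' calcium-dependent rate, starting from the post-release value `(1-P)R`.
#' The recovery Hill factor carries the exponent `delta_k = kmax - kmin`
#' exactly as the map is written; see the methods vignette for why this
#' reading, rather than a rescaled exponent, is the one that reproduces the
#' model's documented rate dependence.
#'
#' The per-pulse response proxy is `Pr = P' R'`, the product of release
#' probability and the pre-release pool, proportional to the peak
#' postsynaptic current evoked by the pulse.
#'
#' @param state list with fields `C`, `R`, `P` (see [fd_rest_state()]).
#' @param isi_ms time since the previous pulse, ms (> 0).
#' @param params a [synapse_params()] object.
#' @return list with elements `state` (the new `C`, `R`, `P`) and `pr`.
#' @export
#' @examples
#' p <- synapse_preset("mixed")
#' fd_step(fd_rest_state(), 1e6, p)$pr # 0.3: first pulse from rest
fd_step <- function(state, isi_ms, params) {
  stopifnot(inherits(params, "synapse_params"))
  check_state(state)
  if (!is.numeric(isi_ms) || length(isi_ms) != 1L || !is.finite(isi_ms) ||
      isi_ms <= 0)
    stop("'isi_ms' must be a single positive number", call. = FALSE)
  dec <- state$C * exp(-isi_ms / params$tau_ca)
  gam <- ((dec + params$Kr) / (params$Kr + state$C))^params$delta_k *
    exp(-params$kmin * isi_ms)
  Cn <- dec + params$delta
  Pn <- params$Pmax * Cn^4 / (Cn^4 + params$K^4)
  Rn <- 1 - (1 - (1 - state$P) * state$R) * gam
  list(state = list(C = Cn, R = Rn, P = Pn), pr = Pn * Rn)
}

#' Simulate a pulse-train response
#'
#' Iterates the FD map over a sequence of inter-spike intervals and returns
#' the per-pulse trajectories, with an initial transient discarded.  Within
#' each row, `R` is the pre-release pool at that pulse, so `Pr = P * R`
#' elementwise; release then depletes the pool to `R (1 - P)`, which enters
#' the next step.
#'
#' @param params a [synapse_params()] object.
#' @param isis positive ISIs in ms, one per pulse.
#' @param init initial state; defaults to [fd_rest_state()].
#' @param discard number of leading pulses dropped as transient (default 100,
#'   the map's collapse onto its attractor is much faster than this).
#' @return A data frame of class `pulse_train` with columns `pulse`,
#'   `isi_ms`, `C`, `P`, `R`, `Pr` and `length(isis) - discard` rows.  The
#'   parameters are attached as attribute `params`.
#' @export
#' @examples
#' p <- synapse_preset("depressing")
#' tr <- fd_simulate(p, rep(20, 200))
#' tail(tr$Pr, 1) # steady-state response at 50 Hz
fd_simulate <- function(params, isis, init = fd_rest_state(), discard = 100L) {
  stopifnot(inherits(params, "synapse_params"))
  n <- length(isis)
  if (n == 0L) stop("empty ISI sequence", call. = FALSE)
  if (!all(is.finite(isis)) || any(isis <= 0))
    stop("all ISIs must be positive and finite", call. = FALSE)
  discard <- as.integer(discard)
  if (discard < 0L || discard >= n)
    stop("'discard' must be a non-negative integer smaller than length(isis)",
         call. = FALSE)
  check_state(init)

  Pmax <- params$Pmax; K4 <- params$K^4; Kr <- params$Kr
  kmin <- params$kmin; dk <- params$delta_k
  tau <- params$tau_ca; delta <- params$delta
  C <- P <- R <- numeric(n)
  c0 <- init$C; r0 <- init$R; p0 <- init$P
  for (i in seq_len(n)) {
    ti <- isis[i]
    dec <- c0 * exp(-ti / tau)
    gam <- ((dec + Kr) / (Kr + c0))^dk * exp(-kmin * ti)
    c0 <- dec + delta
    c4 <- c0^4
    pn <- Pmax * c4 / (c4 + K4)
    r0 <- 1 - (1 - (1 - p0) * r0) * gam
    p0 <- pn
    C[i] <- c0; P[i] <- pn; R[i] <- r0
  }
  keep <- if (discard > 0L) -seq_len(discard) else TRUE
  out <- data.frame(pulse = seq_len(n)[keep], isi_ms = isis[keep],
                    C = C[keep], P = P[keep], R = R[keep],
                    Pr = (P * R)[keep])
  attr(out, "params") <- params
  attr(out, "discard") <- discard
  class(out) <- c("pulse_train", "data.frame")
  out
}

#' Write a pulse-train response as CSV
#'
#' @param x a `pulse_train` from [fd_simulate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pulse_train <- function(x, path) {
  stopifnot(inherits(x, "pulse_train"))
  out <- data.frame(pulse_index = x$pulse, isi_ms = x$isi_ms,
                    C = x$C, P = x$P, R = x$R, Pr = x$Pr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic fixed point of the FD map at a fixed interval
#'
#' For periodic stimulation with interval `T` the map has a single attracting
#' fixed point, available in closed form: calcium sums a geometric series,
#' `Cbar = delta / (1 - exp(-T/tau_ca))`; `Pbar` is the release Hill function
#' at `Cbar`; and the pool fixed point solves the linear recovery relation,
#' `Rbar = (1 - gamma) / (1 - (1 - Pbar) gamma)` with `gamma` the recovery
#' decay factor evaluated at `Cbar`.
#'
#' @param params a [synapse_params()] object.
#' @param T_ms stimulation interval in ms.
#' @return list of class `fd_fixed_point` with `Cbar`, `Pbar`, `Rbar`,
#'   `PRbar = Pbar * Rbar`.
#' @export
#' @examples
#' fd_fixed_point(synapse_preset("depressing"), 20)
fd_fixed_point <- function(params, T_ms) {
  stopifnot(inherits(params, "synapse_params"))
  if (!is.numeric(T_ms) || length(T_ms) != 1L || !is.finite(T_ms) || T_ms <= 0)
    stop("'T_ms' must be a single positive number", call. = FALSE)
  Cb <- params$delta / (1 - exp(-T_ms / params$tau_ca))
  Pb <- params$Pmax * Cb^4 / (Cb^4 + params$K^4)
  dec <- Cb * exp(-T_ms / params$tau_ca)
  gam <- ((dec + params$Kr) / (params$Kr + Cb))^params$delta_k *
    exp(-params$kmin * T_ms)
  Rb <- (1 - gam) / (1 - (1 - Pb) * gam)
  structure(list(Cbar = Cb, Pbar = Pb, Rbar = Rb, PRbar = Pb * Rb),
            class = "fd_fixed_point")
}

#' @export
print.fd_fixed_point <- function(x, ...) {
  cat(sprintf("FD map fixed point: Cbar = %.6g, Pbar = %.6g, Rbar = %.6g, PRbar = %.6g\n",
              x$Cbar, x$Pbar, x$Rbar, x$PRbar))
  invisible(x)
}

#' Fixed-point spectrum across firing rates
#'
#' Evaluates [fd_fixed_point()] at `T = 1000 / rate` for each rate, giving
#' the frequency response of the deterministic map: the decomposition of the
#' normalized response `PRbar` into its release (`Pbar`) and pool (`Rbar`)
#' factors.  Depressing parameters give a monotone decay from `Pmax`;
#' facilitating parameters an increase over the physiological range; mixed
#' parameters a band-pass "resonance" with an interior maximum.
#'
#' @param params a [synapse_params()] object.
#' @param rates_hz distinct positive rates in Hz.
#' @return data frame with columns `rate_hz`, `Cbar`, `Pbar`, `Rbar`, `PRbar`.
#' @export
fixed_point_spectrum <- function(params, rates_hz) {
  if (length(rates_hz) == 0 || any(!is.finite(rates_hz)) ||
      any(rates_hz <= 0) || anyDuplicated(rates_hz))
    stop("'rates_hz' must be distinct positive rates", call. = FALSE)
  rows <- lapply(rates_hz, function(r) {
    fp <- fd_fixed_point(params, 1000 / r)
    data.frame(rate_hz = r, Cbar = fp$Cbar, Pbar = fp$Pbar,
               Rbar = fp$Rbar, PRbar = fp$PRbar)
  })
  do.call(rbind, rows)
}
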