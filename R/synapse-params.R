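#' Synapse model parameters
#'
#' Bundle the seven constants of the facilitation-depression (FD) map for one
#' synapse. Calcium is rescaled by the per-pulse increment of the control
#' condition, so `delta` and the Hill half-heights `K`, `Kr` are dimensionless
#' while the rate constants `kmin`, `kmax` are in 1/ms and `tau_ca` in ms.
#'
#' @param Pmax maximum release probability, in (0, 1].
#' @param K half-height of the release Hill function (coefficient 4), in
#'   rescaled calcium units.
#' @param kmin baseline recovery rate of the releasable pool (1/ms).
#' @param kmax maximal, calcium-saturated recovery rate (1/ms); must be at
#'   least `kmin`. The recovery gain `delta_k = kmax - kmin` is derived here
#'   and nowhere else.
#' @param Kr half-height of the recovery Hill function (coefficient 1).
#' @param tau_ca presynaptic calcium decay time constant (ms).
#' @param delta per-pulse calcium increment, rescaled (dimensionless).
#'
#' @return An object of class `synapse_params`: a named list with the seven
#'   fields plus the derived `delta_k`.
#' @seealso [synapse_preset()] for the shipped parameter sets.
#' @export
#' @examples
#' synapse_params(Pmax = 0.85, K = 0.2, kmin = 0.0017, kmax = 0.0517,
#'                Kr = 0.1, tau_ca = 1.5, delta = 1)
synapse_params <- function(Pmax, K, kmin, kmax, Kr, tau_ca, delta) {
  fields <- list(Pmax = Pmax, K = K, kmin = kmin, kmax = kmax,
                 Kr = Kr, tau_ca = tau_ca, delta = delta)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (Pmax > 1) stop("'Pmax' must not exceed 1", call. = FALSE)
  if (kmax < kmin) stop("'kmax' must be >= 'kmin'", call. = FALSE)
  fields$delta_k <- kmax - kmin
  structure(fields, class = "synapse_params")
}

#' Shipped synapse parameter presets
#'
#' Loads one of the four parameter sets used throughout the package:
#' `"depressing"` (the control fit of the hippocampal basket-cell to pyramidal
#' cell connection), `"muscarine"` (the same synapse under muscarinic
#' neuromodulation: reduced calcium influx, `delta = 0.17`, and reduced
#' `Pmax = 0.27`), and the two mock synapses `"facilitating"` and `"mixed"`
#' obtained by lengthening the calcium decay time to 30 ms and retuning the
#' Hill constants. Presets are read from a plain CSV shipped in
#' `extdata/presets.csv`, one record per preset.
#'
#' @param name preset name, one of `"depressing"`, `"muscarine"`,
#'   `"facilitating"`, `"mixed"`.
#' @return A [synapse_params()] object.
#' @export
#' @examples
#' synapse_preset("mixed")
synapse_preset <- function(name = c("depressing", "muscarine",
                                    "facilitating", "mixed")) {
  name <- match.arg(name)
  tab <- utils::read.csv(system.file("extdata", "presets.csv",
                                     package = "fdmachine"),
                         stringsAsFactors = FALSE)
  row <- tab[tab$name == name, ]
  p <- synapse_params(Pmax = row$Pmax, K = row$K, kmin = row$kmin,
                      kmax = row$kmax, Kr = row$Kr, tau_ca = row$tau_ca,
                      delta = row$delta)
  attr(p, "preset") <- name
  p
}

#' @export
print.synapse_params <- function(x, ...) {
  nm <- attr(x, "preset")
  cat("FD synapse parameters", if (!is.null(nm)) paste0("(preset: ", nm, ")"),
      "\n")
  cat(sprintf("  Pmax = %-7g K = %-7g Kr = %g\n", x$Pmax, x$K, x$Kr))
  cat(sprintf("  kmin = %g 1/ms  kmax = %g 1/ms  (delta_k = %g)\n",
              x$kmin, x$kmax, x$delta_k))
  cat(sprintf("  tau_ca = %g ms  delta = %g\n", x$tau_ca, x$delta))
  invisible(x)
}
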