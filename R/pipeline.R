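#' Configure a complexity-spectrum experiment
#'
#' Collects everything needed to reproduce one experiment: a synapse
#' parameter set, the grid of mean Poisson firing rates, the simulation
#' protocol (number of retained response samples and transient discard) and
#' the reconstruction settings.
#'
#' @param preset preset name passed to [synapse_preset()]; ignored when
#'   `params` is given.
#' @param params a [synapse_params()] object overriding `preset`.
#' @param rates_hz distinct positive mean firing rates in Hz; defaults to
#'   the preset's standard grid (see [default_rates()]).
#' @param n_pulses number of response samples retained per rate (default
#'   `2^15`); `n_pulses + discard` pulses are simulated.
#' @param discard transient pulses dropped (default 100).
#' @param lmax,alpha,test reconstruction settings (see [cssr()]).
#' @param threshold `"auto"` for maximum-complexity selection, or a fixed
#'   numeric threshold in (0, 1).
#' @param n_bins histogram bins (default 50).
#' @param seed master seed; per-rate seeds are derived from it and the rate
#'   value alone, so extending the rate grid never perturbs existing draws.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(preset = "depressing", params = NULL,
                              rates_hz = NULL, n_pulses = 32768L,
                              discard = 100L, lmax = 3L, alpha = 0.01,
                              test = "ks", threshold = "auto",
                              n_bins = 50L, seed = 1L) {
  if (is.null(params)) {
    params <- synapse_preset(preset)
  } else {
    stopifnot(inherits(params, "synapse_params"))
    preset <- attr(params, "preset") %||% "custom"
  }
  if (is.null(rates_hz)) rates_hz <- default_rates(preset)
  if (!length(rates_hz) || any(rates_hz <= 0) || anyDuplicated(rates_hz))
    stop("'rates_hz' must be distinct positive rates", call. = FALSE)
  n_pulses <- as.integer(n_pulses); discard <- as.integer(discard)
  if (n_pulses <= discard)
    stop("'n_pulses' must exceed 'discard'", call. = FALSE)
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1))
    stop("'threshold' must be \"auto\" or a number in (0, 1)", call. = FALSE)
  structure(list(preset = preset, params = params, rates_hz = rates_hz,
                 n_pulses = n_pulses, discard = discard, lmax = as.integer(lmax),
                 alpha = alpha, test = test, threshold = threshold,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard rate grids per preset
#'
#' The rate grids used for the reference complexity spectra: depressing
#' \{0.1, 2, 5, 100\} Hz, facilitating \{50, 77, 100, 125, 200, 250\} Hz,
#' mixed \{5, 25, 50, 125, 250\} Hz.
#'
#' @param preset preset name.
#' @return numeric vector of rates in Hz.
#' @export
default_rates <- function(preset) {
  switch(preset,
         depressing = c(0.1, 2, 5, 100),
         muscarine = c(0.1, 2, 5, 100),
         facilitating = c(50, 77, 100, 125, 200, 250),
         mixed = c(5, 25, 50, 125, 250),
         c(0.1, 1, 5, 20, 50, 100))
}

# Counter-style per-rate substream: a fixed function of (master seed, rate)
# only, so per-rate draws are independent of the grid layout.
rate_seed <- function(seed, rate_hz) {
  as.integer((as.numeric(seed) * 10007 + round(rate_hz * 1000)) %%
               2147483629)
}

#' Run a complexity-spectrum experiment
#'
#' For each rate in the configuration: draws a seeded Poisson train,
#' simulates the FD map, discards the transient, selects (or applies) the
#' binarization threshold, reconstructs the epsilon machine and records its
#' state count and statistical complexity.  A machine that fails
#' [validate_machine()] triggers an automatic decrement of the history
#' length (`lmax`) and re-reconstruction; a record that remains invalid at
#' `lmax = 1` is flagged, not fatal.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, the spectrum CSV, per-rate
#'   machine JSON and DOT files, histogram CSVs, symbol streams and a run
#'   manifest are written there.
#' @return data frame of class `complexity_spectrum` with columns
#'   `rate_hz`, `theta`, `n_states`, `cmu_bits`, `lmax_used`, `valid`,
#'   `fallback`; machines and histograms are attached as attributes
#'   `machines` and `histograms` (lists indexed like the rows).
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config("depressing", rates_hz = c(2, 100),
#'                          n_pulses = 4096, seed = 7)
#' run_experiment(cfg)
#' }
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- vector("list", length(cfg$rates_hz))
  machines <- histograms <- vector("list", length(cfg$rates_hz))
  for (i in seq_along(cfg$rates_hz)) {
    rate <- cfg$rates_hz[i]
    isis <- poisson_isis(rate, cfg$n_pulses + cfg$discard,
                         seed = rate_seed(cfg$seed, rate))
    tr <- fd_simulate(cfg$params, isis, discard = cfg$discard)
    res <- reconstruct_at(tr$Pr, cfg)
    machines[[i]] <- res$machine
    histograms[[i]] <- pr_histogram(tr$Pr, cfg$n_bins)
    rows[[i]] <- data.frame(rate_hz = rate, theta = res$theta,
                            n_states = n_states(res$machine),
                            cmu_bits = statistical_complexity(res$machine),
                            lmax_used = res$lmax_used, valid = res$valid,
                            fallback = res$fallback)
    if (!is.null(out_dir)) {
      tag <- gsub("\\.", "p", sprintf("%g", rate))
      write_machine_json(res$machine,
                         file.path(out_dir, sprintf("machine_%shz.json", tag)))
      write_machine_dot(res$machine,
                        file.path(out_dir, sprintf("machine_%shz.dot", tag)))
      write_histogram(histograms[[i]],
                      file.path(out_dir, sprintf("histogram_%shz.csv", tag)))
      write_symbols(binarize(tr$Pr, res$theta),
                    file.path(out_dir, sprintf("symbols_%shz.txt", tag)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "machines") <- machines
  attr(out, "histograms") <- histograms
  attr(out, "config") <- cfg
  class(out) <- c("complexity_spectrum", "data.frame")
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(out),
                     file.path(out_dir, "spectrum.csv"), row.names = FALSE)
    manifest <- cfg
    manifest$params <- unclass(cfg$params)
    manifest$rate_seeds <- vapply(cfg$rates_hz, rate_seed,
                                  integer(1), seed = cfg$seed)
    writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
  }
  out
}

# Threshold + reconstruction for one response train, with the lmax
# decrement rule for invalid machines.
reconstruct_at <- function(pr, cfg) {
  lmax <- cfg$lmax
  repeat {
    if (identical(cfg$threshold, "auto")) {
      sel <- select_threshold(pr, lmax = lmax, alpha = cfg$alpha,
                              test = cfg$test)
      theta <- sel$theta; machine <- sel$machine; fallback <- sel$fallback
    } else {
      theta <- cfg$threshold
      machine <- cssr(binarize(pr, theta), lmax = lmax, alpha = cfg$alpha,
                      test = cfg$test)
      fallback <- NA_character_
    }
    valid <- validate_machine(machine, lmax = lmax)$valid
    if (valid || lmax == 1L)
      return(list(theta = theta, machine = machine, lmax_used = lmax,
                  valid = valid, fallback = fallback))
    lmax <- lmax - 1L
  }
}

#' Combine complexity spectra across presets
#'
#' Long-format comparison table of statistical complexity against firing
#' rate for several presets, the summary used to contrast synapse types.
#'
#' @param spectra a named list of `complexity_spectrum` objects (names are
#'   used as the preset labels) or a single spectrum.
#' @return data frame with columns `preset`, `rate_hz`, `theta`,
#'   `n_states`, `cmu_bits`.
#' @export
complexity_spectrum_summary <- function(spectra) {
  if (inherits(spectra, "complexity_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "complexity_spectrum"))
    label <- names(spectra)[i] %||% attr(sp, "config")$preset
    if (is.null(label) || !nzchar(label)) label <- attr(sp, "config")$preset
    data.frame(preset = label, rate_hz = sp$rate_hz, theta = sp$theta,
               n_states = sp$n_states, cmu_bits = sp$cmu_bits)
  })
  do.call(rbind, rows)
}
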