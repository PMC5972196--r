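#' Binarize a response train
#'
#' Partitions a sequence of normalized responses into the two-symbol
#' alphabet: symbol 1 ("large response") where `pr >= theta`, symbol 0
#' ("small response") otherwise.  The boundary value maps to 1 by
#' convention.
#'
#' @param pr numeric responses in `[0, 1]`.
#' @param theta threshold in (0, 1).
#' @return integer 0/1 vector of class `symbol_seq` with the threshold in
#'   attribute `threshold`.
#' @export
#' @examples
#' binarize(c(0.1, 0.5, 0.9), 0.5) # 0 1 1
binarize <- function(pr, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("'theta' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(pr) || !length(pr)) stop("'pr' must be numeric",
                                           call. = FALSE)
  structure(as.integer(pr >= theta), threshold = theta, class = "symbol_seq")
}

#' Response histogram
#'
#' Frequency distribution of responses over evenly spaced bins on `[0, 1]`.
#'
#' @param pr numeric responses in `[0, 1]`.
#' @param n_bins number of bins (default 50).
#' @return list of class `pr_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `counts` and `freqs` (summing to 1).
#' @export
pr_histogram <- function(pr, n_bins = 50L) {
  if (!length(pr)) stop("empty response sequence", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be at least 2", call. = FALSE)
  if (any(pr < 0 | pr > 1)) stop("responses must lie in [0, 1]", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(pr, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 freqs = counts / sum(counts)),
            class = "pr_histogram")
}

#' Shannon entropy of a histogram, in bits
#'
#' @param h a [pr_histogram()] or a numeric vector of frequencies summing
#'   to 1.
#' @return entropy in bits.
#' @export
#' @examples
#' entropy_bits(c(0.5, 0.25, 0.25)) # 1.5
entropy_bits <- function(h) {
  f <- if (inherits(h, "pr_histogram")) h$freqs else h
  if (abs(sum(f) - 1) > 1e-9 || any(f < 0))
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Write a histogram as CSV
#' @param h a [pr_histogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "pr_histogram"))
  k <- length(h$freqs)
  utils::write.csv(data.frame(bin_left = h$bin_edges[seq_len(k)],
                              bin_right = h$bin_edges[seq_len(k) + 1L],
                              freq = h$freqs),
                   path, row.names = FALSE)
  invisible(path)
}

#' Sweep reconstruction over a threshold grid
#'
#' Reconstructs one machine per candidate threshold and records its state
#' count and statistical complexity; the robustness of a machine's topology
#' to the partition can be read off directly from the sweep.
#'
#' @param pr numeric responses in `[0, 1]`.
#' @param thetas candidate thresholds in (0, 1).
#' @param lmax,alpha,test reconstruction settings passed to [cssr()].
#' @return data frame with columns `theta`, `n_states`, `cmu_bits`, `valid`,
#'   plus the machines in attribute `machines`.
#' @export
threshold_sweep <- function(pr, thetas, lmax = 3L, alpha = 0.01,
                            test = "ks") {
  machines <- lapply(thetas, function(th)
    cssr(binarize(pr, th), lmax = lmax, alpha = alpha, test = test))
  out <- data.frame(theta = thetas,
                    n_states = vapply(machines, n_states, integer(1)),
                    cmu_bits = vapply(machines, statistical_complexity,
                                      numeric(1)),
                    valid = vapply(machines, function(m)
                      validate_machine(m)$valid, logical(1)))
  attr(out, "machines") <- machines
  out
}

#' Select the partition threshold by maximum statistical complexity
#'
#' Chooses the binarization threshold that maximizes the statistical
#' complexity of the reconstructed machine, the partition that exposes the
#' most structure in the response process.  Candidates are `n_grid` evenly
#' spaced values between the 5th and 95th percentiles of the sample, so
#' that sampling noise in the extreme tails is never resolved.  Ties in
#' complexity are broken toward the candidate nearest the sample median
#' (the most nearly equiprobable partition).
#'
#' A narrow-support guard protects against thresholding what is essentially
#' noise: when the central 99% of the sample spans less than `min_support`,
#' or when every candidate yields a zero-complexity machine, the selection
#' falls back to the midpoint of that central support.  A constant input is
#' rejected with an error.
#'
#' @param pr numeric responses in `[0, 1]`; at least 1000 values.
#' @param lmax,alpha,test reconstruction settings passed to [cssr()].
#' @param n_grid number of candidate thresholds (default 41).
#' @param grid_quantiles quantile range for the candidate grid.
#' @param support_quantiles quantile pair defining the sample support used
#'   by the guard (central 99% by default; robust to a handful of extreme
#'   intervals in a long Poisson train).
#' @param min_support support width below which the guard engages.
#' @return list of class `threshold_selection`: `theta`, `machine`,
#'   `cmu_bits`, `fallback` (`NA`, `"narrow-support"` or
#'   `"zero-complexity"`), and the grid `sweep` (`NULL` when the guard
#'   engaged before the sweep).
#' @export
select_threshold <- function(pr, lmax = 3L, alpha = 0.01, test = "ks",
                             n_grid = 41L,
                             grid_quantiles = c(0.05, 0.95),
                             support_quantiles = c(0.005, 0.995),
                             min_support = 0.2) {
  if (length(pr) < 1000L)
    stop("threshold selection needs at least 1000 responses", call. = FALSE)
  if (diff(range(pr)) < 1e-12)
    stop("narrow-support guard: constant response sequence has no partition",
         call. = FALSE)
  supp <- unname(stats::quantile(pr, support_quantiles, names = FALSE))
  fallback_at <- function(reason, sweep) {
    th <- clamp01(mean(supp))
    m <- cssr(binarize(pr, th), lmax = lmax, alpha = alpha, test = test)
    structure(list(theta = th, machine = m,
                   cmu_bits = statistical_complexity(m),
                   fallback = reason, sweep = sweep),
              class = "threshold_selection")
  }
  if (diff(supp) < min_support)
    return(fallback_at("narrow-support", NULL))

  qs <- unname(stats::quantile(pr, grid_quantiles, names = FALSE))
  thetas <- clamp01(seq(qs[1], qs[2], length.out = n_grid))
  thetas <- unique(thetas)
  sweep <- threshold_sweep(pr, thetas, lmax = lmax, alpha = alpha,
                           test = test)
  if (max(sweep$cmu_bits) <= 0)
    return(fallback_at("zero-complexity", sweep))
  ## A machine whose topology appears at a single grid point is sampling
  ## noise being resolved, not structure: restrict the maximization to
  ## candidates whose topology persists over a finite threshold interval
  ## (a run of at least `min_run` adjacent grid points).
  robust <- robust_candidates(attr(sweep, "machines"))
  pool <- if (any(robust)) which(robust) else seq_len(nrow(sweep))
  best <- pool[sweep$cmu_bits[pool] >= max(sweep$cmu_bits[pool]) - 1e-9]
  med <- stats::median(pr)
  pick <- best[which.min(abs(sweep$theta[best] - med))]
  structure(list(theta = sweep$theta[pick],
                 machine = attr(sweep, "machines")[[pick]],
                 cmu_bits = sweep$cmu_bits[pick],
                 fallback = NA_character_, sweep = sweep),
            class = "threshold_selection")
}

# Flags sweep entries lying in a maximal run of >= min_run adjacent,
# topologically equal machines.
robust_candidates <- function(machines, min_run = 3L) {
  k <- length(machines)
  if (k == 0L) return(logical(0))
  same <- vapply(seq_len(k - 1L), function(i)
    topologically_equal(machines[[i]], machines[[i + 1L]]), logical(1))
  run_id <- cumsum(c(TRUE, !same))
  run_len <- table(run_id)[as.character(run_id)]
  as.vector(run_len) >= min_run
}

clamp01 <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("threshold = %.4f (Cmu = %.4f bits, %d states%s)\n",
              x$theta, x$cmu_bits, n_states(x$machine),
              if (!is.na(x$fallback))
                paste0("; fallback: ", x$fallback) else ""))
  invisible(x)
}

#' Write a symbol sequence as a plain-text 0/1 line
#' @param symbols a [binarize()] result or 0/1 vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_symbols <- function(symbols, path) {
  writeLines(paste(as_symbols(symbols), collapse = ""), path)
  invisible(path)
}
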