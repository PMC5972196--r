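#' Next-symbol morph counts
#'
#' Tabulates, for every suffix (history) of length 0..`L` occurring in a
#' binary sequence, how often each symbol follows it.  Each length is counted
#' independently over the whole sequence: a suffix of length `l` is counted
#' at every position with at least `l` symbols of history (the empty suffix
#' is counted over the transition positions `2..n`, so its counts equal the
#' sum of its one-symbol extensions exactly).
#'
#' @param symbols integer/numeric vector over \{0, 1\} (or a
#'   [binarize()] result).
#' @param L maximum suffix length; must be smaller than the sequence length.
#' @return A matrix of class `morph_table` with one row per observed suffix
#'   (row name is the suffix string, oldest symbol first; `""` is the empty
#'   suffix) and columns `n0`, `n1`.
#' @export
#' @examples
#' count_morphs(c(0,0,1,1,1,0,0,1,0,0), 1)
count_morphs <- function(symbols, L) {
  s <- as_symbols(symbols)
  n <- length(s)
  L <- as.integer(L)
  if (L < 1L) stop("'L' must be a positive integer", call. = FALSE)
  if (L >= n) stop("'L' must be smaller than the sequence length",
                   call. = FALSE)
  blocks <- vector("list", L + 1L)
  for (l in 0:L) {
    pos <- (max(l, 1L) + 1L):n        # positions of the next symbol
    nxt <- s[pos]
    code <- integer(length(pos))
    if (l > 0) for (j in 1:l) code <- code * 2L + s[pos - (l - j + 1L)]
    cnt <- tabulate(code * 2L + nxt + 1L, nbins = 2L^(l + 1L))
    mat <- matrix(cnt, ncol = 2L, byrow = TRUE,
                  dimnames = list(suffix_strings(l), c("n0", "n1")))
    blocks[[l + 1L]] <- mat[rowSums(mat) > 0, , drop = FALSE]
  }
  out <- do.call(rbind, blocks)
  attr(out, "L") <- L
  class(out) <- c("morph_table", class(out))
  out
}

# All binary strings of length l, in code order (oldest symbol first).
suffix_strings <- function(l) {
  if (l == 0L) return("")
  codes <- 0:(2L^l - 1L)
  vapply(codes, function(k)
    paste((k %/% 2L^((l - 1L):0)) %% 2L, collapse = ""), character(1))
}

as_symbols <- function(symbols) {
  s <- as.integer(symbols)
  if (length(s) == 0L || anyNA(s) || any(s != 0L & s != 1L))
    stop("symbol sequences must be over the alphabet {0, 1}", call. = FALSE)
  s
}

# Asymptotic two-sided Kolmogorov Q-function (the p-value tail used by the
# classical two-sample KS test).  The alternating series is only summed for
# lambda >= 0.2, where it converges rapidly; below that Q(lambda) = 1 to
# within 1e-12.
ks_q <- function(lambda) {
  if (lambda < 0.2) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# P-value for the hypothesis that two next-symbol count vectors c(n0, n1)
# come from the same distribution.  "ks": two-sample KS on the binary
# samples (the statistic reduces to |p1 - p2|); "chisq": Pearson chi-squared
# on the 2x2 table.
morph_test_p <- function(c1, c2, test = "ks") {
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 == 0 || n2 == 0) return(1)
  if (test == "ks") {
    D <- abs(c1[2] / n1 - c2[2] / n2)
    ks_q(sqrt(n1 * n2 / (n1 + n2)) * D)
  } else {
    tab <- rbind(c1, c2)
    keep <- colSums(tab) > 0
    if (sum(keep) < 2L) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Advisory maximum history length for CSSR
#'
#' The rule of thumb relating data size to the longest history CSSR can
#' estimate reliably: the largest `L` with
#' `alphabet_size^L / (N - L) <= alpha`.  Returns an error when no `L >= 1`
#' qualifies (insufficient data).
#'
#' @param N sequence length.
#' @param alpha significance level in (0, 1).
#' @param alphabet_size alphabet size (2 for binary).
#' @return largest admissible integer `L`.
#' @export
#' @examples
#' lmax_heuristic(1e5, 0.01) # 9
lmax_heuristic <- function(N, alpha, alphabet_size = 2L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (N <= 2) stop("'N' must exceed 2", call. = FALSE)
  L <- 0L
  while (alphabet_size^(L + 1L) / (N - (L + 1L)) <= alpha) L <- L + 1L
  if (L == 0L)
    stop("insufficient data: no history length satisfies the criterion",
         call. = FALSE)
  L
}

#' Reconstruct an epsilon machine with CSSR
#'
#' From-scratch Causal State Splitting Reconstruction.  Starting from a
#' single state holding the empty history, histories are extended one symbol
#' at a time up to length `lmax`; each extended history's next-symbol
#' distribution (morph) is tested against its state's pooled morph at
#' significance `alpha`.  A history whose morph differs significantly is
#' moved to the existing state with the most compatible morph (largest
#' p-value), or founds a new state when every state rejects.  The state
#' partition is then determinized (states are split until the successor
#' state under each emitted symbol is unique, giving a unifilar machine) and
#' transient states are dropped, keeping the recurrent strongly connected
#' component with the largest share of the data.  Transition probabilities
#' are maximum-likelihood ratios of the pooled full-length suffix counts and
#' the stationary distribution is the left fixed vector of the
#' symbol-summed transition matrix.
#'
#' @param symbols binary sequence (a [binarize()] result or plain 0/1
#'   vector).
#' @param lmax maximum history length (default 3).
#' @param alpha significance level for the splitting test (default 0.01).
#' @param test `"ks"` (two-sample Kolmogorov-Smirnov, default) or `"chisq"`.
#' @return An object of class `epsilon_machine`; see [epsilon_machine()].
#' @seealso [statistical_complexity()], [validate_machine()],
#'   [lmax_heuristic()]
#' @export
#' @examples
#' set.seed(1)
#' m <- cssr(rbinom(2e4, 1, 0.7), lmax = 3)
#' m # a single-state machine: an i.i.d. process has no causal structure
cssr <- function(symbols, lmax = 3L, alpha = 0.01, test = c("ks", "chisq")) {
  test <- match.arg(test)
  s <- as_symbols(symbols)
  lmax <- as.integer(lmax)
  if (lmax < 1L) stop("'lmax' must be a positive integer", call. = FALSE)
  if (length(s) <= lmax + 1L)
    stop("sequence too short for the requested history length", call. = FALSE)
  mt <- count_morphs(s, lmax)
  cnt <- function(sufs) {
    rows <- mt[match(sufs, rownames(mt)), , drop = FALSE]
    colSums(rows)
  }

  ## Phase I: grow histories, split on significant morph differences
  ## (the null suffix cannot be a vector name, so suffixes and their state
  ## ids live in parallel vectors addressed with match())
  sufs <- ""
  st_of <- 1L
  state_counts <- matrix(cnt(""), nrow = 1)
  for (l in 0:(lmax - 1L)) {
    level <- sort(sufs[nchar(sufs) == l])
    for (suf in level) {
      for (a in c("0", "1")) {
        child <- paste0(a, suf)
        if (is.na(match(child, rownames(mt)))) next
        ccnt <- mt[child, ]
        parent_st <- st_of[match(suf, sufs)]
        p_parent <- morph_test_p(ccnt, state_counts[parent_st, ], test)
        if (p_parent >= alpha) {
          target <- parent_st
        } else {
          others <- setdiff(seq_len(nrow(state_counts)), parent_st)
          pvals <- vapply(others, function(st)
            morph_test_p(ccnt, state_counts[st, ], test), numeric(1))
          if (length(others) && max(pvals) >= alpha) {
            target <- others[which.max(pvals)]
          } else {
            state_counts <- rbind(state_counts, 0)
            target <- nrow(state_counts)
          }
        }
        sufs <- c(sufs, child)
        st_of <- c(st_of, target)
        state_counts[target, ] <- state_counts[target, ] + ccnt
      }
    }
  }

  ## Phase II: determinize (unifilarity refinement)
  succ_suffix <- function(suf, a) {
    if (mt[match(suf, rownames(mt)), paste0("n", a)] == 0) return(NA_integer_)
    y <- paste0(suf, a)
    if (nchar(y) > lmax) y <- substr(y, 2L, nchar(y))
    while (is.na(match(y, sufs)) && nchar(y) > 0L) y <- substr(y, 2L, nchar(y))
    st_of[match(y, sufs)]
  }
  repeat {
    succ0 <- vapply(sufs, succ_suffix, integer(1), a = "0")
    succ1 <- vapply(sufs, succ_suffix, integer(1), a = "1")
    changed <- FALSE
    for (st in unique(st_of)) {
      member <- which(st_of == st)
      if (length(member) < 2L) next
      ## group members whose defined successors agree; NA acts as wildcard
      ndef <- (!is.na(succ0[member])) + (!is.na(succ1[member]))
      member <- member[order(-ndef, sufs[member])]
      groups <- list()
      for (mb in member) {
        placed <- FALSE
        for (g in seq_along(groups)) {
          rep0 <- groups[[g]]$s0; rep1 <- groups[[g]]$s1
          ok0 <- is.na(succ0[mb]) || is.na(rep0) || succ0[mb] == rep0
          ok1 <- is.na(succ1[mb]) || is.na(rep1) || succ1[mb] == rep1
          if (ok0 && ok1) {
            groups[[g]]$members <- c(groups[[g]]$members, mb)
            if (is.na(rep0)) groups[[g]]$s0 <- succ0[mb]
            if (is.na(rep1)) groups[[g]]$s1 <- succ1[mb]
            placed <- TRUE
            break
          }
        }
        if (!placed)
          groups[[length(groups) + 1L]] <-
            list(members = mb, s0 = succ0[mb], s1 = succ1[mb])
      }
      if (length(groups) > 1L) {
        for (g in 2:length(groups))
          st_of[groups[[g]]$members] <- max(st_of) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ## Phase III: build the machine over recurrent states
  build_machine(sufs, st_of, mt, lmax, alpha, test, length(s))
}

# Assemble an epsilon_machine from a suffix -> state assignment.
build_machine <- function(sufs, st_of, mt, lmax, alpha, test, n_obs) {
  ids <- sort(unique(st_of))
  succ_of <- function(suf, a) {
    if (mt[match(suf, rownames(mt)), paste0("n", a)] == 0) return(NA_integer_)
    y <- paste0(suf, a)
    if (nchar(y) > lmax) y <- substr(y, 2L, nchar(y))
    while (is.na(match(y, sufs)) && nchar(y) > 0L) y <- substr(y, 2L, nchar(y))
    st_of[match(y, sufs)]
  }
  info <- lapply(ids, function(st) {
    member <- sufs[st_of == st]
    full <- member[nchar(member) == lmax]
    basis <- if (length(full)) full else member[nchar(member) ==
                                                  max(nchar(member))]
    counts <- colSums(mt[match(basis, rownames(mt)), , drop = FALSE])
    s0 <- stats::na.omit(vapply(basis, succ_of, integer(1), a = "0"))[1]
    s1 <- stats::na.omit(vapply(basis, succ_of, integer(1), a = "1"))[1]
    list(id = st, suffixes = member, counts = counts,
         succ = c(`0` = unname(s0), `1` = unname(s1)))
  })
  names(info) <- as.character(ids)

  ## recurrent component: sink SCC carrying the most data
  edges <- do.call(rbind, lapply(info, function(x) {
    to <- x$succ[!is.na(x$succ)]
    if (!length(to)) return(NULL)
    cbind(from = x$id, to = unname(to))
  }))
  if (is.null(edges)) stop("degenerate machine: no transitions", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g, mode = "strong")$membership
  sinks <- vapply(seq_len(max(comp)), function(k) {
    members <- ids[comp == k]
    outs <- edges[edges[, 1] %in% members, 2]
    all(outs %in% members)
  }, logical(1))
  mass <- vapply(seq_len(max(comp)), function(k)
    sum(vapply(info[as.character(ids[comp == k])],
               function(x) sum(x$counts), numeric(1))), numeric(1))
  mass[!sinks] <- -Inf
  keep <- ids[comp == which.max(mass)]

  info <- info[as.character(keep)]
  relabel <- stats::setNames(seq_along(keep) - 1L, as.character(keep))
  states <- lapply(info, function(x) {
    tot <- sum(x$counts)
    list(id = unname(relabel[as.character(x$id)]),
         suffixes = sort(x$suffixes),
         morph = if (tot > 0) unname(x$counts / tot) else c(NA, NA))
  })
  trans <- do.call(rbind, lapply(info, function(x) {
    tot <- sum(x$counts)
    rows <- lapply(c(0L, 1L), function(a) {
      pr <- x$counts[[a + 1L]] / tot
      to <- x$succ[[as.character(a)]]
      if (pr <= 0 || is.na(to) || !(to %in% keep)) return(NULL)
      data.frame(from = unname(relabel[as.character(x$id)]), symbol = a,
                 to = unname(relabel[as.character(to)]), prob = pr)
    })
    do.call(rbind, rows)
  }))
  rownames(trans) <- NULL
  m <- new_epsilon_machine(states, trans, lmax = lmax, alpha = alpha,
                           test = test, n_obs = n_obs)
  ## canonical labels: state 0 is the most visited state
  relabel_by_pi(m)
}

new_epsilon_machine <- function(states, trans, lmax = NA_integer_,
                                alpha = NA_real_, test = NA_character_,
                                n_obs = NA_integer_) {
  states <- states[order(vapply(states, `[[`, integer(1), "id"))]
  names(states) <- vapply(states, `[[`, integer(1), "id")
  m <- structure(list(states = states, trans = trans, pi = NULL,
                      cmu = NA_real_, lmax = lmax, alpha = alpha,
                      test = test, n_obs = n_obs),
                 class = "epsilon_machine")
  m$pi <- tryCatch(stationary_distribution(m), error = function(e) NULL)
  if (!is.null(m$pi)) m$cmu <- -sum(ifelse(m$pi > 0, m$pi * log2(m$pi), 0)) + 0
  m
}

relabel_by_pi <- function(m) {
  if (is.null(m$pi)) return(m)
  ids <- vapply(m$states, `[[`, integer(1), "id")
  key <- vapply(m$states, function(s) paste(s$suffixes, collapse = ","),
                character(1))
  ord <- order(-m$pi, key)
  relabel <- stats::setNames(seq_along(ids) - 1L, ids[ord])
  states <- lapply(m$states[ord], function(s) {
    s$id <- unname(relabel[as.character(s$id)]); s
  })
  trans <- m$trans
  trans$from <- unname(relabel[as.character(trans$from)])
  trans$to <- unname(relabel[as.character(trans$to)])
  trans <- trans[order(trans$from, trans$symbol), ]
  rownames(trans) <- NULL
  new_epsilon_machine(states, trans, lmax = m$lmax, alpha = m$alpha,
                      test = m$test, n_obs = m$n_obs)
}

#' Build an epsilon machine by hand
#'
#' Constructor for unifilar hidden Markov models over the binary alphabet,
#' used for simulation oracles and machine comparison.  States are numbered
#' `0..k-1`; each row of `trans` gives one labeled edge.
#'
#' @param trans data frame with columns `from`, `symbol` (0 or 1), `to`,
#'   `prob`.
#' @param suffixes optional list (one character vector per state) of history
#'   suffixes, as produced by [cssr()].
#' @return An `epsilon_machine` with the stationary distribution and
#'   statistical complexity filled in when the transition structure is
#'   irreducible.
#' @export
#' @examples
#' # the period-2 alternator: two states exchanging 0s and 1s
#' alt <- epsilon_machine(data.frame(from = c(0, 1), symbol = c(1, 0),
#'                                   to = c(1, 0), prob = c(1, 1)))
#' statistical_complexity(alt) # 1 bit
epsilon_machine <- function(trans, suffixes = NULL) {
  stopifnot(is.data.frame(trans),
            all(c("from", "symbol", "to", "prob") %in% names(trans)))
  ids <- sort(unique(c(trans$from, trans$to)))
  states <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    out <- trans[trans$from == id, ]
    morph <- c(sum(out$prob[out$symbol == 0]), sum(out$prob[out$symbol == 1]))
    list(id = as.integer(id),
         suffixes = if (is.null(suffixes)) character(0) else suffixes[[i]],
         morph = morph)
  })
  trans$from <- as.integer(trans$from); trans$to <- as.integer(trans$to)
  trans$symbol <- as.integer(trans$symbol)
  new_epsilon_machine(states, trans)
}

#' Number of causal states
#' @param m an `epsilon_machine`.
#' @return integer state count.
#' @export
n_states <- function(m) {
  stopifnot(inherits(m, "epsilon_machine"))
  length(m$states)
}

#' Stationary distribution of an epsilon machine
#'
#' Left fixed vector of the symbol-summed transition matrix, normalized to
#' sum to 1.  Requires an irreducible (single strongly connected component)
#' transition structure.
#'
#' @param m an `epsilon_machine`.
#' @return numeric vector, one probability per state (in state-id order).
#' @export
stationary_distribution <- function(m) {
  stopifnot(inherits(m, "epsilon_machine"))
  k <- length(m$states)
  ids <- vapply(m$states, `[[`, integer(1), "id")
  if (k == 1L) return(stats::setNames(1, ids))
  A <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(nrow(m$trans)))
    A[as.character(m$trans$from[i]), as.character(m$trans$to[i])] <-
      A[as.character(m$trans$from[i]), as.character(m$trans$to[i])] +
      m$trans$prob[i]
  if (any(abs(rowSums(A) - 1) > 1e-8))
    stop("transition rows must be stochastic", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(A > 0)
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("reducible transition structure: stationary distribution not unique",
         call. = FALSE)
  e <- eigen(t(A))
  j <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, j])
  v <- pmax(v / sum(v), 0)
  stats::setNames(v / sum(v), ids)
}

#' Statistical complexity of an epsilon machine
#'
#' Shannon entropy, in bits, of the stationary distribution over causal
#' states.  Zero if and only if the machine has a single state.
#'
#' @param m an `epsilon_machine`.
#' @return non-negative scalar (bits).
#' @export
statistical_complexity <- function(m) {
  stopifnot(inherits(m, "epsilon_machine"))
  pi <- if (is.null(m$pi)) stationary_distribution(m) else m$pi
  -sum(ifelse(pi > 0, pi * log2(pi), 0)) + 0
}

#' Validate a reconstructed machine
#'
#' Applies the acceptance rule for CSSR output: every state must contain at
#' least one history of the full length `lmax` (otherwise the history length
#' was too long for the data), the machine must be unifilar (at most one
#' outgoing edge per state and symbol), and each state's outgoing
#' probabilities must sum to 1.  Optionally checks state morphs against a
#' [count_morphs()] table.
#'
#' @param m an `epsilon_machine`.
#' @param morphs optional `morph_table` for a consistency check of state
#'   morphs against pooled suffix counts.
#' @param lmax history length to check against; defaults to the machine's.
#' @return list with `valid` (logical) and `diagnostics` (character vector
#'   naming each violation, empty when valid).
#' @export
validate_machine <- function(m, morphs = NULL, lmax = m$lmax) {
  stopifnot(inherits(m, "epsilon_machine"))
  diag <- character(0)
  if (!is.na(lmax)) {
    for (s in m$states)
      if (!any(nchar(s$suffixes) == lmax))
        diag <- c(diag, sprintf("short-state: state %d has no length-%d suffix",
                                s$id, lmax))
  }
  if (anyDuplicated(m$trans[, c("from", "symbol")]))
    diag <- c(diag, "unifilarity: a state emits one symbol along several edges")
  sums <- tapply(m$trans$prob, m$trans$from, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-8]
  if (length(bad))
    diag <- c(diag, sprintf("stochasticity: outgoing probabilities of state %s do not sum to 1",
                            paste(bad, collapse = ", ")))
  if (!is.null(morphs)) {
    for (s in m$states) {
      basis <- s$suffixes[nchar(s$suffixes) == lmax]
      if (!length(basis)) next
      counts <- colSums(morphs[match(basis, rownames(morphs)), , drop = FALSE])
      if (sum(counts) > 0 &&
          max(abs(counts / sum(counts) - s$morph)) > 1e-8)
        diag <- c(diag, sprintf("morph: state %d morph disagrees with pooled counts",
                                s$id))
    }
  }
  list(valid = length(diag) == 0L, diagnostics = diag)
}

#' Structural equality of two machines
#'
#' Tests whether a bijection between the state sets exists that preserves
#' every symbol-labeled edge (transition probabilities are ignored), i.e.
#' whether the machines share their graph topology.
#'
#' @param m1,m2 `epsilon_machine` objects.
#' @return `TRUE` or `FALSE`.
#' @export
topologically_equal <- function(m1, m2) {
  stopifnot(inherits(m1, "epsilon_machine"), inherits(m2, "epsilon_machine"))
  k <- length(m1$states)
  if (k != length(m2$states) || nrow(m1$trans) != nrow(m2$trans))
    return(FALSE)
  succ <- function(m) {
    ids <- vapply(m$states, `[[`, integer(1), "id")
    out <- matrix(NA_integer_, length(ids), 2, dimnames = list(ids, 0:1))
    for (i in seq_len(nrow(m$trans)))
      out[as.character(m$trans$from[i]), m$trans$symbol[i] + 1L] <-
        match(m$trans$to[i], ids)
    out
  }
  s1 <- succ(m1); s2 <- succ(m2)
  perm <- rep(NA_integer_, k)  # perm[i] = state of m2 matched to state i of m1
  used <- rep(FALSE, k)
  compatible <- function(i, j) {
    for (a in 1:2) {
      t1 <- s1[i, a]; t2 <- s2[j, a]
      if (is.na(t1) != is.na(t2)) return(FALSE)
      if (!is.na(t1) && !is.na(perm[t1]) && perm[t1] != t2) return(FALSE)
    }
    TRUE
  }
  assign_next <- function(i) {
    if (i > k) return(TRUE)
    for (j in which(!used)) {
      if (!compatible(i, j)) next
      perm[i] <<- j; used[j] <<- TRUE
      ## full consistency check over edges decided so far
      ok <- all(vapply(seq_len(i), function(ii) compatible(ii, perm[ii]),
                       logical(1)))
      if (ok && assign_next(i + 1L)) return(TRUE)
      perm[i] <<- NA_integer_; used[j] <<- FALSE
    }
    FALSE
  }
  assign_next(1L)
}

#' Simulate a symbol sequence from an epsilon machine
#'
#' Generates symbols by walking the machine: in each state a symbol is drawn
#' from the state's emission probabilities and the unifilar transition is
#' followed.  Used as an oracle to check that [cssr()] recovers known
#' machines.
#'
#' @param m an `epsilon_machine`.
#' @param n number of symbols.
#' @param seed optional integer seed.
#' @param init initial state id; defaults to a draw from the stationary
#'   distribution.
#' @return integer vector of 0/1 symbols.
#' @export
simulate_machine <- function(m, n, seed = NULL, init = NULL) {
  stopifnot(inherits(m, "epsilon_machine"))
  ids <- vapply(m$states, `[[`, integer(1), "id")
  emit <- lapply(ids, function(id) {
    out <- m$trans[m$trans$from == id, ]
    out[order(out$symbol), ]
  })
  names(emit) <- ids
  with_seed(seed, {
    state <- if (is.null(init)) {
      pi <- if (is.null(m$pi)) stationary_distribution(m) else m$pi
      sample(ids, 1, prob = pi)
    } else init
    out <- integer(n)
    for (i in seq_len(n)) {
      e <- emit[[as.character(state)]]
      r <- if (nrow(e) == 1L) 1L else
        sample.int(nrow(e), 1, prob = e$prob)
      out[i] <- e$symbol[r]
      state <- e$to[r]
    }
    out
  })
}

#' @export
print.epsilon_machine <- function(x, ...) {
  k <- length(x$states)
  cat(sprintf("epsilon machine: %d causal state%s, Cmu = %.4f bits\n",
              k, if (k == 1) "" else "s", statistical_complexity(x)))
  if (!is.na(x$lmax))
    cat(sprintf("  reconstructed with Lmax = %d, alpha = %g, %s test, n = %d\n",
                x$lmax, x$alpha, toupper(x$test), x$n_obs))
  for (i in seq_len(nrow(x$trans)))
    cat(sprintf("  %d --[%d | %.3f]--> %d\n", x$trans$from[i],
                x$trans$symbol[i], x$trans$prob[i], x$trans$to[i]))
  invisible(x)
}
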