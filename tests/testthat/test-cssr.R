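test_that("morph counts match hand enumeration and nesting identities", {
  s <- c(0, 0, 1, 1, 1, 0, 0, 1, 0, 0)   # "0011100100"
  mt <- count_morphs(s, 1)
  expect_equal(unname(mt["0", ]), c(3, 2))
  expect_equal(unname(mt["1", ]), c(2, 2))
  # the empty suffix morph is the marginal over transition positions
  expect_equal(unname(mt[1, ]), unname(mt["0", ] + mt["1", ]))

  set.seed(41)
  for (i in 1:5) {
    r <- rbinom(500, 1, 0.4)
    m <- count_morphs(r, 2)
    # suffix "0" counts = "00" + "10" counts up to the first-position boundary
    boundary <- as.integer(r[1] == 0) * c(r[2] == 0, r[2] == 1)
    expect_equal(unname(m["0", ]),
                 unname(m["00", ] + m["10", ] + boundary))
  }
  expect_error(count_morphs(c(0, 1, 2), 1), "alphabet")
  expect_error(count_morphs(c(0, 1), 2), "smaller")
})

test_that("an i.i.d. process reconstructs to the single-state machine", {
  set.seed(42)
  m <- cssr(rbinom(1e5, 1, 0.7), lmax = 3, alpha = 0.01)
  expect_identical(n_states(m), 1L)
  expect_equal(statistical_complexity(m), 0)
  p1 <- m$trans$prob[m$trans$symbol == 1]
  expect_equal(p1, 0.7, tolerance = 0.01 / 0.7)
})

test_that("strict alternation reconstructs to the period-2 machine", {
  m <- cssr(rep(c(0L, 1L), 5000), lmax = 3)
  expect_identical(n_states(m), 2L)
  expect_equal(sort(m$trans$prob), c(1, 1))
  expect_equal(statistical_complexity(m), 1)
  expect_true(topologically_equal(m, alternator_machine()))
})

test_that("the golden-mean generator is recovered within tight tolerance", {
  gm <- golden_mean_machine()
  m <- cssr(simulate_machine(gm, 1e5, seed = 43), lmax = 3)
  expect_identical(n_states(m), 2L)
  expect_true(topologically_equal(m, gm))
  expect_true(validate_machine(m)$valid)
  # match edge probabilities through the topology map: the state with the
  # self-loop on 0 is the low state
  low <- m$trans$from[m$trans$symbol == 0 & m$trans$from == m$trans$to]
  probs <- m$trans[m$trans$from == low, ]
  expect_equal(probs$prob[order(probs$symbol)], c(0.5, 0.5),
               tolerance = 0.02 / 0.5)
})

test_that("reconstruction is deterministic and relabel-invariant", {
  seq1 <- simulate_machine(switching_machine(0.3, 0.6), 2e4, seed = 44)
  expect_identical(cssr(seq1, 3), cssr(seq1, 3))
  # relabeled generators are topologically identical machines
  g1 <- switching_machine(0.3, 0.6)
  g2 <- epsilon_machine(data.frame(from = c(1, 1, 0, 0),
                                   symbol = c(0, 1, 1, 0),
                                   to = c(1, 0, 0, 1),
                                   prob = c(0.7, 0.3, 0.4, 0.6)))
  expect_true(topologically_equal(g1, g2))
})

test_that("known small generators are recovered across many seeds", {
  gens <- list(golden_mean_machine(), switching_machine(0.25, 0.65))
  for (gen in gens) {
    hits <- vapply(1:10, function(sd) {
      m <- cssr(simulate_machine(gen, 5e4, seed = 100 + sd), lmax = 3)
      n_states(m) == n_states(gen) && topologically_equal(m, gen)
    }, logical(1))
    expect_gte(sum(hits), 9)
  }
})

test_that("stationary distributions solve the balance equations", {
  one <- cssr(rbinom(5000, 1, 0.5), lmax = 2)
  expect_equal(unname(stationary_distribution(one)), 1)
  expect_equal(unname(stationary_distribution(switching_machine(0.4, 0.4))),
               c(0.5, 0.5))
  a <- 0.3; b <- 0.1
  expect_equal(unname(stationary_distribution(switching_machine(a, b))),
               c(b / (a + b), a / (a + b)))
  # reducible structure is rejected
  red <- suppressWarnings(epsilon_machine(
    data.frame(from = c(0, 1), symbol = c(0, 1), to = c(0, 1),
               prob = c(1, 1))))
  expect_error(stationary_distribution(red), "reducible")
})

test_that("statistical complexity is the entropy of the state distribution", {
  expect_equal(statistical_complexity(alternator_machine()), 1)
  cyc4 <- epsilon_machine(data.frame(from = 0:3, symbol = 1,
                                     to = c(1, 2, 3, 0), prob = 1))
  expect_equal(statistical_complexity(cyc4), 2)
  expect_equal(statistical_complexity(golden_mean_machine()),
               entropy_bits(c(2 / 3, 1 / 3)))
})

test_that("the history-length heuristic implements the data-size relation", {
  expect_identical(lmax_heuristic(1e5, 0.01), 9L)
  expect_error(lmax_heuristic(100, 0.01), "insufficient")
  expect_error(lmax_heuristic(1e4, 1.5), "alpha")
  ls <- vapply(c(1e3, 1e4, 1e5, 1e6), lmax_heuristic, integer(1),
               alpha = 0.01)
  expect_true(all(diff(ls) >= 0))
})

test_that("machine validation names each violation", {
  good <- cssr(simulate_machine(golden_mean_machine(), 2e4, seed = 45), 3)
  v <- validate_machine(good)
  expect_true(v$valid)
  expect_length(v$diagnostics, 0)

  short <- epsilon_machine(data.frame(from = c(0, 0, 1), symbol = c(0, 1, 0),
                                      to = c(0, 1, 0), prob = c(0.5, 0.5, 1)),
                           suffixes = list("0", "1"))
  vs <- validate_machine(short, lmax = 3)
  expect_false(vs$valid)
  expect_match(vs$diagnostics, "short-state", all = FALSE)

  nonuni <- epsilon_machine(data.frame(from = c(0, 0, 1), symbol = c(1, 1, 0),
                                       to = c(0, 1, 0), prob = c(0.5, 0.5, 1)))
  vn <- validate_machine(nonuni, lmax = NA)
  expect_false(vn$valid)
  expect_match(vn$diagnostics, "unifilarity", all = FALSE)
})

test_that("topological equality is permutation matching of labeled edges", {
  gm <- golden_mean_machine()
  expect_true(topologically_equal(gm, gm))
  one <- cssr(rbinom(5000, 1, 0.5), lmax = 2)
  expect_false(topologically_equal(one, gm))
  expect_false(topologically_equal(alternator_machine(), gm))
  expect_true(topologically_equal(switching_machine(0.2, 0.9),
                                  switching_machine(0.7, 0.1)))
})

test_that("machines serialize to the JSON schema and DOT", {
  m <- switching_machine(0.3, 0.1)
  js <- jsonlite::fromJSON(machine_json(m))
  expect_named(js, c("states", "transitions", "Cmu"))
  expect_equal(nrow(js$transitions), 4)
  expect_equal(sum(js$states$pi), 1, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".dot")
  write_machine_dot(m, path)
  txt <- readLines(path)
  expect_match(txt[1], "digraph")
  expect_match(txt, "1 \\| 0.300", all = FALSE)
})
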