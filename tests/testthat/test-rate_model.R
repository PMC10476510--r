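test_that("Q has the published DEC structure", {
  sp <- enumerate_ranges(3, 2)
  d <- 0.013; e <- 0.021
  m <- matrix(runif(9, 0.5, 2), 3, 3)
  Q <- build_q(sp, dec_params(d, e), m)

  # expansion {1} -> {1,2} at rate d * m[1,2]
  expect_equal(Q["1", "1+2"], d * m[1, 2])
  expect_equal(Q["1", "1+3"], d * m[1, 3])
  # contraction {1,2} -> {1} loses area 2 at the shared extinction rate
  expect_equal(Q["1+2", "1"], e)
  expect_equal(Q["1+2", "2"], e)
  # single-area ranges reach the null range at rate e; null is absorbing
  expect_equal(Q["2", "0"], e)
  expect_true(all(Q["0", ] == 0))
  # no multi-step transitions
  expect_equal(Q["1", "2+3"], 0)
  expect_equal(Q["1+2", "1+3"], 0)
  expect_equal(Q["1+2", "0"], 0)
  # multi-area sources sum their multipliers (needs max_size 3)
  sp3 <- enumerate_ranges(3, 3)
  Q3 <- build_q(sp3, dec_params(d, e), m)
  expect_equal(Q3["1+2", "1+2+3"], d * (m[1, 3] + m[2, 3]))

  # zero rates give the zero matrix
  expect_true(all(build_q(sp, dec_params(0, 0)) == 0))
})

test_that("Q rows sum to zero and scale linearly in the rates", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:5, 1)
    sp <- enumerate_ranges(n, min(n, sample(1:3, 1)))
    d <- runif(1); e <- runif(1)
    m <- matrix(runif(n * n), n, n)
    Q <- build_q(sp, dec_params(d, e), m)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q - diag(diag(Q)) >= 0))
    # scaling invariance
    Q2 <- build_q(sp, dec_params(3 * d, 3 * e), m)
    expect_equal(Q2, 3 * Q, tolerance = 1e-12)
  }
  # with unit multipliers, expansion rate from R into a is d * |R|
  sp <- enumerate_ranges(4, 3)
  Q <- build_q(sp, dec_params(0.2, 0))
  expect_equal(Q["1+2", "1+2+3"], 0.2 * 2)
  expect_equal(Q["1", "1+4"], 0.2 * 1)
})

test_that("transition probabilities are stochastic and satisfy the semigroup law", {
  sp <- enumerate_ranges(3, 2)
  Q <- build_q(sp, dec_params(0.1, 0.07))
  expect_equal(transition_probabilities(Q, 0), diag(7), ignore_attr = TRUE)
  P5 <- transition_probabilities(Q, 5)
  expect_lt(max(abs(rowSums(P5) - 1)), 1e-10)
  expect_true(all(P5 >= 0 & P5 <= 1))
  # P(s + t) = P(s) P(t)
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(9), 3, 3)
    Q <- build_q(sp, dec_params(runif(1, 0, 0.5), runif(1, 0, 0.5)), m)
    s <- runif(1, 0, 8); t <- runif(1, 0, 8)
    expect_equal(transition_probabilities(Q, s + t),
                 transition_probabilities(Q, s) %*% transition_probabilities(Q, t),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # cross-check the exponential against an independent routine
  Q <- build_q(sp, dec_params(0.3, 0.2))
  expect_equal(transition_probabilities(Q, 2.5), ape::matexpo(Q * 2.5),
               tolerance = 1e-10, ignore_attr = TRUE)
  # closed form for the 2-state pure-death chain
  sp1 <- enumerate_ranges(1, 1)
  Q1 <- build_q(sp1, dec_params(0, 0.13))
  expect_equal(transition_probabilities(Q1, 4)["1", "0"],
               1 - exp(-0.13 * 4), tolerance = 1e-12)
  expect_error(transition_probabilities(Q, -1), "non-negative")
})

test_that("epoch matrices honor availability masks", {
  areas <- dec_areas(c("A", "B", "C"))
  ep <- epoch_stratification(c(Inf, 4), c(4, 0),
                             rbind(c(TRUE, TRUE, FALSE), rep(TRUE, 3)),
                             areas$code)
  mod <- dec_model(areas, epochs = ep, name = "strat")
  Qs <- epoch_matrices(mod, dec_params(0.1, 0.05))
  expect_length(Qs, 2)
  # no expansion into the unavailable area C in the old epoch
  expect_equal(Qs[[1]]["A", "A+C"], 0)
  expect_equal(Qs[[1]]["B", "B+C"], 0)
  expect_gt(Qs[[2]]["A", "A+C"], 0)
  # contraction out of C still possible (stranded lineages can die back)
  expect_equal(Qs[[1]]["A+C", "A"], 0.05)
  # identical masks give identical matrices
  ep2 <- epoch_stratification(c(Inf, 4), c(4, 0),
                              rbind(rep(TRUE, 3), rep(TRUE, 3)), areas$code)
  Qs2 <- epoch_matrices(dec_model(areas, epochs = ep2), dec_params(0.1, 0.05))
  expect_equal(Qs2[[1]], Qs2[[2]])
  # degenerate single epoch equals the plain build
  Qplain <- build_q(mod$space, dec_params(0.1, 0.05))
  expect_equal(Qs2[[1]], Qplain)
})

test_that("malformed stratifications are rejected", {
  expect_error(epoch_stratification(c(Inf, 4), c(5, 0),
                                    matrix(TRUE, 2, 2)), "contiguous")
  expect_error(epoch_stratification(10, 1, matrix(TRUE, 1, 2)), "0 Ma")
  expect_error(epoch_stratification(10, 0, matrix(c(TRUE, FALSE), 1, 2)),
               "youngest epoch")
  expect_error(epoch_stratification(c(Inf, 4), c(4, 0),
                                    rbind(c(FALSE, FALSE), c(TRUE, TRUE))),
               "at least one")
})
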