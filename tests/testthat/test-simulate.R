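test_that("tree simulation is deterministic, ultrametric and rescaled", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(tr$edge.length[1], tr$edge.length[2])  # a single cherry
  tr2 <- simulate_tree(40, seed = 3, depth = 20)
  dep <- ape::node.depth.edgelength(tr2)
  expect_equal(max(dep), 20)
  expect_lt(max(abs(dep[1:40] - 20)), 1e-9)  # all tips at the present
  expect_equal(tr2$Nnode, 39)
  expect_identical(ape::write.tree(simulate_tree(15, seed = 9)),
                   ape::write.tree(simulate_tree(15, seed = 9)))
})

test_that("history simulation is seed-reproducible", {
  m <- dec_model(papuan_areas(), name = "DEC")
  tr <- simulate_tree(30, seed = 4)
  s1 <- simulate_dec_history(tr, m, dec_params(0.02, 0.02), "E", seed = 5)
  s2 <- simulate_dec_history(tr, m, dec_params(0.02, 0.02), "E", seed = 5)
  expect_identical(s1$tip_ranges, s2$tip_ranges)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_dec_history(tr, m, dec_params(0.02, 0.02), "E", seed = 6)
  expect_false(identical(s1$node_states, s3$node_states))
})

test_that("a motionless process copies the root range to every tip", {
  # single-area root: the only cladogenetic event is the sympatric copy, and
  # with d = e = 0 no anagenetic events occur either
  m <- toy_model()
  tr <- simulate_tree(12, seed = 8)
  sim <- simulate_dec_history(tr, m, dec_params(0, 0), 2L, seed = 9)
  expect_true(all(vapply(sim$tip_ranges, identical, TRUE, "2")))
  expect_equal(nrow(sim$events), 0)
  expect_length(sim$extinct_tips, 0)
})

test_that("pure-death extinction matches the closed form", {
  m <- dec_model(2, name = "m")
  e <- 0.04; depth <- 20
  set.seed(101)
  seeds <- sample.int(1e7, 300)
  fr <- vapply(1:150, function(i) {
    tr <- simulate_tree(20, seed = seeds[i], depth = depth)
    sim <- simulate_dec_history(tr, m, dec_params(0, e), 1L, seed = seeds[150 + i])
    length(sim$extinct_tips) / 20
  }, 1)
  expected <- 1 - exp(-e * depth)
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se + 1e-6)
})

test_that("branch end-state frequencies converge to P(t)", {
  # two-tip cherry: after the (sympatric) root event the two branches evolve
  # independently from the root state, so tip states are draws from P(t)[root,]
  m <- toy_model()
  t_len <- 3
  tr <- ape::read.tree(text = sprintf("(t1:%d,t2:%d);", t_len, t_len))
  p <- dec_params(0.15, 0.1)
  set.seed(55)
  seeds <- sample.int(1e7, 600)
  ends <- unlist(lapply(seeds, function(s) {
    sim <- simulate_dec_history(tr, m, p, 1L, seed = s)
    sim$node_states[1:2]
  }))
  emp <- tabulate(ends, nbins = m$space$n_states) / length(ends)
  P <- transition_probabilities(build_q(m$space, p), t_len)
  want <- P[range_index(m$space, 1L), ]
  # each state within 4 binomial standard errors (correlated draws inflate
  # this slightly; the cherry's branches are independent given the root)
  se <- sqrt(want * (1 - want) / length(ends))
  expect_true(all(abs(emp - want) < 4 * se + 0.01))
})

test_that("recovery experiments fit back the generating model", {
  m <- toy_model()
  cfg <- simulation_config(m, dec_params(0.08, 0.03), 1L, seed = 77,
                           n_tips = 40, depth = 20, replicates = 2)
  rec <- recovery_experiment(cfg)
  expect_equal(nrow(rec$replicates), 2)
  expect_equal(unname(rec$summary$selection_frequency["toy"]), 1)
  expect_true(all(is.finite(rec$replicates$logL)))
  expect_true(all(rec$replicates$d_hat > 0))
})
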