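test_that("a motionless process on identical tips has probability one", {
  tr <- toy_tree3()
  m <- toy_model()
  ll <- compute_log_likelihood(tr, list(t1 = 1L, t2 = 1L, t3 = 1L), m,
                               dec_params(0, 0))
  expect_equal(ll, 0)
})

test_that("pruning equals brute-force summation over histories", {
  m <- toy_model()
  for (seed in 1:4) {
    tr <- random_toy_tree(4, seed)
    tips <- random_tips(tr, m$space, seed + 100)
    set.seed(seed + 200)
    p <- dec_params(runif(1, 0.01, 0.3), runif(1, 0.01, 0.3))
    a <- compute_log_likelihood(tr, tips, m, p)
    b <- oracle_loglik(tr, tips, m, p)
    expect_equal(a, b, tolerance = 1e-8)
  }
  # 5 tips, constrained multipliers, stratified
  ms <- dec_model(3, multipliers = matrix(c(1, 1, 0.001,
                                            1, 1, 1,
                                            0.001, 1, 1), 3, 3),
                  epochs = toy_epochs(), name = "constrained")
  tr <- random_toy_tree(5, 9)
  tips <- random_tips(tr, ms$space, 42, single_area_only = TRUE)
  p <- dec_params(0.15, 0.08)
  expect_equal(compute_log_likelihood(tr, tips, ms, p),
               oracle_loglik(tr, tips, ms, p), tolerance = 1e-8)
})

test_that("likelihood is invariant to tip order and child rotation", {
  m <- toy_model()
  tr <- random_toy_tree(5, 3)
  tips <- random_tips(tr, m$space, 7)
  p <- dec_params(0.1, 0.05)
  base <- compute_log_likelihood(tr, tips, m, p)
  rot <- ape::rotate(tr, node = ape::Ntip(tr) + 1)
  expect_equal(compute_log_likelihood(rot, tips, m, p), base, tolerance = 1e-12)
  shuffled <- tips[rev(names(tips))]
  expect_equal(compute_log_likelihood(tr, shuffled, m, p), base,
               tolerance = 1e-12)
})

test_that("an all-ones multiplier model reproduces unconstrained DEC exactly", {
  areas <- dec_areas(c("A", "B", "C", "D"))
  un <- dec_model(areas, name = "DEC")
  ones <- dec_model(areas, multipliers = matrix(1, 4, 4),
                    epochs = epoch_stratification(Inf, 0, matrix(TRUE, 1, 4)),
                    name = "ones")
  tr <- random_toy_tree(6, 5)
  tips <- random_tips(tr, un$space, 11)
  p <- dec_params(0.07, 0.04)
  expect_identical(compute_log_likelihood(tr, tips, ones, p),
                   compute_log_likelihood(tr, tips, un, p))
})

test_that("a single-epoch stratified model equals the unstratified model", {
  m <- toy_model()
  ep <- epoch_stratification(c(Inf, 6), c(6, 0), matrix(TRUE, 2, 3))
  ms <- dec_model(3, epochs = ep, name = "two-identical-epochs")
  tr <- random_toy_tree(5, 8)
  tips <- random_tips(tr, m$space, 13)
  p <- dec_params(0.12, 0.06)
  expect_equal(compute_log_likelihood(tr, tips, ms, p),
               compute_log_likelihood(tr, tips, m, p), tolerance = 1e-10)
})

test_that("logL is finite and continuous over the rate box", {
  m <- toy_model()
  tr <- random_toy_tree(4, 2)
  tips <- random_tips(tr, m$space, 5)
  grid <- expand.grid(d = c(1e-6, 1e-3, 1e-1, 1), e = c(1e-6, 1e-3, 1e-1, 1))
  lls <- mapply(function(d, e)
    compute_log_likelihood(tr, tips, m, dec_params(d, e)), grid$d, grid$e)
  expect_true(all(is.finite(lls)))
})

test_that("observed areas must be present in the model", {
  tr <- toy_tree3()
  m <- toy_model(2)
  expect_error(compute_log_likelihood(tr, list(t1 = 1L, t2 = 3L, t3 = 1L), m,
                                      dec_params(0.1, 0.1)), "state space")
  expect_error(compute_log_likelihood(tr, list(t1 = 1L, t2 = 2L), m,
                                      dec_params(0.1, 0.1)), "cover every tip")
  # branch older than the oldest epoch
  ep <- epoch_stratification(c(1.5, 1), c(1, 0),
                             rbind(c(TRUE, FALSE), c(TRUE, TRUE)))
  msh <- dec_model(2, epochs = ep, name = "short")
  expect_error(compute_log_likelihood(tr, list(t1 = 1L, t2 = 2L, t3 = 1L),
                                      msh, dec_params(0.1, 0.1)), "oldest epoch")
  # polytomies are rejected with the node named
  poly <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  expect_error(compute_log_likelihood(poly,
                                      list(a = 1L, b = 1L, c = 1L, d = 1L),
                                      toy_model(), dec_params(0.1, 0.1)),
               "not binary: node")
})

test_that("ML fitting recovers the AIC identity and degenerate optima", {
  tr <- random_toy_tree(6, 4)
  m <- toy_model(2)
  tips <- random_tips(tr, m$space, 21, single_area_only = TRUE)
  fit <- fit_dec(tr, tips, m)
  expect_equal(fit$AIC, 4 - 2 * fit$logL)
  expect_equal(fit$convergence, 0)
  # the optimum beats nearby points
  eps <- 1e-3
  for (f in c(1 - eps, 1 + eps)) {
    expect_gte(fit$logL + 1e-6,
               compute_log_likelihood(tr, tips, m,
                                      dec_params(fit$d * f, fit$e * f)))
  }
  # no dispersal signal: identical single-area tips push d-hat to the bound
  tips1 <- stats::setNames(as.list(rep(1L, 6)), tr$tip.label)
  fit1 <- fit_dec(tr, tips1, m)
  expect_lt(fit1$d, 1e-4)
  expect_equal(fit1$logL, 0, tolerance = 1e-3)
})

test_that("model comparison sorts by AIC and computes delta-AIC", {
  mk <- function(logL, name) structure(
    list(d = 0.01, e = 0.01, logL = logL, AIC = 4 - 2 * logL, convergence = 0L,
         model = name, tree_id = "t", starts = NULL, fingerprint = "fp"),
    class = "dec_fit")
  tab <- compare_models(list(mk(-501, "worse"), mk(-498, "better")))
  expect_equal(tab$model, c("better", "worse"))
  expect_equal(tab$dAIC, c(0, 6))
  expect_equal(tab$neg2logL, c(996, 1002))
  # mismatched data refused
  bad <- mk(-500, "other"); bad$fingerprint <- "different"
  expect_error(compare_models(list(mk(-501, "a"), bad)), "same tree")
  # deterministic name tie-break
  tie <- compare_models(list(mk(-500, "zeta"), mk(-500, "alpha")))
  expect_equal(tie$model, c("alpha", "zeta"))
})

test_that("selection frequencies split ties and sum to one", {
  tr <- random_toy_tree(4, 6)
  m1 <- toy_model(2); m1$name <- "m1"
  m2 <- toy_model(2); m2$name <- "m2"
  tips <- random_tips(tr, m1$space, 31, single_area_only = TRUE)
  freq <- selection_frequency(tr, tips, list(m1, m2))
  expect_equal(sum(freq), 1)
  expect_equal(unname(freq), c(0.5, 0.5))  # identical models tie exactly
})
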