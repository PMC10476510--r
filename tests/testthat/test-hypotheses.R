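printed_matrix <- function(txt) {
  m <- as.matrix(read.table(text = txt, header = TRUE, row.names = 1))
  colnames(m) <- rownames(m)
  m
}

# current-connectivity multiplier matrix as published (11-region display)
printed_d_a <- printed_matrix("
  V C F A E D W M S R B
V 1 1 1 1 0 0 0 0 0 0 0
C 1 1 1 0 0 0 0 0 0 0 0
F 1 1 1 1 1 0 0 0 0 0 0
A 1 0 1 1 1 0 0 0 0 0 0
E 0 0 1 1 1 0 0 0 0 0 0
D 0 0 0 0 0 1 0 0 0 0 0
W 0 0 0 0 0 0 1 0 0 0 0
M 0 0 0 0 0 0 0 1 0 0 0
S 0 0 0 0 0 0 0 0 1 0 0
R 0 0 0 0 0 0 0 0 0 1 0
B 0 0 0 0 0 0 0 0 0 0 1
")

# all-offshore-islands-with-EPCT multiway matrix as published
printed_d_g <- printed_matrix("
  V C F A E D W M S R B
V 1 1 1 1 0 0 0 0 0 0 0
C 1 1 1 0 0 0 0 0 0 0 0
F 1 1 1 1 1 0 0 0 0 0 0
A 1 0 1 1 1 0 0 0 0 0 0
E 0 0 1 1 1 1 1 1 1 1 1
D 0 0 0 0 1 1 1 1 1 1 1
W 0 0 0 0 1 1 1 1 1 1 1
M 0 0 0 0 1 1 1 1 1 1 1
S 0 0 0 0 1 1 1 1 1 1 1
R 0 0 0 0 1 1 1 1 1 1 1
B 0 0 0 0 1 1 1 1 1 1 1
")

test_that("hypotheses a and g reproduce the published display matrices", {
  h <- builtin_hypotheses()
  expect_equal(display_multipliers(h$a), printed_d_a, ignore_attr = FALSE)
  expect_equal(display_multipliers(h$g), printed_d_g, ignore_attr = FALSE)
  # in the fitted 13-region models the displayed zeros are the 0.001 floor
  expect_equal(unclass(h$a$multipliers)["E", "V"], 0.001)
  expect_equal(unclass(h$g$multipliers)["E", "W"], 1)
})

test_that("every builtin multiplier matrix is symmetric with a unit diagonal", {
  h <- builtin_hypotheses()
  expect_named(h, c(letters[1:12], "DEC"))
  for (m in h) {
    mm <- unclass(m$multipliers)
    expect_equal(mm, t(mm))
    expect_equal(unname(diag(mm)), rep(1, 13))
    expect_true(all(mm %in% c(0.001, 0.1, 1)))
  }
  # unconstrained: all ones, single epoch
  expect_true(all(unclass(h$DEC$multipliers) == 1))
  expect_equal(h$DEC$epochs$n_epochs, 1)
})

test_that("the island-distance model carries the stated distance weights", {
  h <- builtin_hypotheses()
  m <- unclass(h$l$multipliers)
  # near islands (D'Entrecasteaux, New Britain) to any mainland terrane: 0.1
  for (isl in c("Y", "G", "B")) {
    expect_equal(unname(m[isl, c("V", "C", "F", "A", "E")]), rep(0.1, 5))
  }
  # far islands (Woodlark, Louisiades) to the mainland: 0.001
  for (isl in c("W", "M", "S", "R")) {
    expect_equal(unname(m[isl, c("V", "C", "F", "A", "E")]), rep(0.001, 5))
  }
  # within-archipelago movement unconstrained
  expect_equal(m["Y", "G"], 1)
  expect_equal(m["W", "M"], 1)
  expect_equal(m["S", "R"], 1)
})

test_that("b shares a's connection matrix but adds the docking stratification", {
  h <- builtin_hypotheses()
  expect_equal(unclass(h$b$multipliers), unclass(h$a$multipliers))
  expect_equal(h$a$epochs$n_epochs, 1)
  expect_equal(h$b$epochs$n_epochs, 2)
  expect_false(h$b$epochs$available[1, "V"])
  expect_true(all(h$b$epochs$available[2, ]))
  # mobile belt: Accreted Terranes unavailable early
  expect_false(h$c$epochs$available[1, "A"])
  # recent emergence: most mainland unavailable early
  expect_equal(unname(h$d$epochs$available[1, c("V", "C", "A")]),
               rep(FALSE, 3))
  expect_true(h$d$epochs$available[1, "E"])
})

test_that("hypothesis building is deterministic and validates codes", {
  areas <- papuan_areas()
  spec <- hypothesis_spec("x", pairwise = list(c("E", "A")),
                          blocks = list(c("M", "S", "R")))
  m1 <- build_hypothesis(spec, areas)
  m2 <- build_hypothesis(spec, areas)
  expect_identical(unclass(m1$multipliers), unclass(m2$multipliers))
  expect_equal(unclass(m1$multipliers)["E", "A"], 1)
  expect_equal(unclass(m1$multipliers)["M", "R"], 1)
  expect_equal(unclass(m1$multipliers)["E", "V"], 0.001)
  bad <- hypothesis_spec("y", pairwise = list(c("E", "ZZ")))
  expect_error(build_hypothesis(bad, areas), "unknown area code")
  expect_error(hypothesis_spec("z", floor = 0), "floor")
})
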