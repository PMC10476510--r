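# hand-built reconstruction object for binning tests
fake_recon <- function(nodes, mr_area, model) {
  structure(list(nodes = nodes, mr_area = mr_area, model = model),
            class = "dec_ancestral")
}

test_that("a shift is binned by its parent node's age (half-open bins)", {
  # root at 12 Ma (E), inner node at 5 Ma (A): one E->A shift on the inner
  # branch, assigned to the parent's age 12, which lies in the 15-10 bin
  tr <- ape::read.tree(text = "((t1:5,t2:5):7,t3:12);")
  areas <- papuan_areas()
  model <- dec_model(areas, name = "toy")
  rec <- fake_recon(c(4L, 5L), c("E", "A"), model)
  tips <- list(t1 = "A", t2 = "A", t3 = "E")
  tab <- count_transitions(tr, rec, tips)
  expect_equal(sum(tab$counts), 1)
  expect_equal(tab$counts["E", "A", "15-10"], 1)

  # identical assignment everywhere: empty table
  rec0 <- fake_recon(c(4L, 5L), c("E", "E"), model)
  tab0 <- count_transitions(tr, rec0, list(t1 = "E", t2 = "E", t3 = "E"))
  expect_equal(sum(tab0$counts), 0)

  # a shift on the edge above a tip belongs to the parent's bin too
  rec2 <- fake_recon(c(4L, 5L), c("E", "E"), model)
  tab2 <- count_transitions(tr, rec2, list(t1 = "A", t2 = "E", t3 = "E"))
  expect_equal(tab2$counts["E", "A", "10-3"], 1)  # parent age 5

  # counts invariant to relabeling/child order
  tr_rot <- ape::rotate(tr, node = 4)
  tabr <- count_transitions(tr_rot, rec, tips)
  expect_equal(tabr$counts, tab$counts)

  # ages older than the oldest break overflow with a warning
  trold <- ape::read.tree(text = "((t1:5,t2:5):20,t3:25);")
  expect_warning(tabo <- count_transitions(trold, rec, tips), "overflow")
  expect_equal(unname(tabo$counts["E", "A", "overflow"]), 1)
})

test_that("the published dispersal table yields its published summaries", {
  areas <- dec_areas(
    c("E", "A", "F", "V", "C", "L", "W", "D", "B"),
    categories = c(rep("mainland-terrane", 5), rep("island", 4)))
  tt <- read.delim(system.file("extdata", "table3_dispersals.tsv",
                               package = "decbiogeo"), comment.char = "#")
  tab <- transition_table(tt, areas,
                          bins = c("20-15", "15-10", "10-3", "3-0"))
  s <- summarize_transitions(tab)
  expect_equal(s$total, 71)
  expect_equal(s$mainland_mainland, 29)
  expect_equal(s$mainland_island, 42)
  expect_equal(unname(s$by_bin["mainland_mainland", ]), c(6, 10, 11, 2))
  expect_equal(unname(s$by_bin["mainland_island", ]), c(0, 11, 23, 8))
  # EPCT shares of dispersal sources, to the nearest percent
  expect_equal(unname(s$source_pct_mainland["E"]), 48)
  expect_equal(unname(s$source_pct_island["E"]), 98)
})

test_that("summaries of empty and single-transition tables behave", {
  areas <- dec_areas(c("E", "A", "D"),
                     categories = c("mainland-terrane", "mainland-terrane",
                                    "island"))
  arr <- array(0, c(3, 3, 1), dimnames = list(areas$code, areas$code, "20-0"))
  s0 <- summarize_transitions(transition_table(arr, areas))
  expect_equal(s0$total, 0)
  expect_equal(unname(s0$source_pct_mainland), c(0, 0))
  arr["A", "D", 1] <- 1
  s1 <- summarize_transitions(transition_table(arr, areas))
  expect_equal(unname(s1$source_pct_island["A"]), 100)
  expect_equal(s1$mainland_island, 1)
})
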