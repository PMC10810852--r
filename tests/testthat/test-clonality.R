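# The worked repertoire used across several tests: donor with a dominant
# (a1, b1) clone, main-clone variants via either dominant chain, one cell
# related through a chain shared with a main-clone cell, a duplicated-
# signature bystander pair and one unique-chain single bystander.
worked_repertoire <- function() {
  make_cells(list(d1 = list(
    c("a1", "b1"), c("a1", "b1"), c("a1", "b1"), c("a1", "b1"),
    c("a1", "b2"), c("a2", "b1"),
    c("a2", "b3"),
    c("a5", "b9"), c("a5", "b9"),
    c("a7", "b8"))))
}

test_that("admission keeps only CD8-negative cells with a reconstructed chain", {
  cells <- make_cells(list(d1 = list(c("a1", "b1"), c("a2"), c("b5"))))
  cells$cd8_positive <- c(TRUE, FALSE, FALSE)
  cells$alpha[[2]] <- character(0)  # strip chains from the second cell
  adm <- admit_cells(cells)
  expect_equal(adm$cell_id, "c003")

  expect_equal(nrow(admit_cells(cells[0, ])), 0L)

  ten <- make_cells(list(d1 = as.list(rep(list(c("a1", "b1")), 10))))
  ten$cd8_positive[c(2, 5)] <- TRUE
  ten$alpha[[7]] <- character(0); ten$beta[[7]] <- character(0)
  expect_equal(nrow(admit_cells(ten)), 7L)
})

test_that("admission can use a CD8A+CD8B expression rule instead of the flag", {
  cells <- make_cells(list(d1 = list(c("a1", "b1"), c("a2", "b2"))))
  expr <- matrix(c(2, 0.2, 0.5, 0.1), 2, 2,
                 dimnames = list(cells$cell_id, c("CD8A", "CD8B")))
  adm <- admit_cells(cells, expr = expr)
  expect_equal(adm$cell_id, "c002")  # 2.5 > 1 excluded; 0.3 kept
})

test_that("dominant pair is the most frequent alpha/beta combination", {
  cells <- make_cells(list(d1 = c(rep(list(c("a1", "b1")), 6),
                                  rep(list(c("a2", "b2")), 2))))
  expect_equal(unname(dominant_pair(cells, "d1")),
               c("TRAV1_ACGT_TRAJ1", "TRBV1_ACGT_TRBJ1-1"))

  single <- make_cells(list(d1 = list(c("a3", "b4"))))
  dp <- dominant_pair(single, "d1")
  expect_equal(unname(dp["alpha"]), single$alpha[[1]])
  expect_equal(unname(dp["beta"]), single$beta[[1]])

  expect_error(dominant_pair(make_cells(list(d1 = list("a1", "b1"))), "d1"),
               "no dominant pair")
})

test_that("dominant-pair ties break by single-chain support then lexicographically", {
  # (a1,b1) and (a2,b2) both occur 3 times, but a1 also appears alone once
  cells <- make_cells(list(d1 = c(rep(list(c("a1", "b1")), 3),
                                  rep(list(c("a2", "b2")), 3),
                                  list("a1"))))
  dp <- dominant_pair(cells, "d1")
  expect_match(dp[["alpha"]], "^TRAV1_")
  # pure tie: lexicographically smallest pair wins deterministically
  tied <- make_cells(list(d1 = c(rep(list(c("a1", "b1")), 3),
                                 rep(list(c("a2", "b2")), 3))))
  dp2 <- dominant_pair(tied, "d1")
  expect_match(dp2[["alpha"]], "^TRAV1_")
})

test_that("the worked repertoire partitions into the four expected groups", {
  lab <- assign_clonality(worked_repertoire())
  expect_equal(as.character(lab$label),
               c(rep("MAIN_CLONE", 6), "RELATED_TO_MAIN_CLONE",
                 rep("BYSTANDER_GROUP", 2), "SINGLE_BYSTANDER"))
  expect_equal(lab$malignancy_target, c(rep(1L, 7), rep(0L, 3)))
})

test_that("a lone cell with unique chains is a single bystander", {
  lab <- assign_clonality(make_cells(list(d1 = list(c("a1", "b1")))))
  # one cell: it is its own main clone (it defines the dominant pair)
  expect_equal(as.character(lab$label), "MAIN_CLONE")
  two <- assign_clonality(make_cells(list(d1 = list(c("a1", "b1"),
                                                    c("a2", "b2")))))
  expect_equal(as.character(two$label)[2], "SINGLE_BYSTANDER")
})

test_that("donors without any paired cell fall back to bystander labels", {
  lab <- assign_clonality(make_cells(list(d1 = list("a1", "a1", "b2"))))
  expect_equal(as.character(lab$label),
               c("BYSTANDER_GROUP", "BYSTANDER_GROUP", "SINGLE_BYSTANDER"))
  expect_true(all(is.na(lab$dominant_alpha)))
})

test_that("labels are invariant to input cell order and donors are independent", {
  cells <- rbind(worked_repertoire(),
                 make_cells(list(d2 = list(c("a1", "b1"), c("a1", "b1"),
                                           c("a9", "b9")))))
  class(cells) <- c("cell_records", "data.frame")
  cells$cell_id <- sprintf("m%03d", seq_len(nrow(cells)))
  lab <- assign_clonality(cells)
  set.seed(42)
  perm <- sample(nrow(cells))
  shuffled <- cells[perm, ]
  class(shuffled) <- c("cell_records", "data.frame")
  lab2 <- assign_clonality(shuffled)
  expect_equal(as.character(lab2$label[match(cells$cell_id, lab2$cell_id)]),
               as.character(lab$label))
  # chains shared across donors never link clonality across donors
  expect_equal(as.character(lab$label[cells$donor_id == "d2"]),
               c("MAIN_CLONE", "MAIN_CLONE", "SINGLE_BYSTANDER"))
})

test_that("one-step association is stricter than the transitive default", {
  # b5 co-occurs with a2; a2 co-occurs with b1 (dominant beta): two steps
  cells <- make_cells(list(d1 = list(
    c("a1", "b1"), c("a1", "b1"), c("a1", "b1"), c("a2", "b1"),
    c("a2", "b5"), c("a6", "b5"))))
  trans <- assign_clonality(cells, related = "transitive")
  ones <- assign_clonality(cells, related = "one-step")
  expect_equal(as.character(trans$label[6]), "RELATED_TO_MAIN_CLONE")
  expect_equal(as.character(ones$label[6]), "SINGLE_BYSTANDER")
  expect_equal(as.character(ones$label[5]), "RELATED_TO_MAIN_CLONE")
})

test_that("clonality fractions sum to one and match hand counts", {
  lab <- assign_clonality(worked_repertoire())
  fr <- clonality_fractions(lab)
  expect_equal(unname(fr), c(0.6, 0.1, 0.2, 0.1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  mc <- assign_clonality(make_cells(list(d1 = rep(list(c("a1", "b1")), 4))))
  expect_equal(unname(clonality_fractions(mc)), c(1, 0, 0, 0))

  lab$label <- factor("EXCLUDED", levels = levels(lab$label))
  expect_error(clonality_fractions(lab), "no non-excluded")
})

test_that("random repertoires match the brute-force reference", {
  set.seed(99)
  for (i in 1:60) {
    cells <- random_repertoire(sample(10:30, 1))
    got <- assign_clonality(cells)
    ref <- brute_clonality(cells)
    expect_equal(as.character(got$label), ref$label,
                 info = paste("repertoire", i))
  }
})
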