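test_that("step counts and MPR enumeration match the worked examples", {
  t4 <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s4 <- c(A = "0", B = "0", C = "1", D = "1")
  expect_identical(fitch_steps(t4, s4), 1L)
  expect_identical(nrow(enumerate_mprs(t4, s4)), 2L)   # root 0 or root 1

  # invariant character: zero steps, a single MPR
  s0 <- setNames(rep("0", 4), names(s4))
  expect_identical(fitch_steps(t4, s0), 0L)
  mpr0 <- enumerate_mprs(t4, s0)
  expect_identical(nrow(mpr0), 1L)
  expect_true(all(mpr0 == "0"))

  # pectinate tree with outgroup: one step, exactly one MPR
  t5 <- read_tree(text = "(O:1,(A:1,(B:1,(C:1,D:1):1):1):1);")
  s5 <- c(O = "0", A = "0", B = "1", C = "1", D = "1")
  expect_identical(fitch_steps(t5, s5), 1L)
  expect_identical(nrow(enumerate_mprs(t5, s5)), 1L)

  expect_error(fitch_steps(t4, s4[-1]), "absent")
  expect_error(enumerate_mprs(t5, random_character(t5, 4), cap = 0L), "cap")
})

test_that("unambiguous changes are the all-MPR intersection", {
  t4 <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s4 <- c(A = "0", B = "0", C = "1", D = "1")
  # the single change floats between the root's daughter branches
  r4 <- unambiguous_changes(t4, one_char_matrix(s4))
  expect_true(all(r4$branch_totals == 0))

  t5 <- read_tree(text = "(O:1,(A:1,(B:1,(C:1,D:1):1):1):1);")
  s5 <- c(O = "0", A = "0", B = "1", C = "1", D = "1")
  r5 <- unambiguous_changes(t5, one_char_matrix(s5))
  expect_identical(r5$total_changes, 1L)
  # the change sits on the branch subtending (B,(C,D))
  anc_bcd <- ape::getMRCA(t5, c("B", "C", "D"))
  expect_identical(unname(r5$branch_totals[paste0("node", anc_bcd)]), 1)
})

test_that("DP and brute-force enumeration agree on random instances", {
  set.seed(421)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- random_character(tree, sample(2:4, 1),
                               p_missing = ifelse(rep %% 5 == 0, 0.2, 0))
    oracle <- brute_parsimony(tree, states)
    expect_identical(fitch_steps(tree, states), as.integer(oracle$steps))
    r_dp <- unambiguous_changes(tree, one_char_matrix(states))
    r_en <- unambiguous_changes(tree, one_char_matrix(states),
                                method = "enumeration")
    expect_identical(as.logical(r_dp$branch_changes), oracle$unambiguous)
    expect_identical(r_dp$branch_changes, r_en$branch_changes)
    expect_identical(nrow(enumerate_mprs(tree, states)),
                     as.integer(oracle$n_mpr))
  }
})

test_that("steps agree with an independent Fitch implementation", {
  set.seed(99)
  for (rep in 1:25) {
    tree <- ape::rtree(sample(5:12, 1))
    states <- random_character(tree, sample(2:4, 1))
    pd <- phangorn::phyDat(matrix(states[tree$tip.label], ncol = 1,
                                  dimnames = list(tree$tip.label, NULL)),
                           type = "USER", levels = sort(unique(states)))
    expect_identical(fitch_steps(tree, states),
                     as.integer(phangorn::parsimony(tree, pd)))
  }
})

test_that("ensemble CI and RI follow their definitions", {
  # single binary character with one step: CI = 1
  t4 <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- unambiguous_changes(t4, one_char_matrix(c(A = "0", B = "0",
                                                  C = "1", D = "1")))
  expect_equal(consistency_index(r1), 1)

  # homoplastic binary character: s = 2, m = 1 -> CI = 0.5
  r2 <- unambiguous_changes(t4, one_char_matrix(c(A = "0", B = "1",
                                                  C = "0", D = "1")))
  expect_identical(unname(r2$steps), 2L)
  expect_equal(consistency_index(r2), 0.5)

  # ensemble over characters with (m, s) = (1, 1), (1, 3): CI = 2/4
  t6 <- read_tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  m6 <- character_matrix(cbind(
    c1 = c(A = "0", B = "0", C = "0", D = "0", E = "1", F = "1"),
    c2 = c(A = "0", B = "1", C = "0", D = "1", E = "0", F = "1")))
  r6 <- unambiguous_changes(t6, m6)
  expect_identical(unname(r6$steps), c(1L, 3L))
  expect_equal(consistency_index(r6), 0.5)

  # s = m everywhere: RI = 1; s = g: RI = 0
  expect_equal(retention_index(r1), 1)
  t5 <- read_tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  r5 <- unambiguous_changes(t5, one_char_matrix(c(A = "1", B = "0", C = "1",
                                                  D = "0", E = "0")))
  expect_identical(unname(r5$steps), 2L)      # g = 5 - 3 = 2, m = 1
  expect_equal(retention_index(r5), 0)

  # all-invariant matrix: undefined
  inv <- one_char_matrix(setNames(rep("0", 4), c("A", "B", "C", "D")))
  expect_error(consistency_index(unambiguous_changes(t4, inv)), "invariant")
})

test_that("CI/RI agree with phangorn on random matrices", {
  set.seed(7)
  tree <- ape::rtree(10)
  m <- sapply(1:12, function(i) random_character(tree, 3))
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("c", 1:12)
  res <- unambiguous_changes(tree, character_matrix(m))
  pd <- phangorn::phyDat(m, type = "USER", levels = c("1", "2", "3"))
  keep <- res$steps > 0
  expect_equal(consistency_index(res),
               sum(res$min_steps[keep]) / as.numeric(phangorn::parsimony(tree, pd)))
  expect_equal(retention_index(res),
               unname(phangorn::RI(tree, pd)))
})

test_that("the two sexes run through identical code paths symmetrically", {
  b <- make_study_fixture(fixture_spec(seed = 11))
  bc <- branch_change_table(b$tree, b$male, b$female)
  bc_sw <- branch_change_table(b$tree, b$female, b$male)
  expect_identical(bc$table$male, bc_sw$table$female)
  expect_identical(bc$table$female, bc_sw$table$male)

  # adding characters never decreases the total of unambiguous changes
  part <- unambiguous_changes(b$tree, b$male[, 1:10])
  full <- unambiguous_changes(b$tree, b$male)
  expect_gte(full$total_changes, part$total_changes)
})
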