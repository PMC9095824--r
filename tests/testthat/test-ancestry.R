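test_that("regional assignment honours specificity and range rules", {
  tree <- default_haplotree()
  expect_equal(assign_region("M39", tree = tree), "SouthAsian")
  expect_equal(assign_region("U7", tree = tree), "WestEurasian")
  # sub-clade carve-out: U2a is South Asian although U2 sits in U1-U5
  expect_equal(assign_region("U2a", tree = tree), "SouthAsian")
  expect_equal(assign_region("U2", tree = tree), "WestEurasian")
  # letter macro-clades are East Eurasian
  expect_equal(assign_region("B", tree = tree), "EastEurasian")
  expect_equal(assign_region("D", tree = tree), "EastEurasian")
  # HV0e inherits from HV via the ancestor path
  expect_equal(assign_region("HV0e", tree = tree), "WestEurasian")
  # macro labels with no rule stay unclassified
  expect_equal(assign_region("L0", tree = tree), "Unclassified")
  expect_error(assign_region("Z9", tree = tree), "unknown")
  # prefix matching stops at class boundaries: M3 must not capture M39
  expect_true(paleoprov:::pattern_matches("M37", "M37e"))
  expect_false(paleoprov:::pattern_matches("M3", "M39"))
})

test_that("assignment is stable when the tree is refined with new children", {
  tree <- default_haplotree()
  before <- vapply(names(tree$nodes), assign_region, character(1),
                   tree = tree)
  lines <- serialize_haplotree(tree)
  i <- which(grepl("^\t*M39\t", lines))
  depth <- nchar(sub("M39.*$", "", lines[i]))
  lines <- append(lines, paste0(strrep("\t", depth + 1), "M39b\tA901G"),
                  after = i)
  tree2 <- parse_haplotree(lines)
  after <- vapply(names(tree$nodes), assign_region, character(1),
                  tree = tree2)
  expect_identical(after, before)
  expect_equal(assign_region("M39b", tree = tree2), "SouthAsian")
})

test_that("ancestry proportions count every call and sum to one", {
  tree <- default_haplotree()
  ap <- ancestry_proportions(c("M39", "U7", "D"), tree = tree)
  expect_equal(unname(ap$fractions[c("SouthAsian", "WestEurasian",
                                     "EastEurasian")]),
               rep(1 / 3, 3))
  expect_equal(sum(ap$fractions), 1.0)
  expect_equal(sum(ap$counts), 3L)

  all_m39 <- ancestry_proportions(rep("M39", 5), tree = tree)
  expect_equal(unname(all_m39$fractions["SouthAsian"]), 1.0)

  # unmapped labels land in Unclassified without breaking conservation
  with_l0 <- ancestry_proportions(c("M39", "L0", "L1"), tree = tree)
  expect_equal(unname(with_l0$fractions["Unclassified"]), 2 / 3)
  expect_equal(sum(with_l0$fractions), 1.0)
  expect_error(ancestry_proportions(character(0), tree = tree), "empty")
})

test_that("two-tailed Fisher p equals brute-force hypergeometric enumeration", {
  # identical proportions give p = 1
  cA <- c(WestEurasian = 5, SouthAsian = 5)
  cB <- c(WestEurasian = 5, SouthAsian = 5)
  expect_equal(compare_ancestry(cA, cB, "WestEurasian"), 1.0)

  # a strongly imbalanced table
  p19 <- compare_ancestry(c(WestEurasian = 1, SouthAsian = 9),
                          c(WestEurasian = 9, SouthAsian = 1),
                          "WestEurasian")
  expect_equal(p19, fisher_oracle(1, 9, 9, 1), tolerance = 1e-10)

  # exhaustive agreement for all tables with row sums <= 12, plus a
  # sample of larger tables with margins up to 30
  for (nA in 1:12) {
    for (nB in 1:12) {
      for (a in 0:nA) {
        for (b in seq(0, nB, by = max(1, nB %/% 4))) {
          got <- compare_ancestry(c(WestEurasian = a, other = nA - a),
                                  c(WestEurasian = b, other = nB - b),
                                  "WestEurasian")
          expect_equal(got, fisher_oracle(a, nA - a, b, nB - b),
                       tolerance = 1e-9,
                       info = paste(a, nA - a, b, nB - b))
        }
      }
    }
  }
  set.seed(7)
  for (i in 1:50) {
    nA <- sample(13:30, 1); nB <- sample(13:30, 1)
    a <- sample(0:nA, 1); b <- sample(0:nB, 1)
    got <- compare_ancestry(c(WestEurasian = a, other = nA - a),
                            c(WestEurasian = b, other = nB - b),
                            "WestEurasian")
    expect_equal(got, fisher_oracle(a, nA - a, b, nB - b),
                 tolerance = 1e-9)
  }
  expect_error(compare_ancestry(c(WestEurasian = 0, other = 0), cB,
                                "WestEurasian"), "non-empty")
})

test_that("a strongly enriched cohort pair is detected below p = 0.005", {
  p <- compare_ancestry(c(WestEurasian = 30, SouthAsian = 20),
                        c(WestEurasian = 4, SouthAsian = 46),
                        "WestEurasian")
  expect_lt(p, 0.005)
  expect_gt(p, 0)
})
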