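# independent depth computation straight off the heap array, used as the
# oracle for regex_tree_depth
oracle_depth <- function(tree) {
  expressed <- which(!vapply(tree$nodes, is.null, logical(1))) - 1L
  max(floor(log2(expressed + 1))) + 1L
}

test_that("hand-built trees render to the expected patterns", {
  expect_equal(regex_pattern(as_regex_tree(rx_leaf("K"))), "K")

  bracket_plus <- as_regex_tree(rx_op("concat",
    rx_op("charclass", rx_leaf("PNYIQ")),
    rx_op("plus", rx_leaf("K"))))
  expect_equal(regex_pattern(bracket_plus), "[PNYIQ]K+")

  alt <- as_regex_tree(rx_op("alternation", rx_leaf("K"), rx_leaf("R")))
  expect_equal(regex_pattern(alt), "(K|R)")
  # grouped alternation is match-equivalent to the bare form
  for (s in c("KAR", "AAA", "RRK", "ARKA")) {
    expect_equal(match_all(regex_pattern(alt), s), match_all("K|R", s))
  }

  # bracket letters are the deduplicated leaves of the subtree, in order
  nested <- as_regex_tree(rx_op("neg_charclass",
    rx_op("concat", rx_leaf("KA"), rx_leaf("K"))))
  expect_equal(regex_pattern(nested), "[^KA]")

  # quantifier operands are parenthesized unless a single token
  rep2 <- as_regex_tree(rx_op("repeat", rx_leaf("QS"), n = 3))
  expect_equal(regex_pattern(rep2), "(QS){3}")
  plusplus <- as_regex_tree(rx_op("plus", rx_op("plus", rx_leaf("K"))))
  expect_equal(regex_pattern(plusplus), "(K+)+")
  expect_no_error(regexpr("(K+)+", "KKK", perl = TRUE))

  grp <- as_regex_tree(rx_op("group", rx_leaf("KL")))
  expect_equal(regex_pattern(grp), "(KL)")
})

test_that("tree depth matches the heap-level oracle", {
  expect_equal(regex_tree_depth(as_regex_tree(rx_leaf("K"))), 1)
  three <- as_regex_tree(rx_op("concat",
    rx_op("plus", rx_leaf("A")), rx_leaf("R")))
  expect_equal(regex_tree_depth(three), 3)
  set.seed(11)
  for (i in 1:300) {
    tr <- random_regex_tree(sample(1:6, 1), sample(c("grow", "full"), 1))
    expect_equal(regex_tree_depth(tr), oracle_depth(tr))
  }
})

test_that("random generation respects depth, validity and determinism", {
  expect_equal(random_regex_tree(1)$nodes[[1]]$kind, "leaf")
  set.seed(21)
  trees <- replicate(500, random_regex_tree(6, sample(c("grow", "full"), 1)),
                     simplify = FALSE)
  expect_true(all(vapply(trees, is_valid_regex_tree, logical(1))))
  expect_true(all(vapply(trees, regex_tree_depth, integer(1)) <= 6))
  pats <- vapply(trees, regex_pattern, character(1))
  compiles <- vapply(pats, function(p)
    !inherits(tryCatch(regexpr(p, "KAKAKAKAKAKAK", perl = TRUE),
                       error = identity), "error"), logical(1))
  expect_true(all(compiles))
  # full trees at depth d have depth exactly d
  set.seed(22)
  fulls <- replicate(50, random_regex_tree(4, "full"), simplify = FALSE)
  expect_true(all(vapply(fulls, regex_tree_depth, integer(1)) == 4))

  set.seed(5); t1 <- random_regex_tree(5, "grow")
  set.seed(5); t2 <- random_regex_tree(5, "grow")
  expect_identical(t1, t2)
  expect_error(random_regex_tree(0), "max_depth")
})

test_that("match scanning is leftmost, non-overlapping and never empty", {
  expect_equal(match_all("[PNYIQ]K+", "APVPKKPRLL"), "PKK")
  expect_equal(match_all("K+", "AKKAKA"), c("KK", "K"))
  expect_equal(match_all("[^K]", "KKK"), character(0))

  # cross-engine agreement between PCRE and TRE: full match lists agree
  # for alternation-free patterns; with alternation the engines follow
  # different (leftmost-first vs leftmost-longest) disambiguation, so the
  # oracle compares match presence
  set.seed(31)
  subjects <- random_peptides(8, 13)
  for (i in 1:250) {
    tr <- random_regex_tree(5, sample(c("grow", "full"), 1))
    p <- regex_pattern(tr)
    for (s in subjects[sample.int(8, 2)]) {
      got <- match_all(p, s)
      tre <- regmatches(s, gregexpr(p, s))[[1]]
      if (grepl("|", p, fixed = TRUE)) {
        expect_identical(length(got) > 0, length(tre) > 0)
      } else {
        expect_identical(got, tre)
      }
      expect_true(all(nchar(got) > 0))
    }
  }
})

test_that("all mutation kinds preserve validity and the depth bound", {
  set.seed(41)
  pool <- replicate(60, random_regex_tree(6, sample(c("grow", "full"), 1)),
                    simplify = FALSE)
  kinds <- c("replace_subtree", "exchange_node", "delete_subtree",
             "add_leaf_aa")
  for (i in 1:2000) {
    t0 <- pool[[sample.int(60, 1)]]
    t1 <- suppressWarnings(mutate_regex_tree(t0, sample(kinds, 1)))
    expect_true(is_valid_regex_tree(t1))
    expect_lte(regex_tree_depth(t1), 6)
  }
})

test_that("exchange, leaf-extension and deletion behave as specified", {
  # exchanging a binary root swaps concat for alternation, children intact
  tr <- as_regex_tree(rx_op("concat", rx_leaf("K"), rx_leaf("R")))
  set.seed(1)
  found_alt <- FALSE
  for (i in 1:50) {
    t1 <- mutate_regex_tree(tr, "exchange_node")
    expect_true(is_valid_regex_tree(t1))
    if (t1$nodes[[1]]$op == "alternation") {
      found_alt <- TRUE
      expect_identical(t1$nodes[[2]], tr$nodes[[2]])
      expect_identical(t1$nodes[[3]], tr$nodes[[3]])
    }
  }
  expect_true(found_alt)

  # adding to a leaf appends 1-4 residues after the original payload
  leafy <- as_regex_tree(rx_leaf("K"))
  set.seed(2)
  for (i in 1:20) {
    t1 <- mutate_regex_tree(leafy, "add_leaf_aa")
    pay <- t1$nodes[[1]]$payload
    expect_true(startsWith(pay, "K"))
    expect_gte(nchar(pay), 2)
    expect_lte(nchar(pay), 5)
  }

  # deletion on a single leaf is a warning no-op
  expect_warning(out <- mutate_regex_tree(leafy, "delete_subtree"),
                 "single-leaf")
  expect_identical(out, leafy)

  # deleting one child of a binary node promotes the sibling
  set.seed(3)
  small <- as_regex_tree(rx_op("concat", rx_leaf("K"), rx_leaf("R")))
  t1 <- mutate_regex_tree(small, "delete_subtree")
  expect_true(t1$nodes[[1]]$kind == "leaf")
  expect_true(t1$nodes[[1]]$payload %in% c("K", "R"))
})

test_that("JSON serialization round-trips trees exactly", {
  set.seed(51)
  for (i in 1:20) {
    tr <- random_regex_tree(5, sample(c("grow", "full"), 1))
    back <- tree_from_json(tree_to_json(tr))
    expect_identical(regex_pattern(back), regex_pattern(tr))
    expect_identical(back$nodes, tr$nodes)
  }
})
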