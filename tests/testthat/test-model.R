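test_that("predicted score sums weights of matching rules by presence", {
  m <- rule_model(c("K+", "RR"), weights = c(2.5, -1))
  expect_equal(predict_score(m, "RRKK"), 1.5)
  expect_equal(predict_score(m, "KKAK"), 2.5)  # K+ matches twice, counts once
  expect_equal(predict_score(m, "AAAA"), 0)
  expect_equal(predict_score(m, c("RRKK", "KKAK", "AAAA")),
               c(1.5, 2.5, 0))

  # linearity: scaling every weight by c scales every score by c
  set.seed(1)
  seqs <- random_peptides(20, 12)
  m3 <- rule_model(c("K", "[ED]", "QS"), weights = c(3, -2, 1.5))
  m3c <- rule_model(c("K", "[ED]", "QS"), weights = 2.5 * c(3, -2, 1.5))
  expect_equal(predict_score(m3c, seqs), 2.5 * predict_score(m3, seqs))
})

test_that("rule weights follow the signed motif-value sum", {
  # db built from one positive sequence: PKK has value 14 >= 12.5
  ds_hi <- peptide_set("APVPKKPRLL", 14)
  db_hi <- build_motif_db(ds_hi, threshold = 12.5)
  expect_equal(train_rule_weight("[PNYIQ]K+", ds_hi, db_hi), 14 * 3)

  # same sequence labeled below threshold: value 10 < 12.5 -> subtracted
  ds_lo <- peptide_set("APVPKKPRLL", 10)
  db_lo <- build_motif_db(ds_lo, threshold = 12.5)
  expect_equal(train_rule_weight("[PNYIQ]K+", ds_lo, db_lo), -10 * 3)

  expect_equal(train_rule_weight("W{3}", ds_hi, db_hi), 0)  # no match

  # matches longer than the largest window contribute nothing
  expect_equal(train_rule_weight("APVPKKP", ds_hi, db_hi), 0)

  # weight sign follows the class of the motifs a rule can reach
  ds <- tiny_labeled_ds()
  db <- build_motif_db(ds, threshold = 12.5)
  expect_gte(train_rule_weight("WK", ds, db), 0)
  expect_lte(train_rule_weight("EE", ds, db), 0)
})

test_that("model training is per-rule independent and order-invariant", {
  ds <- tiny_labeled_ds()
  db <- build_motif_db(ds, threshold = 12.5)
  pats <- c("WK", "EE", "K+", "[ST]T", "Q")
  m <- train_model_weights(rule_model(pats), ds, db)
  for (i in seq_along(pats))
    expect_equal(m$rules[[i]]$weight, train_rule_weight(pats[i], ds, db))
  m_rev <- train_model_weights(rule_model(rev(pats)), ds, db)
  expect_equal(sapply(m_rev$rules, `[[`, "weight"),
               rev(sapply(m$rules, `[[`, "weight")))
})

test_that("fold-evaluator fast path agrees with definitional training", {
  ds <- tiny_labeled_ds()
  ctx <- fold_context(ds, k = 2, threshold = 12.5, seed = 9)
  db_full <- build_motif_db(ds, threshold = 12.5)
  for (p in c("WK", "EE", "K+", "[ST]T", "(Q|R)")) {
    fast <- pepregex:::eval_rule_ctx(p, ctx)
    expect_equal(fast$w[ctx$k + 1], train_rule_weight(p, ds, db_full))
    for (f in 1:2) {
      part <- ds[ctx$folds != f, ]
      class(part) <- class(ds)
      expect_equal(fast$w[f],
                   train_rule_weight(p, part,
                                     build_motif_db(part, 12.5)))
    }
    expect_equal(fast$presence, grepl(p, ds$sequence, perl = TRUE))
  }
})

test_that("Pearson fitness matches the printed formula and its edge rules", {
  set.seed(2)
  for (i in 1:100) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x)) + 0.3 * x
    m <- rule_model("K", 1)  # bypass predict: test the scalar core
    expect_equal(pepregex:::.pearson(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
  ds <- peptide_set(c("KKAA", "AKAA", "AAAA"), c(3, 2, 1))
  perfect <- rule_model(c("KK", "K"), weights = c(1, 1))
  # scores 2,1,0 align exactly with phenotype
  expect_equal(pearson_fitness(perfect, ds), 1)
  inverse <- rule_model(c("KK", "K"), weights = c(-1, -1))
  expect_equal(pearson_fitness(inverse, ds), -1)
  # all-zero predictions fall back to 0 rather than NA
  expect_equal(pearson_fitness(rule_model("W", 5), ds), 0)
  expect_error(pearson_fitness(perfect, ds[1, ]), "two records")
})

test_that("k-fold fitness matches a brute-force two-fold evaluation", {
  ds <- tiny_labeled_ds()
  m <- rule_model(c("WK", "EE"))
  got <- kfold_fitness(m, ds, k = 2, threshold = 12.5, seed = 13)

  # brute force: rebuild db and weights per fold with the same assignment
  folds <- fold_context(ds, k = 2, threshold = 12.5, seed = 13)$folds
  r_tr <- r_va <- numeric(2)
  for (f in 1:2) {
    tr <- ds[folds != f, ]; va <- ds[folds == f, ]
    class(tr) <- class(va) <- class(ds)
    db <- build_motif_db(tr, 12.5)
    mf <- train_model_weights(m, tr, db)
    r_tr[f] <- pearson_fitness(mf, tr)
    r_va[f] <- pearson_fitness(mf, va)
  }
  expect_equal(got$fitness, mean(r_tr))
  expect_equal(got$validation, mean(r_va))

  # fold assignment reproducible under the seed
  again <- kfold_fitness(m, ds, k = 2, threshold = 12.5, seed = 13)
  expect_identical(got, again)
  expect_error(kfold_fitness(m, ds[1:3, ], k = 6), "at least k")
})

test_that("weight randomization is bounded, partial and centered", {
  m <- rule_model(c("K", "R", "Q", "W"), weights = c(1, 2, 3, 4))
  expect_identical(randomize_weights(m, p = 0), m)
  set.seed(3)
  all_new <- randomize_weights(m, p = 1)
  w <- sapply(all_new$rules, `[[`, "weight")
  expect_true(all(w >= -10 & w <= 10))
  expect_false(any(w == c(1, 2, 3, 4)))
  expect_error(randomize_weights(m, p = 0.5, low = 3, high = 1), "below")

  # Monte-Carlo: mean of U(-10,10) redraws is 0 within 3 standard errors
  set.seed(4)
  draws <- replicate(3000, sapply(randomize_weights(m, p = 1)$rules,
                                  `[[`, "weight"))
  se <- (20 / sqrt(12)) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("model files round-trip scores and reject malformed patterns", {
  set.seed(5)
  trees <- replicate(3, random_regex_tree(4, "grow"), simplify = FALSE)
  m <- rule_model(trees, weights = c(2, -1, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_model(m, path)
  back <- read_model(path)
  probes <- random_peptides(100, 12)
  expect_equal(predict_score(back, probes), predict_score(m, probes))
  expect_equal(length(back$rules), 3)
  expect_identical(regex_pattern(back$rules[[1]]$tree),
                   m$rules[[1]]$pattern)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pattern,weight", "1,\"K+\",2", "2,\"(K\",1"), bad)
  expect_error(read_model(bad), "row 2")
})
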