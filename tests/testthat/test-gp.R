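test_that("initial populations honor rule counts, weights and ramping", {
  cfg <- gp_config(population_size = 40, generations = 1, seed = NULL)
  set.seed(6)
  pop <- init_population(cfg)
  expect_length(pop, 40)
  nr <- sapply(pop, function(m) length(m$rules))
  expect_true(all(nr >= 1 & nr <= 8))
  expect_true(all(unlist(lapply(pop, function(m)
    sapply(m$rules, `[[`, "weight"))) == 0))
  depths <- unlist(lapply(pop, function(m)
    sapply(m$rules, function(r) regex_tree_depth(r$tree))))
  expect_true(all(depths <= 6))
  set.seed(6)
  expect_identical(init_population(cfg), pop)

  rnd <- gp_config(population_size = 10, generations = 1,
                   mode = "random_weights")
  set.seed(7)
  w <- unlist(lapply(init_population(rnd), function(m)
    sapply(m$rules, `[[`, "weight")))
  expect_true(all(w >= -10 & w <= 10))
  expect_true(all(w != 0))
})

test_that("tournament selection matches its closed-form win probability", {
  pop <- lapply(1:10, function(i) {
    m <- rule_model("K", 1)
    m$fitness <- i / 10
    m
  })
  # a tournament containing the unique best always returns it:
  # with k = population size and sampling until the best is in hand
  set.seed(8)
  for (i in 1:20) {
    sel <- tournament_select(pop, k = 30)  # almost surely contains best
    expect_equal(sel$fitness, 1)
  }
  # empirical P(select best) at k=5 vs 1 - (1 - 1/n)^5
  set.seed(9)
  hits <- mean(replicate(20000,
                         tournament_select(pop, k = 5)$fitness == 1))
  expect_equal(hits, 1 - (1 - 1 / 10)^5, tolerance = 0.02)
  # k = 1 is a uniform draw: every individual reachable
  set.seed(10)
  drawn <- replicate(200, tournament_select(pop, k = 1)$fitness)
  expect_gt(length(unique(drawn)), 5)
})

test_that("crossover conserves rules and produces valid cut offspring", {
  p1 <- rule_model(c("K", "R", "Q"), weights = c(1, 2, 3))
  p2 <- rule_model(c("W", "S"), weights = c(4, 5))
  set.seed(11)
  for (i in 1:200) {
    kids <- crossover_models(p1, p2, max_rules = 30)
    n1 <- length(kids[[1]]$rules); n2 <- length(kids[[2]]$rules)
    expect_gte(n1, 1); expect_gte(n2, 1)
    expect_equal(n1 + n2, 5)  # conservation, no truncation possible here
    # each offspring is a head of one parent plus a tail of the other
    pats <- function(m) sapply(m$rules, `[[`, "pattern")
    head_tail <- function(o, a, b) {
      for (i1 in 0:length(a)) for (j1 in 0:length(b)) {
        cand <- c(a[seq_len(i1)],
                  if (j1 < length(b)) b[(j1 + 1):length(b)]
                  else character(0))
        if (identical(o, cand)) return(TRUE)
      }
      FALSE
    }
    expect_true(head_tail(pats(kids[[1]]), c("K", "R", "Q"), c("W", "S")))
    expect_true(head_tail(pats(kids[[2]]), c("W", "S"), c("K", "R", "Q")))
    # ids are reassigned sequentially
    expect_equal(sapply(kids[[1]]$rules, `[[`, "id"), seq_len(n1))
  }
  # both parents single-rule: pair passes through unchanged (no valid cut)
  s1 <- rule_model("K", 1); s2 <- rule_model("W", 2)
  kids <- crossover_models(s1, s2)
  expect_identical(kids[[1]]$rules[[1]]$pattern, "K")
  expect_identical(kids[[2]]$rules[[1]]$pattern, "W")
  # truncation respects the cap
  big1 <- rule_model(rep("K", 20)); big2 <- rule_model(rep("W", 20))
  set.seed(12)
  for (i in 1:50) {
    kids <- crossover_models(big1, big2, max_rules = 30)
    expect_true(all(sapply(kids, function(m) length(m$rules)) <= 30))
  }
})

test_that("individual mutation respects rule-count bounds", {
  cfg <- gp_config(population_size = 10, generations = 1, max_rules = 5,
                   mutation_prob = 1)
  set.seed(13)
  capped <- rule_model(lapply(1:5, function(i) random_regex_tree(3, "grow")))
  for (i in 1:50) {
    out <- mutate_model(capped, cfg)
    expect_lte(length(out$rules), 5)
    expect_gte(length(out$rules), 1)
  }
  single <- rule_model(list(random_regex_tree(3, "grow")))
  for (i in 1:50) {
    out <- mutate_model(single, cfg)
    expect_gte(length(out$rules), 1)
  }
  # zero mutation probability leaves the individual untouched
  cfg0 <- gp_config(population_size = 10, generations = 1,
                    mutation_prob = 0)
  m <- rule_model(c("K", "R"), weights = c(1, 2))
  expect_equal(sapply(mutate_model(m, cfg0)$rules, `[[`, "pattern"),
               c("K", "R"))
})

test_that("reduction keeps the best with parsimony tie-breaking", {
  mk <- function(fit, npat) {
    m <- rule_model(rep("K", npat))
    m$fitness <- fit
    m
  }
  pop <- lapply(seq(0.1, 1.5, by = 0.1), function(f) mk(f, 3))
  red <- reduce_population(pop, 10)
  expect_length(red, 10)
  expect_equal(min(sapply(red, `[[`, "fitness")), 0.6)
  # all-equal fitness: the leanest individuals survive
  tie <- c(lapply(1:5, function(i) mk(0.5, 6)),
           lapply(1:5, function(i) mk(0.5, 2)))
  kept <- reduce_population(tie, 5)
  expect_true(all(sapply(kept, function(m) length(m$rules)) == 2))
  expect_identical(reduce_population(red, 10), red)
  expect_error(reduce_population(pop, 99), "smaller")
})

test_that("a smoke evolution run logs and improves monotonically", {
  ds <- simulate_peptides(50, seed = 77)
  cfg <- gp_config(population_size = 20, generations = 5, seed = 78)
  res <- evolve_model(cfg, ds)
  expect_equal(nrow(res$log), 5)
  expect_true(all(diff(res$log$best_fitness) >= -1e-12))
  expect_true(all(res$log$best_n_rules >= 1 &
                  res$log$best_n_rules <= 30))
  expect_s3_class(res$model, "pf_model")
  expect_false(any(is.na(predict_score(res$model, ds$sequence))))
})

test_that("random-weight control mode never enters the training path", {
  ds <- simulate_peptides(50, seed = 79)
  rule_training_count(reset = TRUE)
  cfg <- gp_config(population_size = 16, generations = 4,
                   mode = "random_weights", seed = 80)
  res <- evolve_model(cfg, ds)
  expect_equal(rule_training_count(), 0L)
  expect_equal(nrow(res$log), 4)
  expect_true(all(diff(res$log$best_fitness) >= -1e-12))
  # trained mode does train
  res_t <- evolve_model(gp_config(population_size = 16, generations = 2,
                                  seed = 81), ds)
  expect_gt(rule_training_count(reset = TRUE), 0L)
})
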