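#' Configuration of an evolutionary run
#'
#' Defaults are the study's published hyper-parameters: population 1000,
#' 300 generations, at most 30 rules per model, crossover probability 0.9,
#' mutation probability 0.1, tournament size 5, tree depth 6, 6-fold
#' cross-validation, class threshold 12.5 (the poly-L-lysine phenotype),
#' and 1 to 8 rules per initial individual. Test and example runs scale
#' the population and generation counts down.
#'
#' @param population_size number of individuals kept per generation.
#' @param generations number of generations.
#' @param max_rules maximum rules per model.
#' @param crossover_prob probability that a parent pair recombines.
#' @param mutation_prob per-individual and per-rule mutation rate.
#' @param tournament_k tournament size for parent selection.
#' @param max_depth regex-tree depth bound.
#' @param cv_folds folds for the fitness cross-validation.
#' @param threshold phenotype class boundary for the motif database.
#' @param init_rules integer range (low, high) of initial rule counts.
#' @param mode `"trained"` (weights trained against the motif database)
#'   or `"random_weights"` (control: weights explored at random, no
#'   training step).
#' @param seed optional integer seed for the whole run.
#' @return a `gp_config`.
#' @export
gp_config <- function(population_size = 1000, generations = 300,
                      max_rules = 30, crossover_prob = 0.9,
                      mutation_prob = 0.1, tournament_k = 5,
                      max_depth = 6, cv_folds = 6, threshold = 12.5,
                      init_rules = c(1, 8),
                      mode = c("trained", "random_weights"),
                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(population_size >= 2, generations >= 1, max_rules >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            tournament_k >= 1, max_depth >= 1, cv_folds >= 2,
            length(init_rules) == 2, init_rules[1] >= 1,
            init_rules[2] >= init_rules[1])
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 max_rules = as.integer(max_rules),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_k = as.integer(tournament_k),
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds),
                 threshold = threshold,
                 init_rules = as.integer(init_rules),
                 mode = mode, seed = seed),
            class = "gp_config")
}

## a fresh random rule: ramped depth in 2..max_depth, half full/half grow
.random_rule <- function(id, cfg, random_weight = FALSE) {
  depth <- if (cfg$max_depth <= 2) cfg$max_depth
           else sample(2:cfg$max_depth, 1)
  tree <- random_regex_tree(depth, sample(c("full", "grow"), 1))
  w <- if (random_weight) stats::runif(1, -10, 10) else 0
  new_rule(id, regex_pattern(tree), w, tree = tree)
}

#' Initialize a population
#'
#' Each individual starts with a uniform number of rules in the
#' configured range (default 1 to 8), all weights 0 (or uniform in
#' \[-10, 10\] in the random-weight control mode), and trees generated by
#' ramped half-and-half over depths 2 to `max_depth`.
#'
#' @param cfg a [gp_config()].
#' @return list of `pf_model`s of length `population_size`.
#' @export
init_population <- function(cfg) {
  stopifnot(inherits(cfg, "gp_config"))
  rnd <- cfg$mode == "random_weights"
  lapply(seq_len(cfg$population_size), function(i) {
    nr <- sample(seq(cfg$init_rules[1], cfg$init_rules[2]), 1)
    new_pf_model(lapply(seq_len(nr), .random_rule, cfg = cfg,
                        random_weight = rnd))
  })
}

## ranking key: fitness desc, then fewer rules (parsimony), then insertion
## order -- deterministic under a fixed seed
.rank_population <- function(population) {
  fit <- vapply(population, `[[`, numeric(1), "fitness")
  if (any(is.na(fit))) stop("population has unset fitness", call. = FALSE)
  nr <- vapply(population, n_rules, integer(1))
  order(-fit, nr, seq_along(population))
}

#' Tournament selection
#'
#' Samples `k` individuals uniformly with replacement and returns the one
#' with the highest fitness (ties broken by fewer rules, then position).
#'
#' @param population list of evaluated `pf_model`s.
#' @param k tournament size.
#' @return the selected `pf_model`.
#' @export
tournament_select <- function(population, k = 5) {
  stopifnot(length(population) >= 1)
  idx <- sample.int(length(population), k, replace = TRUE)
  entrants <- population[idx]
  entrants[[.rank_population(entrants)[1]]]
}

#' One-point crossover of two rule lists
#'
#' A cut index is drawn in each parent; the offspring are the head of one
#' parent joined to the tail of the other. Draws that would reproduce
#' both parents verbatim or leave an offspring empty are excluded, so the
#' total rule count is conserved whenever no truncation to `max_rules`
#' triggers. Offspring exceeding `max_rules` are truncated from the tail,
#' and rule ids are reassigned.
#'
#' @param p1,p2 parent `pf_model`s.
#' @param max_rules rule-count cap.
#' @return list of two offspring `pf_model`s.
#' @export
crossover_models <- function(p1, p2, max_rules = 30) {
  n1 <- n_rules(p1); n2 <- n_rules(p2)
  if (n1 < 1 || n2 < 1) stop("parents must have rules", call. = FALSE)
  ## two single-rule parents admit no cut that is neither empty nor a
  ## verbatim copy of both; the pair passes through unchanged
  if (n1 == 1L && n2 == 1L) return(list(p1, p2))
  repeat {
    i <- sample.int(n1 + 1L, 1) - 1L
    j <- sample.int(n2 + 1L, 1) - 1L
    if (i == 0L && j == 0L) next         # reproduces both parents
    if (i == n1 && j == n2) next         # reproduces both parents
    if (i == 0L && j == n2) next         # o1 would be empty
    if (i == n1 && j == 0L) next         # o2 would be empty
    break
  }
  o1 <- c(p1$rules[seq_len(i)], p2$rules[seq_len(n2 - j) + j])
  o2 <- c(p2$rules[seq_len(j)], p1$rules[seq_len(n1 - i) + i])
  trim <- function(rules) {
    if (length(rules) > max_rules) rules <- rules[seq_len(max_rules)]
    lapply(seq_along(rules), function(r) {
      rules[[r]]$id <- r
      rules[[r]]
    })
  }
  list(new_pf_model(trim(o1)), new_pf_model(trim(o2)))
}

#' Mutate an individual
#'
#' With probability `mutation_prob` one whole-list mutation is applied,
#' drawn uniformly among the feasible ones: add a fresh random rule (if
#' under the rule cap), replace a random rule with a fresh one, or delete
#' a random rule (if at least two remain). Then each rule independently
#' receives, with probability `mutation_prob`, one structural tree
#' mutation ([mutate_regex_tree()]); its pattern is recompiled and its
#' weight reset to the untrained state (or redrawn at random in control
#' mode).
#'
#' @param model a `pf_model`.
#' @param cfg a [gp_config()].
#' @return the mutated `pf_model`.
#' @export
mutate_model <- function(model, cfg) {
  rnd <- cfg$mode == "random_weights"
  if (stats::runif(1) < cfg$mutation_prob) {
    ops <- c("add", "replace", "delete")
    if (n_rules(model) >= cfg$max_rules) ops <- setdiff(ops, "add")
    if (n_rules(model) < 2) ops <- setdiff(ops, "delete")
    op <- .sample1(ops)
    if (op == "add") {
      model$rules <- c(model$rules,
                       list(.random_rule(0L, cfg, random_weight = rnd)))
    } else if (op == "replace") {
      at <- sample.int(n_rules(model), 1)
      model$rules[[at]] <- .random_rule(0L, cfg, random_weight = rnd)
    } else {
      at <- sample.int(n_rules(model), 1)
      model$rules[[at]] <- NULL
    }
  }
  model$rules <- lapply(model$rules, function(r) {
    if (stats::runif(1) < cfg$mutation_prob) {
      tree <- r$tree
      if (is.null(tree)) return(r)  # externally loaded pattern: no genotype
      ## infeasible deletions are spec'd as warning no-ops at the API
      ## level; inside the engine loop they are routine
      tree <- withCallingHandlers(
        mutate_regex_tree(tree),
        warning = function(w) {
          if (grepl("no-op|single-leaf", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      r$tree <- tree
      r$pattern <- regex_pattern(tree)
      r$weight <- if (rnd) stats::runif(1, -10, 10) else 0
    }
    r
  })
  model$rules <- lapply(seq_along(model$rules), function(r) {
    model$rules[[r]]$id <- r
    model$rules[[r]]
  })
  model$fitness <- NA_real_
  model$validation <- NA_real_
  new_pf_model(model$rules, NA_real_, NA_real_)
}

#' Truncation reduction of a population
#'
#' Keeps the `S` best individuals by fitness; ties are broken by fewer
#' rules (parsimony) and then by position, so reduction is deterministic
#' and idempotent.
#'
#' @param population list of evaluated `pf_model`s.
#' @param S target population size.
#' @return list of `S` individuals.
#' @export
reduce_population <- function(population, S) {
  if (length(population) < S)
    stop("population smaller than S", call. = FALSE)
  population[.rank_population(population)[seq_len(S)]]
}

#' Evolve a rule-list model by genetic programming
#'
#' The full evolutionary loop: evaluate the population (k-fold
#' cross-validated Pearson fitness in `trained` mode; plain Pearson
#' fitness of randomly drawn weights in the `random_weights` control
#' mode), preserve the best individual unchanged (elitism), select
#' parents by tournament, recombine with probability `crossover_prob`,
#' mutate offspring, evaluate the newcomers and truncate back to the
#' population size. Fold assignment is fixed once per run so the elite's
#' fitness is stable and the best-so-far fitness never decreases.
#'
#' @param cfg a [gp_config()].
#' @param dataset a [peptide_set()] with phenotypes (the training set).
#' @return list with `model` (the best-ever individual; in trained mode
#'   its weights are retrained on the full training set), `log` (one row
#'   per generation: `generation`, `best_fitness`, `mean_fitness`,
#'   `validation`, `best_n_rules`) and `config`.
#' @export
evolve_model <- function(cfg, dataset) {
  stopifnot(inherits(cfg, "gp_config"))
  if (any(is.na(dataset$cest))) stop("dataset needs phenotypes",
                                     call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ctx <- fold_context(dataset, k = cfg$cv_folds,
                      threshold = cfg$threshold)
  trained <- cfg$mode == "trained"
  evaluate <- function(ind) {
    if (trained) {
      res <- eval_model_ctx(ind, ctx)
      ind$fitness <- res$fitness
      ind$validation <- res$validation
    } else {
      ind$fitness <- eval_model_fixed_weights(ind, ctx)
      ind$validation <- NA_real_
    }
    ind
  }
  population <- lapply(init_population(cfg), evaluate)
  S <- cfg$population_size
  best_ever <- population[[.rank_population(population)[1]]]
  log <- vector("list", cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    elite_at <- .rank_population(population)[1]
    if (!trained) {
      ## control mode: weights drift at random (elite untouched)
      population <- lapply(seq_along(population), function(i) {
        if (i == elite_at) return(population[[i]])
        evaluate(randomize_weights(population[[i]], p = cfg$mutation_prob))
      })
      elite_at <- .rank_population(population)[1]
    }
    offspring <- vector("list", 2L * (S %/% 2L))
    for (pair in seq_len(S %/% 2L)) {
      pa <- tournament_select(population, cfg$tournament_k)
      pb <- tournament_select(population, cfg$tournament_k)
      kids <- if (stats::runif(1) < cfg$crossover_prob)
        crossover_models(pa, pb, cfg$max_rules) else list(pa, pb)
      kids <- lapply(kids, mutate_model, cfg = cfg)
      offspring[[2L * pair - 1L]] <- evaluate(kids[[1]])
      offspring[[2L * pair]] <- evaluate(kids[[2]])
    }
    population <- reduce_population(c(population, offspring), S)
    top <- population[[.rank_population(population)[1]]]
    rank_pair <- .rank_population(list(best_ever, top))
    if (rank_pair[1] == 2L) best_ever <- top
    log[[gen]] <- data.frame(
      generation = gen,
      best_fitness = top$fitness,
      mean_fitness = mean(vapply(population, `[[`, numeric(1), "fitness")),
      validation = top$validation,
      best_n_rules = n_rules(top))
  }
  if (trained) {
    res <- eval_model_ctx(best_ever, ctx)
    w <- res$weights_full
    best_ever$rules <- lapply(seq_along(best_ever$rules), function(i) {
      best_ever$rules[[i]]$weight <- w[i]
      best_ever$rules[[i]]
    })
  }
  list(model = best_ever, log = do.call(rbind, log), config = cfg)
}
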