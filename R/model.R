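#' Rule-list protein-function models
#'
#' A model is an ordered list of rules; each rule carries an integer id, a
#' regular-expression pattern (optionally with its generating tree) and a
#' trained weight. A peptide's predicted score is the sum of the weights
#' of all rules whose pattern matches somewhere in the sequence.
#'
#' @param patterns character vector of patterns, or a list of
#'   `regex_tree`s.
#' @param weights numeric weights (default 0, the untrained state).
#' @return a `pf_model`.
#' @examples
#' m <- rule_model(c("K+", "RR"), weights = c(2.5, -1))
#' predict_score(m, c("RRKK", "KKAK"))
#' @export
rule_model <- function(patterns, weights = 0) {
  trees <- NULL
  if (is.list(patterns) && all(vapply(patterns, inherits, logical(1),
                                      "regex_tree"))) {
    trees <- patterns
    patterns <- vapply(trees, regex_pattern, character(1))
  }
  patterns <- as.character(patterns)
  n <- length(patterns)
  if (n < 1) stop("a model needs at least one rule", call. = FALSE)
  weights <- rep_len(as.numeric(weights), n)
  rules <- lapply(seq_len(n), function(i)
    new_rule(i, patterns[i], weights[i],
             tree = if (is.null(trees)) NULL else trees[[i]]))
  new_pf_model(rules)
}

new_rule <- function(id, pattern, weight = 0, tree = NULL) {
  .check_pattern(pattern)
  list(id = as.integer(id), pattern = pattern, weight = as.numeric(weight),
       tree = tree)
}

.check_pattern <- function(pattern) {
  ok <- tryCatch({suppressWarnings(regexpr(pattern, "", perl = TRUE)); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("invalid pattern: ", pattern, call. = FALSE)
  invisible(TRUE)
}

new_pf_model <- function(rules, fitness = NA_real_,
                         validation = NA_real_) {
  ids <- vapply(rules, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("rule ids must be unique", call. = FALSE)
  structure(list(rules = rules, fitness = fitness,
                 validation = validation), class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf("rule-list model: %d rule(s), fitness %s\n",
              length(x$rules),
              if (is.na(x$fitness)) "unset" else sprintf("%.4f", x$fitness)))
  for (r in x$rules[seq_len(min(10, length(x$rules)))])
    cat(sprintf("  %3d  %-30s %10.4f\n", r$id, r$pattern, r$weight))
  if (length(x$rules) > 10) cat("  ...\n")
  invisible(x)
}

n_rules <- function(model) length(model$rules)

model_weights <- function(model)
  vapply(model$rules, `[[`, numeric(1), "weight")

model_patterns <- function(model)
  vapply(model$rules, `[[`, character(1), "pattern")

#' Train the weight of a single rule
#'
#' The rule's pattern is scanned over every training sequence; every
#' matched substring that exists in the motif database contributes its
#' motif value times the motif length -- added when the value is at or
#' above the database threshold, subtracted when below. Matches absent
#' from the database (unseen, or longer than the largest window)
#' contribute nothing. The trained weight is the sum over all sequences
#' and matches.
#'
#' @param pattern a rule pattern (or a single-rule list as stored in a
#'   model).
#' @param train a [peptide_set()] of training sequences.
#' @param db a `motif_db` built from the same training data.
#' @return the trained weight (numeric scalar).
#' @export
train_rule_weight <- function(pattern, train, db) {
  stopifnot(inherits(db, "motif_db"))
  if (is.list(pattern)) pattern <- pattern$pattern
  .bump_train_counter()
  total <- 0
  for (s in train$sequence) {
    for (m in match_all(pattern, s)) {
      rec <- motif_lookup(db, m)
      if (is.null(rec)) next
      contrib <- rec$cest * nchar(m)
      total <- total + if (rec$cest >= db$threshold) contrib else -contrib
    }
  }
  total
}

#' Train all rule weights of a model
#'
#' Applies [train_rule_weight()] to every rule. Rules are independent, so
#' the result does not depend on evaluation order.
#'
#' @param model a `pf_model`.
#' @inheritParams train_rule_weight
#' @return the model with trained weights.
#' @export
train_model_weights <- function(model, train, db) {
  stopifnot(inherits(model, "pf_model"))
  model$rules <- lapply(model$rules, function(r) {
    r$weight <- train_rule_weight(r$pattern, train, db)
    r
  })
  model
}

#' Predicted score of peptides under a model
#'
#' The predicted score of a sequence is the sum of the weights of all
#' rules whose pattern matches at least once in it -- match presence, not
#' match count. Linear in the weights.
#'
#' @param model a `pf_model` with weights set.
#' @param sequences character vector of peptide sequences.
#' @return numeric vector of scores, one per sequence.
#' @export
predict_score <- function(model, sequences) {
  stopifnot(inherits(model, "pf_model"))
  pres <- .presence_matrix(model_patterns(model), sequences)
  as.numeric(pres %*% model_weights(model))
}

## n x R logical/numeric matrix of match presence
.presence_matrix <- function(patterns, sequences) {
  out <- matrix(0, nrow = length(sequences), ncol = length(patterns))
  for (j in seq_along(patterns)) {
    hit <- tryCatch(grepl(patterns[j], sequences, perl = TRUE),
                    error = function(e) rep(FALSE, length(sequences)))
    out[, j] <- as.numeric(hit)
  }
  out
}

## Pearson correlation with the degenerate-variance rule: a constant
## vector on either side yields 0 (an uninformative model is treated as
## uncorrelated rather than an error).
.pearson <- function(x, y) {
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Pearson fitness of a model on labeled peptides
#'
#' The objective function of the evolutionary search: the Pearson
#' correlation coefficient between the model's predicted scores and the
#' measured phenotypes. When either vector is constant (e.g. an
#' all-zero-weight model) the fitness is defined as 0.
#'
#' @param model a `pf_model` with weights set.
#' @param data a [peptide_set()] with phenotypes (at least two records).
#' @return correlation in \[-1, 1\].
#' @export
pearson_fitness <- function(model, data) {
  if (nrow(data) < 2) stop("need at least two records", call. = FALSE)
  if (any(is.na(data$cest))) stop("all records need phenotypes",
                                  call. = FALSE)
  .pearson(predict_score(model, data$sequence), data$cest)
}

#' k-fold cross-validated fitness
#'
#' Records are partitioned into `k` folds (reproducibly under `seed`).
#' For each fold, the motif database is rebuilt from the other k-1 folds
#' only -- held-out phenotypes never leak into weights -- the rule weights
#' are trained on those folds, and the Pearson correlation is computed
#' both on the training folds and on the held-out fold. The model's
#' fitness is the mean of the k training-fold correlations; the mean of
#' the k held-out correlations is reported as an overfitting monitor.
#'
#' @param model a `pf_model`.
#' @param train a [peptide_set()] with phenotypes, at least `k` records.
#' @param k number of folds.
#' @param threshold class boundary passed to [build_motif_db()].
#' @param seed optional seed fixing the fold assignment.
#' @param ctx a prebuilt fold context from [fold_context()]; when given,
#'   `k`, `threshold` and `seed` are taken from it.
#' @return list with `fitness`, `validation` and the `folds` assignment.
#' @export
kfold_fitness <- function(model, train, k = 6, threshold = 12.5,
                          seed = NULL, ctx = NULL) {
  if (is.null(ctx)) {
    if (nrow(train) < k) stop("need at least k records", call. = FALSE)
    ctx <- fold_context(train, k = k, threshold = threshold, seed = seed)
  }
  res <- eval_model_ctx(model, ctx)
  list(fitness = res$fitness, validation = res$validation,
       folds = ctx$folds)
}

#' Randomize model weights (control mode)
#'
#' Each rule's weight is independently replaced, with probability `p`, by
#' a draw from Uniform(`low`, `high`). With `p = 1` this is the
#' random-weight initialization of the control algorithm in which the
#' training step is disabled and weight space is explored by chance.
#'
#' @param model a `pf_model`.
#' @param p per-rule replacement probability.
#' @param low,high bounds of the uniform draw.
#' @return the model with (partly) randomized weights.
#' @export
randomize_weights <- function(model, p = 0.1, low = -10, high = 10) {
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  model$rules <- lapply(model$rules, function(r) {
    if (stats::runif(1) < p) r$weight <- stats::runif(1, low, high)
    r
  })
  model
}

#' Read and write rule-list models
#'
#' Models are stored as CSV with header `id,pattern,weight`. When any
#' rule retains its generating tree, a JSON side file (same path with a
#' `.trees.json` suffix) preserves the heap arrays; it is picked up again
#' on load when present. Patterns are validated row by row.
#'
#' @param model a `pf_model`.
#' @param path CSV file path.
#' @return `read_model()` returns a `pf_model`; `write_model()` the path,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pf_model"))
  tab <- data.frame(id = vapply(model$rules, `[[`, integer(1), "id"),
                    pattern = model_patterns(model),
                    weight = model_weights(model))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  trees <- lapply(model$rules, `[[`, "tree")
  if (any(!vapply(trees, is.null, logical(1)))) {
    js <- lapply(trees, function(tr)
      if (is.null(tr)) NULL else jsonlite::fromJSON(tree_to_json(tr),
                                                    simplifyVector = FALSE))
    jsonlite::write_json(js, paste0(path, ".trees.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "pattern", "weight")
  if (!all(need %in% names(tab)))
    stop("model file must have columns id,pattern,weight: ", path,
         call. = FALSE)
  rules <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({.check_pattern(tab$pattern[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("malformed pattern at row %d: %s", i,
                          tab$pattern[i]), call. = FALSE)
    rules[[i]] <- new_rule(tab$id[i], tab$pattern[i], tab$weight[i])
  }
  tree_path <- paste0(path, ".trees.json")
  if (file.exists(tree_path)) {
    js <- jsonlite::fromJSON(tree_path, simplifyVector = FALSE)
    for (i in seq_along(rules)) {
      if (!is.null(js[[i]]))
        rules[[i]]$tree <- tree_from_json(jsonlite::toJSON(
          js[[i]], auto_unbox = TRUE, null = "null"))
    }
  }
  new_pf_model(rules)
}
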