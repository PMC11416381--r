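## Fold-evaluation machinery.
##
## During a GP run the same rules are evaluated against the same training
## data thousands of times, so the engine precomputes, once per run:
##   * a fixed k-fold assignment of the training records,
##   * one motif database per fold complement (and one on the full set),
##   * a motif -> signed contribution matrix M (value x length, signed by
##     the threshold rule), one column per fold complement plus one for
##     the full training set.
## Evaluating a rule then costs one regex scan over the training
## sequences plus O(#matches) row lookups, and per-rule results are cached
## by pattern string. The definitional path (train_rule_weight) and this
## fast path are asserted to agree in the test suite.

#' Build a fold-evaluation context
#'
#' Precomputes the fold assignment, per-fold motif databases and motif
#' contribution table used to evaluate many models against the same
#' training set, as during an evolutionary run.
#'
#' @param train a [peptide_set()] with phenotypes.
#' @param k number of cross-validation folds.
#' @param threshold class boundary for the motif databases.
#' @param sizes motif window sizes.
#' @param seed optional seed fixing the fold assignment.
#' @return a `fold_context` (used by [kfold_fitness()] and
#'   [evolve_model()]).
#' @export
fold_context <- function(train, k = 6, threshold = 12.5, sizes = 1:6,
                         seed = NULL) {
  stopifnot(inherits(train, "data.frame"))
  n <- nrow(train)
  if (n < k) stop("need at least k records", call. = FALSE)
  if (any(is.na(train$cest))) stop("all records need phenotypes",
                                   call. = FALSE)
  folds <- local_seed(seed, sample(rep_len(seq_len(k), n)))
  full_db <- build_motif_db(train, threshold, sizes)
  fold_dbs <- lapply(seq_len(k), function(f)
    build_motif_db(train[folds != f, , drop = FALSE], threshold, sizes))
  motifs <- full_db$table$motif
  M <- matrix(0, nrow = length(motifs), ncol = k + 1L)
  signed_value <- function(db, motif) {
    rec <- motif_lookup(db, motif)
    if (is.null(rec)) return(0)
    v <- rec$cest * nchar(motif)
    if (rec$cest >= threshold) v else -v
  }
  for (f in seq_len(k))
    M[, f] <- vapply(motifs, signed_value, numeric(1), db = fold_dbs[[f]])
  M[, k + 1L] <- vapply(motifs, signed_value, numeric(1), db = full_db)
  index <- new.env(parent = emptyenv(), size = length(motifs))
  for (i in seq_along(motifs)) assign(motifs[i], i, envir = index)
  structure(list(sequences = train$sequence, y = train$cest,
                 folds = folds, k = k, threshold = threshold,
                 full_db = full_db, M = M, index = index,
                 cache = new.env(parent = emptyenv())),
            class = "fold_context")
}

## One regex scan of `pattern` over the context's training sequences:
## presence vector plus the rule's trained weight for each fold complement
## and for the full set. Cached by pattern string.
eval_rule_ctx <- function(pattern, ctx) {
  hit <- get0(pattern, envir = ctx$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  .bump_train_counter()
  n <- length(ctx$sequences)
  k <- ctx$k
  contrib <- matrix(0, nrow = n, ncol = k + 1L)
  presence <- logical(n)
  ms <- tryCatch(gregexpr(pattern, ctx$sequences, perl = TRUE),
                 error = function(e) {
                   warning("pattern rejected by regex engine: ", pattern,
                           call. = FALSE)
                   NULL
                 })
  if (!is.null(ms)) {
    for (i in seq_len(n)) {
      m <- ms[[i]]
      if (m[1] == -1L) next
      presence[i] <- TRUE
      subs <- substring(ctx$sequences[i], m,
                        m + attr(m, "match.length") - 1L)
      rows <- unlist(lapply(subs, get0, envir = ctx$index,
                            inherits = FALSE), use.names = FALSE)
      if (length(rows))
        contrib[i, ] <- colSums(ctx$M[rows, , drop = FALSE])
    }
  }
  w <- numeric(k + 1L)
  for (f in seq_len(k)) w[f] <- sum(contrib[ctx$folds != f, f])
  w[k + 1L] <- sum(contrib[, k + 1L])
  out <- list(presence = presence, w = w)
  assign(pattern, out, envir = ctx$cache)
  out
}

## Presence-only evaluation (random-weight control mode): never touches
## the training machinery or the counter.
presence_ctx <- function(pattern, ctx) {
  key <- paste0("p\r", pattern)
  hit <- get0(key, envir = ctx$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(grepl(pattern, ctx$sequences, perl = TRUE),
                  error = function(e) rep(FALSE, length(ctx$sequences)))
  assign(key, out, envir = ctx$cache)
  out
}

## Full model evaluation under the context: trains every rule per fold,
## scores every training sequence, and returns the mean training-fold and
## held-out-fold Pearson correlations plus the full-set weights.
eval_model_ctx <- function(model, ctx) {
  res <- lapply(model_patterns(model), eval_rule_ctx, ctx = ctx)
  n <- length(ctx$sequences)
  k <- ctx$k
  P <- vapply(res, function(r) as.numeric(r$presence), numeric(n))
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  W <- t(vapply(res, `[[`, numeric(k + 1L), "w"))
  if (ncol(W) != k + 1L) W <- matrix(W, ncol = k + 1L)
  S <- P %*% W   # n x (k+1) predicted scores per fold weighting
  r_train <- numeric(k); r_val <- numeric(k)
  for (f in seq_len(k)) {
    tr <- ctx$folds != f
    r_train[f] <- .pearson(S[tr, f], ctx$y[tr])
    r_val[f] <- if (sum(!tr) >= 2) .pearson(S[!tr, f], ctx$y[!tr]) else NA_real_
  }
  list(fitness = mean(r_train), validation = mean(r_val, na.rm = TRUE),
       weights_full = W[, k + 1L])
}

## Fitness of a model with fixed (externally set) weights: plain Pearson
## on the full training set, via cached presence vectors.
eval_model_fixed_weights <- function(model, ctx) {
  P <- vapply(model_patterns(model), function(p)
    as.numeric(presence_ctx(p, ctx)), numeric(length(ctx$sequences)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(ctx$sequences))
  s <- as.numeric(P %*% model_weights(model))
  .pearson(s, ctx$y)
}
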