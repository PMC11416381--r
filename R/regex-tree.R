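## Regular expressions encoded as depth-bounded binary trees in heap
## layout: the tree lives in a fixed list of 2^max_depth - 1 slots where
## the node at 0-based index i has children at 2i+1 and 2i+2, and
## unexpressed slots hold NULL. Internal nodes are operators, leaves hold
## one or more amino-acid letters.

.OP_ARITY <- c(concat = 2L, alternation = 2L, plus = 1L, "repeat" = 1L,
               charclass = 1L, neg_charclass = 1L, group = 1L)

## operators drawn during random generation; `group` only arises from
## rendering (quantifier operands are parenthesized automatically) and
## bracket subtrees are restricted to structure-only operators so that
## quantifiers never sit beneath a character class
.GEN_OPS <- c("concat", "alternation", "plus", "repeat",
              "charclass", "neg_charclass")
.BRACKET_OPS <- c("concat", "alternation")
.REPEAT_RANGE <- 2:9
.GROW_LEAF_PROB <- 0.35

.leaf_node <- function(payload) list(kind = "leaf", payload = payload)
.op_node <- function(op, n = NULL) {
  out <- list(kind = "op", op = op)
  if (op == "repeat") out$n <- as.integer(n)
  out
}

.heap_size <- function(max_depth) 2L^max_depth - 1L
.level0 <- function(i) floor(log2(i + 1))          # root has level 0
.node_at <- function(tree, i) tree$nodes[[i + 1L]]
.arity_of <- function(node)
  if (node$kind == "leaf") 0L else .OP_ARITY[[node$op]]

#' Build regular-expression trees by hand
#'
#' `rx_leaf()` makes a terminal node holding one or more amino-acid
#' letters; `rx_op()` makes an operator node (`concat`, `alternation`,
#' `plus`, `repeat`, `charclass`, `neg_charclass`, `group`) over its
#' children; `as_regex_tree()` packs the nested structure into the heap
#' layout used throughout the package.
#'
#' @param payload string of amino-acid letters for a leaf.
#' @param op operator name.
#' @param ... child nodes (one for unary operators, two for binary).
#' @param n repeat count, required for the `repeat` operator.
#' @param x a nested node built from `rx_leaf()`/`rx_op()`.
#' @param max_depth maximum tree depth (the heap holds
#'   `2^max_depth - 1` slots).
#' @return `as_regex_tree()` returns a `regex_tree`.
#' @examples
#' tr <- as_regex_tree(rx_op("concat",
#'   rx_op("charclass", rx_leaf("PNYIQ")),
#'   rx_op("plus", rx_leaf("K"))))
#' regex_pattern(tr)  # "[PNYIQ]K+"
#' @export
rx_leaf <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1, nzchar(payload))
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), payload))
    stop("leaf payload must use amino-acid letters only", call. = FALSE)
  c(.leaf_node(payload), list(children = list()))
}

#' @rdname rx_leaf
#' @export
rx_op <- function(op, ..., n = NULL) {
  op <- match.arg(op, names(.OP_ARITY))
  children <- list(...)
  if (length(children) != .OP_ARITY[[op]])
    stop(sprintf("operator `%s` takes %d child(ren)", op, .OP_ARITY[[op]]),
         call. = FALSE)
  if (op == "repeat" && is.null(n))
    stop("`repeat` needs a count `n`", call. = FALSE)
  c(.op_node(op, n), list(children = children))
}

#' @rdname rx_leaf
#' @export
as_regex_tree <- function(x, max_depth = 6) {
  nodes <- vector("list", .heap_size(max_depth))
  place <- function(node, i) {
    if (i >= length(nodes))
      stop("tree deeper than max_depth = ", max_depth, call. = FALSE)
    nodes[[i + 1L]] <<- node[setdiff(names(node), "children")]
    for (k in seq_along(node$children))
      place(node$children[[k]], 2L * i + k)
  }
  place(x, 0L)
  new_regex_tree(nodes, max_depth)
}

new_regex_tree <- function(nodes, max_depth) {
  structure(list(nodes = nodes, max_depth = max_depth),
            class = "regex_tree")
}

#' Generate a random regular-expression tree
#'
#' Draws a tree of depth at most `max_depth` using the standard tree
#' initialization methods of genetic programming: `full` places operators
#' on every level above the deepest (leaves only at the bottom), `grow`
#' may close any branch early with a leaf. Population-level ramping (half
#' `full`, half `grow`, depths spread over a range) is done by the caller.
#' Leaves are single amino acids drawn uniformly; inside character-class
#' subtrees only structural operators are drawn so that quantifiers never
#' end up beneath a bracket.
#'
#' @param max_depth maximum depth (a single leaf has depth 1).
#' @param method `"grow"` or `"full"`.
#' @return a `regex_tree`.
#' @export
random_regex_tree <- function(max_depth = 6, method = c("grow", "full")) {
  method <- match.arg(method)
  if (!is.numeric(max_depth) || max_depth < 1)
    stop("`max_depth` must be >= 1", call. = FALSE)
  max_depth <- as.integer(max_depth)
  nodes <- vector("list", .heap_size(max_depth))
  gen <- function(i, budget, in_bracket) {
    make_leaf <- budget == 1L ||
      (method == "grow" && stats::runif(1) < .GROW_LEAF_PROB)
    if (make_leaf) {
      nodes[[i + 1L]] <<- .leaf_node(sample(AA_ALPHABET, 1))
      return(invisible())
    }
    ops <- if (in_bracket) .BRACKET_OPS else .GEN_OPS
    op <- sample(ops, 1)
    nodes[[i + 1L]] <<- .op_node(op, n = if (op == "repeat")
      sample(.REPEAT_RANGE, 1))
    child_bracket <- in_bracket || op %in% c("charclass", "neg_charclass")
    for (k in seq_len(.OP_ARITY[[op]]))
      gen(2L * i + k, budget - 1L, child_bracket)
  }
  gen(0L, max_depth, FALSE)
  new_regex_tree(nodes, max_depth)
}

#' Depth of a regular-expression tree
#'
#' A single leaf has depth 1; an operator node has depth one more than its
#' deepest child.
#'
#' @param tree a `regex_tree`.
#' @return integer depth.
#' @export
regex_tree_depth <- function(tree) {
  stopifnot(inherits(tree, "regex_tree"))
  d <- function(i) {
    node <- .node_at(tree, i)
    a <- .arity_of(node)
    if (a == 0L) return(1L)
    1L + max(vapply(seq_len(a), function(k) d(2L * i + k), integer(1)))
  }
  d(0L)
}

#' Validate a regular-expression tree
#'
#' Checks the heap-layout invariants: a root is present, every expressed
#' operator has exactly arity-many expressed children at its child slots,
#' no orphan slots are expressed, leaf payloads use the amino-acid
#' alphabet, repeat counts are in range, and the depth respects
#' `max_depth`.
#'
#' @param tree object to check.
#' @return `TRUE`, invisibly, or an error describing the violation.
#' @export
validate_regex_tree <- function(tree) {
  if (!inherits(tree, "regex_tree")) stop("not a regex_tree", call. = FALSE)
  nodes <- tree$nodes
  if (length(nodes) != .heap_size(tree$max_depth))
    stop("heap has wrong size", call. = FALSE)
  if (is.null(nodes[[1]])) stop("root slot is empty", call. = FALSE)
  reachable <- logical(length(nodes))
  walk <- function(i) {
    node <- nodes[[i + 1L]]
    if (is.null(node)) stop("expressed node missing at index ", i,
                            call. = FALSE)
    reachable[i + 1L] <<- TRUE
    if (node$kind == "leaf") {
      if (!nzchar(node$payload) ||
          grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                node$payload))
        stop("invalid leaf payload at index ", i, call. = FALSE)
      return(invisible())
    }
    if (!node$op %in% names(.OP_ARITY))
      stop("unknown operator at index ", i, call. = FALSE)
    if (node$op == "repeat" &&
        (is.null(node$n) || node$n < min(.REPEAT_RANGE) ||
         node$n > max(.REPEAT_RANGE)))
      stop("repeat count out of range at index ", i, call. = FALSE)
    for (k in seq_len(.OP_ARITY[[node$op]])) {
      ci <- 2L * i + k
      if (ci >= length(nodes))
        stop("child of node ", i, " exceeds the depth bound", call. = FALSE)
      walk(ci)
    }
  }
  walk(0L)
  orphan <- which(!vapply(nodes, is.null, logical(1)) & !reachable)
  if (length(orphan))
    stop("unreachable expressed slot at index ", orphan[1] - 1L,
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname validate_regex_tree
#' @export
is_valid_regex_tree <- function(tree) {
  !inherits(tryCatch(validate_regex_tree(tree), error = identity), "error")
}

## distinct amino-acid letters over all leaves of a subtree, in order of
## first appearance (used to flatten bracket subtrees when rendering)
.class_letters <- function(tree, i) {
  acc <- character(0)
  walk <- function(i) {
    node <- .node_at(tree, i)
    if (node$kind == "leaf") {
      acc <<- c(acc, strsplit(node$payload, "")[[1]])
    } else {
      for (k in seq_len(.arity_of(node))) walk(2L * i + k)
    }
  }
  walk(i)
  unique(acc)
}

## a rendered fragment is a single token when quantifying it needs no
## extra parentheses: one character, one bracket expression, or one
## fully parenthesized group
.is_token <- function(s) {
  if (nchar(s) == 1L) return(TRUE)
  if (grepl("^\\[\\^?[A-Z]+\\]$", s)) return(TRUE)
  if (!startsWith(s, "(") || !endsWith(s, ")")) return(FALSE)
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  for (j in seq_along(chars)) {
    if (chars[j] == "(") depth <- depth + 1L
    if (chars[j] == ")") {
      depth <- depth - 1L
      if (depth == 0L && j < length(chars)) return(FALSE)
    }
  }
  depth == 0L
}

#' Render a tree as a regular-expression pattern
#'
#' Deterministic rendering: concatenation juxtaposes its children,
#' alternation renders as `(A|B)`, quantifiers as `X+` / `X{n}` with
#' parentheses added when the operand is more than one token, and
#' character classes as `[...]` (`[^...]` when negated) over the distinct
#' amino-acid letters of all leaves in the bracket subtree.
#'
#' @param tree a valid `regex_tree`.
#' @return pattern string (Perl-compatible syntax).
#' @export
regex_pattern <- function(tree) {
  validate_regex_tree(tree)
  render <- function(i) {
    node <- .node_at(tree, i)
    if (node$kind == "leaf") return(node$payload)
    switch(node$op,
      concat = paste0(render(2L * i + 1L), render(2L * i + 2L)),
      alternation = paste0("(", render(2L * i + 1L), "|",
                           render(2L * i + 2L), ")"),
      plus = {
        s <- render(2L * i + 1L)
        if (.is_token(s)) paste0(s, "+") else paste0("(", s, ")+")
      },
      "repeat" = {
        s <- render(2L * i + 1L)
        if (.is_token(s)) paste0(s, "{", node$n, "}")
        else paste0("(", s, "){", node$n, "}")
      },
      charclass = paste0("[", paste(.class_letters(tree, 2L * i + 1L),
                                    collapse = ""), "]"),
      neg_charclass = paste0("[^", paste(.class_letters(tree, 2L * i + 1L),
                                         collapse = ""), "]"),
      group = paste0("(", render(2L * i + 1L), ")"))
  }
  render(0L)
}

#' Find all matches of a pattern in a sequence
#'
#' Standard non-overlapping, leftmost-first regex scan (PCRE). Empty
#' matches cannot occur because leaves are non-empty and all quantifiers
#' require at least one repetition. A pattern that the engine rejects or
#' that exceeds its internal backtracking budget is treated as matching
#' nothing, with a warning.
#'
#' @param pattern pattern string.
#' @param sequence subject string.
#' @return character vector of matched substrings, in scan order.
#' @examples
#' match_all("[PNYIQ]K+", "APVPKKPRLL")  # "PKK"
#' @export
match_all <- function(pattern, sequence) {
  m <- tryCatch(gregexpr(pattern, sequence, perl = TRUE)[[1]],
                error = function(e) {
                  warning("pattern rejected by regex engine: ", pattern,
                          call. = FALSE)
                  NULL
                })
  if (is.null(m) || m[1] == -1L) return(character(0))
  substring(sequence, m, m + attr(m, "match.length") - 1L)
}

## ---- subtree surgery on the heap ----------------------------------------

.expressed_indices <- function(tree)
  which(!vapply(tree$nodes, is.null, logical(1))) - 1L

.subtree_indices <- function(tree, i) {
  acc <- integer(0)
  walk <- function(i) {
    acc <<- c(acc, i)
    node <- .node_at(tree, i)
    for (k in seq_len(.arity_of(node))) walk(2L * i + k)
  }
  walk(i)
  acc
}

.subtree_depth <- function(tree, i) {
  node <- .node_at(tree, i)
  a <- .arity_of(node)
  if (a == 0L) return(1L)
  1L + max(vapply(seq_len(a), function(k) .subtree_depth(tree, 2L * i + k),
                  integer(1)))
}

## copy the subtree rooted at `si` of `src` into position `di` of `dst`
## (slots under di must already be cleared); returns dst's node list
.graft <- function(dst_nodes, src, si, di) {
  rec <- function(si, di) {
    node <- .node_at(src, si)
    dst_nodes[[di + 1L]] <<- node
    for (k in seq_len(.arity_of(node))) rec(2L * si + k, 2L * di + k)
  }
  rec(si, di)
  dst_nodes
}

.clear_subtree <- function(tree, i) {
  tree$nodes[.subtree_indices(tree, i) + 1L] <- list(NULL)
  tree
}

.has_bracket_ancestor <- function(tree, i) {
  while (i > 0L) {
    i <- (i - 1L) %/% 2L
    node <- .node_at(tree, i)
    if (node$kind == "op" && node$op %in% c("charclass", "neg_charclass"))
      return(TRUE)
  }
  FALSE
}

#' Structural mutation of a regular-expression tree
#'
#' The four rule-level mutation kinds: `replace_subtree` substitutes a
#' uniformly chosen subtree with a freshly grown one whose depth keeps the
#' whole tree within its bound; `exchange_node` swaps one node's value
#' within its arity class (concatenation with alternation, including with
#' excluding bracket, `+` with `{n}`, a leaf amino acid with another, a
#' repeat count with another); `delete_subtree` removes a non-root subtree
#' and repairs the tree by promoting the sibling (binary parent) or
#' dropping the unary wrapper; `add_leaf_aa` appends one to four random
#' amino acids to a leaf. Every kind maps valid trees to valid trees.
#'
#' @param tree a valid `regex_tree`.
#' @param kind one of `"replace_subtree"`, `"exchange_node"`,
#'   `"delete_subtree"`, `"add_leaf_aa"`; drawn uniformly when missing.
#' @return the mutated `regex_tree`.
#' @export
mutate_regex_tree <- function(tree, kind = NULL) {
  stopifnot(inherits(tree, "regex_tree"))
  kinds <- c("replace_subtree", "exchange_node", "delete_subtree",
             "add_leaf_aa")
  kind <- if (is.null(kind)) sample(kinds, 1) else match.arg(kind, kinds)
  switch(kind,
         replace_subtree = .mut_replace(tree),
         exchange_node = .mut_exchange(tree),
         delete_subtree = .mut_delete(tree),
         add_leaf_aa = .mut_add_leaf(tree))
}

.mut_replace <- function(tree) {
  i <- .sample1(.expressed_indices(tree))
  budget <- tree$max_depth - .level0(i)
  depth <- if (budget == 1L) 1L else sample.int(budget, 1)
  sub <- if (.has_bracket_ancestor(tree, i))
    .random_bracket_subtree(depth) else random_regex_tree(depth, "grow")
  tree <- .clear_subtree(tree, i)
  tree$nodes <- .graft(tree$nodes, sub, 0L, i)
  tree
}

## a random subtree safe to live under a bracket (no quantifiers)
.random_bracket_subtree <- function(max_depth) {
  nodes <- vector("list", .heap_size(max(max_depth, 1L)))
  gen <- function(i, budget) {
    if (budget == 1L || stats::runif(1) < .GROW_LEAF_PROB) {
      nodes[[i + 1L]] <<- .leaf_node(sample(AA_ALPHABET, 1))
      return(invisible())
    }
    op <- sample(.BRACKET_OPS, 1)
    nodes[[i + 1L]] <<- .op_node(op)
    for (k in seq_len(.OP_ARITY[[op]])) gen(2L * i + k, budget - 1L)
  }
  gen(0L, as.integer(max_depth))
  new_regex_tree(nodes, as.integer(max_depth))
}

.mut_exchange <- function(tree) {
  i <- .sample1(.expressed_indices(tree))
  node <- .node_at(tree, i)
  if (node$kind == "leaf") {
    chars <- strsplit(node$payload, "")[[1]]
    j <- .sample1(seq_along(chars))
    chars[j] <- .sample1(setdiff(AA_ALPHABET, chars[j]))
    node$payload <- paste(chars, collapse = "")
  } else {
    node <- switch(node$op,
      concat = .op_node("alternation"),
      alternation = .op_node("concat"),
      charclass = .op_node("neg_charclass"),
      neg_charclass = .op_node("charclass"),
      plus = .op_node("repeat", n = sample(.REPEAT_RANGE, 1)),
      "repeat" = if (stats::runif(1) < 0.5) .op_node("plus")
                 else .op_node("repeat",
                               n = .sample1(setdiff(.REPEAT_RANGE, node$n))),
      group = node)
  }
  tree$nodes[[i + 1L]] <- node
  tree
}

.mut_delete <- function(tree) {
  candidates <- setdiff(.expressed_indices(tree), 0L)
  if (!length(candidates)) {
    warning("cannot delete the only node of a single-leaf tree",
            call. = FALSE)
    return(tree)
  }
  d <- .sample1(candidates)
  repeat {
    p <- (d - 1L) %/% 2L
    pnode <- .node_at(tree, p)
    if (.arity_of(pnode) == 2L) {
      sib <- if (d %% 2L == 1L) 2L * p + 2L else 2L * p + 1L
      keep <- new_regex_tree(
        .graft(vector("list", .heap_size(tree$max_depth)), tree, sib, 0L),
        tree$max_depth)
      tree <- .clear_subtree(tree, p)
      tree$nodes <- .graft(tree$nodes, keep, 0L, p)
      return(tree)
    }
    if (p == 0L) {
      warning("deletion would empty the tree; no-op", call. = FALSE)
      return(tree)
    }
    d <- p  # unary wrapper goes with its child
  }
}

.mut_add_leaf <- function(tree) {
  leaves <- Filter(function(i) .node_at(tree, i)$kind == "leaf",
                   .expressed_indices(tree))
  i <- .sample1(leaves)
  node <- .node_at(tree, i)
  extra <- paste(sample(AA_ALPHABET, sample.int(4L, 1), replace = TRUE),
                 collapse = "")
  node$payload <- paste0(node$payload, extra)
  tree$nodes[[i + 1L]] <- node
  tree
}

## sample(x, 1) without the length-1 surprise
.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' @export
print.regex_tree <- function(x, ...) {
  cat(sprintf("regex_tree (depth %d/%d): %s\n", regex_tree_depth(x),
              x$max_depth, regex_pattern(x)))
  invisible(x)
}

#' Serialize a tree to and from JSON
#'
#' The heap array is written verbatim (with `null` for unexpressed slots)
#' together with the compiled pattern, so files remain readable and
#' round-trip exactly.
#'
#' @param tree a `regex_tree`.
#' @param json JSON string produced by `tree_to_json()`.
#' @return `tree_to_json()` a JSON string; `tree_from_json()` a
#'   `regex_tree`.
#' @export
tree_to_json <- function(tree) {
  validate_regex_tree(tree)
  jsonlite::toJSON(list(max_depth = tree$max_depth,
                        pattern = regex_pattern(tree),
                        nodes = tree$nodes),
                   auto_unbox = TRUE, null = "null")
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    if (is.null(nd)) return(NULL)
    if (nd$kind == "leaf") .leaf_node(nd$payload)
    else .op_node(nd$op, n = nd$n)
  })
  tree <- new_regex_tree(nodes, as.integer(obj$max_depth))
  validate_regex_tree(tree)
  tree
}
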