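#' Per-residue hydropathy scale
#'
#' The default scale is the Wimley-White water-to-membrane-interface
#' free-energy scale (kcal/mol), with the charged-side-chain values for
#' Asp, Glu, Lys and Arg and the neutral value for His, appropriate for
#' peptides near physiological pH. Positive values mark residues that
#' prefer water, so a peptide whose residue sum is positive is treated as
#' hydrophilic (soluble) by the candidate filter.
#'
#' @return named numeric vector over the 20 amino acids.
#' @examples
#' sum(hydropathy_interface()[strsplit("QDGSKKSLKSCK", "")[[1]]])  # 5.37
#' @export
hydropathy_interface <- function() {
  c(A =  0.17, C = -0.24, D =  1.23, E =  2.02, F = -1.13,
    G =  0.01, H =  0.17, I = -0.31, K =  0.99, L = -0.56,
    M = -0.23, N =  0.42, P =  0.45, Q =  0.58, R =  0.81,
    S =  0.13, T =  0.14, V =  0.07, W = -1.85, Y = -0.94)
}

#' @rdname hydropathy_interface
#' @param path a CSV/TSV file with columns `aa` (one-letter code) and
#'   `value`; must cover all 20 amino acids exactly once.
#' @export
read_hydropathy_scale <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("aa", "value") %in% names(tab)))
    stop("scale file needs columns aa,value: ", path, call. = FALSE)
  scale <- stats::setNames(as.numeric(tab$value), toupper(tab$aa))
  if (!setequal(names(scale), AA_ALPHABET) || length(scale) != 20)
    stop("scale must have exactly one value per canonical amino acid",
         call. = FALSE)
  scale[AA_ALPHABET]
}

#' Hydrophilicity of peptides
#'
#' The sum of the per-residue hydropathy values over the peptide;
#' additive and order-invariant. An empty peptide scores 0.
#'
#' @param peptides character vector of peptides.
#' @param scale named per-residue scale, as from [hydropathy_interface()].
#' @return numeric vector of sums.
#' @export
hydrophilicity <- function(peptides, scale = hydropathy_interface()) {
  vapply(as.character(peptides), function(p) {
    if (!nzchar(p)) return(0)
    aa <- strsplit(p, "")[[1]]
    miss <- setdiff(aa, names(scale))
    if (length(miss)) stop("residue not covered by scale: ", miss[1],
                           call. = FALSE)
    sum(scale[aa])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Configuration of an in-silico directed-evolution run
#'
#' Defaults follow the screening protocol: a random library of 1000
#' 12-mers, hill-climbed for a chosen number of cycles (10, 100 and 1000
#' were the published settings), with the top 20 hydrophilic peptides
#' reported.
#'
#' @param library_size number of peptides in the library.
#' @param cycles number of mutate-evaluate-select cycles.
#' @param peptide_length length of every library peptide.
#' @param top_n number of candidates to report.
#' @param scale hydropathy scale for the solubility filter.
#' @param seed optional integer seed.
#' @return a `de_config`.
#' @export
de_config <- function(library_size = 1000, cycles = 100,
                      peptide_length = 12, top_n = 20,
                      scale = hydropathy_interface(), seed = NULL) {
  stopifnot(library_size >= 1, cycles >= 1, peptide_length >= 1,
            top_n >= 1)
  structure(list(library_size = as.integer(library_size),
                 cycles = as.integer(cycles),
                 peptide_length = as.integer(peptide_length),
                 top_n = as.integer(top_n), scale = scale, seed = seed),
            class = "de_config")
}

#' Random peptide library
#'
#' @param n number of peptides.
#' @param length peptide length.
#' @return character vector of `n` peptides with residues drawn uniformly
#'   from the 20-letter alphabet.
#' @export
random_peptide_library <- function(n, length = 12) {
  stopifnot(n >= 1, length >= 1)
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1))
}

#' One directed-evolution cycle
#'
#' Each library slot independently proposes a single-residue substitution
#' (the new residue always differs from the old) and keeps the mutant
#' only when its predicted score strictly exceeds the current peptide's,
#' so every slot's score is non-decreasing and the library size never
#' changes.
#'
#' @param library character vector of peptides (all the same length).
#' @param model a `pf_model` serving as the screening oracle.
#' @param scores optional precomputed scores of `library` (recycled
#'   across cycles to avoid rescoring).
#' @return the updated library, with the new scores in attribute
#'   `"scores"`.
#' @export
de_cycle <- function(library, model, scores = NULL) {
  n <- length(library)
  if (is.null(scores)) scores <- predict_score(model, library)
  len <- nchar(library)
  pos <- vapply(len, function(l) sample.int(l, 1L), integer(1))
  cur <- substr(library, pos, pos)
  new_aa <- vapply(cur, function(a) .sample1(setdiff(AA_ALPHABET, a)),
                   character(1), USE.NAMES = FALSE)
  mutants <- library
  substr(mutants, pos, pos) <- new_aa
  mutant_scores <- predict_score(model, mutants)
  accept <- mutant_scores > scores
  library[accept] <- mutants[accept]
  scores[accept] <- mutant_scores[accept]
  attr(library, "scores") <- scores
  library
}

#' Run in-silico directed evolution
#'
#' Generates a random library, applies [de_cycle()] for the configured
#' number of cycles while recording the mean and maximum predicted score
#' per cycle, then filters and ranks candidates with
#' [select_candidates()].
#'
#' @param model a `pf_model` with trained weights.
#' @param cfg a [de_config()].
#' @return a `de_result`: list with `library` (final peptides), `scores`,
#'   `trace` (per-cycle mean/max score) and `candidates` (the top
#'   hydrophilic peptides).
#' @export
run_directed_evolution <- function(model, cfg = de_config()) {
  stopifnot(inherits(cfg, "de_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  library <- random_peptide_library(cfg$library_size, cfg$peptide_length)
  scores <- predict_score(model, library)
  trace <- data.frame(cycle = seq_len(cfg$cycles), mean_score = NA_real_,
                      max_score = NA_real_)
  for (cy in seq_len(cfg$cycles)) {
    library <- de_cycle(library, model, scores)
    scores <- attr(library, "scores")
    trace$mean_score[cy] <- mean(scores)
    trace$max_score[cy] <- max(scores)
  }
  attributes(library) <- NULL
  structure(list(library = library, scores = scores, trace = trace,
                 candidates = select_candidates(library, scores,
                                                cfg$scale, cfg$top_n)),
            class = "de_result")
}

#' Filter and rank candidate peptides
#'
#' Drops every peptide whose hydrophilicity is zero or negative
#' (classified non-soluble), then returns the `top_n` remaining peptides
#' by predicted score; ties are broken by higher hydrophilicity, then
#' alphabetically. Warns when fewer than `top_n` peptides survive the
#' filter.
#'
#' @param peptides character vector.
#' @param scores predicted scores aligned with `peptides`.
#' @param scale hydropathy scale.
#' @param top_n number of candidates to keep.
#' @return data frame `rank`, `peptide`, `score`, `hydrophilicity`.
#' @export
select_candidates <- function(peptides, scores,
                              scale = hydropathy_interface(),
                              top_n = 20) {
  stopifnot(length(peptides) == length(scores))
  hyd <- hydrophilicity(peptides, scale)
  keep <- hyd > 0
  if (!any(keep)) {
    warning("no peptide passed the hydrophilicity filter", call. = FALSE)
    return(data.frame(rank = integer(0), peptide = character(0),
                      score = numeric(0), hydrophilicity = numeric(0)))
  }
  pep <- peptides[keep]; sc <- scores[keep]; hy <- hyd[keep]
  ord <- order(-sc, -hy, pep)
  n_keep <- min(top_n, length(ord))
  if (length(ord) < top_n)
    warning(sprintf("only %d peptide(s) survive the filter (requested %d)",
                    length(ord), top_n), call. = FALSE)
  ord <- ord[seq_len(n_keep)]
  data.frame(rank = seq_len(n_keep), peptide = pep[ord], score = sc[ord],
             hydrophilicity = hy[ord], stringsAsFactors = FALSE)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("directed evolution: %d peptides, %d cycles, max score %.3f\n",
              length(x$library), nrow(x$trace),
              max(x$trace$max_score)))
  print(utils::head(x$candidates, 5))
  invisible(x)
}
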