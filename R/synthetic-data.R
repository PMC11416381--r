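#' Planted motif effects for synthetic peptide data
#'
#' Defines the generative model behind [simulate_peptides()]: the
#' phenotype of a sequence is `baseline` plus, for every planted motif,
#' its additive effect times the number of (overlapping) occurrences,
#' plus Gaussian noise, clamped to a range. The default profile
#' qualitatively mirrors the composition of measured CEST peptide panels:
#' lysine-rich pair motifs push the phenotype up, acidic pairs pull it
#' down, and values live on a 0-25 scale around a class boundary of 12.5.
#'
#' @param effects named numeric vector: motif (1-6 amino acids) to
#'   additive effect.
#' @param baseline phenotype of a sequence containing no planted motif.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param clamp length-2 range to which phenotypes are clamped.
#' @return a `planted_effects` object.
#' @export
planted_effects <- function(effects = c(KK = 4, SK = 3, QS = 2, EE = -3),
                            baseline = 6, noise_sd = 1,
                            clamp = c(0, 25)) {
  stopifnot(is.numeric(effects), !is.null(names(effects)),
            all(nzchar(names(effects))), noise_sd >= 0,
            length(clamp) == 2, clamp[1] <= clamp[2])
  validate_aa_sequences(names(effects))
  if (any(nchar(names(effects)) > 6))
    stop("planted motifs must be 1-6 residues", call. = FALSE)
  structure(list(effects = effects, baseline = baseline,
                 noise_sd = noise_sd, clamp = clamp),
            class = "planted_effects")
}

#' Residue composition biased towards measured CEST peptide panels
#'
#' Sampling weights enriched in lysine, arginine, serine and threonine
#' (the residues dominating measured high-contrast peptides) and depleted
#' in the rare aromatics, normalized to sum to one.
#'
#' @return named numeric vector of sampling probabilities.
#' @export
default_composition <- function() {
  w <- stats::setNames(rep(1, 20), AA_ALPHABET)
  w[c("K", "T", "R", "S")] <- c(4, 3, 3, 3)
  w["W"] <- 1.8
  w[c("Y", "F")] <- c(0.5, 0.6)
  w / sum(w)
}

#' @rdname default_composition
#' @description `engineered_composition()` instead mimics designed
#'   high-contrast candidates (poly-lysine-like variants) that measured
#'   screening panels always contain: strongly lysine- and serine-heavy.
#'   Mixing background and engineered draws yields a panel with a
#'   meaningful class split at the 12.5 boundary.
#' @export
engineered_composition <- function() {
  w <- stats::setNames(rep(1, 20), AA_ALPHABET)
  w[c("K", "S", "R", "T")] <- c(12, 6, 2, 2)
  w / sum(w)
}

## overlapping occurrence count of `motif` in each sequence
count_occurrences <- function(sequences, motif) {
  w <- nchar(motif)
  vapply(sequences, function(s) {
    L <- nchar(s)
    if (L < w) return(0L)
    starts <- seq_len(L - w + 1L)
    sum(substring(s, starts, starts + w - 1L) == motif)
  }, integer(1), USE.NAMES = FALSE)
}

#' Simulate a peptide dataset with planted motif effects
#'
#' Draws `n` sequences residue-wise from a composition distribution with
#' lengths uniform over `lengths`, then assigns each sequence the
#' phenotype `clamp(baseline + sum_m effect(m) * occurrences(m) + noise)`
#' with overlapping occurrence counting (consistent with the sliding
#' windows of [build_motif_db()]). Fully reproducible under `seed`.
#'
#' @param n number of peptides.
#' @param lengths integer vector of admissible lengths.
#' @param effects a [planted_effects()] profile.
#' @param composition named sampling weights over the 20 amino acids, or
#'   `NULL` for uniform.
#' @param seed optional integer seed.
#' @return a [peptide_set()] with phenotypes.
#' @export
simulate_peptides <- function(n, lengths = 10:13,
                              effects = planted_effects(),
                              composition = default_composition(),
                              seed = NULL) {
  stopifnot(n >= 1, inherits(effects, "planted_effects"))
  if (is.null(composition))
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  composition <- composition[AA_ALPHABET] / sum(composition[AA_ALPHABET])
  local_seed(seed, {
    lens <- lengths[sample.int(length(lengths), n, replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
            collapse = ""), character(1))
    y <- rep(effects$baseline, n)
    for (m in names(effects$effects))
      y <- y + effects$effects[[m]] * count_occurrences(seqs, m)
    if (effects$noise_sd > 0) y <- y + stats::rnorm(n, 0, effects$noise_sd)
    y <- pmin(pmax(y, effects$clamp[1]), effects$clamp[2])
    peptide_set(seqs, y, provenance = "simulated")
  })
}

#' Fraction of peptides containing a motif
#'
#' @param peptides character vector of peptides.
#' @param motif a non-empty motif string (matched as a fixed substring).
#' @return fraction in \[0, 1\].
#' @export
motif_enrichment <- function(peptides, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  mean(grepl(motif, peptides, fixed = TRUE))
}

#' A small fixed model with known scores
#'
#' Three hand-written rules (`K+` at +3, `[ED]` at -2, `QS` at +1.5) used
#' across the test suite and examples: any run of lysines adds 3, any
#' acidic residue subtracts 2, a glutamine-serine pair adds 1.5.
#'
#' @return a `pf_model`.
#' @examples
#' predict_score(demo_model(), c("KKKK", "EDED", "AAAA"))  # 3, -2, 0
#' @export
demo_model <- function() {
  rule_model(c("K+", "[ED]", "QS"), weights = c(3, -2, 1.5))
}
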