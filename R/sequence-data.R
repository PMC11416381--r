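#' Peptide datasets
#'
#' A `peptide_set` is a plain data frame with a character column `sequence`
#' (uppercase, 20-letter amino-acid alphabet) and a numeric column `cest`
#' holding the measured phenotype -- here the CEST contrast (MTR_asym, in
#' percent, at 3.6 ppm) -- which may be `NA` for unlabeled libraries.
#'
#' @param sequence character vector of peptide sequences.
#' @param cest numeric phenotype per sequence, or `NULL` for none.
#' @param provenance optional free-text note on where the data came from.
#' @return a `peptide_set` (data frame with columns `sequence`, `cest`).
#' @examples
#' ps <- peptide_set(c("KKKKKKKKKKKK", "APVPKKPRLL"), c(12.5, 9.1))
#' nrow(ps)
#' @export
peptide_set <- function(sequence, cest = NULL, provenance = NULL) {
  sequence <- as.character(sequence)
  validate_aa_sequences(sequence)
  if (is.null(cest)) cest <- rep(NA_real_, length(sequence))
  cest <- as.numeric(cest)
  if (length(cest) != length(sequence))
    stop("`cest` must have one value per sequence", call. = FALSE)
  if (any(!is.na(cest) & !is.finite(cest)))
    stop("phenotype values must be finite or NA", call. = FALSE)
  dup <- duplicated(sequence)
  if (any(dup))
    warning(sprintf("%d duplicated sequence(s) in dataset (e.g. %s)",
                    sum(dup), sequence[which(dup)[1]]), call. = FALSE)
  out <- data.frame(sequence = sequence, cest = cest,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("peptide_set", "data.frame")
  out
}

validate_aa_sequences <- function(sequence) {
  if (length(sequence) == 0) return(invisible(TRUE))
  if (any(is.na(sequence) | nchar(sequence) == 0))
    stop("empty or missing sequence at row ",
         which(is.na(sequence) | nchar(sequence) == 0)[1], call. = FALSE)
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                 sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' in sequence at row %d",
                 substr(sequence[i], bad[i], bad[i]), i), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write peptide datasets
#'
#' Reads a delimited table with a header naming at least a `sequence`
#' column (a `cest` phenotype column is optional; extra columns are ignored
#' with a message), or a FASTA file for unlabeled libraries.
#'
#' @param path file path.
#' @param format `"auto"` (by extension/content), `"csv"`, `"tsv"` or
#'   `"fasta"`.
#' @return a [peptide_set()].
#' @export
read_peptides <- function(path, format = c("auto", "csv", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta"
              else if (ext == "tsv") "tsv"
              else if (ext == "csv") "csv"
              else if (startsWith(readLines(path, n = 1L), ">")) "fasta"
              else "csv"
  }
  if (format == "fasta") {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      seqs <- as.character(Biostrings::readAAStringSet(path))
    } else {
      seqs <- read_fasta_fallback(path)
    }
    return(peptide_set(unname(seqs), provenance = path))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (!"sequence" %in% names(tab))
    stop("dataset file must have a `sequence` column: ", path, call. = FALSE)
  extra <- setdiff(names(tab), c("sequence", "cest"))
  if (length(extra))
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("empty data section in ", path, call. = FALSE)
    return(peptide_set(character(0), provenance = path))
  }
  cest <- if ("cest" %in% names(tab)) tab$cest else NULL
  peptide_set(tab$sequence, cest, provenance = path)
}

## minimal FASTA reader used only when Biostrings is unavailable
read_fasta_fallback <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  vapply(split(lines[!hdr], grp[!hdr]),
         function(x) paste(x, collapse = ""), character(1))
}

#' @rdname read_peptides
#' @param ds a [peptide_set()].
#' @param sep field separator for writing (`","` or `"\t"`).
#' @export
write_peptides <- function(ds, path, sep = ",") {
  utils::write.table(as.data.frame(ds)[, c("sequence", "cest")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a peptide dataset into training and test sets
#'
#' Draws `ceiling(train_fraction * n)` records at random into the training
#' set; the remainder form the test set. With 158 records and an 80 percent
#' fraction this gives the conventional 127/31 split.
#'
#' @param ds a [peptide_set()].
#' @param train_fraction fraction of records to train on, in (0, 1].
#' @param seed optional integer seed for a reproducible draw.
#' @return list with elements `train` and `test`, both `peptide_set`s.
#' @export
split_peptides <- function(ds, train_fraction = 0.8, seed = NULL) {
  stopifnot(inherits(ds, "peptide_set"))
  n <- nrow(ds)
  if (n == 0) stop("cannot split an empty dataset", call. = FALSE)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction > 1)
    stop("`train_fraction` must be a single number in (0, 1]", call. = FALSE)
  n_train <- min(n, as.integer(ceiling(train_fraction * n)))
  idx <- local_seed(seed, sample.int(n, n_train))
  train <- ds[sort(idx), , drop = FALSE]
  test <- ds[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("peptide_set", "data.frame")
  list(train = train, test = test)
}

#' Pairwise percent identity of two peptides
#'
#' Counts positions (left-anchored, no alignment) at which the two
#' sequences carry the same residue and divides by the length of the
#' longer sequence, times 100. Symmetric in its arguments.
#'
#' @param a,b peptide sequences (non-empty strings).
#' @return identity in percent, in \[0, 100\].
#' @examples
#' percent_identity("KKKR", "KKKK")  # 75
#' @export
percent_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty",
                                     call. = FALSE)
  la <- nchar(a); lb <- nchar(b)
  m <- min(la, lb)
  same <- sum(strsplit(substr(a, 1, m), "")[[1]] ==
              strsplit(substr(b, 1, m), "")[[1]])
  100 * same / max(la, lb)
}

#' Distribution of pairwise sequence identities
#'
#' Computes [percent_identity()] over all unordered pairs and bins the
#' values into `[i, i + bin_width)` intervals (the top bin is closed at
#' 100). Also reports the fraction of pairs strictly above `cutoff`.
#'
#' @param x a [peptide_set()] or character vector of sequences (>= 2).
#' @param bin_width histogram bin width in percent.
#' @param cutoff identity cutoff in percent for the exceedance fraction.
#' @return list with `histogram` (data frame `bin_low`, `bin_high`,
#'   `fraction`), `fraction_above` (pairs with identity > `cutoff`),
#'   `cutoff`, and the raw `identities` vector.
#' @export
identity_distribution <- function(x, bin_width = 10, cutoff = 50) {
  seqs <- if (inherits(x, "data.frame")) x$sequence else as.character(x)
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  pairs <- utils::combn(n, 2)
  ids <- vapply(seq_len(ncol(pairs)), function(j)
    percent_identity(seqs[pairs[1, j]], seqs[pairs[2, j]]), numeric(1))
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  bin <- pmin(findInterval(ids, breaks), length(breaks) - 1L)
  frac <- tabulate(bin, nbins = length(breaks) - 1L) / length(ids)
  list(histogram = data.frame(bin_low = breaks[-length(breaks)],
                              bin_high = breaks[-1],
                              fraction = frac),
       fraction_above = mean(ids > cutoff),
       cutoff = cutoff,
       identities = ids)
}

#' Amino-acid frequencies of a dataset
#'
#' Relative frequency of each of the 20 amino acids over all residues of
#' all sequences. Frequencies sum to one.
#'
#' @param x a [peptide_set()] or character vector of sequences.
#' @return named numeric vector over the 20-letter alphabet.
#' @export
aa_frequencies <- function(x) {
  seqs <- if (inherits(x, "data.frame")) x$sequence else as.character(x)
  if (length(seqs) == 0) stop("dataset is empty", call. = FALSE)
  chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- AA_ALPHABET
  out
}

#' Magnetization transfer ratio asymmetry
#'
#' The CEST contrast readout: `(s_neg - s_pos) / s0`, where `s_neg` and
#' `s_pos` are the z-spectral amplitudes at the negative and positive
#' saturation offset (here -3.6 and +3.6 ppm) and `s0` is the unsaturated
#' reference signal.
#'
#' @param s_neg signal at the negative offset.
#' @param s_pos signal at the positive offset.
#' @param s0 reference signal (> 0).
#' @return MTR_asym (dimensionless; multiply by 100 for percent).
#' @export
mtr_asym <- function(s_neg, s_pos, s0) {
  if (any(s0 <= 0)) stop("`s0` must be positive", call. = FALSE)
  (s_neg - s_pos) / s0
}
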