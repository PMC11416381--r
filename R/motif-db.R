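#' Extract sliding-window motifs from a peptide sequence
#'
#' Applies a sliding window of each size in `sizes` (default 1 to 6
#' residues) to the sequence, yielding every contiguous substring with its
#' 0-based start position, left to right, sizes in increasing order.
#'
#' @param sequence a single peptide sequence.
#' @param sizes integer window sizes.
#' @return data frame with columns `motif`, `start` (0-based), `size`.
#' @examples
#' extract_motifs("KK")  # K at 0, K at 1, KK at 0
#' @export
extract_motifs <- function(sequence, sizes = 1:6) {
  validate_aa_sequences(sequence)
  stopifnot(length(sequence) == 1)
  L <- nchar(sequence)
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes >= 1 & sizes <= L]
  out <- lapply(sizes, function(w) {
    starts <- seq_len(L - w + 1L)
    data.frame(motif = substring(sequence, starts, starts + w - 1L),
               start = starts - 1L, size = w, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build the motif database from a training set
#'
#' Every training sequence is classed positive (1) when its phenotype is
#' `>= threshold`, else negative (0). For each unique sliding-window motif
#' the occurrences in positive and negative sequences are counted; the
#' majority class wins (ties go to class 0) and the motif's value is the
#' mean phenotype over its occurrences in the winning class. Overlapping
#' occurrences all count, and the average is over occurrences (not distinct
#' sequences), which makes the construction order-invariant.
#'
#' @param train a [peptide_set()] in which every record has a phenotype.
#' @param threshold class boundary on the phenotype scale; the default is
#'   the phenotype of the poly-L-lysine gold standard.
#' @param sizes window sizes to extract.
#' @return a `motif_db`: list with a `table` data frame (`motif`, `class`,
#'   `cest`, `count1`, `count0`), the `threshold`, `sizes` and a fast
#'   lookup index.
#' @export
build_motif_db <- function(train, threshold = 12.5, sizes = 1:6) {
  stopifnot(inherits(train, "data.frame"), nrow(train) >= 1)
  if (any(is.na(train$cest))) {
    i <- which(is.na(train$cest))[1]
    stop(sprintf("record %d (%s) has no phenotype", i, train$sequence[i]),
         call. = FALSE)
  }
  cls <- as.integer(train$cest >= threshold)
  win <- lapply(seq_len(nrow(train)), function(i) {
    m <- extract_motifs(train$sequence[i], sizes)
    data.frame(motif = m$motif, class = cls[i], cest = train$cest[i],
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, win)
  key <- win$motif
  count1 <- rowsum(win$class, key)
  count0 <- rowsum(1L - win$class, key)
  sum1 <- rowsum(win$cest * win$class, key)
  sum0 <- rowsum(win$cest * (1L - win$class), key)
  motifs <- rownames(count1)
  n1 <- as.integer(count1); n0 <- as.integer(count0)
  cls_m <- as.integer(n1 > n0)  # tie -> class 0
  cest_m <- ifelse(cls_m == 1L, as.numeric(sum1) / n1,
                   as.numeric(sum0) / n0)
  tab <- data.frame(motif = motifs, class = cls_m, cest = cest_m,
                    count1 = n1, count0 = n0, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new_motif_db(tab, threshold, sizes, nrow(train))
}

new_motif_db <- function(tab, threshold, sizes, n_sequences) {
  index <- new.env(parent = emptyenv(), size = nrow(tab))
  for (i in seq_len(nrow(tab))) assign(tab$motif[i], i, envir = index)
  structure(list(table = tab, threshold = threshold, sizes = sizes,
                 n_sequences = n_sequences, index = index),
            class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  cat(sprintf("motif database: %d motifs (window sizes %s) from %d sequences, threshold %.3g\n",
              nrow(x$table), paste(range(x$sizes), collapse = "-"),
              x$n_sequences, x$threshold))
  invisible(x)
}

#' Look up a motif in a motif database
#'
#' Exact-string lookup. Motifs that were never extracted (including any
#' string longer than the largest window) are absent.
#'
#' @param db a `motif_db` from [build_motif_db()].
#' @param motif motif string.
#' @return a one-row data frame, or `NULL` when absent.
#' @export
motif_lookup <- function(db, motif) {
  stopifnot(inherits(db, "motif_db"))
  i <- get0(motif, envir = db$index, inherits = FALSE)
  if (is.null(i)) return(NULL)
  db$table[i, , drop = FALSE]
}

#' @rdname build_motif_db
#' @param db a `motif_db`.
#' @param path file path for TSV serialization.
#' @export
write_motif_db <- function(db, path) {
  stopifnot(inherits(db, "motif_db"))
  hdr <- sprintf("# threshold=%.10g sizes=%s n_sequences=%d",
                 db$threshold, paste(db$sizes, collapse = ","),
                 db$n_sequences)
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(db$table, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname build_motif_db
#' @export
read_motif_db <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", meta),
                          sub("=.*$", "", meta))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE)
  new_motif_db(tab,
               threshold = as.numeric(meta[["threshold"]]),
               sizes = as.integer(strsplit(meta[["sizes"]], ",")[[1]]),
               n_sequences = as.integer(meta[["n_sequences"]]))
}
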