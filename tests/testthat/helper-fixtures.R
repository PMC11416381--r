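# Shared fixtures, built in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# a small labeled dataset with clearly separated classes
tiny_labeled_ds <- function() {
  peptide_set(c("WKTTAKQRLL", "AWKSTQKRIL", "TTEEDGALVP", "GEEDTALPVL",
                "WKRSQTKLIA", "DEETGALPVV"),
              c(15, 16, 5, 4, 14, 6))
}

# brute-force motif-database construction, independent of the package's
# vectorized implementation: plain loops and named-list accumulators
oracle_motif_db <- function(sequences, phenotypes, threshold, sizes = 1:6) {
  acc <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    cls <- if (phenotypes[i] >= threshold) 1L else 0L
    for (w in sizes) {
      if (w > nchar(s)) next
      for (st in 1:(nchar(s) - w + 1)) {
        m <- substr(s, st, st + w - 1)
        if (is.null(acc[[m]])) acc[[m]] <- list(n1 = 0L, n0 = 0L,
                                                v1 = 0, v0 = 0)
        if (cls == 1L) {
          acc[[m]]$n1 <- acc[[m]]$n1 + 1L
          acc[[m]]$v1 <- acc[[m]]$v1 + phenotypes[i]
        } else {
          acc[[m]]$n0 <- acc[[m]]$n0 + 1L
          acc[[m]]$v0 <- acc[[m]]$v0 + phenotypes[i]
        }
      }
    }
  }
  out <- data.frame(motif = names(acc),
                    class = NA_integer_, cest = NA_real_,
                    count1 = NA_integer_, count0 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(acc)) {
    a <- acc[[j]]
    cls <- if (a$n1 > a$n0) 1L else 0L      # tie -> class 0
    out$class[j] <- cls
    out$cest[j] <- if (cls == 1L) a$v1 / a$n1 else a$v0 / a$n0
    out$count1[j] <- a$n1
    out$count0[j] <- a$n0
  }
  out[order(out$motif), ]
}

# the Pearson correlation exactly as printed: sum of cross-deviations
# over the product of root-sum-square deviations
oracle_pearson <- function(ps, cest) {
  dp <- ps - mean(ps)
  dc <- cest - mean(cest)
  sum(dp * dc) / (sqrt(sum(dp^2)) * sqrt(sum(dc^2)))
}

random_peptides <- function(n, len = 10) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE), collapse = ""), character(1))
}
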