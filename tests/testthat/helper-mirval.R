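# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-derivations, kept independent of the package's
# implementation paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_mirna_seq <- function(len = 22) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Independent reverse complement (no Biostrings, no package code).
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Naive sliding-window seed-site scanner: builds the four literal patterns
# from first principles and tests every offset, then applies the
# highest-class-only rule by direct double loop.
oracle_seed_scan <- function(utr, mirna_seq, mirna_name = "mir") {
  dna <- chartr("U", "T", toupper(mirna_seq))
  p28 <- oracle_revcomp(substr(dna, 2, 8))
  p27 <- oracle_revcomp(substr(dna, 2, 7))
  pats <- c("8mer" = paste0(p28, "A"), "7mer-m8" = p28,
            "7mer-A1" = paste0(p27, "A"), "6mer" = p27)
  rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)
  n <- nchar(utr)
  hits <- list()
  for (cls in names(pats)) {
    L <- nchar(pats[[cls]])
    if (n < L) next
    offs <- 0:(n - L)
    subs <- substring(utr, offs + 1L, offs + L)
    found <- offs[subs == pats[[cls]]]
    for (s in found) {
      hits[[length(hits) + 1L]] <- list(cls = cls, start = s, end = s + L)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(mirna = character(), site_class = character(),
                      start = integer(), end = integer()))
  }
  keep <- rep(TRUE, length(hits))
  for (i in seq_along(hits)) {
    for (j in seq_along(hits)) {
      if (i == j) next
      if (rank[[hits[[j]]$cls]] > rank[[hits[[i]]$cls]] &&
          hits[[j]]$start <= hits[[i]]$start &&
          hits[[j]]$end >= hits[[i]]$end) {
        keep[[i]] <- FALSE
      }
    }
  }
  hits <- hits[keep]
  out <- data.frame(
    mirna = mirna_name,
    site_class = vapply(hits, `[[`, "", "cls"),
    start = vapply(hits, `[[`, 1L, "start"),
    end = vapply(hits, `[[`, 1L, "end"))
  out[order(out$start, out$site_class), ]
}

site_key <- function(df) {
  sort(paste(df$mirna, df$site_class, df$start, df$end, sep = ":"))
}

# Migration counts with one field per compartment holding the given totals:
# convenient for constructing observation-level P values exactly.
counts_from_totals <- function(treatment, M, S) {
  n <- length(M)
  do.call(rbind, lapply(seq_len(n), function(r) {
    data.frame(treatment = treatment, replicate = r, field = c(1L, 1L),
               compartment = c("migrated", "non_migrated"),
               count = c(M[[r]], S[[r]]))
  }))
}

# Independent exhaustive two-sided permutation p-value over observation
# values (labels permuted across all assignments of size nA).
oracle_exhaustive_perm_p <- function(PA, PB) {
  P <- c(PA, PB)
  nA <- length(PA)
  obs <- mean(PA) - mean(PB)
  cmb <- utils::combn(length(P), nA)
  diffs <- apply(cmb, 2, function(idx) mean(P[idx]) - mean(P[-idx]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
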