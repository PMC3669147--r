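# Annotation of a 3'UTR with canonical miRNA seed-match sites and
# cis-regulatory motifs, inter-site spacing, cooperativity pairing and
# site-ablating restriction-site mutations.
#
# Seed matching is the canonical Watson-Crick definition: the site on the
# UTR (sense strand only -- mRNA biology) is the reverse complement of
# miRNA positions 2-7 or 2-8, optionally followed by an adenosine opposite
# miRNA position 1. G:U wobble pairing is not allowed and N never matches.

SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
SITE_CLASS_RANK <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)

#' Construct a mature miRNA
#'
#' @param name miRNA name, e.g. `"mmu-miR-151-5p"`.
#' @param sequence Mature sequence, 5' to 3', RNA alphabet (A,C,G,U).
#'   Position 1 is the 5' end; natural mature miRNAs are 19-24 nt, and at
#'   least 8 nt are required for seed matching.
#' @return An object of class `mature_mirna`.
#' @export
mature_mirna <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGU]", sequence)) {
    stopf("miRNA '%s' must use the RNA alphabet A,C,G,U", name)
  }
  if (nchar(sequence) < 8) {
    stopf("miRNA '%s' is shorter than 8 nt; seed classes are undefined", name)
  }
  structure(list(name = name, sequence = sequence), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s  5'-%s-3' (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Literal DNA patterns for the four canonical seed-site classes
#'
#' On the UTR (read 5' to 3'): the 8mer is the reverse complement of miRNA
#' positions 2-8 followed by A; the 7mer-m8 omits the A; the 7mer-A1 is the
#' reverse complement of positions 2-7 followed by A; the 6mer omits the A.
#'
#' @param mirna A [mature_mirna].
#' @return Named character vector of DNA patterns, names = site classes.
#' @export
seed_site_patterns <- function(mirna) {
  stopifnot(inherits(mirna, "mature_mirna"))
  dna <- chartr("U", "T", mirna$sequence)
  seed28 <- reverse_complement(substr(dna, 2, 8))  # revcomp of positions 2-8
  seed27 <- substr(seed28, 2, 7)                    # = revcomp of positions 2-7
  c("8mer" = paste0(seed28, "A"),
    "7mer-m8" = seed28,
    "7mer-A1" = paste0(seed27, "A"),
    "6mer" = seed27)
}

# All 0-based start offsets of literal `pattern` in character vector `chars`
# (overlapping occurrences included). Vectorized over offsets.
match_starts0 <- function(chars, pattern) {
  L <- nchar(pattern)
  n <- length(chars)
  if (n < L) return(integer(0))
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    ok <- ok & chars[k:(n - L + k)] == p[[k]]
  }
  which(ok) - 1L
}

empty_sites <- function() {
  tibble::tibble(mirna = character(), site_class = character(),
                 start = integer(), end = integer(),
                 matched_subsequence = character())
}

# Drop a hit when a higher-class hit's span contains it.
drop_subsumed <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  rank <- SITE_CLASS_RANK[hits$site_class]
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    !any(rank > rank[[i]] & hits$start <= hits$start[[i]] &
           hits$end >= hits$end[[i]])
  }, TRUE)
  hits[keep, , drop = FALSE]
}

#' Find canonical seed-match sites of one miRNA on a UTR
#'
#' Scans the sense strand of a DNA-normalized UTR for every occurrence of
#' the requested site classes. Overlapping occurrences are all reported,
#' but a span is labeled with its highest class only (an 8mer is not
#' additionally reported as the 7mer/6mer it contains).
#'
#' @param utr A [seq_record] (DNA) or plain string.
#' @param mirna A [mature_mirna].
#' @param classes Site classes to scan; default all four.
#' @return A tibble with columns `mirna`, `site_class`, `start`, `end`
#'   (0-based half-open on the UTR) and `matched_subsequence`, sorted by
#'   `start` then decreasing class.
#' @examples
#' mir <- mature_mirna("example-miR", "UAGCAGCACGUAAAUAUUGGCG")
#' utr <- paste0(strrep("C", 10), "TGCTGCTA", strrep("C", 10))
#' find_seed_sites(utr, mir)  # one 8mer at (10, 18)
#' @export
find_seed_sites <- function(utr, mirna, classes = SITE_CLASSES) {
  stopifnot(inherits(mirna, "mature_mirna"))
  classes <- match.arg(classes, SITE_CLASSES, several.ok = TRUE)
  residues <- as_residues(utr, "utr")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  pats <- seed_site_patterns(mirna)[classes]
  hits <- lapply(names(pats), function(cls) {
    starts <- match_starts0(chars, pats[[cls]])
    if (length(starts) == 0) return(NULL)
    L <- nchar(pats[[cls]])
    tibble::tibble(mirna = mirna$name, site_class = cls,
                   start = starts, end = starts + L,
                   matched_subsequence = substring(residues, starts + 1L,
                                                   starts + L))
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(empty_sites())
  hits <- drop_subsumed(hits)
  hits[order(hits$start, -SITE_CLASS_RANK[hits$site_class]), , drop = FALSE]
}

#' Scan a UTR with several miRNAs at once
#'
#' @inheritParams find_seed_sites
#' @param mirnas List of [mature_mirna] objects.
#' @return Row-bound tibble of [find_seed_sites()] results.
#' @export
scan_seed_sites <- function(utr, mirnas, classes = SITE_CLASSES) {
  if (inherits(mirnas, "mature_mirna")) mirnas <- list(mirnas)
  out <- dplyr::bind_rows(lapply(mirnas, function(m) {
    find_seed_sites(utr, m, classes = classes)
  }))
  if (nrow(out) == 0) empty_sites() else out[order(out$start, out$mirna), ]
}

#' Default consensus sets for UTR regulatory motifs
#'
#' Nuclear polyadenylation signals (AATAAA family), cytoplasmic
#' polyadenylation elements (U-rich) and the AU-rich destabilization
#' pentamer, as DNA patterns. Every set is configuration, not a constant of
#' nature: published UTR annotations are often graphical, so the sets are
#' meant to be overridden when calibrating against a specific figure.
#'
#' @return Named list of character vectors (`polyA_signal`, `CPE`,
#'   `AU_rich`).
#' @export
motif_consensus_default <- function() {
  list(polyA_signal = c("AATAAA", "ATTAAA"),
       CPE = c("TTTTAT", "TTTTAAT", "TTTTTAT"),
       AU_rich = c("ATTTA"))
}

#' Find cis-regulatory motif occurrences on a UTR
#'
#' Reports every occurrence of any pattern in the consensus set, including
#' mutually overlapping hits (overlapping polyadenylation signals are a real
#' feature of UTRs and must be representable). Sense strand only.
#'
#' @param utr A [seq_record] or string (DNA).
#' @param kind Motif kind: `"polyA_signal"`, `"CPE"` or `"AU_rich"`.
#' @param consensus Character vector of DNA patterns; defaults to
#'   [motif_consensus_default()] for the kind.
#' @return Tibble with columns `kind`, `pattern`, `start`, `end` (0-based
#'   half-open), sorted by `start` then `end`.
#' @export
find_motifs <- function(utr, kind = c("polyA_signal", "CPE", "AU_rich"),
                        consensus = NULL) {
  kind <- match.arg(kind)
  if (is.null(consensus)) consensus <- motif_consensus_default()[[kind]]
  if (length(consensus) == 0) stopf("empty consensus set for %s", kind)
  consensus <- toupper(consensus)
  if (any(grepl("[^ACGT]", consensus))) {
    stopf("consensus patterns must be over the DNA alphabet")
  }
  residues <- as_residues(utr, "utr")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  hits <- dplyr::bind_rows(lapply(consensus, function(p) {
    starts <- match_starts0(chars, p)
    if (length(starts) == 0) return(NULL)
    tibble::tibble(kind = kind, pattern = p, start = starts,
                   end = starts + nchar(p))
  }))
  if (nrow(hits) == 0) {
    return(tibble::tibble(kind = character(), pattern = character(),
                          start = integer(), end = integer()))
  }
  hits[order(hits$start, hits$end), ]
}

#' Nucleotide gap between two non-overlapping sites
#'
#' The default convention counts the nucleotides strictly between the two
#' sites (`downstream$start - upstream$end`); start-to-start and end-to-end
#' conventions are provided because published inter-site distances rarely
#' state which convention they use.
#'
#' @param a,b Sites (one-row tibbles or lists with `start` and `end`).
#'   Order does not matter; the upstream site is determined by position.
#' @param convention `"between"` (default), `"start_start"` or `"end_end"`.
#' @return Integer distance under the chosen convention.
#' @export
site_gap <- function(a, b, convention = c("between", "start_start",
                                          "end_end")) {
  convention <- match.arg(convention)
  sa <- as.integer(a$start); ea <- as.integer(a$end)
  sb <- as.integer(b$start); eb <- as.integer(b$end)
  if (sb < sa || (sb == sa && eb < ea)) {  # ensure a is upstream
    tmp <- c(sa, ea); sa <- sb; ea <- eb; sb <- tmp[1]; eb <- tmp[2]
  }
  if (sb < ea) stopf("sites overlap; gap is undefined")
  switch(convention,
         between = sb - ea,
         start_start = sb - sa,
         end_end = eb - ea)
}

#' Cooperativity pairing of seed sites
#'
#' Two miRNA sites can act cooperatively when the gap between them falls in
#' the experimentally established optimal window of 6 to 40 nt. All ordered
#' (upstream, downstream) pairs of non-overlapping sites are examined; by
#' default only pairs inside the window are returned, and `all = TRUE` also
#' returns the pairs outside it with `within_optimum = FALSE`.
#'
#' @param sites Tibble of sites as returned by [find_seed_sites()] /
#'   [scan_seed_sites()] (any input order; sorted internally).
#' @param min_gap,max_gap Optimal-window bounds in nucleotides (default
#'   6 and 40).
#' @param all Return pairs outside the window too?
#' @param convention Gap convention passed to [site_gap()].
#' @return Tibble with upstream/downstream site columns, `gap_nt` and
#'   `within_optimum`.
#' @export
cooperative_pairs <- function(sites, min_gap = 6, max_gap = 40, all = FALSE,
                              convention = "between") {
  if (nrow(sites) < 2) {
    return(tibble::tibble(upstream_mirna = character(),
                          upstream_class = character(),
                          upstream_start = integer(), upstream_end = integer(),
                          downstream_mirna = character(),
                          downstream_class = character(),
                          downstream_start = integer(),
                          downstream_end = integer(),
                          gap_nt = integer(), within_optimum = logical()))
  }
  sites <- sites[order(sites$start, sites$end, sites$mirna), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sites) - 1)) {
    for (j in seq(i + 1, nrow(sites))) {
      if (sites$start[[j]] < sites$end[[i]]) next  # overlapping: no pairing
      gap <- site_gap(sites[i, ], sites[j, ], convention = convention)
      within <- gap >= min_gap && gap <= max_gap
      if (!within && !all) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        upstream_mirna = sites$mirna[[i]], upstream_class = sites$site_class[[i]],
        upstream_start = sites$start[[i]], upstream_end = sites$end[[i]],
        downstream_mirna = sites$mirna[[j]],
        downstream_class = sites$site_class[[j]],
        downstream_start = sites$start[[j]], downstream_end = sites$end[[j]],
        gap_nt = as.integer(gap), within_optimum = within)
    }
  }
  dplyr::bind_rows(rows)
}

#' Recognition sequences of the restriction enzymes used for site ablation
#' @export
restriction_sites <- c(SacI = "GAGCTC", AgeI = "ACCGGT", SalI = "GTCGAC")

#' Mutate a seed site into a restriction enzyme recognition site
#'
#' Replaces part of a seed-match span with a 6-nt restriction recognition
#' sequence so that (i) the recognition sequence lies inside the edited
#' span, (ii) re-scanning with the same miRNA finds no site of class 6mer
#' or better overlapping the edited span, and (iii) nothing outside the
#' original site span changes. The recognition sequence is right-aligned to
#' the seed-match core (the 7-nt match for 8mer/7mer-m8 sites, the 6-nt
#' match for 7mer-A1/6mer sites), which maximally disrupts seed pairing and
#' is deterministic.
#'
#' @param utr A [seq_record].
#' @param site One row of a [find_seed_sites()] result.
#' @param enzyme Enzyme name (`"SacI"`, `"AgeI"`, `"SalI"`) or a raw 6-nt
#'   recognition sequence.
#' @param mirna The [mature_mirna] the site belongs to (used to verify the
#'   ablation).
#' @return The edited [seq_record] (id suffixed with the enzyme).
#' @export
mutate_site_to_restriction <- function(utr, site, enzyme, mirna) {
  stopifnot(inherits(utr, "seq_record"), inherits(mirna, "mature_mirna"))
  if (enzyme %in% names(restriction_sites)) {
    recog <- restriction_sites[[enzyme]]
    enz_name <- enzyme
  } else {
    recog <- toupper(enzyme)
    enz_name <- recog
    if (nchar(recog) != 6 || grepl("[^ACGT]", recog)) {
      stopf("`enzyme` must be a known enzyme name or a 6-nt DNA sequence")
    }
  }
  s <- as.integer(site$start); e <- as.integer(site$end)
  cls <- as.character(site$site_class)
  if (nchar(recog) > e - s) stopf("recognition sequence longer than the site")
  seed_len <- if (cls %in% c("8mer", "7mer-m8")) 7L else 6L
  repl_end <- s + seed_len            # 0-based exclusive end of the seed core
  repl_start <- repl_end - nchar(recog)
  residues <- utr$residues
  edited <- paste0(substr(residues, 1, repl_start),
                   recog,
                   substr(residues, repl_end + 1, nchar(residues)))
  stopifnot(nchar(edited) == nchar(residues))

  before <- find_seed_sites(residues, mirna)
  after <- find_seed_sites(edited, mirna)
  overlaps_span <- after$start < e & after$end > s
  if (any(overlaps_span)) {
    stopf("ablation failed: a %s site for %s still overlaps the edited span",
          paste(after$site_class[overlaps_span], collapse = ","), mirna$name)
  }
  near <- after$start < e + 8L & after$end > s - 8L
  if (any(near)) {
    key_b <- paste(before$site_class, before$start)
    key_a <- paste(after$site_class[near], after$start[near])
    new_site <- !(key_a %in% key_b)
    if (any(new_site)) {
      stopf(paste0("replacement created a new %s site for %s at position %d ",
                   "within 8 nt of the edited span"),
            after$site_class[near][new_site][[1]], mirna$name,
            after$start[near][new_site][[1]])
    }
  }
  seq_record(paste0(utr$id, "_", enz_name, "mut"), edited,
             species = utr$species, moltype = utr$moltype)
}

#' Write seed-site or motif hits as BED6
#'
#' 0-based half-open intervals; name is `miRNA|class` for seed sites and the
#' motif kind otherwise; strand is always `"+"` (sense-strand scanning).
#'
#' @param hits Tibble from [scan_seed_sites()] or [find_motifs()].
#' @param seq_id Chromosome/sequence name column value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, seq_id, path) {
  name <- if ("mirna" %in% names(hits)) {
    paste(hits$mirna, hits$site_class, sep = "|")
  } else {
    hits$kind
  }
  bed <- data.frame(chrom = seq_id, start = hits$start, end = hits$end,
                    name = name, score = 0L, strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
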