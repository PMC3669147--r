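# Sequence input/output and coordinate handling.
#
# Internal coordinates are 0-based half-open throughout the package; anything
# quoted from the literature (GenBank-style spans) is 1-based inclusive and is
# converted at the boundary, here. The DNA alphabet is the working alphabet:
# RNA input is converted on load according to the declared moltype, so all
# scanning downstream runs on A/C/G/T/N.

DNA_LETTERS <- c("A", "C", "G", "T", "N")
RNA_LETTERS <- c("A", "C", "G", "U", "N")

normalize_residues <- function(residues, moltype) {
  residues <- toupper(residues)
  if (moltype == "DNA") chartr("U", "T", residues) else chartr("T", "U", residues)
}

validate_residues <- function(residues, moltype) {
  pat <- if (moltype == "DNA") "[^ACGTN]" else "[^ACGUN]"
  bad <- regmatches(residues, regexpr(pat, residues))
  if (length(bad) > 0) {
    stopf("illegal residue '%s' for moltype %s", bad, moltype)
  }
  invisible(residues)
}

#' Construct a sequence record
#'
#' A lightweight container for one nucleotide sequence: an identifier
#' (accession or free label), an optional species annotation, the molecule
#' type and the residues. Residues are uppercased and U/T are interconverted
#' so that a record never mixes the two alphabets; `N` is permitted but never
#' matches any motif or seed pattern downstream.
#'
#' @param id Unique identifier (accession or label).
#' @param residues Nucleotide string over A,C,G,T,U,N (case-insensitive).
#' @param species Optional free-text species annotation.
#' @param moltype `"DNA"` or `"RNA"`; residues are normalized to this
#'   alphabet (U to T for DNA, T to U for RNA).
#' @return An object of class `seq_record`.
#' @examples
#' rec <- seq_record("utr1", "acguACGT", moltype = "DNA")
#' rec$residues  # "ACGTACGT"
#' @export
seq_record <- function(id, residues, species = NA_character_,
                       moltype = c("DNA", "RNA")) {
  moltype <- match.arg(moltype)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stopf("`id` must be a non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stopf("`residues` must be a non-empty string")
  }
  residues <- toupper(residues)
  # validate before normalization so truly foreign letters are caught
  if (grepl("[^ACGTUN]", residues)) {
    bad <- regmatches(residues, regexpr("[^ACGTUN]", residues))
    stopf("illegal residue '%s' in sequence '%s'", bad, id)
  }
  residues <- normalize_residues(residues, moltype)
  structure(
    list(id = id, species = species, moltype = moltype, residues = residues),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 50) paste0(substr(x$residues, 1, 50), "...") else x$residues
  cat(sprintf("<seq_record> %s (%s, %d nt)%s\n%s\n", x$id, x$moltype, n,
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              preview))
  invisible(x)
}

seq_length <- function(rec) nchar(rec$residues)

#' Read a FASTA file into sequence records
#'
#' Parses a (possibly multi-record) FASTA file. Residues are uppercased and
#' converted to the requested alphabet (U to T when `moltype = "DNA"`).
#' Malformed headers or illegal residues raise an error naming the offending
#' line number; record order is preserved and ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @param moltype Target alphabet for the records, `"DNA"` (default) or
#'   `"RNA"`.
#' @return A list of [seq_record] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, moltype = c("DNA", "RNA")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  cur_id <- NULL
  cur_species <- NA_character_
  cur_chunks <- character()
  flush <- function() {
    if (is.null(cur_id)) return()
    residues <- paste(cur_chunks, collapse = "")
    if (!nzchar(residues)) stopf("FASTA entry '%s' has no residues", cur_id)
    rec <- seq_record(cur_id, residues, species = cur_species, moltype = moltype)
    if (rec$id %in% vapply(records, `[[`, "", "id")) {
      stopf("duplicate FASTA id '%s'", rec$id)
    }
    records[[length(records) + 1L]] <<- rec
  }
  for (k in seq_along(lines)) {
    line <- trimws(lines[[k]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      header <- trimws(sub("^>", "", line))
      if (!nzchar(header)) stopf("malformed FASTA header on line %d", k)
      toks <- strsplit(header, "\\s+")[[1]]
      cur_id <- toks[[1]]
      cur_species <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else NA_character_
      cur_chunks <- character()
    } else {
      if (is.null(cur_id)) stopf("expected FASTA header on line %d", k)
      up <- toupper(line)
      if (grepl("[^ACGTUN]", up)) {
        bad <- regmatches(up, regexpr("[^ACGTUN]", up))
        stopf("illegal residue '%s' on line %d", bad, k)
      }
      cur_chunks <- c(cur_chunks, up)
    }
  }
  flush()
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records A list of [seq_record] objects (or a single record).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "seq_record")) records <- list(records)
  stopifnot(length(records) > 0)
  seqs <- vapply(records, `[[`, "", "residues")
  ids <- vapply(records, function(r) {
    if (is.na(r$species)) r$id else paste(r$id, r$species)
  }, "")
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Extract a subsequence, optionally removing internal stretches
#'
#' Coordinates follow the 1-based inclusive convention used by sequence
#' databases (e.g. a 3'UTR quoted as "nucleotide position 926-1634"), with
#' optional 1-based inclusive exclusion spans nested inside the main span --
#' the convention used when a reference sequence is compared "without"
#' certain stretches. The result length is always the span length minus the
#' summed exclusion lengths.
#'
#' @param rec A [seq_record].
#' @param span_1based Integer pair `c(start, end)`, 1-based inclusive.
#' @param exclude_1based List of 1-based inclusive pairs to remove; must lie
#'   within the span and must not overlap each other.
#' @return A new [seq_record] with a derived id.
#' @export
extract_region <- function(rec, span_1based, exclude_1based = list()) {
  stopifnot(inherits(rec, "seq_record"))
  len <- seq_length(rec)
  s <- as.integer(span_1based[[1]]); e <- as.integer(span_1based[[2]])
  if (is.na(s) || is.na(e) || s < 1L || e < s || e > len) {
    stopf("span (%s, %s) out of bounds for sequence '%s' of length %d",
          span_1based[[1]], span_1based[[2]], rec$id, len)
  }
  if (length(exclude_1based) > 0) {
    ex <- do.call(rbind, lapply(exclude_1based, function(p) {
      as.integer(c(p[[1]], p[[2]]))
    }))
    if (any(is.na(ex)) || any(ex[, 1] > ex[, 2])) stopf("malformed exclusion span")
    if (any(ex[, 1] < s) || any(ex[, 2] > e)) {
      stopf("exclusion outside span (%d, %d)", s, e)
    }
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      stopf("overlapping exclusion spans")
    }
  } else {
    ex <- matrix(integer(), ncol = 2)
  }
  keep <- rep(TRUE, e - s + 1L)
  for (r in seq_len(nrow(ex))) {
    keep[(ex[r, 1] - s + 1L):(ex[r, 2] - s + 1L)] <- FALSE
  }
  chars <- strsplit(rec$residues, "", fixed = TRUE)[[1]][s:e]
  out <- paste(chars[keep], collapse = "")
  new_id <- sprintf("%s_%d-%d%s", rec$id, s, e,
                    if (nrow(ex) > 0) "_edited" else "")
  seq_record(new_id, out, species = rec$species, moltype = rec$moltype)
}

#' Reverse complement of a nucleotide string
#'
#' An involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param residues Nucleotide string (A,C,G,T,N for DNA; A,C,G,U,N for RNA).
#' @param moltype `"DNA"` (default) or `"RNA"`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(residues, moltype = c("DNA", "RNA")) {
  moltype <- match.arg(moltype)
  residues <- toupper(residues)
  validate_residues(residues, moltype)
  if (moltype == "DNA") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(residues)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(residues)))
  }
}
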