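#' Load a genome from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file into an
#' in-memory genome store. Sequences are uppercased, `U` is mapped to `T`,
#' and any other IUPAC ambiguity code is mapped to `N` with a warning, so the
#' stored alphabet is exactly `{A, C, G, T, N}`. The record name is the first
#' whitespace-delimited token of the header line.
#'
#' @param fasta_path path to a FASTA file.
#' @return an object of class `genome_store`: a list with elements
#'   `sequences` (named character vector of chromosome sequences) and
#'   `lengths` (named integer vector of base counts).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- load_genome(fa)
#' g$lengths
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path, call. = FALSE)
  }
  recs <- tryCatch(
    Biostrings::readBStringSet(fasta_path, format = "fasta"),
    error = function(e) {
      stop("failed to parse FASTA '", fasta_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(recs) == 0L) {
    stop("no FASTA records in ", fasta_path, call. = FALSE)
  }
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  seqs <- toupper(as.character(recs))
  seqs <- chartr("U", "T", seqs)
  n_other <- sum(nchar(seqs)) - sum(nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_other > 0L) {
    warning(n_other, " non-ACGTN base(s) mapped to N on load", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- nm
  structure(
    list(sequences = seqs, lengths = setNames(nchar(seqs), nm)),
    class = "genome_store"
  )
}

#' @export
print.genome_store <- function(x, ...) {
  cat("<genome_store> ", length(x$sequences), " chromosome(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n",
      sep = "")
  for (nm in utils::head(names(x$lengths), 10L)) {
    cat("  ", nm, ": ", x$lengths[[nm]], " bp\n", sep = "")
  }
  if (length(x$lengths) > 10L) cat("  ...\n")
  invisible(x)
}

#' Fetch a genomic subsequence
#'
#' Extracts the subsequence `[start, end)` of a chromosome using 0-based,
#' half-open coordinates (the package-internal convention; all user-facing
#' coordinates in input and output tables are 1-based inclusive). For the
#' minus strand the reverse complement of the plus-strand slice is returned.
#' Out-of-range requests are an error, never silently clipped.
#'
#' @param store a `genome_store` from [load_genome()].
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return a DNA string of length `end - start`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AACGGT"), fa)
#' g <- load_genome(fa)
#' fetch_sequence(g, "chr1", 1, 4)        # "ACG"
#' fetch_sequence(g, "chr1", 1, 4, "-")   # "CGT"
#' @export
fetch_sequence <- function(store, chrom, start, end, strand = "+") {
  stopifnot(inherits(store, "genome_store"))
  if (!chrom %in% names(store$sequences)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  len <- store$lengths[[chrom]]
  if (!(start >= 0 && start < end && end <= len)) {
    stop("interval [", start, ", ", end, ") out of range for ", chrom,
         " (length ", len, ")", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  s <- substr(store$sequences[[chrom]], start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Reverse complement with case preservation
#'
#' Standard reverse complement over `{A, C, G, T, N}`. Case is preserved per
#' character (the complement of a lowercase base is lowercase), supporting the
#' convention that variant-derived bases are rendered in lowercase within a
#' guide sequence.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' reverse_complement("AcGT")  # "ACgT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop("non-DNA character in sequence: ", seq[bad][1L], call. = FALSE)
  }
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}
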