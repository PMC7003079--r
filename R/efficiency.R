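# Position-weight-matrix efficiency scoring.
#
# The matrix config is a flat TSV with an optional "# name: <label>" header
# line and columns position, A, C, G, T. Positions are counted 1..20 from
# the PAM-distal end of the protospacer (position 20 is adjacent to the PAM).

#' Read an efficiency matrix config file
#'
#' @param path TSV file with columns `position`, `A`, `C`, `G`, `T` (20 rows,
#'   one per protospacer position counted from the PAM-distal end) and an
#'   optional leading comment line `# name: <label>` identifying the matrix
#'   version. Efficiency scores are only comparable within one matrix
#'   version; the label is stamped into result files.
#' @return an object of class `efficiency_matrix`: list with `weights`
#'   (20 x 4 numeric matrix, columns A, C, G, T) and `name`.
#' @export
read_efficiency_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("efficiency matrix file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  name <- "unnamed-matrix"
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("name:\\s*\\S+", hdr))
  if (length(m)) name <- sub("name:\\s*", "", m[1L])
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  need <- c("POSITION", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("matrix file must have columns position, A, C, G, T", call. = FALSE)
  }
  df <- df[order(df$POSITION), ]
  if (nrow(df) != 20L || !identical(as.integer(df$POSITION), 1:20)) {
    stop("matrix file must have exactly positions 1..20", call. = FALSE)
  }
  w <- as.matrix(df[, c("A", "C", "G", "T")])
  if (!all(is.finite(w))) stop("matrix weights must be finite", call. = FALSE)
  rownames(w) <- 1:20
  structure(list(weights = w, name = name), class = "efficiency_matrix")
}

#' Built-in default efficiency matrix
#'
#' Returns the package's bundled position-weight matrix
#' (`efficiency_matrix_synthetic_v1`). The weights are synthetic defaults
#' constructed for this package — they encode broad, literature-style
#' tendencies (G favored near the PAM, long-run T disfavored at the 3' end)
#' but are not fitted to any experimental cleavage dataset. For real design
#' campaigns supply a matrix trained on data for your system via the
#' `matrix` argument of [run_config()] / [score_designs()].
#'
#' @return an `efficiency_matrix`.
#' @export
default_efficiency_matrix <- function() {
  read_efficiency_matrix(
    system.file("extdata", "efficiency_matrix_synthetic_v1.tsv",
                package = "varguide", mustWork = TRUE)
  )
}

#' Protospacer efficiency score
#'
#' Sum over protospacer positions of the matrix weight for the base observed
#' at that position: `sum_i weights[i, base_i]`, positions counted 1..20
#' from the PAM-distal end. Deterministic; reported to two decimals in
#' result files.
#'
#' @param protospacer 20-nt string over A/C/G/T (case ignored).
#' @param matrix an `efficiency_matrix` (default: the bundled matrix).
#' @return numeric score.
#' @export
efficiency_score <- function(protospacer, matrix = default_efficiency_matrix()) {
  stopifnot(inherits(matrix, "efficiency_matrix"))
  p <- toupper(protospacer)
  if (nchar(p) != 20L) {
    stop("protospacer must be 20 nt, got ", nchar(p), call. = FALSE)
  }
  b <- strsplit(p, "", fixed = TRUE)[[1]]
  col <- match(b, c("A", "C", "G", "T"))
  if (anyNA(col)) stop("protospacer contains non-ACGT base", call. = FALSE)
  sum(matrix$weights[cbind(1:20, col)])
}
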