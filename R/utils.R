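`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
# Fixture generation must be a pure function of its spec, independent of
# whatever the session RNG was doing.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Longest run of consecutive T residues
#'
#' Case-insensitive longest run of T in each sequence. Runs of four or more
#' T act as RNA polymerase III terminators, so guides containing them are
#' removed by [filter_polyt()].
#'
#' @param seq character vector of DNA sequences.
#' @return integer vector of maximal T-run lengths (0 for T-free sequences).
#' @examples
#' max_t_run(c("ACGTTTAC", "TTTT", "ACGA"))
#' @export
max_t_run <- function(seq) {
  vapply(seq, function(s) {
    r <- rle(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    runs <- r$lengths[r$values == "T"]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}
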