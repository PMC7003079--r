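# Template construction and candidate guide enumeration.
#
# A template is the local reference window around a variant group together
# with the variant-applied sequence and per-base bookkeeping:
#   chars    — variant-applied sequence as a character vector
#   refcoord — for each variant-applied base, its 0-based window-relative
#              reference coordinate, or NA for inserted bases
#   derived  — variant id for bases that differ from the reference
#              (substituted or inserted), NA otherwise
#   junc     — variant id on the base immediately 3' (genome orientation) of
#              a deleted span; marks the deletion junction
# Variants are applied right-to-left (descending position) so that window
# coordinates of not-yet-applied variants stay valid.

#' Build a variant-applied template around a variant group
#'
#' Extracts the reference window spanning
#' `[first variant start - flank, last variant ref-end + flank]` (clipped to
#' the chromosome) and applies every variant of the group to produce the
#' variant-allele template sequence. Substituted and inserted bases are
#' tracked per position, deletions leave a junction marker on the first
#' retained base 3' of the deleted span, and every variant-applied position
#' maps back to a reference coordinate (or to "inserted").
#'
#' @param group a `variant_group`.
#' @param store a `genome_store`.
#' @param flank flank size in bp around the variant span (default 25, enough
#'   for any 23-nt guide + PAM footprint covering the variant, with margin
#'   for small indels).
#' @return an object of class `guide_template`, or `NULL` (with a message)
#'   when the clipped window is shorter than 23 bp or the group lies outside
#'   the chromosome.
#' @export
build_template <- function(group, store, flank = 25L) {
  stopifnot(inherits(group, "variant_group"), inherits(store, "genome_store"))
  v <- group$variants[order(pos)]
  ch <- group$chrom
  if (!ch %in% names(store$sequences)) {
    message("template skipped for ", group$id, ": unknown chromosome ", ch)
    return(NULL)
  }
  clen <- store$lengths[[ch]]
  last_end0 <- max(v$pos - 1L + nchar(v$ref))
  if (last_end0 > clen) {
    message("template skipped for ", group$id, ": variant beyond chromosome end")
    return(NULL)
  }
  ws <- max(0L, v$pos[1L] - 1L - flank)
  we <- min(clen, last_end0 + flank)
  if (we - ws < 23L) {
    message("template skipped for ", group$id,
            ": window shorter than 23 bp after clipping")
    return(NULL)
  }
  wt_seq <- substr(store$sequences[[ch]], ws + 1L, we)
  chars <- strsplit(wt_seq, "", fixed = TRUE)[[1]]
  refcoord <- seq.int(0L, length(chars) - 1L)
  derived <- rep(NA_character_, length(chars))
  junc <- rep(NA_character_, length(chars))

  for (i in rev(seq_len(nrow(v)))) {
    p0 <- v$pos[i] - 1L - ws                 # 0-based window coord of ref base 1
    rl <- nchar(v$ref[i])
    al <- nchar(v$alt[i])
    altc <- strsplit(v$alt[i], "", fixed = TRUE)[[1]]
    refc <- strsplit(v$ref[i], "", fixed = TRUE)[[1]]
    keep_n <- min(rl, al)
    sub_idx <- p0 + seq_len(keep_n)          # 1-based vector indices
    chars[sub_idx] <- altc[seq_len(keep_n)]
    diff <- altc[seq_len(keep_n)] != refc[seq_len(keep_n)]
    derived[sub_idx[diff]] <- v$id[i]
    if (al > rl) {
      # insertion: splice alt tail after the retained ref block
      at <- p0 + rl                          # insert after this 1-based index
      ins <- altc[(rl + 1L):al]
      n_ins <- length(ins)
      head_idx <- seq_len(at)
      tail_idx <- if (at < length(chars)) (at + 1L):length(chars) else integer(0)
      chars <- c(chars[head_idx], ins, chars[tail_idx])
      refcoord <- c(refcoord[head_idx], rep(NA_integer_, n_ins), refcoord[tail_idx])
      derived <- c(derived[head_idx], rep(v$id[i], n_ins), derived[tail_idx])
      junc <- c(junc[head_idx], rep(NA_character_, n_ins), junc[tail_idx])
    } else if (rl > al) {
      # deletion: drop the ref tail, mark the junction on the next base
      rm_idx <- (p0 + al + 1L):(p0 + rl)
      after_old <- p0 + rl + 1L
      keep <- setdiff(seq_along(chars), rm_idx)
      chars <- chars[keep]
      refcoord <- refcoord[keep]
      derived <- derived[keep]
      junc <- junc[keep]
      after_new <- p0 + al + 1L
      if (after_old <= length(keep) + length(rm_idx) &&
          after_new <= length(chars)) {
        junc[after_new] <- v$id[i]
      }
    }
  }

  structure(
    list(group = group, chrom = ch, window_start0 = ws, window_end0 = we,
         wt_seq = wt_seq, var_seq = paste(chars, collapse = ""),
         chars = chars, refcoord = refcoord, derived = derived, junc = junc),
    class = "guide_template"
  )
}

#' @export
print.guide_template <- function(x, ...) {
  cat("<guide_template> ", x$group$id, " on ", x$chrom, " [",
      x$window_start0 + 1L, "-", x$window_end0, "]\n  wt : ", x$wt_seq,
      "\n  var: ", x$var_seq, "\n", sep = "")
  invisible(x)
}

empty_designs <- function() {
  data.table(
    group_id = character(), chrom = character(), strand = character(),
    tpl_start0 = integer(), target_start = integer(), target_end = integer(),
    wt_sequence = character(), var_sequence = character(),
    wt_protospacer = character(), var_protospacer = character(),
    wt_pam = character(), var_pam = character(), pam_class = character(),
    variant_ids = character(), variant_dists = character(),
    polyt_wt = integer(), polyt_var = integer(), note = character()
  )
}

#' Enumerate candidate guide designs on a template
#'
#' Scans the variant-applied template sequence on both strands for every
#' position where a 20-nt protospacer is followed by a PAM matching one of
#' the requested patterns (`NGG` by default, optionally also `NAG`). A
#' candidate is kept only if at least one variant-derived base — a
#' substituted or inserted base, or a deletion junction — lies within the
#' 23-nt protospacer + PAM footprint (PAM positions included: a
#' PAM-creating or PAM-destroying variant is maximally allele-specific).
#' Footprints containing `N` are dropped.
#'
#' For every kept design the wild-type counterpart is rendered from the
#' reference window: for SNP-only groups it is simply the same coordinates
#' read from the reference; for indel groups it is anchored at the same
#' PAM-proximal reference coordinate and extended to exactly 23 reference
#' bases, so both alleles are directly comparable at one locus.
#'
#' Variant-derived bases within the footprint are lowercased in the variant
#' rendering and annotated with their distance to the PAM: 1 for the
#' protospacer base adjacent to the PAM, 20 for the PAM-distal base, and
#' 0/-1/-2 for the PAM positions N/G/G. A deletion junction is annotated at
#' the base on its PAM-proximal side.
#'
#' @param template a `guide_template` from [build_template()].
#' @param pams design PAM patterns, a subset of `c("NGG", "NAG")`.
#' @return a `data.table` with one row per design: coordinates
#'   (`target_start`/`target_end`, 1-based inclusive reference coordinates
#'   of the wild-type footprint), both renderings, PAM class, covered
#'   variant ids, distances to PAM, poly-T run lengths, and an `offsets`
#'   list-column of per-base `(id, dist)` annotations. No efficiency or
#'   specificity filtering is applied: all possible designs are returned.
#' @export
enumerate_guides <- function(template, pams = "NGG") {
  stopifnot(inherits(template, "guide_template"))
  stopifnot(all(pams %in% c("NGG", "NAG")), length(pams) >= 1L)
  ch <- template$chars
  L <- length(ch)
  if (L < 23L) return(empty_designs())
  s0s <- 0:(L - 23L)
  plus_ok <- rep(FALSE, length(s0s))
  minus_ok <- rep(FALSE, length(s0s))
  if ("NGG" %in% pams) {
    plus_ok <- plus_ok | (ch[s0s + 22L] == "G" & ch[s0s + 23L] == "G")
    minus_ok <- minus_ok | (ch[s0s + 1L] == "C" & ch[s0s + 2L] == "C")
  }
  if ("NAG" %in% pams) {
    plus_ok <- plus_ok | (ch[s0s + 22L] == "A" & ch[s0s + 23L] == "G")
    minus_ok <- minus_ok | (ch[s0s + 1L] == "C" & ch[s0s + 2L] == "T")
  }
  rows <- list()
  offsets <- list()
  for (s0 in s0s[plus_ok]) {
    r <- render_design(template, s0, "+")
    if (!is.null(r)) { rows[[length(rows) + 1L]] <- r$row
                       offsets[[length(offsets) + 1L]] <- r$offsets }
  }
  for (s0 in s0s[minus_ok]) {
    r <- render_design(template, s0, "-")
    if (!is.null(r)) { rows[[length(rows) + 1L]] <- r$row
                       offsets[[length(offsets) + 1L]] <- r$offsets }
  }
  if (!length(rows)) return(empty_designs())
  out <- rbindlist(rows)
  out[, offsets := offsets]
  # duplicates can arise within a group when overlapping candidates render
  # identically; keep the first occurrence
  keep <- !duplicated(out[, .(strand, target_start, var_sequence)])
  out <- out[keep]
  out[]
}

# Render one candidate footprint [s0, s0+22] (0-based template coords) as a
# design row, or NULL if the footprint has no variant-derived base, touches
# an N, or its wild-type counterpart falls outside the template window.
render_design <- function(template, s0, strand) {
  ch <- template$chars
  foot <- (s0 + 1L):(s0 + 23L)             # 1-based vector indices
  fc <- ch[foot]
  if (any(fc == "N")) return(NULL)
  dmask <- !is.na(template$derived[foot])
  jset <- foot[!is.na(template$junc[foot])]
  jset <- jset[jset > s0 + 1L]             # junction needs both flanks inside
  if (!any(dmask) && !length(jset)) return(NULL)

  dist_of <- function(q) {                 # q: 1-based template index
    if (strand == "+") s0 + 21L - q else q - 2L - s0 - 1L
  }
  jflank <- if (length(jset)) {
    if (strand == "+") jset else jset - 1L
  } else integer(0)
  der_idx <- foot[dmask]
  lower_idx <- sort(unique(c(der_idx, jflank)))

  off <- rbind(
    if (length(der_idx))
      data.table(id = template$derived[der_idx],
                 dist = vapply(der_idx, dist_of, integer(1))),
    if (length(jset))
      data.table(id = template$junc[jset],
                 dist = vapply(jflank, dist_of, integer(1)))
  )
  off <- unique(off)[order(-dist)]

  # wild-type counterpart, anchored at the PAM-proximal reference coordinate
  refcoord <- template$refcoord
  if (strand == "+") {
    p <- s0 + 23L
    while (p > s0 && is.na(refcoord[p])) p <- p - 1L
    if (p == s0) return(NULL)              # footprint entirely inserted bases
    d <- (s0 + 23L) - p
    wt_end <- refcoord[p] + d
    wt_start <- wt_end - 22L
  } else {
    p <- s0 + 1L
    while (p <= s0 + 23L && is.na(refcoord[p])) p <- p + 1L
    if (p > s0 + 23L) return(NULL)
    d <- p - (s0 + 1L)
    wt_start <- refcoord[p] - d
    wt_end <- wt_start + 22L
  }
  if (wt_start < 0L || wt_end >= nchar(template$wt_seq)) return(NULL)
  wt23 <- substr(template$wt_seq, wt_start + 1L, wt_end + 1L)
  if (grepl("N", wt23, fixed = TRUE)) return(NULL)

  vfc <- fc
  rel <- lower_idx - s0
  vfc[rel] <- tolower(vfc[rel])
  var23 <- paste(vfc, collapse = "")
  if (strand == "-") {
    var23 <- reverse_complement(var23)
    wt23 <- reverse_complement(wt23)
  }
  pam <- toupper(substr(var23, 21L, 23L))
  pam_class <- if (substr(pam, 2L, 3L) == "GG") "NGG" else "NAG"

  row <- data.table(
    group_id = template$group$id,
    chrom = template$chrom,
    strand = strand,
    tpl_start0 = s0,
    target_start = template$window_start0 + wt_start + 1L,
    target_end = template$window_start0 + wt_end + 1L,
    wt_sequence = wt23,
    var_sequence = var23,
    wt_protospacer = substr(wt23, 1L, 20L),
    var_protospacer = substr(var23, 1L, 20L),
    wt_pam = substr(wt23, 21L, 23L),
    var_pam = substr(var23, 21L, 23L),
    pam_class = pam_class,
    variant_ids = paste(unique(off$id), collapse = ";"),
    variant_dists = paste(off$dist, collapse = ";"),
    polyt_wt = max_t_run(substr(wt23, 1L, 20L)),
    polyt_var = max_t_run(substr(var23, 1L, 20L)),
    note = ""
  )
  list(row = row, offsets = off)
}

#' Remove guides with poly-T Pol III terminators
#'
#' Drops every design whose variant protospacer (sense orientation, as
#' synthesized; case-insensitive) contains a run of more than `maxT`
#' consecutive thymines. Runs of four or more T terminate RNA polymerase III
#' transcription, so such guides cannot be expressed from standard sgRNA
#' cassettes. The variant allele governs the filter (that is the sequence
#' actually synthesized); both alleles' maximal T runs are reported in the
#' design table for transparency.
#'
#' @param designs a design `data.table` from [enumerate_guides()].
#' @param maxT longest permitted T run (default 3, i.e. reject `TTTT`).
#' @return the retained designs; the number removed is attached as the
#'   `"n_removed"` attribute.
#' @export
filter_polyt <- function(designs, maxT = 3L) {
  if (nrow(designs) == 0L) {
    setattr(designs, "n_removed", 0L)
    return(designs)
  }
  keep <- designs$polyt_var <= maxT
  out <- designs[keep]
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(n_removed, " design(s) removed by poly-T filter")
  }
  setattr(out, "n_removed", n_removed)
  out[]
}
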