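# Genome-wide mismatch-tolerant off-target search.
#
# Every 23-nt genomic site (both strands) whose last 3 nt match NGG or NAG
# is enumerated once, up front. Queries are then resolved by seed-and-extend:
# the 20-nt protospacer is partitioned into max_mm + 1 non-overlapping seed
# k-mers (k = floor(20 / (max_mm + 1))); by the pigeonhole principle a site
# within max_mm mismatches must match at least one seed exactly, so exact
# seed lookup followed by full Hamming verification retrieves every hit —
# the search is lossless, unlike heuristic alignment.

#' Build a genome-wide PAM-site index for off-target search
#'
#' Enumerates every 23-nt site on both strands whose 3' 3-mer matches a PAM
#' pattern (for off-target purposes both `NGG` and `NAG` are always
#' considered, regardless of the design PAM set) and prepares the site table
#' for seed-indexed mismatch search. Sites whose protospacer contains `N`
#' are excluded.
#'
#' @param store a `genome_store`.
#' @param pams PAM classes to index; default (and recommended) both
#'   `c("NGG", "NAG")`.
#' @return an object of class `offtarget_index`.
#' @export
build_offtarget_index <- function(store, pams = c("NGG", "NAG")) {
  stopifnot(inherits(store, "genome_store"), all(pams %in% c("NGG", "NAG")))
  parts <- list()
  for (chrom in names(store$sequences)) {
    s <- store$sequences[[chrom]]
    L <- store$lengths[[chrom]]
    if (L < 23L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    i0 <- 0:(L - 23L)                       # 0-based footprint starts
    # plus strand: PAM at positions 21-23 of the footprint
    b2 <- ch[i0 + 22L]; b3 <- ch[i0 + 23L]
    p_ngg <- if ("NGG" %in% pams) b2 == "G" & b3 == "G" else FALSE
    p_nag <- if ("NAG" %in% pams) b2 == "A" & b3 == "G" else FALSE
    # minus strand: footprint read 3'->5' on plus; NGG appears as CCN,
    # NAG as CTN at the footprint's left end
    c1 <- ch[i0 + 1L]; c2 <- ch[i0 + 2L]
    m_ngg <- if ("NGG" %in% pams) c1 == "C" & c2 == "C" else FALSE
    m_nag <- if ("NAG" %in% pams) c1 == "C" & c2 == "T" else FALSE
    rcs <- reverse_complement(s)
    add_sites <- function(idx, strand, pam_class) {
      if (!length(idx)) return(NULL)
      if (strand == "+") {
        proto <- substring(s, idx + 1L, idx + 20L)
      } else {
        # protospacer = revcomp of plus-strand [i+3, i+23); read from the
        # precomputed chromosome reverse complement
        proto <- substring(rcs, L - idx - 22L, L - idx - 3L)
      }
      ok <- !grepl("N", proto, fixed = TRUE)
      if (!any(ok)) return(NULL)
      data.table(chrom = chrom, start0 = idx[ok], strand = strand,
                 pam_class = pam_class, protospacer = proto[ok])
    }
    parts[[length(parts) + 1L]] <- add_sites(i0[p_ngg], "+", "NGG")
    parts[[length(parts) + 1L]] <- add_sites(i0[p_nag], "+", "NAG")
    parts[[length(parts) + 1L]] <- add_sites(i0[m_ngg], "-", "NGG")
    parts[[length(parts) + 1L]] <- add_sites(i0[m_nag], "-", "NAG")
  }
  sites <- rbindlist(parts[!vapply(parts, is.null, logical(1))])
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.table(chrom = character(), start0 = integer(),
                        strand = character(), pam_class = character(),
                        protospacer = character())
  }
  setorder(sites, chrom, start0, strand)
  mat <- if (nrow(sites)) {
    vapply(sites$protospacer, utf8ToInt, integer(20), USE.NAMES = FALSE)
  } else {
    matrix(integer(0), nrow = 20L)
  }
  structure(
    list(sites = sites, mat = mat, seeds = new.env(parent = emptyenv())),
    class = "offtarget_index"
  )
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat("<offtarget_index> ", nrow(x$sites), " PAM-adjacent sites\n", sep = "")
  invisible(x)
}

seed_table <- function(index, max_mm) {
  key <- as.character(max_mm)
  tab <- index$seeds[[key]]
  if (!is.null(tab)) return(tab)
  ns <- max_mm + 1L
  k <- 20L %/% ns
  starts <- (seq_len(ns) - 1L) * k + 1L
  n <- nrow(index$sites)
  tab <- rbindlist(lapply(seq_len(ns), function(j) {
    data.table(
      key.. = paste0(j, ":", substring(index$sites$protospacer,
                                       starts[j], starts[j] + k - 1L)),
      site = seq_len(n)
    )
  }))
  setkey(tab, key..)
  assign(key, tab, envir = index$seeds)
  tab
}

empty_hits <- function() {
  data.table(chrom = character(), start0 = integer(), strand = character(),
             mismatches = integer(), pam_class = character(),
             is_on_target = logical())
}

#' Find all off-target sites of a protospacer
#'
#' Returns every indexed PAM-adjacent genomic site whose protospacer is
#' within `max_mm` substitutions (Hamming distance; no gaps) of the query.
#' Completeness is guaranteed by the non-overlapping seed construction. The
#' hit overlapping `on_target` on the same strand, if any, is flagged
#' `is_on_target`.
#'
#' @param protospacer 20-nt query (case ignored).
#' @param index an `offtarget_index`.
#' @param max_mm maximum mismatches (default 3; sensible range 0..5).
#' @param on_target optional list `(chrom, start0, end0, strand)` describing
#'   the intended 23-nt footprint in 0-based half-open coordinates.
#' @return a `data.table` of hits: `chrom`, `start0`, `strand`,
#'   `mismatches`, `pam_class`, `is_on_target`, ordered by position.
#' @export
find_offtargets <- function(protospacer, index, max_mm = 3L, on_target = NULL) {
  stopifnot(inherits(index, "offtarget_index"))
  q <- toupper(protospacer)
  if (nchar(q) != 20L || grepl("[^ACGT]", q)) {
    stop("query protospacer must be 20 nt over ACGT", call. = FALSE)
  }
  if (max_mm < 0L) stop("max_mm must be >= 0", call. = FALSE)
  if (nrow(index$sites) == 0L) return(empty_hits())
  tab <- seed_table(index, max_mm)
  ns <- max_mm + 1L
  k <- 20L %/% ns
  starts <- (seq_len(ns) - 1L) * k + 1L
  qkeys <- paste0(seq_len(ns), ":", substring(q, starts, starts + k - 1L))
  cand <- unique(tab[J(qkeys), site, nomatch = 0L])
  if (!length(cand)) return(empty_hits())
  qv <- utf8ToInt(q)
  mm <- colSums(index$mat[, cand, drop = FALSE] != qv)
  keep <- mm <= max_mm
  if (!any(keep)) return(empty_hits())
  hits <- index$sites[cand[keep],
                      .(chrom, start0, strand, pam_class)]
  hits[, mismatches := as.integer(mm[keep])]
  hits[, is_on_target := FALSE]
  if (!is.null(on_target)) {
    hits[chrom == on_target$chrom & strand == on_target$strand &
           start0 < on_target$end0 & start0 + 23L > on_target$start0,
         is_on_target := TRUE]
  }
  setorder(hits, chrom, start0, strand)
  setcolorder(hits, c("chrom", "start0", "strand", "mismatches",
                      "pam_class", "is_on_target"))
  hits[]
}

#' Aggregate off-target hits into a specificity score
#'
#' `spec = 1 / (1 + sum over off-target hits of 4^(-m) * p)` where `m` is
#' the hit's mismatch count and `p` is 1 for NGG hits and 0.2 for the weaker
#' NAG PAM. The on-target hit is excluded. The score is 1 when the guide has
#' no off-target site within the searched mismatch radius and decreases
#' monotonically as hits are added, close hits weighing most. This scalar is
#' a convenience summary — the per-mismatch tallies reported alongside carry
#' the full information.
#'
#' @param hits a hit `data.table` from [find_offtargets()].
#' @return numeric in (0, 1].
#' @export
specificity_score <- function(hits) {
  if (nrow(hits) == 0L) return(1)
  off <- hits[!(is_on_target)]
  if (nrow(off) == 0L) return(1)
  w <- 4^(-off$mismatches) * ifelse(off$pam_class == "NGG", 1, 0.2)
  1 / (1 + sum(w))
}

format_hit_tally <- function(hits, max_mm) {
  off <- hits[!(is_on_target)]
  tal <- function(cls) {
    cnt <- tabulate(off[pam_class == cls, mismatches] + 1L, nbins = max_mm + 1L)
    paste(cnt, collapse = "/")
  }
  paste0("NGG:", tal("NGG"), ";NAG:", tal("NAG"))
}

#' Score a single design on both alleles
#'
#' Computes efficiency scores for the wild-type and variant protospacers and
#' runs the off-target search for both: the wild-type guide against the
#' reference index and the variant guide against the alternate-genome index
#' when one is provided, else against the reference index (in which case a
#' variant-specific guide typically shows a near-hit at its own wild-type
#' locus whose mismatch count equals the number of variant bases in the
#' protospacer — directly informative for allele discrimination).
#'
#' @param design one row of a design `data.table`.
#' @param matrix an `efficiency_matrix`.
#' @param ref_index `offtarget_index` of the reference genome.
#' @param alt_index optional `offtarget_index` of an alternate genome.
#' @param max_mm maximum mismatches searched (default 3).
#' @return a list: `design`, `eff_wt`, `eff_var`, `hits_wt`, `hits_var`,
#'   `spec_wt`, `spec_var`.
#' @export
score_design <- function(design, matrix = default_efficiency_matrix(),
                         ref_index, alt_index = NULL, max_mm = 3L) {
  on_target <- list(chrom = design$chrom, start0 = design$target_start - 1L,
                    end0 = design$target_end, strand = design$strand)
  hits_wt <- find_offtargets(design$wt_protospacer, ref_index, max_mm,
                             on_target)
  hits_var <- find_offtargets(toupper(design$var_protospacer),
                              alt_index %||% ref_index, max_mm, on_target)
  list(
    design = design,
    eff_wt = efficiency_score(design$wt_protospacer, matrix),
    eff_var = efficiency_score(toupper(design$var_protospacer), matrix),
    hits_wt = hits_wt, hits_var = hits_var,
    spec_wt = specificity_score(hits_wt),
    spec_var = specificity_score(hits_var)
  )
}

#' Score a design table on both alleles
#'
#' Vectorised wrapper around the per-design scoring of [score_design()],
#' appending score and hit-summary columns to the design table:
#' `eff_wt`/`eff_var`, `spec_wt`/`spec_var`, `hits_wt_by_mm`/`hits_var_by_mm`
#' (off-target counts per mismatch level, split by PAM class, on-target hit
#' excluded) and `ontarget_wt_mm`/`ontarget_var_mm` (mismatch count of the
#' on-target-locus hit, `NA` when the locus carries no indexed PAM site).
#'
#' @inheritParams score_design
#' @param designs a design `data.table` from [enumerate_guides()] /
#'   [filter_polyt()].
#' @return the design table with scoring columns appended.
#' @export
score_designs <- function(designs, matrix = default_efficiency_matrix(),
                          ref_index, alt_index = NULL, max_mm = 3L) {
  n <- nrow(designs)
  out <- copy(designs)
  cols <- list(eff_wt = numeric(n), eff_var = numeric(n),
               spec_wt = numeric(n), spec_var = numeric(n),
               hits_wt_by_mm = character(n), hits_var_by_mm = character(n),
               ontarget_wt_mm = rep(NA_integer_, n),
               ontarget_var_mm = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    sc <- score_design(out[i], matrix, ref_index, alt_index, max_mm)
    cols$eff_wt[i] <- sc$eff_wt
    cols$eff_var[i] <- sc$eff_var
    cols$spec_wt[i] <- sc$spec_wt
    cols$spec_var[i] <- sc$spec_var
    cols$hits_wt_by_mm[i] <- format_hit_tally(sc$hits_wt, max_mm)
    cols$hits_var_by_mm[i] <- format_hit_tally(sc$hits_var, max_mm)
    ot_wt <- sc$hits_wt[is_on_target == TRUE]
    ot_var <- sc$hits_var[is_on_target == TRUE]
    if (nrow(ot_wt)) cols$ontarget_wt_mm[i] <- min(ot_wt$mismatches)
    if (nrow(ot_var)) cols$ontarget_var_mm[i] <- min(ot_var$mismatches)
  }
  for (nm in names(cols)) set(out, j = nm, value = cols[[nm]])
  out[]
}

#' Write off-target hits as BED6
#'
#' Dumps a hit table as BED6 lines (`chrom`, `start`, `end`,
#' `name=<guide_id>;mm=<k>;pam=<class>`, `score=mismatches`, `strand`).
#'
#' @param hits hit `data.table` from [find_offtargets()].
#' @param guide_id identifier written into the name field.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, guide_id, path) {
  bed <- hits[, .(chrom, start = start0, end = start0 + 23L,
                  name = sprintf("%s;mm=%d;pam=%s", guide_id, mismatches,
                                 pam_class),
                  score = mismatches, strand)]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
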