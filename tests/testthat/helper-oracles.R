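# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's index/enumeration code paths: sites are found by direct
# 23-mer extraction, mismatches by per-position character comparison.

library(data.table)

rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

make_store <- function(seqs) load_genome(write_fasta(seqs))

write_variant_csv <- function(dt, path = tempfile(fileext = ".csv")) {
  header <- if ("id" %in% names(dt)) "chrom,pos,ref,alt,id" else "chrom,pos,ref,alt"
  writeLines(c(header, do.call(paste, c(unname(as.list(dt)), sep = ","))), path)
  path
}

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
        collapse = "")
}

# Exhaustive both-strand scan for PAM-adjacent 23-nt sites.
oracle_sites <- function(seq, chrom) {
  L <- nchar(seq)
  empty <- data.table(chrom = character(), start0 = integer(),
                      strand = character(), pam_class = character(),
                      protospacer = character())
  if (L < 23L) return(empty)
  starts <- 1:(L - 22L)
  mer <- substring(seq, starts, starts + 22L)
  p2 <- substring(mer, 22L, 22L); p3 <- substring(mer, 23L, 23L)
  m1 <- substring(mer, 1L, 1L); m2 <- substring(mer, 2L, 2L)
  pieces <- list(
    list(sel = p2 == "G" & p3 == "G", strand = "+", pam = "NGG"),
    list(sel = p2 == "A" & p3 == "G", strand = "+", pam = "NAG"),
    list(sel = m1 == "C" & m2 == "C", strand = "-", pam = "NGG"),
    list(sel = m1 == "C" & m2 == "T", strand = "-", pam = "NAG")
  )
  out <- rbindlist(lapply(pieces, function(p) {
    idx <- which(p$sel)
    if (!length(idx)) return(NULL)
    proto <- if (p$strand == "+") {
      substring(mer[idx], 1L, 20L)
    } else {
      vapply(substring(mer[idx], 4L, 23L), oracle_rc, character(1),
             USE.NAMES = FALSE)
    }
    keep <- !grepl("N", proto, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table(chrom = chrom, start0 = idx[keep] - 1L, strand = p$strand,
               pam_class = p$pam, protospacer = proto[keep])
  }))
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out
}

# Exhaustive Hamming hit scan over a brute-force site table.
oracle_hits <- function(guide, sites, max_mm) {
  if (nrow(sites) == 0L) {
    return(data.table(chrom = character(), start0 = integer(),
                      strand = character(), mismatches = integer(),
                      pam_class = character()))
  }
  qs <- strsplit(toupper(guide), "", fixed = TRUE)[[1]]
  mm <- integer(nrow(sites))
  for (i in 1:20) {
    mm <- mm + (substring(sites$protospacer, i, i) != qs[i])
  }
  out <- sites[mm <= max_mm, .(chrom, start0, strand, pam_class)]
  out[, mismatches := mm[mm <= max_mm]]
  setorder(out, chrom, start0, strand)
  out[]
}

# Positional brute force over a variant-applied template: every 23-mer on
# both strands passing (PAM match AND variant coverage). derived0 are
# 0-based variant-derived base positions in var_seq; junc0 are 0-based
# indices of the first retained base after a deleted span.
oracle_enumerate <- function(var_seq, derived0, junc0, pams = "NGG") {
  ch <- strsplit(var_seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- list()
  if (L < 23L) return(data.table(strand = character(), s0 = integer()))
  for (s in 0:(L - 23L)) {
    if (any(ch[(s + 1L):(s + 23L)] == "N")) next
    cover <- any(derived0 >= s & derived0 <= s + 22L) ||
      any(junc0 > s & junc0 <= s + 22L)
    if (!cover) next
    plus <- ("NGG" %in% pams && ch[s + 22L] == "G" && ch[s + 23L] == "G") ||
      ("NAG" %in% pams && ch[s + 22L] == "A" && ch[s + 23L] == "G")
    minus <- ("NGG" %in% pams && ch[s + 1L] == "C" && ch[s + 2L] == "C") ||
      ("NAG" %in% pams && ch[s + 1L] == "C" && ch[s + 2L] == "T")
    if (plus) out[[length(out) + 1L]] <- data.table(strand = "+", s0 = s)
    if (minus) out[[length(out) + 1L]] <- data.table(strand = "-", s0 = s)
  }
  if (!length(out)) return(data.table(strand = character(), s0 = integer()))
  rbindlist(out)
}

# Apply a single variant to a window string by plain splicing (independent
# of build_template), returning the variant sequence and its derived /
# junction annotation for oracle_enumerate.
oracle_apply <- function(window, wpos, ref, alt) {
  stopifnot(substr(window, wpos, wpos + nchar(ref) - 1L) == ref)
  before <- substr(window, 1L, wpos - 1L)
  after <- substr(window, wpos + nchar(ref), nchar(window))
  var_seq <- paste0(before, alt, after)
  rl <- nchar(ref); al <- nchar(alt)
  keep <- min(rl, al)
  refc <- strsplit(ref, "")[[1]][seq_len(keep)]
  altc <- strsplit(alt, "")[[1]][seq_len(keep)]
  derived0 <- (wpos - 1L) + which(altc != refc) - 1L
  if (al > rl) derived0 <- c(derived0, (wpos - 1L + rl):(wpos - 1L + al - 1L))
  junc0 <- if (rl > al) wpos - 1L + al else integer(0)
  list(var_seq = var_seq, derived0 = derived0, junc0 = junc0)
}

# A deterministic single-variant design scenario on a random genome: store,
# one validated variant group, and its template.
scenario_single_variant <- function(seed, glen = 600L, vclass = "SNP") {
  set.seed(seed)
  g <- rand_dna(glen)
  pos <- sample(100:(glen - 100L), 1L)
  ref1 <- substr(g, pos, pos)
  v <- switch(vclass,
    SNP = data.table(chrom = "chr1", pos = pos, ref = ref1,
                     alt = sample(setdiff(c("A", "C", "G", "T"), ref1), 1L)),
    INS = data.table(chrom = "chr1", pos = pos, ref = ref1,
                     alt = paste0(ref1, rand_dna(sample(1:5, 1L)))),
    DEL = {
      dl <- sample(1:5, 1L)
      data.table(chrom = "chr1", pos = pos,
                 ref = substr(g, pos, pos + dl), alt = ref1)
    })
  store <- make_store(c(chr1 = g))
  vars <- parse_variants(write_variant_csv(v))
  vars <- validate_reference(vars, store)
  grp <- group_variants(vars, "individual")[[1]]
  list(store = store, variant = vars, group = grp,
       template = build_template(grp, store))
}

# In-memory genome store (documented structure of load_genome's return),
# avoiding file round trips in high-iteration property tests.
mem_store <- function(seqs) {
  structure(list(sequences = seqs,
                 lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_store")
}

# Minimal validated variant table, bypassing file parsing.
mem_variants <- function(chrom, pos, ref, alt, id = NULL) {
  n <- length(pos)
  data.table(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = mapply(function(r, a) {
               if (nchar(r) == 1 && nchar(a) == 1) "SNP"
               else if (nchar(a) > nchar(r) && startsWith(a, r)) "INS"
               else if (nchar(r) > nchar(a) && startsWith(r, a)) "DEL"
               else "MNV"
             }, ref, alt, USE.NAMES = FALSE),
             id = id %||% sprintf("v%04d", seq_len(n)),
             ref_valid = TRUE, src_row = seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
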