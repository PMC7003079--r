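# Seeded synthetic genomes and variant sets.
#
# Generation is a pure function of the fixture spec: the same spec always
# produces byte-identical files, and every implanted motif is listed in a
# manifest so tests can check ground truth directly. Fixture genomes emulate
# base composition only (i.i.d. bases at a chosen GC content) — no repeats,
# no chromatin, no realistic mutation spectrum — which is exactly what the
# enumeration/search correctness tests need and nothing more.

#' Describe a synthetic fixture
#'
#' @param seed integer RNG seed; generation is fully determined by the spec.
#' @param chrom_lengths named integer vector of chromosome lengths (>= 100).
#' @param gc GC fraction of the i.i.d. base composition (default 0.5).
#' @param n_snps,n_ins,n_dels variant counts; insertions add 1-5 bp,
#'   deletions remove 1-5 bp.
#' @param decoys optional list of `list(mm =, copies =)` entries: for each,
#'   a source NGG guide site is picked from the generated genome and
#'   `copies` additional sites at Hamming distance `mm` (intact NGG PAM) are
#'   implanted at recorded loci — known ground truth for off-target tests.
#' @param edge_cases character subset of `c("variant_at_start",
#'   "variant_at_end", "adjacent_pair", "polyt_site")`: a SNP at position 1,
#'   a SNP on the last base, two SNPs 8 bp apart, and an implanted guide
#'   site whose protospacer contains TTTT.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, chrom_lengths = c(chr1 = 20000L),
                         gc = 0.5, n_snps = 10L, n_ins = 0L, n_dels = 0L,
                         decoys = NULL, edge_cases = character()) {
  stopifnot(all(chrom_lengths >= 100L), !is.null(names(chrom_lengths)),
            gc > 0, gc < 1)
  stopifnot(all(edge_cases %in% c("variant_at_start", "variant_at_end",
                                  "adjacent_pair", "polyt_site")))
  structure(
    list(seed = as.integer(seed),
         chrom_lengths = setNames(as.integer(chrom_lengths),
                                  names(chrom_lengths)),
         gc = gc, n_snps = as.integer(n_snps), n_ins = as.integer(n_ins),
         n_dels = as.integer(n_dels), decoys = decoys,
         edge_cases = edge_cases),
    class = "fixture_spec"
  )
}

rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome
#'
#' Writes a FASTA file of i.i.d. bases at the spec's composition, implants
#' any requested decoy off-target sites and edge-case motifs at
#' non-overlapping loci, and writes a manifest TSV listing every implant
#' (type, chrom, 1-based start, strand, sequence, detail).
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list: `fasta`, `manifest` (paths), `store`
#'   (the in-memory `genome_store`) and `manifest_dt`.
#' @export
make_genome <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(spec$seed, generate_genome(spec))
  fasta <- file.path(dir, "genome.fa")
  manifest <- file.path(dir, "genome_manifest.tsv")
  writeLines(unlist(lapply(names(res$seqs), function(nm) {
    c(paste0(">", nm), res$seqs[[nm]])
  })), fasta)
  utils::write.table(res$manifest, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  store <- structure(
    list(sequences = res$seqs, lengths = setNames(nchar(res$seqs),
                                                  names(res$seqs))),
    class = "genome_store"
  )
  invisible(list(fasta = fasta, manifest = manifest, store = store,
                 manifest_dt = res$manifest))
}

generate_genome <- function(spec) {
  chars <- lapply(spec$chrom_lengths, function(L) rand_bases(L, spec$gc))
  occupied <- lapply(spec$chrom_lengths, function(L) integer(0))
  manifest <- list()

  place <- function(chrom, motif, type, detail, tries = 200L) {
    L <- spec$chrom_lengths[[chrom]]
    w <- nchar(motif)
    for (t in seq_len(tries)) {
      pos <- sample.int(L - w - 60L, 1L) + 30L     # 1-based, keep margins
      span <- pos:(pos + w - 1L)
      if (!any(span %in% occupied[[chrom]])) {
        chars[[chrom]][span] <<- strsplit(motif, "", fixed = TRUE)[[1]]
        occupied[[chrom]] <<- c(occupied[[chrom]], span)
        manifest[[length(manifest) + 1L]] <<-
          data.table(type = type, chrom = chrom, start = pos,
                     strand = "+", seq = motif, detail = detail)
        return(pos)
      }
    }
    stop("implant collision: cannot place ", type, " motif", call. = FALSE)
  }

  first_chrom <- names(spec$chrom_lengths)[1L]

  if ("polyt_site" %in% spec$edge_cases) {
    proto <- paste(rand_bases(20L, spec$gc), collapse = "")
    substr(proto, 8L, 11L) <- "TTTT"
    place(first_chrom, paste0(proto, "TGG"), "polyt_site", "protospacer has TTTT")
  }

  for (dk in seq_along(spec$decoys %||% list())) {
    d <- spec$decoys[[dk]]
    # pick a source NGG site from the random background
    src <- NULL
    for (t in seq_len(500L)) {
      pos <- sample.int(spec$chrom_lengths[[first_chrom]] - 90L, 1L) + 30L
      span <- pos:(pos + 22L)
      if (any(span %in% occupied[[first_chrom]])) next
      site <- paste(chars[[first_chrom]][span], collapse = "")
      if (substr(site, 22L, 23L) == "GG") { src <- list(pos = pos, site = site); break }
      # force a PAM if background has none here
      chars[[first_chrom]][pos + 21L] <- "G"
      chars[[first_chrom]][pos + 22L] <- "G"
      site <- paste(chars[[first_chrom]][pos:(pos + 22L)], collapse = "")
      src <- list(pos = pos, site = site)
      break
    }
    if (is.null(src)) stop("implant collision: no source site found", call. = FALSE)
    occupied[[first_chrom]] <- c(occupied[[first_chrom]],
                                 src$pos:(src$pos + 22L))
    guide <- substr(src$site, 1L, 20L)
    manifest[[length(manifest) + 1L]] <-
      data.table(type = "decoy_source", chrom = first_chrom, start = src$pos,
                 strand = "+", seq = src$site,
                 detail = sprintf("decoy_set=%d", dk))
    for (cp in seq_len(d$copies)) {
      g <- strsplit(guide, "", fixed = TRUE)[[1]]
      mut_at <- sample.int(20L, d$mm)
      for (p in mut_at) g[p] <- sample(setdiff(c("A", "C", "G", "T"), g[p]), 1L)
      motif <- paste0(paste(g, collapse = ""), "AGG")
      place(first_chrom, motif, "decoy",
            sprintf("decoy_set=%d;mm=%d;source_start=%d", dk, d$mm, src$pos))
    }
  }

  seqs <- vapply(chars, paste, character(1), collapse = "")
  manifest <- if (length(manifest)) rbindlist(manifest) else
    data.table(type = character(), chrom = character(), start = integer(),
               strand = character(), seq = character(), detail = character())
  list(seqs = seqs, manifest = manifest)
}

#' Generate a synthetic variant set matching a genome
#'
#' Samples `n_snps` SNPs (alternate base differs from the reference),
#' `n_ins` insertions (1-5 bp) and `n_dels` deletions (1-5 bp) at
#' non-overlapping, well-separated loci of the fixture genome, so every
#' variant passes reference validation by construction. Identical variant
#' sets are written in both supported formats (VCF v4.2 and the CSV
#' dialect).
#'
#' @param spec the `fixture_spec` used for the genome.
#' @param store the `genome_store` returned by [make_genome()].
#' @param dir output directory.
#' @param spacing minimum distance in bp between sampled variant loci
#'   (default 60, keeping default-window groups singleton).
#' @return invisibly, a list: `vcf`, `csv` (paths) and `variants`
#'   (`data.table`).
#' @export
make_variants <- function(spec, store, dir, spacing = 60L) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(store, "genome_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vars <- with_seed(spec$seed + 1L, generate_variants(spec, store, spacing))
  vcf <- file.path(dir, "variants.vcf")
  csv <- file.path(dir, "variants.csv")
  vlines <- c(
    "##fileformat=VCFv4.2",
    "##source=varguide-fixtures",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            vars$chrom, vars$pos, vars$id, vars$ref, vars$alt)
  )
  writeLines(vlines, vcf)
  write_variants_csv(vars, csv)
  invisible(list(vcf = vcf, csv = csv, variants = vars))
}

generate_variants <- function(spec, store, spacing) {
  bases <- c("A", "C", "G", "T")
  chroms <- names(spec$chrom_lengths)
  taken <- list()  # per chrom: sorted positions already used
  ok_locus <- function(ch, pos, width) {
    prior <- taken[[ch]] %||% integer(0)
    if (any(abs(prior - pos) < spacing + width)) return(FALSE)
    taken[[ch]] <<- c(prior, pos)
    TRUE
  }
  pick_locus <- function(width, margin = 30L) {
    for (t in seq_len(500L)) {
      ch <- sample(chroms, 1L)
      L <- spec$chrom_lengths[[ch]]
      if (L < 2L * margin + width + 2L) next
      pos <- sample.int(L - 2L * margin - width, 1L) + margin
      if (ok_locus(ch, pos, width)) return(list(chrom = ch, pos = pos))
    }
    stop("insufficient space to place non-overlapping variants", call. = FALSE)
  }
  ref_at <- function(ch, pos, n = 1L) {
    substr(store$sequences[[ch]], pos, pos + n - 1L)
  }
  rows <- list()
  add <- function(ch, pos, ref, alt, id) {
    rows[[length(rows) + 1L]] <<-
      data.table(chrom = ch, pos = pos, ref = ref, alt = alt, id = id)
  }

  for (i in seq_len(spec$n_snps)) {
    lo <- pick_locus(1L)
    ref <- ref_at(lo$chrom, lo$pos)
    add(lo$chrom, lo$pos, ref, sample(setdiff(bases, ref), 1L),
        sprintf("snp%03d", i))
  }
  for (i in seq_len(spec$n_ins)) {
    lo <- pick_locus(1L)
    ref <- ref_at(lo$chrom, lo$pos)
    ins <- paste(sample(bases, sample.int(5L, 1L), replace = TRUE),
                 collapse = "")
    add(lo$chrom, lo$pos, ref, paste0(ref, ins), sprintf("ins%03d", i))
  }
  for (i in seq_len(spec$n_dels)) {
    dl <- sample.int(5L, 1L)
    lo <- pick_locus(dl + 1L)
    ref <- ref_at(lo$chrom, lo$pos, dl + 1L)
    add(lo$chrom, lo$pos, ref, substr(ref, 1L, 1L), sprintf("del%03d", i))
  }

  ch1 <- chroms[1L]
  if ("variant_at_start" %in% spec$edge_cases) {
    ref <- ref_at(ch1, 1L)
    add(ch1, 1L, ref, sample(setdiff(bases, ref), 1L), "edge_start")
  }
  if ("variant_at_end" %in% spec$edge_cases) {
    L <- spec$chrom_lengths[[ch1]]
    ref <- ref_at(ch1, L)
    add(ch1, L, ref, sample(setdiff(bases, ref), 1L), "edge_end")
  }
  if ("adjacent_pair" %in% spec$edge_cases) {
    lo <- pick_locus(9L, margin = 40L)
    r1 <- ref_at(lo$chrom, lo$pos)
    r2 <- ref_at(lo$chrom, lo$pos + 8L)
    add(lo$chrom, lo$pos, r1, sample(setdiff(bases, r1), 1L), "edge_pair_a")
    add(lo$chrom, lo$pos + 8L, r2, sample(setdiff(bases, r2), 1L),
        "edge_pair_b")
  }

  vars <- if (length(rows)) rbindlist(rows) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), id = character())
  setorder(vars, chrom, pos)
  vars[]
}
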