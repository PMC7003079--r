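zero_matrix <- function() {
  m <- default_efficiency_matrix()
  m$weights[] <- 0
  m
}

test_that("efficiency score is the position-wise table-lookup sum", {
  expect_equal(efficiency_score(strrep("A", 20), zero_matrix()), 0)
  ind <- zero_matrix()
  ind$weights[, "A"] <- 1
  expect_equal(efficiency_score(strrep("A", 20), ind), 20)
  expect_equal(efficiency_score(paste0(strrep("A", 10), strrep("G", 10)), ind), 10)
  set.seed(11)
  m <- zero_matrix()
  m$weights[] <- round(runif(80, -1, 1), 3)
  set.seed(12)
  for (i in 1:20) {
    p <- rand_dna(20)
    want <- 0
    b <- strsplit(p, "")[[1]]
    for (j in 1:20) want <- want + m$weights[j, b[j]]
    expect_equal(efficiency_score(p, m), want)
  }
  expect_error(efficiency_score("ACGT", zero_matrix()), "20 nt")
  expect_error(efficiency_score(strrep("N", 20), zero_matrix()), "non-ACGT")
})

test_that("matrix config round trip preserves weights and name", {
  m <- default_efficiency_matrix()
  expect_equal(m$name, "efficiency_matrix_synthetic_v1")
  expect_equal(dim(m$weights), c(20L, 4L))
  p <- tempfile(fileext = ".tsv")
  writeLines(c("# name: custom_v9",
               paste(c("position", "A", "C", "G", "T"), collapse = "\t"),
               vapply(1:20, function(i) {
                 paste(c(i, i * 0.1, -i * 0.1, 0.5, -0.5), collapse = "\t")
               }, character(1))), p)
  m2 <- read_efficiency_matrix(p)
  expect_equal(m2$name, "custom_v9")
  expect_equal(unname(m2$weights[7, "A"]), 0.7)
})

test_that("site index equals a brute-force PAM scan", {
  # one engineered plus-strand NGG site in a PAM-poor background
  g <- "TTTTGACTGACTGACTGACTGACTAGGTTTT"
  idx <- build_offtarget_index(make_store(c(chr1 = g)))
  want <- oracle_sites(g, "chr1")
  data.table::setorder(want, chrom, start0, strand)
  expect_equal(idx$sites[, .(chrom, start0, strand, pam_class, protospacer)],
               want)
  # PAM-free genome -> empty index
  idx0 <- build_offtarget_index(make_store(c(chr1 = strrep("A", 100))))
  expect_equal(nrow(idx0$sites), 0L)
  # random fixture genome
  set.seed(3)
  g2 <- rand_dna(5000)
  idx2 <- build_offtarget_index(make_store(c(chr1 = g2)))
  want2 <- oracle_sites(g2, "chr1")
  data.table::setorder(want2, chrom, start0, strand)
  expect_equal(idx2$sites[, .(chrom, start0, strand, pam_class, protospacer)],
               want2)
})

test_that("exact self-match is found and flagged on-target", {
  set.seed(14)
  g <- rand_dna(3000)
  store <- make_store(c(chr1 = g))
  idx <- build_offtarget_index(store)
  site <- idx$sites[strand == "+"][10]
  hits <- find_offtargets(site$protospacer, idx, max_mm = 0,
                          on_target = list(chrom = "chr1",
                                           start0 = site$start0,
                                           end0 = site$start0 + 23L,
                                           strand = "+"))
  self <- hits[is_on_target == TRUE]
  expect_equal(nrow(self), 1L)
  expect_equal(self$mismatches, 0L)
  expect_equal(self$start0, site$start0)
})

test_that("a verbatim duplicate on another chromosome gives two 0-mm hits", {
  set.seed(15)
  g <- rand_dna(2000)
  store1 <- make_store(c(chr1 = g))
  idx1 <- build_offtarget_index(store1)
  site <- idx1$sites[strand == "+" & pam_class == "NGG"][5]
  dup <- paste0(substr(g, site$start0 + 1, site$start0 + 23))
  store2 <- make_store(c(chr1 = g, chr2 = paste0(strrep("A", 50), dup,
                                                 strrep("A", 50))))
  idx2 <- build_offtarget_index(store2)
  hits <- find_offtargets(site$protospacer, idx2, max_mm = 0,
                          on_target = list(chrom = "chr1",
                                           start0 = site$start0,
                                           end0 = site$start0 + 23L,
                                           strand = "+"))
  expect_equal(nrow(hits), 2L)
  expect_equal(sum(hits$is_on_target), 1L)
  expect_equal(hits$mismatches, c(0L, 0L))
})

test_that("indexed search equals the exhaustive Hamming scan", {
  set.seed(16)
  for (rep in 1:4) {
    g <- rand_dna(4000, probs = c(0.3, 0.2, 0.2, 0.3))
    store <- make_store(c(chr1 = g))
    idx <- build_offtarget_index(store)
    sites <- oracle_sites(g, "chr1")
    queries <- c(
      sample(sites$protospacer, 3),
      vapply(1:3, function(i) rand_dna(20), character(1))
    )
    for (q in queries) {
      for (mm in c(0L, 2L, 4L)) {
        got <- find_offtargets(q, idx, mm)[, .(chrom, start0, strand,
                                               pam_class, mismatches)]
        want <- oracle_hits(q, sites, mm)[, .(chrom, start0, strand,
                                              pam_class, mismatches)]
        data.table::setorder(got, chrom, start0, strand, pam_class)
        data.table::setorder(want, chrom, start0, strand, pam_class)
        expect_equal(got, want)
      }
    }
  }
})

test_that("specificity score evaluates the stated aggregation", {
  on <- data.table::data.table(chrom = "chr1", start0 = 0L, strand = "+",
                               mismatches = 0L, pam_class = "NGG",
                               is_on_target = TRUE)
  expect_equal(specificity_score(on), 1)
  h1 <- rbind(on, data.table::data.table(chrom = "chr2", start0 = 5L,
                                         strand = "+", mismatches = 0L,
                                         pam_class = "NGG",
                                         is_on_target = FALSE))
  expect_equal(specificity_score(h1), 0.5)
  h2 <- rbind(on,
              data.table::data.table(chrom = "chr2", start0 = 5L,
                                     strand = "+", mismatches = 2L,
                                     pam_class = "NGG", is_on_target = FALSE),
              data.table::data.table(chrom = "chr3", start0 = 9L,
                                     strand = "-", mismatches = 0L,
                                     pam_class = "NAG", is_on_target = FALSE))
  # hand evaluation: 1 / (1 + 4^-2 * 1 + 4^0 * 0.2) = 1 / 1.2625
  expect_equal(specificity_score(h2), 1 / 1.2625, tolerance = 1e-12)
})

test_that("specificity decreases monotonically as hits accumulate", {
  set.seed(17)
  hits <- data.table::data.table(
    chrom = "chr1", start0 = seq_len(12) * 100L, strand = "+",
    mismatches = sample(0:4, 12, replace = TRUE),
    pam_class = sample(c("NGG", "NAG"), 12, replace = TRUE),
    is_on_target = FALSE)
  scores <- vapply(seq_len(nrow(hits)), function(k) {
    specificity_score(hits[seq_len(k)])
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores > 0 & scores < 1))
  # invariant to hit ordering
  expect_equal(specificity_score(hits), specificity_score(hits[sample(12)]))
})

test_that("variant guides report the wt locus as a near-hit on the reference", {
  sc <- scenario_single_variant(91, vclass = "SNP")
  idx <- build_offtarget_index(sc$store)
  des <- enumerate_guides(sc$template, pams = c("NGG", "NAG"))
  des <- filter_polyt(des)
  expect_gt(nrow(des), 0)
  scored <- score_designs(des, default_efficiency_matrix(), idx,
                          max_mm = 3L)
  for (i in seq_len(nrow(scored))) {
    n_lower_proto <- nchar(gsub("[^acgt]", "", scored$var_protospacer[i]))
    wt_pam_ok <- substr(scored$wt_pam[i], 2, 3) %in% c("GG", "AG")
    if (wt_pam_ok) {
      expect_equal(scored$ontarget_var_mm[i], n_lower_proto)
    }
    expect_equal(scored$ontarget_wt_mm[i],
                 if (wt_pam_ok) 0L else NA_integer_)
  }
})

test_that("an alternate genome gives the variant guide a 0-mm on-target", {
  sc <- scenario_single_variant(92, vclass = "SNP")
  # alternate genome = reference with the variant applied
  g <- sc$store$sequences[["chr1"]]
  v <- sc$variant
  alt_g <- paste0(substr(g, 1, v$pos - 1), v$alt,
                  substr(g, v$pos + nchar(v$ref), nchar(g)))
  alt_store <- make_store(c(chr1 = alt_g))
  ref_idx <- build_offtarget_index(sc$store)
  alt_idx <- build_offtarget_index(alt_store)
  des <- filter_polyt(enumerate_guides(sc$template, pams = c("NGG", "NAG")))
  scored <- score_designs(des, ref_index = ref_idx, alt_index = alt_idx)
  # SNP designs keep their coordinates in the alternate genome, so the
  # variant guide must self-match there with zero mismatches
  expect_true(all(scored$ontarget_var_mm == 0L))
})

test_that("an engineered 2-mismatch decoy is scored via the brute-force hit set", {
  spec <- fixture_spec(seed = 19, chrom_lengths = c(chr1 = 8000),
                       decoys = list(list(mm = 2L, copies = 3L)))
  gg <- make_genome(spec, tempfile())
  man <- gg$manifest_dt
  src <- man[type == "decoy_source"]
  guide <- substr(src$seq, 1, 20)
  idx <- build_offtarget_index(gg$store)
  hits <- find_offtargets(guide, idx, max_mm = 3,
                          on_target = list(chrom = src$chrom,
                                           start0 = src$start - 1L,
                                           end0 = src$start + 22L,
                                           strand = "+"))
  # all three implanted decoys appear at exactly 2 mismatches
  dec <- man[type == "decoy"]
  expect_equal(nrow(dec), 3L)
  for (i in seq_len(nrow(dec))) {
    h <- hits[chrom == dec$chrom[i] & start0 == dec$start[i] - 1L &
                strand == "+"]
    expect_equal(h$mismatches, 2L)
  }
  # scalar equals the independent aggregation of the brute-force hit set
  sites <- oracle_sites(gg$store$sequences[["chr1"]], "chr1")
  bf <- oracle_hits(guide, sites, 3)
  bf_on <- bf$chrom == src$chrom & bf$start0 == src$start - 1L &
    bf$strand == "+"
  w <- 4^(-bf$mismatches[!bf_on]) * ifelse(bf$pam_class[!bf_on] == "NGG", 1, 0.2)
  expect_equal(specificity_score(hits), 1 / (1 + sum(w)))
})
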