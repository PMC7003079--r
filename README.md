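# varguide

Variant-aware CRISPR-Cas9 sgRNA design in R.

Reference-based guide design tools assume the target chromosome matches the
reference genome. A SNP or small indel inside the 20-nt protospacer (or its
PAM) breaks that assumption twice over: it silently degrades
reference-designed guides, and it creates the opportunity to design guides
that cut one allele but not the other — e.g. a dominant disease allele.
varguide takes a reference genome (FASTA) and a variant set (VCF v4.x or a
minimal `chrom,pos,ref,alt[,id]` CSV), rebuilds the variant-applied template
around each variant (or cluster of nearby variants), enumerates every
candidate protospacer+PAM on both strands whose 23-nt footprint covers the
variation, and reports wild-type and variant-allele designs side by side.
Variant-derived bases are lowercased and annotated with their distance to
the PAM (1 = PAM-adjacent, 20 = PAM-distal, 0/−1/−2 = inside the PAM).

Each design is scored on both alleles:

- **Efficiency** — a position-weight-matrix sum over the protospacer,
  `eff = Σᵢ W[i, bᵢ]` (positions 1..20 from the PAM-distal end), with the
  matrix supplied as a versioned TSV config. The bundled default matrix is
  synthetic (see the vignette) — substitute a trained matrix for real work.
- **Specificity** — from an exact, mismatch-tolerant genome-wide search:
  every NGG/NAG-adjacent 23-nt site is indexed by non-overlapping seed
  k-mers so that all sites within `max_mm` Hamming mismatches are retrieved
  (pigeonhole-complete, unlike heuristic alignment), then aggregated as
  `spec = 1 / (1 + Σ 4^(−m) · p)` with `p = 1` for NGG and `0.2` for NAG
  hits, on-target excluded. Per-mismatch hit tallies are always reported
  alongside the scalar.

Guides whose variant protospacer contains `TTTT` (an RNA-polymerase-III
terminator) are filtered out; everything else is reported unfiltered, with
selection left to the user.

## Worked example

```r
library(varguide)

# seeded synthetic fixture: two small chromosomes + 5 SNPs, 2 ins, 2 dels
spec <- fixture_spec(seed = 3, chrom_lengths = c(chr1 = 3000L, chr2 = 2000L),
                     n_snps = 5, n_ins = 2, n_dels = 2)
dir <- tempfile()
g <- make_genome(spec, dir)
v <- make_variants(spec, g$store, dir)

cfg <- run_config(genome = g$fasta, variants = v$vcf, mode = "individual")
res <- run_pipeline(cfg)
res
#> <varguide_result> 14 design(s), 1 warning(s)
#>   stage counts: parsed=9, accepted=9, validated=9, designed_from=9,
#>   groups=9, enumerated=14, polyt_removed=0, scored=14

res$results[1, .(variant_ids, chrom, target_start, strand,
                 var_sequence, variant_dists, eff_var, spec_var,
                 ontarget_var_mm)]
#>    variant_ids chrom target_start strand            var_sequence
#> 1:      snp002  chr1           89      + TACGGAAGGGCTtTCTTGCGCGG
#>    variant_dists eff_var spec_var ontarget_var_mm
#> 1:             8    0.39        1               1
```

Reading the row: a plus-strand design at chr1:89–111 targets `snp002`; the
lowercase `t` is the variant base, 8 positions from the PAM. `eff_var` is
its matrix score, `spec_var = 1` means no off-target site within 3
mismatches anywhere in the genome, and `ontarget_var_mm = 1` says the
variant guide sees the wild-type locus with exactly 1 mismatch — the
allele-discrimination readout (`NA` would mean the variant destroyed the
PAM, the most discriminating case).

`write_results(res, "designs.csv")` writes the full table (scores at two
decimals, matrix version stamped in the header); `write_warnings()` writes
the per-variant warnings report. A thin CLI wraps the same functions:

```sh
exec/varguide design --genome ref.fa --variants in.vcf -o out.csv \
    [--mode combined] [--alt-genome alt.fa] [--pam NGG,NAG] [--max-mm 3] \
    [--threads 4] [--no-strict] [--max-batch 2000]
exec/varguide validate --genome ref.fa --variants in.vcf
exec/varguide fixtures --seed 1 --out fixtures/
```

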