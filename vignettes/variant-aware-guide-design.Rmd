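---
title: "Variant-aware sgRNA design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-aware sgRNA design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

SpCas9 cuts where a single guide RNA (sgRNA) base-pairs with a 20-nt genomic
protospacer lying immediately 5' of a protospacer-adjacent motif (PAM, NGG
canonically, NAG more weakly). Guide-target mismatches reduce binding, so a
SNP or small indel inside the protospacer region changes both the efficiency
and the specificity of a guide designed from the reference sequence. This
cuts two ways: variants silently degrade reference-based designs, and —
turned around — a deliberately variant-matched guide can discriminate
between alleles, for example to disrupt a dominant disease allele while
sparing the wild-type copy.

varguide takes a reference genome (FASTA) and a variant set (VCF or a
minimal CSV), reconstructs the variant-applied template around each variant
or variant cluster, enumerates every candidate protospacer + PAM on both
strands whose footprint covers the variation, and reports wild-type and
variant-allele designs side by side with efficiency and specificity scores
for each. No quality filtering is applied beyond the poly-T rule: all
candidate designs are reported with their scores, and selection is left to
the user.

## Pipeline stages

1. **Genome loading.** Sequences are uppercased; `U` becomes `T`; any other
   IUPAC ambiguity code becomes `N` (with a warning). Internally all
   coordinates are 0-based half-open; everything user-facing (VCF/CSV input,
   the result table) is 1-based inclusive, matching VCF convention. The
   half-open internal arithmetic is what keeps window/PAM index computations
   free of ±1 adjustments.

2. **Variant parsing and validation.** Multi-allelic VCF records are split
   per ALT allele; symbolic alleles and non-ACGT alleles are skipped with a
   logged reason; reference alleles longer than 20 bp are rejected (an indel
   longer than the protospacer cannot sit inside one guide). Each variant's
   stated reference allele is compared with the genome; a mismatch usually
   signals a genome-assembly-version mixup. By default (`strict = TRUE`)
   mismatching variants are excluded and reported; `strict = FALSE` designs
   them anyway using the user-stated allele, for users who trust their
   coordinates more than the supplied FASTA.

3. **Grouping.** In `individual` mode each variant is its own design
   target. In `combined` mode variants whose start positions lie within 22
   bp of their neighbour (single-linkage, window = protospacer + PAM = 23)
   are designed together. Clustering is only a candidate-generation step:
   which variants are actually applied and lowercased in a particular guide
   is decided by that guide's own 23-nt footprint, so a cluster member
   outside a given footprint never contaminates that design.

4. **Template construction.** A window spanning the variant span plus a
   25-bp flank is extracted. 25 was chosen as the smallest flank that
   guarantees every footprint covering the variation — and its wild-type
   counterpart, which for indels can span a few additional reference bases —
   stays inside the window for indels up to 5 bp; it is configurable.
   Variants are applied right-to-left so unapplied coordinates stay valid.
   Every variant-applied base keeps a link to its reference coordinate (or
   "inserted"); deletions leave a junction marker on the first retained base.

5. **Enumeration.** Both strands of the variant template are scanned for
   20-nt + PAM candidates. A design is kept iff a variant-derived base or a
   deletion junction lies inside the 23-nt footprint, *PAM included*: a
   variant that creates or destroys a PAM is the most allele-discriminating
   case of all, and is flagged by a distance-to-PAM of 0/−1/−2. Distances
   count 1 at the protospacer base adjacent to the PAM up to 20 at the
   PAM-distal end. Variant bases are rendered lowercase. Footprints touching
   an `N` are dropped — a design through ambiguous sequence is meaningless.
   For indel groups the wild-type rendering is anchored at the design's
   PAM-proximal reference coordinate and read out to exactly 23 reference
   bases, so the two alleles are comparable at one locus.

6. **Poly-T filter.** Designs whose *variant* protospacer (the sequence
   actually synthesized) contains ≥ 4 consecutive T are removed: such runs
   terminate RNA-polymerase-III transcription of the sgRNA cassette. The
   wild-type counterpart's T-runs do not govern the filter but both runs
   are reported per row.

7. **Scoring.** See below. The default design PAM is NGG (`--pam NGG,NAG`
   opts into NAG designs), but the off-target search always considers both
   NGG and NAG sites, since weak-PAM sites still bind.

## Efficiency score

`efficiency_score()` is a position-weight-matrix sum: for protospacer base
$b_i$ at position $i$ (counted 1..20 from the PAM-distal end),

$$\mathrm{eff} = \sum_{i=1}^{20} W[i, b_i].$$

The matrix ships as an editable TSV (`position`, `A`, `C`, `G`, `T`, plus a
`# name:` version line) and the matrix version is stamped into every result
file, because scores are comparable only within one matrix. The bundled
default (`efficiency_matrix_synthetic_v1`) is a synthetic construction —
it encodes broad tendencies (G favored near the PAM, 3' T disfavored) but
is not fitted to cleavage data, and real campaigns should substitute a
matrix trained for their system. Both alleles' protospacers are scored;
which one matters depends on whether the guide is meant for the variant or
the reference allele, so both are reported.

## Off-target search and specificity score

Heuristic alignment (BLAST-style seeding with gapped extension) is neither
reproducible across parameter choices nor guaranteed complete at fixed
mismatch radii. varguide instead enumerates, once per genome, every 23-nt
site on either strand ending in NGG or NAG, and resolves queries by
seed-and-extend over non-overlapping seeds: with at most $m$ mismatches
allowed, the 20-mer is split into $m + 1$ disjoint seeds of length
$\lfloor 20/(m+1) \rfloor$; a site within $m$ mismatches must match at
least one seed exactly (pigeonhole), so exact seed lookup followed by full
Hamming verification retrieves *every* hit. Matches are mismatch-only — no
bulges or gapped off-targets. The central correctness property, index
search ≡ exhaustive Hamming scan, is asserted in the test suite across
twenty 10–100-kb genomes at all radii 0–5.

The scalar specificity summary is

$$\mathrm{spec} = \frac{1}{1 + \sum_{\text{off-target hits}} 4^{-m} \, p},
\qquad p = \begin{cases} 1 & \text{NGG hit} \\ 0.2 & \text{NAG hit} \end{cases}$$

with $m$ the hit's mismatch count and the on-target site excluded. It is 1
exactly when the guide is unique at the searched radius and decreases
monotonically with every added hit, close hits dominating. The $4^{-m}$
decay and the 0.2 NAG down-weight are this package's own pragmatic
definition, not an empirically fitted model (and deliberately not a CFD/MIT
score); the per-mismatch tallies (`hits_*_by_mm`) are always emitted so any
other aggregation can be recomputed downstream.

The wild-type guide is searched against the reference genome. The variant
guide is searched against the alternate genome when one is supplied, else
also against the reference — in which case its own locus shows up as a
near-hit whose mismatch count equals the number of variant bases in the
protospacer. That number is reported as `ontarget_var_mm` and is the
directly usable allele-discrimination readout: a variant guide with
`ontarget_var_mm = 0` cannot discriminate alleles at all, while larger
values mean more mismatches against the wild-type chromosome. When the
variant destroys the PAM, the wild-type locus is not a site at all
(`ontarget_var_mm = NA`) — maximal discrimination. With an alternate
genome, on-target flagging uses reference coordinates; for genomes with
many upstream indels the coordinates of a locus can shift, a known
limitation.

## Determinism and parallelism

Work is partitioned by chromosome (`threads` workers via fork), then merged
and sorted by (chrom, target_start, strand, variant_ids). Output files are
therefore byte-identical for any thread count, which the suite asserts for
1/2/4 threads. Scores are written with two decimals to keep files stable.

## The fixture generator

`fixture_spec()` / `make_genome()` / `make_variants()` generate i.i.d.
genomes at a chosen GC content with implanted ground-truth motifs (decoy
off-target sites at known Hamming distance, poly-T guide sites, adjacent
SNP pairs, boundary variants) and matched variant sets whose reference
alleles are read from the generated genome, so validation passes by
construction. Generation is a pure function of the spec: one seed, one
byte-identical FASTA/VCF/CSV triple, with a manifest listing every implant.

Fixture genomes emulate base composition and nothing else — no repeat
families, no homopolymer structure beyond chance, no realistic mutation
spectrum or linkage. Tests passing on them establish the *algorithmic*
contracts (complete enumeration, complete off-target retrieval, exact
variant application, filter and determinism behavior); they do not certify
score calibration on real genomes, where repeat content makes off-target
landscapes far denser.

## Problem sizes used in the checks

The test suite exercises: twenty genomes of 10–100 kb × 20 guides × radii
0–5 for search completeness; 100 random templates (SNP/insertion/deletion)
for enumeration equivalence; 1,000 apply/revert round trips; and one
2,000-variant batch over 4 × 80-kb chromosomes run end to end, with every
input variant accounted for in results or warnings. These sizes were chosen
so each brute-force oracle stays exact (no sampling shortcuts) while the
whole suite runs in minutes on a single core.

## Known limitations

- Mismatch-only off-target model; DNA/RNA-bulge off-targets are out of scope.
- The bundled efficiency matrix is synthetic; treat its scores as relative
  orderings under an explicit matrix version, not calibrated activities.
- Indel left-alignment/normalization is not performed; variants are applied
  exactly as stated (after reference validation).
- Whole-genome in-memory storage: appropriate for desk-scale genomes; an
  indexed backend could be substituted behind `genome_store`'s contract.
- No CFD/MIT scores, machine-learned efficiency models, Cas12a PAMs, or
  base-editing window annotation.
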