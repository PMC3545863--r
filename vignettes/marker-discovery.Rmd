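---
title: "In silico SNP and SSR marker discovery from transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico SNP and SSR marker discovery from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(capsimark)
library(dplyr)
```

## The problem

Breeding programs in crops without a reference genome rely on transcript
assemblies as the substrate for marker discovery. `capsimark` implements the
two marker-mining computations used for pepper (*Capsicum annuum*)
transcriptomes, as a tested and reusable pipeline:

* **SNP discovery** from short-read pileups of three near-isogenic,
  homozygous lines mapped against a common transcript assembly, and from
  pileups of Sanger EST members against their contig consensus;
* **SSR discovery** (microsatellites) with MISA-style scanning, compound
  merging and Primer3 assay-task generation;
* **cross-assembly marker comparison** through 101-nt SNP-centred flanking
  windows;
* **assembly summary statistics** (N50, GC content, size bins, marker
  density).

Because the original read sets are hundreds of millions of reads, the
package ships a first-class synthetic-data module that generates transcript
contigs, three genotypes with planted variants and SSRs, exon–exon junction
coordinates and Phred-scored 85-nt reads, so every downstream stage can be
verified against a known truth.

## The three-genotype SNP caller

Reads of each line are mapped separately to the assembly and piled up per
contig position (`build_pileup()`, CIGAR-aware over M/I/D/S). Each line is
then genotyped at each position (`call_lines()`):

* **homozygous** for base $b$ when depth $\ge$ 10 and $b$ carries at least a
  fraction $f$ of the reads (default $f = 0.9$);
* **heterozygous** when depth suffices, no base reaches $f$, and the second
  allele has at least 2 reads;
* **low depth** otherwise.

A position is a **putative SNP** when all three lines are homozygous, two
share an allele and the third differs (the two-out-of-three rule); for
example G/G/C yields a biallelic SNP with reference allele G and alternate
allele C. Positions with any heterozygous call go to a separate track:
residual heterozygosity in inbred lines (or collapsed paralogs) must not be
reported as line-diagnostic SNPs, but must still disqualify neighbouring
candidates.

Candidates are then filtered (`filter_iga_snps()`): a SNP is kept only when
it lies at least 50 bp from every exon–exon junction, every other candidate
SNP and every heterozygote position, and has a summed depth across the
three lines of at least 20 reads. Rejected candidates carry the specific
rule name(s) in a `flags` column, so the manifest can report per-rule
rejection counts and the candidate set partitions exactly into kept plus
rejected.

Parameter notes, all exposed as arguments with these defaults:

* `min_line_depth = 10` reads per line — the published calling depth;
* `total_min_depth = 20` summed reads — reconciles the per-line depth with
  the 20-read filtering criterion quoted for validation; both knobs are
  independent, so a strictly per-line interpretation is reachable by
  setting `total_min_depth = 0`.
* `hom_fraction = 0.9`, `het_min_count = 2` — the source protocol states
  the depth threshold and the heterozygote category but not the fractions;
  these defaults are deliberately conservative and the recovery properties
  hold for any `hom_fraction` in (0.5, 1].
* distances are `|pos_a - pos_b|` in contig bases and "at least 50 bp"
  reads as $\ge 50$ (a 49 bp gap fails, 50 passes).

## The EST consensus caller

EST contigs assembled from at least two member sequences are scanned
column by column (`est_pileup()`, `call_est_snps()`): a position is
polymorphic when two distinct bases each reach depth 2. Alignment gap
characters carry no information (the original pipeline's gap handling is
not documented; treating gaps as missing is the conservative choice).
Tri-allelic columns are emitted with a `tri_allelic` flag rather than
silently dropped — downstream filtering excludes them by default, but the
records remain inspectable. Count ties break alphabetically, which makes
the output deterministic.

`filter_est_snps()` removes SNPs within 50 bp of a contig end (positions
1–50 and the last 50), then makes a greedy left-to-right pass over each
contig: of two candidates closer than 50 bp, the one with higher total
coverage survives (ties keep the leftmost), and subsequent candidates are
re-evaluated against the survivor.

## SSR scanning and compound merging

`find_ssrs()` reports maximal perfect tandem runs of unit size 2–6 at
thresholds (2/6) (3/5) (4/5) (5/5) (6/5) — mononucleotide runs are
excluded because the threshold list starts at dinucleotides. Runs are
detected via a shifted self-comparison of the sequence; each maximal
repeat region is reported once, anchored at its leftmost base and
truncated to complete repeats, so `end - start + 1 = unit_size *
repeat_count` always holds. A motif that is itself a tandem of a smaller
unit (`ATAT`) is reported only at the smaller unit size; overlapping runs
of different irreducible unit sizes are all reported (MISA behaviour).
`N` breaks every run. Note the reported motif is the leftmost frame of
the repeat region — a region `..GGAAGAAGAAG..` is reported with motif
`GAA`, which is the same canonical class as `AAG`.

Motif classes (`canonical_motif()`) collapse rotation and reverse
complement: `CT` belongs to AG/CT, `GTT` to AAC/GTT, and the
self-complementary `TA` to AT/TA. The representative is the
lexicographically smallest member of the combined rotation set.

`merge_compound()` chains consecutive SSRs separated by at most 100
intervening bases into compound records, formatted MISA-style with the
spacer in lower case (`(AC)6tt(AG)7`); overlapping members are joined with
`*`. `make_primer3_input()` emits one Primer3 boulder-IO task per SSR
(amplicon 100–300 bp, optimal Tm 60 °C, optimal primer length 20 nt);
`SEQUENCE_TARGET` uses Primer3's own 0-based convention, the single
exception to the package's 1-based serialized coordinates, because the
format defines it that way. Primer optimisation itself is external;
`parse_primer3_output()` reads the result back into a tidy table.

## Cross-assembly comparison

For every filtered SNP a 101-nt window (50 bases of flank each side,
`extract_snp_windows()`) is aligned against every window of the other
assembly with exact Smith–Waterman local alignment (match +1, mismatch −2,
a gap of length $L$ costs $5 + 2L$), in both orientations. A valid hit has
at least 80 matching bases; a SNP pair is **common** when each member is
the other's best valid hit (reciprocal best hit, ties toward the smaller
index), otherwise the SNP is unique to its assembly, and the partition
`common + unique = total` is exact on each side. Replacing the original
heuristic BLASTN step with exact DP removes E-values (which depend on
database size) and makes the comparison bit-reproducible; at a fixed
window length of 101 the operative published criterion is the 80-base
match rule, which is kept as-is. The same engine drives
`kaspar_window_lookup()`, where a hit requires identity ≥ 0.95 over at
least 80 aligned bases — a deterministic surrogate for the published
"95% similarity at e^-20" rule. SSR cross-matching
(`match_ssrs_across_assemblies()`) requires identical canonical class and
repeat count plus a valid flanking-window alignment, with greedy
best-first one-to-one assignment.

## Summary statistics

`assembly_stats()` computes N50 by the cumulative-length definition (sort
descending, accumulate until half the assembled bases), GC% with `N`
excluded from the denominator, and the conventional size bins (<1 KB
through 10–20 KB, plus an overflow bin so the bins always partition the
contig set). `rate_pct()` and `snp_density()` round half-up at the
reported precision — the convention that reproduces every checkable
published figure (89.7%, 98.6%, 1 SNP per 2,798 bases, 1 per 2,523) — via
one shared helper, `round_half_up()`. "N50" here is the standard
length-weighted median; the plain median is reported separately.

## The synthetic-data generator

`simulate_truth()` builds `n_genes` transcripts (default 200 of ~2 kb,
about 400 kb — large enough for stable statistics, small enough that a
full run takes about a minute on one core). Each gene gets 2–6 exons with
junctions at cumulative exon-length boundaries; SNPs are planted at 0.4/kb
and heterozygous sites at 0.2/kb (matching the observed transcriptome SNP
density of roughly 1 per 2.5 kb); each planted SNP is carried homozygously
by exactly one of the three lines. SSR tracts are planted with
flanking "breaker" bases so their span and repeat count are exactly
recoverable. A configurable share of planted SNPs deliberately violates
each 50-bp rule (near a junction, an adjacent pair, near a het site) so
the tests can assert that every violator is flagged with the right rule
and never kept.

Two deliberate design choices trade a little realism for exactness:

* **Read starts are systematic with random jitter** rather than i.i.d.
  uniform. Marginally the coverage is the same, but realised per-base
  depth is pinned to the target (away from contig ends), which makes
  "recall = 100% at depth 20" a property of the method rather than of
  coverage luck. Compliant SNPs are planted ≥ 100 bp from contig ends,
  inside the fully covered interior.
* **Het sites alternate their two alleles across overlapping reads**
  rather than drawing 50/50 per read, so a het site always presents a
  balanced pileup and is deterministically rejected by the homozygote
  rule. With per-read coin flips a het site can masquerade as homozygous
  with probability ~4·10⁻⁴ per site at depth 20, which would make the
  precision property flaky.

What the generator does *not* emulate: expression-level variation (uniform
coverage per transcript), indels, paired-end geometry, adapter
contamination, position-correlated error profiles, and paralogy beyond
what random sequence provides. Passing the planted-truth suite therefore
demonstrates the correctness of the callers and filters under their stated
assumptions, not robustness to misassembly or alignment artefacts in real
data.

`naive_map()` is a deliberately simple seed-and-extend mapper (exact
21-mer seeds at offsets 0, k, 2k, …; ungapped end-to-end placement;
unique-Hamming-best or discarded): enough to map synthetic reads exactly,
and verified against an exhaustive all-position scan. Real data would go
through a production aligner and enter the pipeline via `read_sam()`.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(n_genes = 50, seed = 7, error_rate = 0))
run <- run_pipeline(cfg)
glance(run)
evaluate_recovery(run$snps, run$truth)
autoplot(run$stats)
```

## Numerical conventions and degenerate inputs

Internally everything is 1-based inclusive, matching the serialized
formats (VCF, TSV, MISA-style tables); only Primer3 targets are 0-based.
Only Phred+33 FASTQ is accepted (never auto-detected). Empty SNP sets
produce header-only VCFs; `snp_density()` with zero markers reports NA;
`assembly_stats()` on an empty assembly is an error. All randomness flows
from a single integer seed through one RNG stream per stage, so identical
configurations give byte-identical manifests.

## Known limitations

* The callers are biallelic and substitution-only by design; indels are
  out of scope.
* The toy mapper discards multi-mapping reads rather than distributing
  them; repeat-rich transcripts lose coverage accordingly.
* The cross-assembly matcher defines its own deterministic criterion
  (reciprocal best hit at ≥ 80 matches); counts from heuristic
  BLASTN-based comparisons are similar in spirit but not numerically
  identical.
* Quality trimming strips single terminal bases while below Q20 (the
  simplest reading of the published rule); running-sum trimmers give
  slightly different retained lengths on noisy tails.
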