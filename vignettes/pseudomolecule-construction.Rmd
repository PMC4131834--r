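---
title: "Reference-guided pseudomolecule construction: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided pseudomolecule construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A draft assembly of a resequenced genome — here modelled on an *aus* rice
cultivar assembled from long and short reads — arrives as tens of thousands
of contigs. A finished reference from a related cultivar (a *japonica*
genome in the motivating case) lets us order and orient those contigs into
chromosome **pseudomolecules**, and the resulting genome pair supports a
catalogue of differences: millions of SNPs, thousands of large
insertions/deletions, and presence/absence variation of genes. This package
implements that workflow end-to-end, together with a synthetic-genome
simulator whose planted truth lets every stage be scored rather than merely
run.

The two genomes being compared are diverged at roughly 1% of aligned
nucleotides, which is the regime all defaults target: dense enough that
exact matches break every ~100 bp, sparse enough that 20-mers are usually
intact.

# Pipeline model and assumptions

The stage order is polish → align → filter → rescue → pseudomolecules →
variants → genes (`run_pipeline()` orchestrates it; the `analysis/` scripts
present it as a narrative). Key modelling choices per stage, with the
rationale where the design was genuinely open:

## Polishing

Reads aligned to the draft contigs are tallied per column; a correction is
applied when the majority non-contig allele has frequency ≥ 0.70 among
quality-filtered reads (MAPQ ≥ 20, base quality ≥ 20), depth ≥ 10, and
consensus quality ≥ Q30; the procedure runs twice, the second round on the
output of the first. "Homozygous" is operationalized as the 70% majority
rule itself — single-sample contig polishing has no genotype model — and an
exact 50/50 tie never calls. The consensus quality is a deliberate
surrogate: `min(999, sum of supporting base qualities − sum of conflicting
base qualities)`. It is monotone in support and exercisable
deterministically (the simulator emits Q35 for correct bases and Q15 for
injected errors), but it is not the full samtools consensus model; the
threshold of 30 therefore acts on a simpler, slightly more permissive
scale. The frequency denominator counts quality-filtered reads only — the
alternative (all covering reads) would make the Q20 base filter partly
self-defeating.

Read-to-contig alignment in self-contained mode uses the package's MEM-vote
mapper (`map_reads()`), which reports gapless alignments with soft clips at
contig edges. Reads that straddle a shear boundary are assigned to the
contig holding the majority of their bases; the minority bases fall outside
the contig and are skipped, so boundary reads cannot inject false evidence.

## Alignment and placement

Anchors are maximal exact matches (MEMs) of ≥ 20 bp, found from a 2-bit
k-mer index. The 20 bp default balances survival at 1% divergence
(a given 20-mer is intact with probability ~0.82) against seed count; it is
configurable (`anchor_min_len`). Chaining maximizes total anchor length
over strictly collinear subsets with no gap penalty — the exhaustive-search
oracle in the tests pins this definition down exactly. Within a chain,
consecutive anchors separated by more than `max_join_gap` (1 kb) on either
axis start a new **block**; blocks of one chain stay grouped as one
placement candidate, which is what lets a split alignment witness a large
indel. Inter-anchor segments up to 5 kb are aligned by banded global
alignment (+1/−1/−2, linear gaps); if the optimal path touches the band it
is retried once at 4× the width, then the block is split rather than
accepting a potentially clipped alignment.

Identity is matches / alignment columns, gap columns included — one fixed
convention, re-derivable from the stored blocks. Coverage is the union of
query-aligned intervals across all blocks of a candidate divided by contig
length, so split contigs keep full coverage credit. Acceptance requires
identity ≥ 0.90 and coverage ≥ 0.80. Contigs whose two best candidates
score within 5% of each other are rejected as non-unique — an explicit
stand-in for the one-to-one filtering role that alignment suites perform,
since no published margin exists. Tiling is greedy by score with no
reference interval claimed twice, up to a 100 bp overlap tolerance:
sheared-contig boundaries drift by small-indel offsets, and rejecting a
whole 20 kb contig over a 3 bp boundary overlap would cost far more signal
than deduplicating the handful of doubly-called SNPs it produces.

## Rescue anchoring and pseudomolecules

BES reads map with the same aligner; contig-side hits need ≥ 90% identity
and ≥ 95% coverage, reference-side hits ≥ 90% / ≥ 90%, only uniquely
aligned BES are used, and reference-side clone pairs must land < 300 kb
apart. Rule (i) places an unplaced contig at a unique BES reference hit in
a region no placed contig claims — implemented strictly as "wholly
unclaimed", not as new slots squeezed between aligned neighbours, which is
the conservative reading. Rule (ii) places it adjacent to the placed contig
carrying the clone mate, offset by the clone insert mean; the coordinate is
documented as an estimate, and "recovered at the correct flanking locus" is
scored as the placement midpoint falling within one insert length of the
true locus. Conflicting rescues resolve to the higher BES support. Paired-
end anchoring needs ≥ 3 links agreeing on chromosome, a 10 kb window, and
orientation; a 50/50 orientation split leaves the contig unplaced rather
than guessed.

Gap sizes between consecutive contigs take the reference-projected distance
with a 100 N floor (N rows with alignment evidence); rescues get fixed
100 N "U" gaps because their spacing is estimated, not measured. The AGP is
the authoritative record: rebuilding the FASTA from AGP plus contigs must
be byte-identical, and both the tests and the drivers assert it.

## Variant calling

SNPs are mismatching M columns of accepted placements; `aligned_bp` counts
columns where both genomes contribute a base, which is the denominator the
1.00% SNP frequency implies (whether the published "alignment length"
included gap columns is not stated; this convention is fixed and
documented). Insertions are query-only gaps ≥ 100 bp with reference-side
gap ≤ 10 bp; deletions are reference-only gaps of 100–50,000 bp with
query-side gap ≤ 10 bp; both require ≥ 200 bp aligned flanks. The 10 bp
other-side tolerance is a choice — the split-alignment diagrams imply
near-zero but print no number. Events gapped ≥ 100 bp on both sides are
classified COMPLEX and excluded from INS/DEL counts so the summary stays
clean; they remain in the output. Both between-block gaps and within-block
I/D runs are scanned: a 400 bp deletion is typically absorbed into one
block as a D run, while a 12 kb deletion splits blocks — the same
biological event class at two alignment scales. Contig-terminal unaligned
tails are never called.

Validation projects each breakpoint through the AGP onto the
pseudomolecule and requires ≥ 5 reads crossing it with ≥ 20 bp on both
sides plus one read pair whose fragment straddles the event; calls in
uncovered regions are flagged NO_DATA rather than failed.

## Genes

Exon coverage intersects collapsed exon intervals (optionally per
transcript, taking the best-covered one — the published reduction across
alternative transcripts is unstated, so both modes exist) with aligned
block intervals; genes below 5% covered fraction are called absent. SNP
effects are classified positionally (intergenic / intron / UTR) and through
the codon table on the coding strand for CDS positions; changes in the
first or last two intron bases are splice-site. Harmful = nonsense or
splice-site, matching the definition used for the published count of
affected genes. The category set here (adding start_loss, stop_loss,
synonymous, missense) is a superset of what the motivating figure shows.
Transcript classification aligns in spliced mode — reference gaps beyond
60 bp start a new block, so introns do not dilute identity — and applies
mapped ≥ 90%/70%, donor-unique < 50% coverage.

# The simulator: what it emulates and what it does not

`random_genome()` embeds tandem-repeat tracts (random 300–500 bp units
repeated) whose sizes are drawn from the large-deletion size mixture;
`mutate_reference()` then deletes whole tracts for the repeat-tagged share
of deletions. This emulates transposon presence/absence polymorphism — the
published deletion-size spectrum has modes at 4 kb and 12–13 kb with 58.5%
repetitive content at the first mode — while keeping breakpoints
unambiguous, because no partial tandem copies remain at the junction. The
deletion-size mixture is 0.55·N(4 kb, 0.5 kb) + 0.30·N(12.5 kb, 1 kb) +
0.15·lognormal tail, truncated to [100, 50,000] bp: the two peaks are the
published structure, the exact weights and the tail are this package's
choice. `repeat_fraction` (default 0.585) is applied per event; since sizes
are drawn iid, the nucleotide fraction converges to the same value.

Event counts for large indels are explicit parameters
(`large_del_count`, `large_ins_count`) because the source workflow reports
size distributions and genome-wide totals, not a per-bp rate; SNPs and
small indels are per-bp rates. All events are planted non-overlapping
(rejection sampling, 100× retry cap, hard failure on exhaustion), and
applying the truth table to the reference reproduces the donor
byte-for-byte — a tested invariant, reconstructed independently in the test
suite.

Features of real data the simulator does **not** model: nested or truncated
transposons and target-site duplications, GC and coverage bias, indel
sequencing errors (read errors are substitutions only), diploid
heterozygosity, and RNA-Seq. Consequently, passing recovery tests show the
pipeline's logic is correct under clean divergence of the stated structure;
they do not certify performance on repeat-nested breakpoints or biased
coverage.

Two targeted experimental designs deserve note. For BES rescue, the planted
insertions use unique (non-repeat) sequence: a BES read inside a tandem
array cannot be uniquely aligned by construction, and the unique-alignment
filter rightly discards it, so a repeat-content rescue experiment would
measure the filter, not the rescue geometry. For the mapping-rate
comparison, the package's MEM-vote mapper is deliberately divergence-
tolerant, so the own-reference advantage is directional but smaller than
what stricter production mappers show on real cultivar panels.

# Numerical choices and problem sizes

Seeds: every simulator operation derives its RNG stream from
`params$seed` plus a fixed per-operation offset, making all outputs
byte-reproducible; the acceptance script derives sub-seeds from `--seed`
the same way. Quality strings are constant Q35/Q15 so the Q30 polish rule
is exercised deterministically. Ties: insertion consensus ties break
lexicographically; chain extraction is greedy best-first; equal-scoring
placement candidates fall under the 5% ambiguity rejection.

The shipped test and driver problem sizes are chosen as the smallest at
which each claim is meaningful: SNP recovery on a 2 Mb pair at 1%
divergence (~20,000 planted SNPs), the indel landscape on 9 Mb with 230
deletions and 60 insertions (enough for a stable bimodal histogram),
polishing on 150 kb at 30× (a few hundred planted errors), BES rescue with
12 insertion-only contigs and 1,500 clones. The published genome-scale
numbers (2.79 M SNPs, 330.55 Mb assembly) are not reproducible at desk
scale; their arithmetic — totals, frequencies, means across the printed
per-chromosome and per-class rows — is verified exactly from the fixture
tables instead (`verify_published_stats()`).

# Known limitations

- The lightweight read mapper reports gapless alignments; reads spanning
  small indels relative to their target are placed but their tail columns
  mismatch. Polishing is therefore most reliable with externally aligned
  SAM when the draft contains many indel errors.
- Rule-(ii) rescue coordinates are insert-length estimates; downstream
  consumers should treat `method = "BES"` placements as ordered and
  oriented but not base-accurate.
- Inversions and translocations are out of scope; a contig whose halves
  align in opposite orientations is rejected by the uniqueness filter
  rather than reported as a rearrangement.
- One printed value in the assembly-statistics fixture does not reproduce
  from its own row: the mapped-contig mean length (total / count gives
  7846, the table prints 7847, presumably a rounding artifact upstream).
  The verification targets use the self-consistent quantities; the
  discrepant mean is shipped in the fixture as printed.
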