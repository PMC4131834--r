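# pseudoref

Reference-guided pseudomolecule construction and comparative genomics for
resequenced genomes, modelled on the workflow that built chromosome-scale
sequences for an *aus* rice cultivar from draft contigs and the *japonica*
reference. The package is aimed at genome-assembly practitioners who have a
draft contig set, short reads, and a related finished reference, and want
chromosome pseudomolecules plus a catalogue of the differences between the
two genomes.

## What it does

Every stage of the comparative pipeline is implemented and testable
end-to-end on simulated data with planted truth:

- **Simulator** (`sim_params()`, `simulate_dataset()`): a reference with
  tandem-repeat tracts and embedded gene models; a donor genome carrying
  SNPs at ~1%, small indels, and large (≥100 bp) indels whose deletion
  sizes follow a bimodal mixture with modes near 4 kb and 12–13 kb; sheared
  contigs, paired-end reads, and BAC-end (BES) clone pairs — all with
  machine-readable truth tables.
- **Polish** (`polish_contigs()`): pileup-based contig error correction.
  A variant is applied when it is effectively homozygous: frequency ≥ 70%
  of quality-filtered reads (`-q 20 -Q 20` equivalents), depth ≥ 10, and
  consensus quality ≥ Q30; the procedure runs twice.
- **Align** (`align_contigs()`): maximal-exact-match seeding, max-weight
  collinear chaining, banded inter-anchor extension (match +1, mismatch −1,
  gap −2), and acceptance at ≥90% nucleotide identity and ≥80% sequence
  coverage with one-to-one tiling; split contigs flag large-indel sites.
- **Scaffold** (`map_bes()`, `rescue_anchor()`, `paired_end_anchor()`,
  `build_pseudomolecules()`): BES hits kept at 90/95 (contig side) and
  90/90 (reference side) with clone mates <300 kb apart; unplaced contigs
  rescued when their BES hits an unclaimed reference region (rule i) or the
  clone mate sits on a placed contig (rule ii), then paired-end links
  (≥3 concordant); FASTA + AGP v2.0 output that reconstructs byte-for-byte.
- **Variants** (`call_snps()`, `classify_insertions()`,
  `classify_deletions()`, `validate_boundaries()`): SNPs from mismatching
  alignment columns; insertions from unaligned contig fragments ≥100 bp
  with ≥200 bp aligned flanks; deletions from gapped alignments of
  100–50,000 bp with ≥200 bp flanks; breakpoints validated by ≥5 spanning
  reads plus a straddling pair. Summaries report per-chromosome counts, the
  SNP frequency (% of aligned bp), and mean indel length.
- **Genes** (`exon_coverage()`, `classify_snp_effects()`,
  `transcript_uniqueness()`): genes called absent below 5% exon coverage;
  SNPs classified through the codon table (premature stops and altered
  GT/AG splice motifs are flagged harmful); transcripts mapped at ≥90%
  identity / ≥70% coverage, donor-unique below 50% coverage.
- **Mapping rates** (`unique_mapping_rate()`): uniquely mapped / total
  reads × 100 per read set and reference.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
1.5 Mb genome pair (1% SNPs, 30 planted large indels, 20× reads, 800 BES
clones) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_polish.R
...
Rscript analysis/08_verify_published_stats.R
```

Output actually printed by a run (seed 20260927):

```
02: planted errors: 659; reverted: 656 (99.5%)
    corrections outside the planted set: 0
03: contigs >= 5 kb placed at their true locus (+-50 bp): 59/59 (100.0%)
04: AGP reconstruction is byte-identical to the emitted FASTA
05: snp_total 12994, snp_frequency_pct 0.98, indel_total 29
    SNP precision 99.98%, recall (all planted) 99.82%
    large-indel recall (+-20 bp): 29/30; validated calls: 28/29
06: harmful SNPs (nonsense or splice-site): 16
07: unique mapping rate: 99.9% on own pseudomolecules vs 99.6% on the
    diverged reference
08: 12/12 recomputed statistics match the printed values
```

Reading the numbers: polishing reverted 99.5% of the planted contig errors
and introduced none; alignment placed every contig ≥5 kb at its true locus;
the SNP frequency recovered on the simulated pair (0.98% of aligned bp) sits
at the planted 1% rate; 29 of 30 planted large indels were recalled with
breakpoints within ±20 bp, 28 of them validated by read support.

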