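---
title: "Characterizing a wild-accession transcriptome against a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a wild-accession transcriptome against a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildtx)
```

## The analysis

`wildtx` post-processes a de novo assembled, strand-specific transcriptome
from a wild accession and characterizes it against an annotated reference
genome of the same species. The pipeline runs six stages in order:

1. **qc** — assembly summary statistics (N50, mean length, GC content),
   polyA-tail trimming, and removal of strand-orientation assembly
   artifacts. In a strand-specific library, incomplete digestion of the
   second strand during library construction produces mirror contigs written
   in the antisense direction; a contig whose sense read count is strictly
   below 1/10 of its antisense read count is discarded.
2. **map** — spliced alignment of each contig to the genome and
   classification into mapping categories: unmapped, multiple loci, or (for
   a unique alignment) intergenic, small gene overlap, sense-of-gene or
   antisense-of-gene, using a 90% gene-overlap fraction and the alignment
   strand relative to the gene strand.
3. **distinct** — redundancy clustering (sequence identity ≥ 97% over
   ≥ 100 bp, single linkage, longest representative kept) followed by
   identification of *distinct* transcripts: cluster representatives with no
   qualifying genome alignment, i.e. sequences absent from or highly
   diverged relative to the reference. These are split into protein-coding
   and non-coding by a coding-potential score.
4. **variants** — homozygous SNP and small-indel calling from read pileups
   (PCR-duplicate removal, ≥ 4 distinct supporting reads, allele frequency
   strictly above 70%), followed by effect annotation against the gene
   models: synonymous/nonsynonymous, start lost, stop lost, stop gained,
   frameshift, in-frame indel, splice-site disruption, or noncoding, plus
   the NS/S count ratio.
5. **cisnat** — discovery of cis-natural antisense transcript (cis-NAT)
   pairs: contig pairs that align to each other in reverse orientation over
   more than 50 bp, are confirmed to co-locate on opposite genomic strands
   with distinct splicing patterns, and are classified by overlap geometry
   (head-to-head, tail-to-tail, contained) and coding pairing.
6. **enrich** — GO-term over-representation of the distinct protein-coding
   set against the transcriptome background by the upper-tail
   hypergeometric test with Bonferroni correction, flagged at corrected
   P ≤ 0.05.

## Thresholds and their defaults

All tunable thresholds live in `pipeline_config()`:

| parameter | default | role |
|---|---|---|
| `min_identity` | 0.97 | alignment and clustering identity floor |
| `overlap_threshold` | 0.90 | gene-overlap fraction for sense/antisense classes |
| `cluster_min_overlap` | 100 bp | minimum aligned columns for a cluster edge |
| `strand_ratio` | 0.1 | sense/antisense artifact boundary (strict `<`) |
| `min_support` | 4 reads | distinct reads carrying the variant allele |
| `min_af` | 0.70 | allele-frequency floor (strict `>`) |
| `cisnat_min_overlap` | 50 bp | reverse-orientation overlap (strict `>`) |
| `orf_ref_len` | 300 nt | reference ORF length of the coding score |
| `alpha` | 0.05 | corrected-P threshold for enrichment calls |

The inequality directions are deliberate and tested at their boundaries: a
contig with sense reads exactly 1/10 of antisense is kept; a variant at
allele frequency exactly 0.70, or with exactly 3 supporting reads, is not
called; a reverse-orientation overlap of exactly 50 bp is not a cis-NAT
candidate; a 100 bp cluster overlap is sufficient.

## Design choices

Several parts of this analysis are under-determined by common practice, and
the package fixes them as follows.

**Coordinates.** All internal coordinates are 0-based half-open; conversion
to the 1-based conventions of GFF3, VCF and the pileup TSV happens only at
file boundaries. A single convention removes an entire class of off-by-one
errors, and the conversions are tested at position 0 and at chromosome ends.

**Gene models.** One transcript per gene is used; when a gene carries
several mRNAs the first in file order is retained with a warning. Gene
regions include introns when computing mapping-category overlap, so a contig
contained in an intron still counts as overlapping the gene.

**Spliced alignment.** A seed–chain–extend aligner is provided at synthetic
scale: exact 31-mer seeds, per-locus chaining of colinear seed runs, genomic
gaps of ≥ 4 bp beyond the contig gap treated as introns, ungapped gap-fill
and end extension with score-based retraction (+1 match / −3 mismatch).
Adjacent seed runs can overhang an exon junction by a few bases when intron
bases coincide with exon bases, so chaining tolerates and trims small block
overlaps. A *qualifying* alignment additionally requires ≥ 90% contig
coverage — identity alone cannot distinguish a unique full-length placement
from a short fragmentary hit, so "unique alignment" is defined over
qualifying alignments only. Externally produced alignments can be imported
through a PSL-inspired TSV and used in place of the built-in aligner.

**Coding potential.** SVM-based coding-potential classifiers are replaced by
a transparent monotone surrogate: `score = longest_orf / 300 − 1`, with the
longest sense-strand ATG-to-stop ORF (an ORF running off the 3' end counts).
The sign convention matches the usual coding/noncoding split: positive means
coding. The 300 nt reference follows the common long-ORF convention.
Downstream logic consumes only the coding/noncoding label, not the score
magnitude.

**Clustering.** The redundancy criterion (identity ≥ 97%, overlap ≥ 100 bp)
is interpreted with single linkage over the pair graph, since transitive
clustering is what "clustered with other transcripts" implies; the
implementation (15-mer seeded candidate pairs, Smith–Waterman identity,
union-find) is tested for equality against a brute-force all-pairs oracle.
The representative is the longest member, ties broken toward the smaller id.

**Variant calling.** "At least four distinct reads" is read as four reads
carrying the *variant allele*, the stricter of the two possible readings.
Homozygosity is enforced solely through the allele-frequency rule; no
genotype likelihoods are computed. Ties between two non-reference alleles
yield no call.

**Effect annotation.** Region precedence is splice (the 2 bp GT/AG intron
ends) > CDS > UTR exon > intron > intergenic across all overlapping genes,
and one effect per variant is retained under the severity order start_lost >
stop_gained > stop_lost > frameshift > splice_disruption > nonsynonymous >
synonymous > noncoding. The standard nuclear codon table is used and
alternative start codons are not honoured. An insertion is assigned to a
feature only when both flanking bases lie inside it. The NS/S statistic is a
ratio of variant counts, not a per-site normalized dN/dS; the normalized
variant is deliberately not implemented.

**cis-NATs.** "Distinct splicing patterns" is operationalized as: the two
members' genomic block sets are not identical. A pair with identical blocks
on opposite strands is one transcript assembled twice (a strand artifact),
not two overlapping transcripts. Geometry is decided by genomic span
arithmetic with strand-aware ends (the 3' end of a minus-strand alignment is
the smaller coordinate); exact-boundary containment counts as contained. The
0.97 identity used in the self-comparison mirrors the genome-mapping
threshold and is exposed as a flag.

**Enrichment.** Bonferroni over the tested terms (those with at least one
study hit) is the default correction; Benjamini–Hochberg is available. GO
DAG propagation is the caller's responsibility, which keeps the module
ontology-agnostic.

## The synthetic-data generator

`synth_config()` + `generate_reference()` + `generate_accession()` emulate
the statistical structure the analysis assumes, with machine-readable truth
tables:

- multi-exon gene models with ATG-initiated, stop-terminated CDS and GT–AG
  introns, on both strands, packed with ≥ 500 bp intergenic spacing;
- accession transcripts carrying planted SNPs (default rate 0.010/bp) and
  1–3 bp indels (0.0015/bp). Planted sites are spaced ≥ 40 bp apart and kept
  ≥ 40 bp from exon junctions and ≥ 35 bp from transcript ends: the spacing
  caps mismatch density at 2.5% (so the ≥ 97% identity contract always
  holds) and guarantees an intact 31-mer seed in every exon segment;
- distinct contigs screened to share no 31-mer with the genome (so
  "unmapped" is deterministic for a seed-based aligner), with a > 300 nt ORF
  (coding) or all ORFs < 150 nt (noncoding);
- genuine cis-NAT loci at intergenic positions cycling through the three
  geometries and three coding pairings, with ORFs planted in the members'
  private regions;
- antisense-to-gene contigs placed inside long introns, so they overlap the
  gene region without sharing spliced sequence with the gene's transcript
  (sharing would create spurious cluster edges or cis-NAT candidates);
- strand-flip artifacts (reverse complements with sense counts below 1/10 of
  antisense), a contig at exactly the 1/10 boundary, truncated redundant
  copies, small-overlap and intergenic contigs, and a duplicated intergenic
  segment yielding multi-locus contigs;
- pileups in which every planted variant has the configured depth (default
  10, support depth−1) and every decoy violates exactly one calling rule —
  allele frequency exactly 0.70 (7/10) or support exactly 3 (3/4) — pinning
  the strict inequalities;
- ground-truth variant effects computed at generation time by an independent
  substitute-translate-diff oracle (`effect_oracle()`), which applies the
  allele to the genome, shifts the annotation, re-extracts and translates
  the whole CDS and diffs the protein. The annotator under test rebuilds
  codons arithmetically and shares no code path with it.

All randomness flows through one RNG stream seeded from `seed`; outputs are
byte-identical across runs of the same seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing errors and base qualities, read-level
coverage variation and misassembly, heterozygosity, alternative splicing
isoforms beyond truncated copies, paralogy beyond a single duplicated
segment, contamination, and expression levels. The planted mutation spacing
also means densely clustered variants and junction-adjacent variants are not
exercised through the alignment path (junction-proximal CDS variants are
exercised directly in the effect-annotation tests).

## Problem sizes

Defaults are sized for a desk-scale run: 2 chromosomes × 150 kb, 60 genes,
~120 contigs, ~470 planted variants plus ~140 decoys, 6 cis-NAT pairs. The
end-to-end synthetic run completes in about a minute on one CPU; the
acceptance checks (oracle equivalence over ≥ 1000 effect annotations,
brute-force clustering of 200 contigs, 1000-multiset N50 oracle, exhaustive
hypergeometric enumeration to N = 60) each run in seconds to a couple of
minutes.

## Known limitations

- The built-in aligner assumes seeds survive between mutations; real
  high-divergence regions (below ~97% identity) are outside its contract,
  matching the analysis' own identity floor.
- Overlapping genes are resolved by effect severity only; compound effects
  of one variant on several transcripts of the same gene are not reported.
- The pileup dialect carries no base qualities; calling is purely
  count-based, as in the thresholds above.
- The NS/S ratio is a count ratio; see the design-choices section. On
  synthetic data it sits near the neutral mutational expectation (~3),
  because planted substitutions are random; in real transcriptomes purifying
  selection pushes it well below 1, a feature the generator makes no attempt
  to model.
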