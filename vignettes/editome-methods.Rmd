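---
title: "Methods: A-to-I editome detection, quantification and differential analysis"
author: "editomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-to-I editome detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomeR)
```

# The model

A-to-I RNA editing is the deamination of adenosine to inosine by ADAR
enzymes; inosine base-pairs like guanosine, so an edited position appears
as an A→G mismatch between RNA reads and the genomic DNA of the same
individual, on the transcribed strand. The package's observation model is
the *site evidence* table: one record per supporting read per genomic
position, carrying the observed base, its phred quality, the distance of
the position from each read end, and the library strand of the read
(dUTP-style strand-specific protocols make the read strand equal the
transcribed strand, so strand assignment never has to be guessed from
annotation alone).

Editing at a site is modelled as a per-site, per-sample binomial: of the
`n` reads covering a site, `Binomial(n, p)` carry G, where `p` is the
editing level. The per-site estimator is `nG / (nA + nG)` over reads with
quality ≥ 25, reported only when `nA + nG ≥ 10` and `nG ≥ 3`; the
per-sample *overall editing rate* pools reads across all A-to-I sites
(`Σ nG / Σ (nA + nG)`) with no per-site coverage requirement, and a
stage's rate is the unweighted mean over its replicates (the read-pooled
stage ratio is also reported, because with uneven depth the two
aggregations differ slightly).

# The filter cascade

Candidate RNA–DNA differences are called from reads pooled across all
samples, then filtered. All filters are pure predicates on the candidate
set — they commute, and the per-filter attrition is logged.

| step | rule | default |
|---|---|---|
| calling | base quality cut | phred ≥ 25 |
| calling | allele types (see below) | ≤ 2 |
| calling | minor-allele support | ≥ 3 reads |
| SNP | WGS genotype het or hom-alt, or known-SNP position | — |
| splice | intronic sites within `spliceWindow` of a junction | 4 bp |
| homopolymer | inside a maximal run ≥ `homopolymerMinRun` | 5 nt |
| read end | alt reads within `readEndMargin` of either end dropped, support recounted | 6 bp |
| multimap | second-best/best local alignment score of the ±`multimapFlank` window | ratio ≥ 0.95, flank 25 bp |

Decisions taken where the procedure was genuinely open:

* **Allele types.** An "allele type" is a base supported by at least
  `minAltReads` quality reads, plus the reference. Counting every stray
  read as an allele would let a single sequencing error (rate ~10⁻³, 450
  pooled reads per site) veto a quarter of all genuine sites, which no
  variant caller does; the threshold-based reading matches GATK-style
  call sets from which such filters historically operate.
* **WGS exclusion covers hom-alt as well as het genotypes**: a
  homozygous-alternative position is a reference error masquerading as
  100% editing. Known-SNP filtering is positional, not allele-matched
  (the stricter reading).
* **Read ends**: "within 6 bp of both ends" is applied as *either* end —
  the artifact being excluded (errors at read extremities) occurs at each
  end independently, and for 150 bp reads the literal conjunction would
  be an empty condition.
* **Multimap filter**: with unit match/mismatch scores and gap penalties
  that make gaps unprofitable, "some other locus aligns the window with
  ≥ 0.95 of the perfect score" is exactly "the window occurs elsewhere
  with ≤ floor(w·0.05/2) mismatches". The default method searches for
  such near-exact occurrences (with a pigeonhole k-mer prescreen: any
  ≤ k-mismatch copy must share one of k+1 disjoint exact chunks), and an
  explicit local-alignment route (`method = "alignment"`, self-masked
  genome, both strands) is kept as the cross-check; tests assert the two
  agree. BLAT itself is replaced by this exhaustive search, which is
  exact at the genome sizes the package targets; an external aligner can
  be substituted upstream by supplying pre-flagged calls.
* **Strand resolution**: gene strand when the site lies within genes of a
  single strand; otherwise the majority library strand of the covering
  reads; ties and opposite-strand gene overlaps stay unresolved and are
  excluded from the mismatch-type tally.
* **Candidate calling pools reads across samples** (maximizing detection
  power); quantification is per sample downstream, and per-sample counts
  are retained in the call set so either convention can be audited.

# Differential editing

Between two stages the package runs an equal-variance two-sample
Student's t-test per site on the replicate editing levels (Welch is
available behind `varEqual = FALSE`). Only sites with at least two
defined levels per group are tested, and excluded sites do not enter the
Benjamini–Hochberg denominator. A site is differentially edited when
q ≤ 0.05 **and** |Δ| ≥ 0.1, with Δ = mean(later) − mean(earlier), "up"
meaning higher in the later stage. The FDR procedure is the textbook BH
step-up ladder (the package's own implementation, cross-checked against
`p.adjust` to 10⁻¹²; the t statistics are vectorized and cross-checked
against `t.test` to 10⁻⁹). Degenerate sites with zero variance in both
groups and equal means get p = 1, never NaN. Sample clustering uses
1 − Pearson correlation over sites defined in all samples with average
linkage, columns pre-sorted by name so the result is invariant to input
order. Enrichment of differentially edited genes is a one-sided
hypergeometric tail via `phyper`, BH-corrected across terms — a generic
over-representation test standing in for web-service annotation tools.

# miRNA binding

For each 3′-UTR editing site the package extracts 50 bp of context on
each side on the transcribed strand (truncated at transcript/contig
boundaries, truncation lengths recorded) and builds the reference and
edited sequence differing only at the central A/G. Each mature miRNA is
aligned 3′→5′ against both flanks with a Smith–Waterman scanner using
classic miRNA-target complementarity scores — match +5, G:U wobble +1,
mismatch −3, gap open −9, gap extend −4, pair scores doubled at miRNA
positions 2–8 (the seed) — reporting hits with score ≥ 140 and duplex
energy ≤ −7 kcal/mol. Up to four non-overlapping hits per miRNA are
recovered by masking and rescanning; overlapping candidates resolve to
the best score with deterministic tie-breaks. These thresholds are
documented approximations of the defaults of the classic Miranda
scanner; exact numeric parity with any particular binary is not a goal.

The duplex energy is a simplified RNA/RNA nearest-neighbor sum over
consecutive paired positions — G:C-on-G:C stacks −3.3, A:U-on-A:U −1.1,
mixed Watson–Crick −2.1, any stack containing a G:U wobble −0.5 kcal/mol,
+4.1 per interior unpaired stretch — deterministic, monotone in pairing
strength, and adequate for classifying the *sign* of an editing-induced
energy change; it is not an ensemble folding model. Each (site, miRNA)
pair is classified gained / lost / energy-changed / unchanged from the
best hits of the two scans, and energy distributions are compared with a
two-sided Wilcoxon rank-sum test (both all-pairs and per-site-best modes
are possible by feeding the corresponding energy vectors).

# The synthetic-data generator

`simulateStudy()` builds, deterministically from one seed: a single
contig with `nGenes` gene cassettes on alternating strands (5′-UTR /
split CDS / introns / long 3′-UTR; the last two genes are annotated as
known and novel lncRNAs), an A-rich ~250 nt SINE family
("SINE/tRNA:Pre0_SS") planted in introns and 3′-UTRs with 12% per-copy
divergence (so copies are detectably repeats yet pass the uniqueness
filter, as diverged SINEs do in real genomes), homopolymer runs inside
transcribed regions, and one 400 bp intronic segment duplicated exactly
into intergenic space as the multi-mapping trap.

True sites are placed only on transcribed-strand adenosines, 80% inside
repeats (emulating the strong repeat enrichment of mammalian editomes),
away from splice-window margins, homopolymers and the duplication. Site
levels are `stage mean + N(0, siteLevelSd)` shared across stages, with
`nDiffSites` sites additionally shifted by `diffDelta` in one stage;
per-replicate levels add `N(0, replicateSd)` noise (the within-stage
replicate variance of editing levels is not something desk data pins
down; 0.02 is a stand-in exposed in `SimConfig`). Default stage means
0.1663 / 0.2087 / 0.1886 for Y30 / Y180 / Y300 mirror the
infancy–puberty–adulthood profile of the motivating design; coverage is
Poisson(50) with floor 1 per site and sample; base-call errors hit at
10⁻³ per read with a random wrong base; qualities are N(36, 4) clipped to
[2, 41]. Heterozygous SNPs appear at ~50% alternative allele in RNA;
artifact sites carry a 0.3 alternative fraction and are constructed to
violate exactly one filter each (all alternative reads within 6 bp of a
read end; inside a planted homopolymer run; inside the duplicated
segment). Synthetic miRNAs are reverse complements of edited or unedited
3′-UTR flank windows with the edited base at seed position 4, plus
random 22-mers.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: alignment and mapping errors beyond the
single duplicated-segment class, PCR duplicates, coverage correlation
along transcripts, hyper-edited read clusters, allele-specific
expression, and genuine dbSNP allele frequencies. Passing the planted
-truth checks shows the cascade implements its stated rules exactly, not
that those rules are sufficient for any particular real library.

# Numerical choices and check sizes

* Internal coordinates are 1-based closed (`GenomicRanges` convention);
  on-disk formats keep their native dialects (GTF/VCF 1-based, BED
  0-based half-open).
* Feature annotation precedence CDS > 3′-UTR > 5′-UTR > ncRNA exon >
  intron > intergenic, so every site gets exactly one label.
* The per-stage overall rate defaults to the replicate mean; the pooled
  ratio is emitted alongside.
* Estimator accuracy is assessed on the site-level estimate pooled
  across the nine samples (a per-sample estimate at coverage 100 has
  binomial MAE ≈ 0.8·√(p(1−p)/100) ≈ 0.03 at p ≈ 0.2 — no implementation
  could beat that floor; the pooled estimate is the quantity with the
  precision the checks demand). Bias is checked at coverage 1000 over
  200 sites; accuracy at coverage 100 over 500 sites.
* DES power is defined per planted site: a Δ = 0.4 site counts as
  recovered when any of its two affected stage comparisons calls it.
  Type-I control is measured over 20 seeds of a null design (equal stage
  means, 200 sites); the t/BH implementations are compared to
  `t.test`/`p.adjust` at 10⁻⁹.
* The deterministic end-to-end checks use the default study size (500
  sites, 150 artifacts, 9 samples, ~60 kb genome, ~400k evidence
  records), which keeps a full simulate–detect cycle under a few seconds
  and the whole verification sweep within minutes on one CPU.
* Strand symmetry is asserted exactly: reverse-complementing the genome,
  annotations and evidence and rerunning detection yields the identical
  mapped A-to-I site set.

# Limitations

The package consumes site evidence, not BAM files: producing evidence
tables from alignments (computing read-end offsets from CIGAR strings)
is upstream of its scope, as are alignment, duplicate marking and
variant calling from raw reads. The hypergeometric enrichment needs a
user-supplied term-to-gene mapping; no annotation database is bundled.
The duplex-energy model is a constant-per-stack simplification, suitable
for sign and ranking questions, not for absolute free energies. Printed
headline counts of the motivating study (tens of thousands of sites)
require its raw sequencing data and are outside desk-scale reproduction;
the package's checks are property-based on synthetic truth plus
arithmetic self-consistency of the published tallies.
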