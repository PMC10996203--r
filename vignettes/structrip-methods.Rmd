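---
title: "Methods: structured-RNA RIP-seq analysis with planted-truth simulation"
author: "structrip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured-RNA RIP-seq analysis with planted-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structrip)
```

## Scope and model of the data

`structrip` analyzes RNA immunoprecipitation sequencing (RIP-seq) experiments
in which an RNA-binding protein is pulled down together with its bound RNAs
(the IP library) and compared against total lysate RNA (the Input library).
The package is aimed at experiments where the interesting targets are
*abundant structured RNAs* — ribosomal RNA, snoRNAs, scaRNAs — whose multicopy
or highly expressed nature breaks the assumptions of ordinary gene-level
RNA-seq tooling in two ways:

1. Reads from the multicopy 45S rDNA unit (5′ETS–18S–ITS1–5.8S–ITS2–28S–3′ETS)
   are multi-mapped and are usually discarded. Here they are first-class: they
   are partitioned out, assigned to ncRNA classes and rDNA subregions, and
   profiled at base resolution on the rRNA unit.
2. Enrichment of an abundant transcript cannot be judged from IP read counts
   alone; every comparison is IP versus Input, normalized for library size.

Every stage is testable without any external data because the package ships a
synthetic-data generator that plants known binding structure and emits gold
alignments.

## The synthetic-data generator

`build_reference()` lays out a single-chromosome toy genome: protein-coding
genes with exon/intron/UTR structure, `n_rdna_copies` sequence-identical 45S
units (sequence identity is what produces multi-mapped reads), identical 5S
copies, and single-copy snoRNA (H/ACA and C/D box), scaRNA and miRNA genes.
The default 45S subregion lengths approximate the human unit (13,358 nt with
a 5,070-nt 28S), and the 28S carries a six-domain interval table whose domain
II contains residues 1776–2242 and the 2′-O-methylation sites Am2388, Cm2409
and Gm2411. Domain boundaries are data (an input table), not something the
package computes.

`simulate_libraries()` draws per-source fragment counts from a negative
binomial with mean `baseline × enrichment` (enrichment applies to IP
libraries only) and shared dispersion, then places fragment start positions
uniformly within each source — except inside enrichment windows, where the
placement probability is multiplied by the window factor and renormalized.
Reads from the multicopy rDNA are recorded once per copy with the copy count
as an NH-style multiplicity. Reads are single-end with a fixed length and
unstranded counting downstream; neither convention is critical to any
statistic the package computes, and both are exposed as configuration.

The default truth (`default_binding_truth()`) encodes the study conditions
the package is designed around:

* two IP and two Input replicate libraries;
* the 45S unit at an 8× IP count enrichment over a baseline that puts roughly
  9–10% of Input fragments on rDNA — yielding ~35–40% multi-mapped reads in
  IP libraries and an IP:Input 45S fraction ratio of about 4;
* an 8× placement window on 28S residues 1776–2242 (domain II);
* 30 planted IP-enriched snoRNAs (factor 6, baseline ≥ 50 fragments), all
  H/ACA box by default, among 174 expressed snoRNAs;
* planted genomic peak sites (60 nt, placement factor 50) in a mix of CDS,
  intron, intergenic and antisense contexts, half of them carrying an
  embedded (CA)₁₀ repeat;
* negative-binomial dispersion 0.01, the technical-replicate regime typical
  of deeply sequenced abundant transcripts.

What the generator deliberately does **not** emulate: sequencing errors
beyond N-contamination, adapter read-through, crosslink-induced truncations
or mutations, mappability structure of a real genome, and biological
replicate variability of the count noise. Tests that pass on this generator
therefore demonstrate the *algorithmic* correctness and calibration of the
pipeline, not robustness to every artifact of real libraries.

## Read-level processing

QC applies two rules in fixed order, matching the usual preprocessing
convention for these libraries: reads with more than 2 `N` bases are
discarded first, then reads shorter than 16 nt (a 16-nt read is kept; the
rule is strict "shorter than").

A read is *uniquely mapped* when its multiplicity is 1, *multi-mapped*
otherwise, counted once per read rather than once per placement. Multi-mapped
reads are assigned to exactly one ncRNA class by best placement; ties across
classes are broken by the fixed priority
rRNA > snoRNA > scaRNA > snRNA > tRNA > miRNA > lincRNA > other, then by the
lexicographically smallest reference id. This deterministic rule replaces
whatever unstated tie policy the original aligner-based workflows use, and is
recorded here so the per-class fraction tables are reproducible. Subregion
assignment on the 45S unit uses the read midpoint, which avoids
double-counting junction-spanning reads.

## Peak calling

The caller is a single, fully specified algorithm (rather than a wrapper
around external CLIP-seq tools, whose internals differ and are not
re-implemented here):

1. candidate peaks are maximal runs of positions with IP depth ≥ `min_depth`,
   merged across gaps ≤ `merge_gap` (default 20 nt);
2. the empirical p-value of a candidate is the fraction of permutations — the
   same number of IP reads placed uniformly on the same reference — whose
   maximum coverage depth reaches the candidate's maximum depth. The add-one
   convention `p = (1 + k)/(1 + B)` makes null p-values super-uniform.
   Permuting within the same reference, rather than genome-wide, preserves
   per-reference read budgets;
3. enrichment is the library-size-normalized IP/Input density ratio with a
   one-read pseudocount on the Input window (so Input-empty windows are
   finite, not errors); peaks require `p < alpha` and enrichment ≥
   `min_enrichment`;
4. the summit is the leftmost position of maximum IP depth.

Because the permutation statistic is a maximum over the reference, a null
run produces a "significant" candidate only when its own maximum is in the
upper tail of the re-placement distribution — this is what makes the
fraction of null runs with any peak track `alpha`. In practice the
enrichment filter removes even those, since IP ≈ Input under the null.

Annotation assigns exactly one category per peak at its summit, by the fixed
priority CDS > 5′UTR > 3′UTR > ncRNA-exon > intron > antisense > intergenic.
"Antisense" requires a stranded peak inside a gene on the opposite strand
only; unstranded peaks match features on either strand. Confident bound
genes are those with at least one non-intergenic peak in each of two IP
replicates.

The (CA)-repeat scan reports, per peak sequence, the maximal (CA)ₙ run
length (n ≥ 3, both strands, AC phase included), and compares the fraction
of peaks with a run ≥ `min_units` against the same statistic on
dinucleotide-shuffled sequences. The shuffle permutes the sequence's
non-overlapping 2-mers — it preserves the tiled dinucleotide composition and
destroys long runs, which is the property the statistic needs; an exact
Eulerian (Altschul–Erickson) shuffle was not necessary for this purpose.

## Enrichment statistics

Abundance is FPKM — `count / (length/1000) / (library_total/1e6)` — computed
from uniquely mapped reads only, since multi-mapped rDNA reads would swamp
the per-transcript table and are analyzed separately. The top-abundant list
ranks by IP FPKM (configurable to Input or the mean; the choice is recorded
in the output), with ties broken by transcript id.

Per-transcript IP enrichment uses a two-sided Fisher's exact test on the
2×2 table `[[ip, ip_total − ip], [input, input_total − input]]` of pooled
replicate counts, a pseudocounted FPKM ratio
`(FPKM_IP + ε)/(FPKM_Input + ε)` with ε = 0.01, and the flag rule
`fold change ≥ 2 and p < 0.05` (raw p; BH-adjusted q is reported alongside).
Fisher is exact at toy depths and has a brute-force enumeration oracle,
which is why it was chosen over asymptotic count tests. "Expressed" means
Input FPKM ≥ 1 by default.

Gene-set overlap uses the upper-tail hypergeometric probability
`P[X ≥ |A∩B|]`, `X ~ Hypergeom(N, |A|, |B|)`, computed by exact summation,
with Benjamini–Hochberg adjustment available for families of tests.

## 28S domain profiling

Per-base depth on the 28S (multi-copy placements collapsed to one count per
read on the unit consensus, since the copies are identical by construction)
is summarized per domain as reads-per-base per million mapped fragments;
the per-million scaling is this package's choice and is recorded in the
output. Binding regions are maximal runs of depth ≥ `threshold × max depth`
(default 0.5) merged across ≤ 20-nt gaps; regions shrink setwise as the
threshold rises, and at threshold 1 only argmax positions remain.
Modification-site containment is plain interval membership in the called
regions.

## Differential expression

The DEG stage implements the threshold rule — up if fold change ≥ 2 and
FDR < 0.05, down if fold change ≤ 0.5 and FDR < 0.05 — on top of
median-of-ratios size factors and a deliberately simple per-gene test:
two-sided Fisher's exact on condition-pooled counts versus pooled totals.
This is a labeled stand-in, not a reimplementation of a negative-binomial
GLM. Its null sampling model is counting noise, so the count simulator's
default dispersion (0.002) sits in the near-technical regime where the test
is calibrated; with biologically sized dispersion the Fisher stand-in is
anticonservative, which is exactly why real studies use an NB GLM. That
limitation is intentional and documented: the reproducible content here is
the threshold rule, the normalization, and the overlap logic. The fold
change is the raw pseudocounted ratio of normalized condition means
(ε = 0.5), not a shrunken estimate.

## RTL-P quantification

RTL-P (reverse transcription at low dNTP followed by PCR) infers ribose
2′-O-methylation from the fact that reverse transcriptase stalls at
methylated residues when dNTPs are scarce. Amplicon signals are modeled as
`efficiency^−Ct` (100% efficiency by default; a config parameter for
sensitivity analysis). The per-level signal ratio is FU/FD (read-through
over read-through-independent amplicon); the scalar methylation index is

\[ \text{index} = \frac{\text{ratio(LD)}}{\text{ratio(HD)}} , \]

anchoring at the high-dNTP level as the full-read-through reference makes
the index unit-free; the middle level is reported descriptively. A lower
index means more stalling, i.e. higher inferred methylation. Condition
contrasts are ratios of indices with a paired Student's t-test on
replicate-level log₂ indices (ratios are log-normal under Gaussian Ct
noise, so the test is taken on the log scale).

The simulator's closed form plants `index = 1 − m·s` for methylated fraction
`m` and stall efficiency `s` (default 0.9), with Gaussian Ct noise (default
sd 0.1 cycles, typical RT-qPCR technical precision). Default conditions are
Ctrl `m = 0.5`, overexpression `m = 0.9` (contrast < 1) and knockdown
`m = 0.1` (contrast > 1).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (alignment convention) and
  1-based closed in all reports (rRNA residue numbering).
* Empty inputs are answers, not errors: QC of an empty read set returns a
  zeroed report; zero coverage gives an `NA` max domain; a transcript with
  no reads in either library has fold change 1 and p 1.
* Ties are deterministic everywhere: class priority then lexicographic id;
  first domain on density ties; leftmost summit; id-ordered abundance ranks.
* All randomness flows from per-stage seeds derived from one global seed;
  identical configuration reproduces every output file byte-identically.
* Validation errors name the offending object (read id with inconsistent
  multiplicity, unclassified structured reference, missing qPCR level).

## Problem sizes

The bundled demo (the default `pipeline_config()`) uses an ~280-kb genome,
80 coding genes, 174 snoRNAs, 3 rDNA copies and roughly 35,000–70,000
fragments per library; it completes in well under a minute on one CPU. The
package's Monte-Carlo validation loops use 50–100 seeded replicates of this
scale (or of smaller targeted simulations, e.g. a 2-kb reference at 50×
depth for peak-caller calibration), which keeps the whole validation suite
in the minutes range while leaving the per-run statistics comfortably away
from their decision thresholds.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(out_dir = "demo_run", seed = 1)
report <- run_pipeline(cfg)
print(report)
report$profile$domains        # per-domain density table
report$class_summary          # per-class enrichment fractions
report$rtlp$contrasts         # RTL-P condition contrasts
```

## Known limitations

* The peak caller is a defined reference algorithm, not a re-implementation
  of any published CLIP/RIP caller; absolute peak counts are not comparable
  across tools, only the planted-truth recovery behavior is.
* The Fisher stand-ins (enrichment and DEG) assume counting noise; they are
  anticonservative under biological overdispersion.
* The dinucleotide shuffle is tile-based, slightly coarser than an Eulerian
  shuffle.
* The generator's genome has uniform base composition and no repeat families
  beyond rDNA, so mappability artifacts of real genomes are out of reach of
  these tests.
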