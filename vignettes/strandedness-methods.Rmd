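---
title: "How strandcheck decides whether a library is stranded"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How strandcheck decides whether a library is stranded}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandcheck)
```

## The model

A paired-end RNA-seq fragment is sequenced from both ends, giving one read
in file 1 and one in file 2. If the library preparation preserved strand
information, one file consistently carries the sense strand of the original
RNA: file 1 in an **FR** library, file 2 in an **RF** library. If it did
not, each pair is an independent fair coin between the two layouts.

Write $n_{FR}$ and $n_{RF}$ for the numbers of sampled pairs classified
into each layout. The statistic of interest is the **stranded proportion**

$$ sp = \frac{\max(n_{FR}, n_{RF})}{n_{FR} + n_{RF}} \in [0.5, 1], $$

the fraction of determinable pairs explained by the dominant layout. Under
a stranded protocol $sp \approx 1$; under an unstranded one $n_{FR}$ is
Binomial$(n, 1/2)$ and $sp \approx 0.5$. The verdict applies two strict
thresholds: $sp > 0.9$ calls the dominant layout, $sp < 0.6$ calls the
library unstranded, and the band between — thresholds included — is
INCONCLUSIVE. Intermediate values are flagged as possible contamination:
genomic DNA and residual small RNAs both dilute a stranded library towards
0.5, which is why an INCONCLUSIVE verdict is worth a contamination check
rather than a shrug.

## Orientation classification

Each mate is assigned to the transcriptome independently with an exact
k-mer voting index. The index stores every sense-strand k-mer of the
transcripts (k odd, 11–31; default 31 — k-mers are packed two bits per base
into a 64-bit word, which imposes the 31 cap shared with the common
pseudoalignment tools). A query counts how many of the read's $m = L-k+1$
k-mers are present (sense votes $v_s$) and how many of its
reverse-complement k-mers are present (antisense votes $v_a$):

* **ASSIGNED** if $\max(v_s, v_a) \ge f \cdot m$ and the winner strictly
  beats the loser, with orientation given by the winner;
* **AMBIGUOUS_STRAND** if both orientations reach the threshold and are
  within one vote of each other (palindromic or low-complexity sequence
  must not vote a strand);
* **UNMAPPED** otherwise (including reads shorter than k; such reads are
  never an error).

The vote threshold $f$ (`min_vote_frac`, default 0.25) is an engineering
choice: at read length 100 and k = 31 a single substitution error destroys
at most 31 of 70 k-mers, so 0.25 tolerates roughly one error per 100 bases
while random sequence virtually never reaches 17 of 70 matching 31-mers.
The assigned transcript set is the intersection of the id-sets of the
matching k-mers, falling back to their union when the intersection is
empty (a read spanning an exon junction absent from one isoform); the
orientation is still trusted in that case because it comes from the vote
counts, not the id-sets.

The pair decision table: mate 1 sense + mate 2 antisense is FR, the
converse RF. A pair with exactly one assigned mate is classified by that
mate alone (mate 1 sense → FR, mate 1 antisense → RF, mate 2 sense → RF,
mate 2 antisense → FR) rather than discarded — per-read classifiers in the
RSeQC tradition do the same, and discarding them would bias libraries with
one weak mate. Both mates mapping with the same orientation (discordant),
either mate strand-ambiguous, or mates assigned to disjoint transcript
sets (likely chimeric) give FAILED; neither mate assigned gives UNMAPPED.

Two denominator conventions exist for $sp$. The default excludes FAILED
pairs (`denominator = "determined"`): FAILED reflects mapping quality, and
counting it would let poor mapping masquerade as unstrandedness. The
failed fraction is reported separately and warned about above 20%;
`denominator = "total"` is available for comparison with tools that divide
by all sampled pairs.

All decisions are made in transcript (sense/antisense) space, so a GTF is
optional; when provided it only enables the genome-space RSeQC code
strings (`1++,1--,2+-,2-+` for FR, `1+-,1-+,2++,2--` for RF) in reports.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_pairs` | 200,000 | read pairs sampled; at this size the binomial standard error of percent stranded is ≈ 0.11 points, so replicate scatter is well under half a point |
| `k` | 31 | k-mer size (odd, 11–31) |
| `min_vote_frac` | 0.25 | fraction of a read's k-mers that must match for assignment |
| `stranded_min` | 0.9 | strict lower threshold for a stranded verdict |
| `unstranded_max` | 0.6 | strict upper threshold for an unstranded verdict |
| `low_align_warn` | 0.1 | aligned fraction below which the verdict is flagged unreliable |
| `min_determined_pairs` | 1000 | low-evidence warning floor (warning only) |
| `ci_level` | 0.99 | level of the reported Clopper–Pearson interval |

Sampling is the head of the file by default — deterministic, and adequate
because strandedness is a global library property; a `reservoir` strategy
(a seeded uniform random subset, drawn after a full pass over both files)
is available for files with positional composition bias. The interval is
Clopper–Pearson (exact); it is reporting only and never enters the
verdict.

## The simulator

The simulator exists so that every claim the package makes about itself is
checkable without downloads. It emulates the validation design of
strandedness checkers: a synthetic transcriptome of i.i.d. uniform-base
sequences (1000 transcripts of 500–3000 bases in the shipped validation
runs), fragments drawn per pair from a transcript chosen by a
lognormal(0, 1) abundance model (uniform available for analytic checks),
fragment length Normal(250, 25) truncated to `[read_len, transcript
length]` — typical Illumina values, chosen once and configurable — start
positions uniform, and pair orientation following the stranded layout with
probability `p` (so `p = 1` is fully stranded FR, `p = 0.5` unstranded).
Errors are i.i.d. substitutions (no indels; the voting assigner tolerates
substitutions and nothing downstream depends on indel realism). Ground
truth is encoded in read names and a sidecar table. Mixtures of a stranded
and an unstranded pool at ratio $r$ have expected percent stranded
$100\,(r + (1-r)/2)$ by the law of total probability, giving a linear
calibration check.

The genomic-DNA control mode mirrors the intergenic-region diagnostic for
gDNA contamination: a random reference partitioned into 1-kb features all
labelled `+`, with each fragment's source strand a fair coin. Genomic DNA
carries no strand bias, so the pipeline must report $sp \approx 50\%$ on
this input; a stranded library progressively contaminated with gDNA slides
from 1 towards 0.5, which is exactly the INCONCLUSIVE band.

What the simulator does **not** emulate: real transcript sequence
(repeats, paralogy, low-complexity regions — random sequence understates
multi-mapping and strand ambiguity), quality-score structure (qualities
are never used), adapter read-through, splice isoform sharing beyond what
random k-mer collisions produce, and abundance models seeded from real
samples (the lognormal stands in for those). Passing the shipped validation therefore demonstrates the
statistical machinery (sampling noise, calibration, thresholds, symmetry)
on clean input, not robustness to every pathology of real libraries; on
real data the aligned fraction and FAILED fraction in the report are the
relevant diagnostics.

## Numerical and design choices

* **Strict thresholds.** "Over 90%" and "more than 60%" are read
  literally: values exactly at a threshold are INCONCLUSIVE.
* **Ties.** $n_{FR} = n_{RF}$ gives $sp = 0.5$ with FR reported as
  dominant; the verdict is UNSTRANDED either way.
* **Vote near-ties.** A read whose two orientations both pass the
  threshold and differ by ≤ 1 vote is AMBIGUOUS_STRAND, and any pair
  containing such a mate is FAILED.
* **Degenerate inputs.** A sample in which no pair's orientation can be
  determined raises an error (the proportion is undefined), mentioning the
  aligned fraction when it is below the low-alignment threshold — the
  typical cause is an unrelated transcriptome.
* **Determinism.** Head sampling, index construction and classification
  are fully deterministic; every stochastic component (simulator,
  reservoir sampling) takes an explicit seed and restores the caller's RNG
  state.
* **Index persistence** is a versioned flat binary artifact storing k,
  transcript ids and the k-mer table; corrupt or truncated artifacts fail
  loudly with an instruction to rebuild, and a stored k always wins over a
  conflicting flag (with a warning).
* **Problem sizes in the shipped validation.** Replicate precision uses 30
  unstranded replicates of 200,000 pairs on a 1000-transcript
  transcriptome; accuracy uses stranded/unstranded mixtures at ratios in
  steps of 0.1 with 3 seeds per ratio; calibration runs use single
  200,000-pair samples. These match the operating point the thresholds
  were designed for while keeping a full validation run in the
  minutes range on one CPU.

## Known limitations

* Paired-end only; single-end strandedness needs annotation-strand
  information that this transcript-space method deliberately avoids.
* Exact k-mer matching: highly divergent reads (old samples, heavy
  damage, wrong species) lose votes and inflate UNMAPPED — visible in the
  aligned fraction, which is why the low-alignment warning exists.
* The transcript id-set logic does not model splice junctions; junction
  reads fall back to the union id-set, which is harmless for orientation
  but makes `transcripts` occasionally over-inclusive.
* Verdicts describe the sampled pairs; per the usual QC practice,
  strandedness should be checked on several samples of a study before
  committing a pipeline parameter.
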