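---
title: "Methods: quantifying chloroplast C-to-U editing, differential editing, PPR target prediction and ortholog phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast C-to-U editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chloroplast transcripts undergo C-to-U RNA editing: specific cytidines are
deaminated to uridine after transcription, most often restoring conserved
codons. In cDNA sequencing an edited position appears as a C→T substitution
on the coding strand — or, for genes on the reverse strand of the reference,
as G→A in forward coordinates. Editing at a site is rarely all-or-none;
the biologically meaningful quantity is the *editing efficiency*, the
fraction of transcript molecules edited. PLS-class pentatricopeptide-repeat
(PPR) proteins select the sites: each repeat recognizes roughly one
nucleotide through the residues at motif position 6 and position 1′ of the
following motif (the "PPR code"), and DYW-domain proteins carry the
deaminase activity. The package covers four connected analyses:

1. **Editing quantification** from aligned RNA-seq reads (pileup-based) or
   from Sanger trace channel heights.
2. **Differential editing** between conditions — e.g. plants silenced for a
   nuclear editing factor by VIGS versus non-silenced controls, or old
   versus young leaves — with per-site signature classification.
3. **PPR binding-site prediction**: a PWM built from a protein's PLS motifs
   through the PPR code, scanned over the plastome with exact P-values.
4. **Ortholog phylogeny**: p-distance neighbor-joining with bootstrap.

Because the original deep-sequencing data underlying such analyses is not
needed to validate the machinery, the package ships a first-class
synthetic-data generator that plants known editing fractions in a toy
plastome, so every stage can be verified against ground truth.

## Editing efficiency and site calling

The efficiency statistic is `T/(C+T)`: edited reads over edited plus
unedited reads at the site, computed on coding-strand counts only (G/A
counts for reverse-strand genes). Other bases at the position are treated as
sequencing noise and excluded from the ratio, though they count towards
depth. When both counts are zero the efficiency is undefined and reported as
`NA`, deliberately distinct from a true 0. The same statistic applies to
Sanger traces using channel peak *heights* (`height_T/(height_C+height_T)`,
complement channels for an antisense trace). Peak height rather than area is
used because it is the simpler deterministic choice; with the simulated
traces the two coincide.

A site is called at a position when (a) the coding-strand reference base is
C, (b) depth ≥ `min_depth` (default 10), (c) edited reads ≥
`min_edited_reads` (default 2) and efficiency ≥ `min_efficiency` (default
0.01). These defaults are intentionally permissive — read-level discovery in
this field typically runs the mapper with a low SNP-filter stringency — and
every threshold is exposed in `call_thresholds()`. Positions outside
annotated genes are scanned in both orientations and labelled
`intergenic`. A user-supplied exclusion mask (known SNPs, RT artifacts) is
honored; no RT-artifact model is built in.

Multi-mapping reads (MAPQ 0 and secondary alignments) are **included by
default**, because the inverted repeat duplicates genes such as ndhB and
dropping multi-mappers silently removes exactly the sites on the IR copy.
With `include_multimapped = FALSE` those records are excluded, and the
per-position depth difference equals the number of MAPQ-0 records — a
property the test suite checks exactly. A multi-mapped read counts once per
reported location.

Sites are named `<gene>-<k>` with k assigned in 5′→3′ transcript order
(descending genome coordinate for reverse-strand genes); a gene with a
single site gets its bare name (`psbL`). A gene with two IR placements
contributes a numbered site per placement; the two mirrored positions are
the same transcript site observed twice, which is the price of reporting in
genome coordinates.

Coordinates are 1-based inclusive throughout, matching SAM and GFF3, the two
formats consumed.

## Differential editing

Replicate efficiencies are compared per site with Welch's unequal-variance
t-test and a **one-tailed** p-value, the test used for silencing
experiments with 3 control and 4 test libraries. Two conventions needed
fixing where practice is ambiguous:

* **Direction.** Published analyses report both significant decreases and
  significant increases from a one-tailed test without stating the
  direction rule. `compare_conditions()` takes the tail from the sign of
  the observed difference, which reproduces that behavior; a fixed tail or
  a two-tailed mode are available via `mode`.
* **Degenerate samples.** Zero variance in both groups with equal means
  gives t = 0, p = 0.5 by convention rather than an error, so saturated
  sites (all replicates at 1.0) flow through pipelines.

Raw p-values are compared to `alpha` (default 0.05) with **no**
multiple-testing correction by default, mirroring the per-site asterisk
convention of the experiments this supports; Benjamini–Hochberg is a flag.
Efficiencies are tested on the raw [0, 1] scale. Beta-binomial
overdispersion and mixed models across plants are out of scope.

`age_trend()` applies the same machinery to leaf-age series. Leaves are
numbered from the bottom of the plant, so the lowest-numbered class is the
oldest and is compared against the youngest.

`classify_signatures()` partitions sites by which silencing conditions
affected them: significant in a designated chlorosis stress control (a
PDS-like silencing) ⇒ `general_stress`, i.e. likely a secondary effect of
chloroplast dysfunction; significant in exactly one other condition ⇒
`specific:<condition>`; in several ⇒ `shared`; nowhere ⇒ `unaffected`.
Stress-control significance takes precedence by design: a site that also
fails in bleached leaves cannot be attributed to the silenced factor.

`conservation_compare()` intersects two species' site tables on
(gene, within-gene offset) keys, the natural cross-species coordinate.

## PPR-code PWM and exact P-values

One PWM column per P/L/S motif in N-to-C order (the N-terminal motif pairs
with the 5′-most base); E/E+/DYW regions contribute no columns. The shipped
code table transcribes the canonical published (aa6, aa1′) nucleotide
preferences for the common residue pairs and is an editable TSV; pairs
absent from the table — including gap residues — get a uniform fallback
column, so unusual motifs degrade the model gracefully instead of breaking
it. Columns get a pseudocount (default 0.01, configurable) before log2-odds
against the background, keeping scores finite.

The background is by default estimated from the scanned genome as 0-order
frequencies (plastomes are AT-rich, ~62% AT, and a uniform background would
inflate AT-rich hits); uniform is available.

P-values are exact: per-column scores are shifted to be non-negative and
discretized to integer bins with granularity = (total score range)/1000,
and the null distribution of the total score of a random background
sequence is built by column-wise convolution. A hit's p-value is the upper
tail at its integer score. The test suite checks the DP distribution
against full enumeration over all 4^L sequences for short PWMs; agreement
is within one discretization step per column, the standard accuracy of this
construction. Both strands are scanned; minus-strand hits are reported in
forward coordinates. Ambiguous bases score as the background-weighted
column average. The ranked output is capped at the top ten by default,
with deterministic tie-breaks (p, then score, then coordinate, then
strand). Q-values are not computed by default since predictions of this
kind are conventionally ranked by raw P-value; BH adjustment can be applied
downstream.

## Phylogeny

p-distances (amino acid differences per compared site) use pairwise
deletion of gap columns by default — complete deletion is a flag — and a
pair with no comparable columns is an error naming the pair. The NJ tree is
the standard Saitou–Nei agglomeration; negative branch lengths, possible on
non-additive inputs, are clamped to zero with a warning for presentation.
Bootstrap resamples alignment columns, rebuilds the NJ tree, and reports
for each internal edge of the full-data tree the **fraction** of replicates
containing that bipartition (default 1000 replicates, deterministic under a
seed). Fractions are reported rather than "per-million" style units, which
we treat as a typographical artifact of figure legends in this literature.

## What the simulator emulates — and what it does not

`simulate_plastome()`/`simulate_reads()` emulate the relevant structure of a
chloroplast RNA-seq experiment: an AT-rich genome with genes on both
strands; one ndhB-like gene duplicated in inverted-repeat orientation;
250-nt paired-end reads (the platform read length of the experiments this
mirrors); an unstranded library (random-hexamer-primed double-stranded
cDNA, so fragments come from both strands uniformly); molecule-level
editing — each fragment is edited at each covered site independently with
the planted fraction, and both mates share the molecule's state; uniform
per-base substitution errors at a constant quality; and multi-mapping
records (MAPQ-0 primary plus a mirrored secondary) for reads fully
contained in either IR copy. Reads are emitted pre-aligned as a truth SAM,
since mapping itself is out of scope.

Not modeled: indels, PCR duplicates, position-dependent quality, splicing,
coverage bias, reverse-transcription artifacts, and fragments spanning the
circular origin (the genome is linearized for read placement; circularity
is an annotation-level fact only). Passing tests therefore demonstrate the
correctness of the statistical machinery under binomial sampling, not
robustness to alignment artifacts of real libraries.

Default study conditions follow the experimental design this package
mirrors: 3 control versus 4 silenced replicates, planted fractions spanning
the observed range from ~0.05 (the weakest efficiencies seen in practice,
e.g. ~5.43%) to 1.0 (fully edited sites).

## Numerical and scale choices

* Discretization granularity 1/1000 of the score range; pseudocount 0.01.
* Binomial-recovery tests use a 20 kb genome at depth 1000 and the demo a
  20 kb genome at depth 120 — sizes chosen so efficiencies are
  well-resolved at every planted fraction while a full run stays in the
  minutes range on a laptop.
* The Welch null calibration uses 10,000 replicates (type-I error), power
  checks 500 replicates at the 3-vs-4 design.
* Determinism: every stochastic routine takes a seed, and identical
  configuration plus seed reproduces outputs byte-for-byte.
* `run_demo()` keys per-replicate site tables by planted-truth positions so
  that a rare noise call inside a gene cannot shift the `<gene>-<k>`
  numbering between replicates.

## Known limitations

* U-to-C editing and mitochondrial transcripts are out of scope.
* The shipped PPR code table is a qualitative transcription of the
  canonical preferences, not a refit; users with calibrated weightings
  should supply their own TSV.
* The packaged motif table and ortholog alignment are synthetic stand-ins
  (marked `_syn`/`synthetic` in names) for figure-only data that has no
  machine-readable source; they exercise the machinery, not the biology of
  the real protein.
* Welch's test on 3-vs-4 replicates is slightly conservative (empirical
  type-I error ≈ 0.043 at nominal 0.05 in the packaged calibration run).
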