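---
title: "Predicting mRNA-processing outcomes of induced mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mRNA-processing outcomes of induced mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefate)
```

## The problem

Reverse-genetics projects routinely induce point mutations or small
deletions expecting a loss-of-function allele, yet a surprising fraction of
such lines keeps near-wildtype transcript levels or protein activity. A
recurring cause is permissive mRNA processing: when a mutation destroys an
essential splice site (ESS) — the invariant GT at an intron's 5' donor or
the AG at its 3' acceptor — the spliceosome does not simply fail. In order
of observed frequency it (1) skips the adjacent exon, (2) activates a
nearby cryptic GT/AG, (3) creates a pseudo-exon inside the intron, or
(4) retains the intron when it is short or terminal. Nonsense mutations can
likewise trigger skipping of the PTC-bearing exon (nonsense-associated
altered splicing), particularly when the mutated base sits in an exonic
splice enhancer (ESE). Whether any of these products is degraded depends on
nonsense-mediated decay (NMD), which fails when the premature termination
codon (PTC) lies in the last exon or within roughly 50–55 nt of the last
exon–exon junction.

splicefate turns that decision tree into a deterministic, testable
pipeline: classify the lesion, enumerate candidate transcripts, derive the
ORF consequence of each, and predict whether transcript levels should be
reduced or wildtype-like.

## The pipeline and its model

`predict_outcomes()` chains four steps, all exposed individually:

1. **Classification** (`classify_mutation()`). Intron positions +1/+2
   relative to the donor are `ESS_donor`; −2/−1 relative to the acceptor
   are `ESS_acceptor`. Exonic substitutions are compared codon-wise in the
   transcript's annotated frame; exonic deletions are in-frame or
   frameshifting by length mod 3. Only the annotated isoform's frame is
   used — no alternative-frame search.

2. **Outcome enumeration** (`enumerate_outcomes()`), ranked by the
   frequency order above: skip first, then cryptic sites nearest-first,
   then intron retention. Design choices worth knowing:
   * A donor loss proposes skipping the *upstream* exon, an acceptor loss
     the *downstream* exon — the directions observed in the cases this
     package models. The opposite-side skip is not enumerated.
   * When the downstream exon of a lost acceptor is terminal there is
     nothing to skip to; a `no_rescue` candidate is emitted instead and
     classed "reduced" with a caveat flag, because no PTC-bearing isoform
     can be exhibited even though transcript loss is expected.
   * Retention is proposed only for introns up to
     `intron_retention_max_nt` (default 1000 nt) — plus always for the
     terminal intron, which has no downstream splicing unit.
   * Pseudo-exon creation is **not** enumerated; every report carries a
     fixed `pseudo_exon_not_evaluated` flag so the omission is explicit.
   * Equidistant cryptic candidates are both reported, exonic side first.

3. **ORF consequence** (`consequence()`). The mature mRNA is rebuilt from
   the outcome's exon structure, the wildtype start codon is re-mapped onto
   it (if the start is lost the record is flagged `start_lost`; downstream
   start-codon rescue is out of scope), and translation runs to the first
   in-frame stop. A stop strictly upstream of the re-mapped wildtype stop
   is a PTC. Frame status is decided by coding-length arithmetic — the net
   change in coding nucleotides (including an exonic indel's own length)
   mod 3 — rather than by protein-string comparison, so the call is exact
   and independent of filler sequence. `diff_protein()` supplies the
   residue bookkeeping (removed/gained residues via longest common
   prefix/suffix).

4. **NMD call** (`classify_nmd()`). Escape iff the PTC is downstream of the
   last junction or within `escape_threshold_nt` of it; degraded otherwise;
   single-exon transcripts always escape. The default threshold is 55 nt,
   the upper end of the canonical 50–55 nt range, so a junction-adjacent
   PTC (1 nt upstream) is robustly escape; values outside 50–55 are
   accepted with a warning. "PTC in the last exon" and "PTC within the
   threshold of the last junction" are collapsed into the single predicate
   above. Predicted transcript class is "reduced" exactly when the call is
   degraded (plus the `no_rescue` caveat case).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_nt` | 100 | scan distance (nt) each side of a lost splice site. Observed cryptic sites sit 2–40 nt away; 100 is generous while keeping reports short. |
| `intron_retention_max_nt` | 1000 | longest intron for which retention is proposed (terminal introns always). |
| `donor_motif`, `acceptor_motif` | GT, AG | the scanned dinucleotides. |
| `escape_threshold_nt` | 55 | NMD escape distance from the last junction. |

Coordinates everywhere are 1-based inclusive (HGVS g. and GFF3
conventions); exon/intron indices are 1-based in transcription order on
either strand, so "intron 33–34" is the intron after the 33rd transcribed
exon. Minus-strand models are normalised to transcript orientation at
load, and strand symmetry is enforced by property tests.

## ESE scanning

`scan_ese()` implements the additive position-weight-matrix scan used by
web-based ESE predictors: a window scores the sum of per-position weights
and is a hit at `score >= threshold`; no log-odds conversion is applied.
The proprietary SRSF matrices of those tools are not shipped — the
tab-delimited format (`load_ese_matrices()`) accepts any PWM, and the test
fixtures plant synthetic consensus motifs instead. `mutation_in_ese()`
reports whether a substitution falls inside a wildtype hit and which hits
drop below threshold in the mutant, the mechanism proposed for
nonsense-associated exon skipping.

## Exon mod-3 symmetry

`summarize_symmetry()` tabulates, for exon index 1..10, the remainder of
each exon's length divided by 3 and tests the counts against the uniform
1/3 split with `chi_squared_uniform()` (df = 2; with two degrees of freedom
the p-value is exactly `exp(-statistic/2)`, which the tests verify to
1e-10). "Exon length" is the annotated exon span including UTR portions;
`cds_only = TRUE` switches to per-exon coding widths, and `dedupe_genes`
keeps one transcript per gene — the upstream feature dump conventions
differ between annotation releases, so both modes are provided and neither
is asserted as canonical. Text output prints p-values below 2.2e-16 as
"< 2.2e-16" by convention; exact values stay in the data.frame/JSON.

## What the synthetic generator emulates

`build_mimic()` produces seven seeded fixtures that reproduce the
*structural* parameters of the studied mutant lines: exon sizes (116, 210,
114 nt), planted cryptic sites at the observed offsets (acceptor AG at
exon bases 2–3; donor GT 4 nt into an intron beginning ATATGT; internal
exon-2 AGs giving 13- and 40-nt truncations), a terminal exon encoding
exactly 154 residues with the mutant PTC 1 nt from the last junction, a
nonsense codon inside a planted 7-mer ESE consensus, and a terminal-exon
acceptor lesion. Each lesion sits at the published genomic coordinate
(e.g. g.3431) by construction of the upstream flank.

Everything else is random filler, constrained so the expected outcome is
deterministic for *any* seed: coding sequence is generated with a global
reading-frame tracker (no in-frame stop can arise in the wildtype ORF),
scanner windows are generated free of the scanned motif so the planted
cryptic site is the only candidate, and regions a frameshifted ribosome
traverses before a planted stop are T-free (no stop codon exists without
T). An independent post-build verification re-checks these invariants.

What the fixtures do **not** emulate: real flanking sequence, splice-site
strength, branch points and polypyrimidine tracts, GC content, or the
actual residue content of novel ORFs. Passing the end-to-end tests
therefore demonstrates that the *logic* reproduces the reported outcome
structure, not that the package predicts splicing from sequence context —
candidate sites are motif matches, deliberately, with no MaxEnt-style
scoring (see Limitations).

`build_symmetry_genome()` draws exon lengths with
P(length ≡ 0 mod 3) = 1/3 + excess. The calibration tests use 200
replicates of 250 genes (null rejection rate ≈ 5% at α = 0.05) and a
50,000-gene genome for recovering a planted 5.1-point excess — sizes
chosen so the whole suite runs in a couple of minutes on one core while
keeping Monte-Carlo noise well below the asserted tolerances.

## Numerical and degenerate-input choices

* Deletions are lifted through annotations by shifting downstream exon
  boundaries left; a deletion overlapping an exon boundary or an ESS
  dinucleotide is rejected as unsupported (no studied case needs it).
* One studied deletion is published with an 8-position span
  (g.6948_6955del) but described as 7 bp; the fixture plants 7 nt and
  notes the discrepancy in its metadata rather than resolving it.
* A cryptic-site offset is measured first-base-to-first-base from the
  wildtype site; `delta_nt` (bases retained/removed) is the verifiable
  quantity and is what reports and tests assert.
* N bases are allowed in genomes; motif matches never overlap N (the
  motifs are pure ACGT) and PWM windows containing N are skipped.
* Translation uses the standard genetic code; the annotated start codon is
  translated literally (no initiation-codon special-casing).
* `unspliced_ptc` outcomes for in-frame exonic deletions can legitimately
  yield "maintained" frame with no PTC; the class is then WT-like.

## Known limitations

* No splice-site strength model: every GT/AG in the window is a candidate,
  ranked by distance only.
* No pseudo-exon or cryptic translation-start enumeration (flagged, not
  silently ignored).
* Transcript-level predictions are binary (reduced vs WT-like); measured
  fold-changes are wet-lab quantities this package does not estimate.
* Exon indexing follows the supplied transcript; no canonical-isoform
  guessing. Analyses of multi-isoform genes should pass the isoform whose
  numbering they mean.
```{r example}
fx <- build_mimic("slc27a2a_mimic", seed = 1)
rep <- predict_outcomes(fx$genome, fx$model, fx$mutation)
as.data.frame(rep)[, c("rank", "kind", "delta_nt", "frame_status",
                       "outcome_phrase", "transcript_level_class")]
```
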