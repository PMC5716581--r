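# splicefate

Predicting the mRNA-processing consequences of induced point mutations and
small deletions in gene models.

## Why

Mutant lines carrying "obvious" loss-of-function lesions — a destroyed
essential splice site (ESS), a nonsense codon, a small frameshifting
deletion — often keep near-wildtype transcript levels. The transcript can
be rescued by exon skipping, by activation of a nearby cryptic splice
site, or by retention of a short or terminal intron; and even a
PTC-bearing message escapes nonsense-mediated decay (NMD) when the
premature termination codon (PTC) lies in the last exon or within
50–55 nt of the last exon–exon junction. splicefate is for anyone
designing or validating such mutants: it predicts, before any wet-lab
work, which alternative transcripts a lesion can produce and whether each
should be degraded (`reduced`) or not (`WT-like`).

## What it computes

For a mutation `m` on transcript `T` (exons $e_1..e_n$, introns
$i_k$ between $e_k$ and $e_{k+1}$):

* **Classification** — intron positions +1/+2 → ESS donor (GT), −2/−1 →
  ESS acceptor (AG); exonic substitutions by codon comparison in the
  annotated frame; exonic deletions frameshift iff length mod 3 ≠ 0.
* **Outcome enumeration**, in the observed frequency order
  *skip < cryptic site < intron retention*: a donor loss proposes skipping
  $e_k$, an acceptor loss $e_{k+1}$ (or `no_rescue` when $e_{k+1}$ is
  terminal); every GT/AG within a 100-nt window of the lost site is a
  cryptic candidate, nearest first; retention is proposed for introns
  ≤ 1000 nt and always for the terminal intron.
* **ORF consequence** — mature mRNA, protein, frame status (net coding-nt
  change mod 3), PTC position and its distance $d$ to the last junction.
* **NMD call** — escape iff $d \le$ 55 nt (configurable within 50–55) or
  the PTC sits in the terminal exon; degraded otherwise. Degraded ⇒
  predicted transcript level `reduced`.
* **ESE scan** — additive position-weight-matrix scanning of exon
  sequence; `mutation_in_ese()` flags nonsense mutations that destroy a
  predicted exonic splice enhancer hit.
* **Exon symmetry** — per exon index 1..10, the distribution of exon
  length mod 3, the excess of remainder-0 ("symmetric", skip-tolerant)
  exons over the 33.33% chance level, and a χ² goodness-of-fit test
  (df = 2, p = exp(−χ²/2)).

A seeded generator (`build_mimic()`) builds synthetic genomes that
reproduce the structural parameters of seven studied zebrafish mutant
lines, so the entire pipeline is testable offline.

## Worked example

```r
library(splicefate)

fx  <- build_mimic("slc27a2a_mimic", seed = 1)   # donor G>A in intron 2-3
rep <- predict_outcomes(fx$genome, fx$model, fx$mutation)
rep
#> <prediction_report> slc27a2a_mimic_tx g.3431G>A [ESS_donor]
#>  rank             kind delta_nt frame_status  nmd_predicted
#>     1        exon_skip     -210   maintained not_applicable
#>     2 intron_retention      154   frameshift       degraded
#>                              outcome_phrase transcript_level_class
#>     skipped exon (210 bp), frame maintained                WT-like
#>  intron retained (154 bp), frame shift, PTC                reduced
#> note: pseudo-exon outcomes not evaluated
```

Reading: the destroyed donor of intron 2–3 most plausibly skips exon 2;
since exon 2 is 210 nt (divisible by 3) the reading frame is preserved, no
PTC arises, and transcript levels are predicted `WT-like` — the mutant is
*not* a reliable knockout. The lower-ranked retention of the 154-nt intron
would frameshift and be degraded.

The pre-design counterpart:

```r
design_checklist(fx$genome, fx$model, exon_index = 2)
#> <design_checklist> slc27a2a_mimic_tx exon 2 (210 nt)
#>   - divisible by 3: skip-tolerant
#>   - flanking introns: upstream 154 nt, downstream 154 nt
#>     [retention risk: short upstream intron]
#>   - acceptor-side cryptic sites: -16, 17, -29, 48, -49, 52, -55, 71, 89, -92
#>   - donor-side cryptic sites: none in window
```

A 210-nt exon is flagged skip-tolerant: targeting it with a splice-site
mutation is unlikely to yield a null allele.

Batch runs, GFF3/GTF + FASTA input, and the `symmetry` analysis are
available both as functions (`predict_batch()`, `read_annotation()`,
`summarize_symmetry()`) and through the thin CLI at
`inst/cli/splicefate.R` (subcommands `predict`, `checklist`, `symmetry`,
`fixtures`).

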