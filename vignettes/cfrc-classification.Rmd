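---
title: "Classifying crustacean CHH-family receptor candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying crustacean CHH-family receptor candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrckit)
```

## The biological problem

Molting in decapod crustaceans is controlled by ecdysteroids whose synthesis
is suppressed by molt-inhibiting hormone (MIH), a member of the crustacean
hyperglycemic hormone (CHH) neuropeptide superfamily. The receptors for
these peptides are thought to be Class A (rhodopsin-like) G protein-coupled
receptors, but none has been functionally deorphanized. Candidate receptors
— CHH Family Receptor Candidates (CFRCs) — are identified by homology to the
three characterized silk-moth ion transport peptide receptors (BNGR-A2,
-A24, -A34) and fall into three clades named after them. Within decapods,
eleven subclades occur (A2α1, A2β, A24α, A24β1–β3, A34α1–α2, A34β1–β3),
distinguishable by conserved sequence motifs in the second and third
extracellular loops (ECL2, ECL3) of the receptor — the ligand-binding
region.

`cfrckit` implements the full in silico screening chain as a reusable,
tested pipeline: candidate curation, seven-transmembrane (7-TM) topology
delineation, degenerate motif matching anchored on the conserved ECL2
cysteine, clade/subclade classification, CHH-superfamily peptide typing,
alignment consensus and logo statistics, and presence/absence
summarization.

## Candidate curation

Curation composes four deterministic, auditable filters, in order:

1. **E-value screen.** Hits with e-value strictly below `1e-10` survive
   (a hit exactly at the threshold is removed). The notation `e^-10` in
   homology-search output conventions is read as `1e-10`.
2. **Domain check.** A hit must be annotated as carrying the Class A
   seven-transmembrane domain (`7tm_1`). Annotation is tri-state
   (yes/no/unknown): unknowns fail closed, with the explicit reason
   `"unannotated"` so users can re-annotate rather than silently keep or
   drop them.
3. **TM count.** Sequences with fewer than six predicted transmembrane
   segments are discarded; a count of exactly six is kept. When no external
   TM count is annotated, the filter falls back to counting membrane runs
   in supplied per-residue topology labels, then to the built-in hydropathy
   segmentation.
4. **Same-species redundancy removal.** Within each species, greedy
   clustering by descending length: a sequence joins the first cluster
   whose representative is at least 95% identical; representatives (the
   longest member, ties to the lexicographically smallest id) are retained.

Known fragments from exempt taxa (default: Brachyura, the true crabs, a
focal group in which partial transcripts are common) bypass filters 2 and 3
only — never the e-value screen. The original screening procedure removed
redundant sequences manually after inspecting percent homology; no numeric
threshold or identity metric was stated. We use a reproducible proxy: global
alignment identity (match 1, mismatch 0, gap open −5, gap extend −1; the
score only selects the alignment) with terminal overhangs excluded, at a
configurable 0.95 default. Keep-longest is chosen because longer contigs
carry more complete domain structure. With a zero mismatch penalty the
optimal alignment can be degenerate; any optimum yields the same decisions
at the thresholds used, and the test suite checks the returned identity
against the full set of optimal-alignment identities on small cases.

The curation report partitions the input: every id appears exactly once,
retained or removed at a named stage with a reason.

## Topology delineation

The architecture is the canonical Class A layout: extracellular N-terminus,
seven transmembrane helices TMM1–TMM7 alternating with intracellular loops
ICL1–ICL3 and extracellular loops ECL1–ECL3, intracellular C-terminus.
Orientation is fixed (N-out); topology labels implying an intracellular
N-terminus are an error, not silently reinterpreted, as are labels that
break inside/outside alternation between membrane runs. Region intervals
are 1-based inclusive and tile the sequence exactly; loops may be empty.

External deep-learning topology predictions are consumed as per-residue
O/M/I labels. When none are available, a built-in hydropathy fallback is
used:

* **Profile.** Centered moving average of the Kyte–Doolittle scale,
  window 19 (the conventional width for TM detection), truncated at the
  ends; `X` is treated as neutral (0).
* **Segmentation.** Maximal runs of positions with windowed hydropathy
  ≥ 1.6 are candidate helices. Runs separated by fewer than 3 residues are
  merged; runs shorter than 5 positions are discarded as noise. Window
  smoothing necessarily erodes run flanks (a 21-residue helix between polar
  loops yields an ~11-position run), so short runs are emitted at a target
  length of 21 — the midpoint of the 17–25 length bounds and the canonical
  helix length — centered on the run's *upper-half mass centroid*: the
  center of mass of profile values above halfway between the threshold and
  the run maximum. The smoothed profile reaches its maximum only where the
  window lies fully inside the helix, so this estimator resists one-sided
  shoulders created by partly hydrophobic loop content (e.g. aromatic motif
  residues in ECL2). Runs longer than 25 are split at the minimum-profile
  position within their central stretch (a plateau's minimum is taken at
  its middle) and the pieces re-examined.

On synthetic receptors with planted 21-residue helices the label path and
the hydropathy path agree in TM count, with interval midpoints within ±3
residues; with plain polar loops, boundaries land within ±2 of the planted
coordinates. Loop sequences that are themselves membrane-like in hydropathy
can still shift a detected helix — this is an intrinsic limit of
single-scale sliding-window segmentation, which is why externally predicted
labels take precedence whenever present.

## The motif grammar and anchored matching

Diagnostic motifs are written in a compact degenerate grammar: an uppercase
letter is a conserved residue, `x` an unconserved site, `[AB]` a site
admitting either residue, a `-` inside brackets marks a site that may be
deleted (observed indel), and `(C)` marks the *anchor*: the conserved ECL2
cysteine around which all positional diagnostics are expressed. The
packaged decapod library holds 22 patterns — one ECL2 and one ECL3 motif
for each of the 11 subclades; every ECL2 pattern is anchored.

Matching is exhaustive: all start offsets × all deletion on/off
combinations over gap-allowed sites. A placement is valid only if the whole
(post-deletion) pattern fits inside the region and the anchor, when
present, sits on a cysteine. The score is the fraction of evaluated
non-wildcard sites whose residue is allowed; wildcards carry no reward,
because `x` means "not conserved", and rewarding them would inflate scores
of long, poorly conserved patterns. Ties break to the smallest start, then
the fewest deletions. The implementation is vectorized over offsets; the
test suite holds it equal to an independent naive triple-loop oracle on
thousands of random regions.

Positions in the source material are alignment-column numbers that shift
between figures; all positional diagnostics here are therefore expressed
relative to the anchor cysteine:

* A2: a `PxGxDxP` stretch upstream of the anchor.
* A24: `WPDG` starting exactly four residues C-terminal to the anchor with
  a serine eight residues after the tryptophan (kept exact, as stated); and
  a threonine pair upstream. In gapped reference-alignment coordinates the
  pair sits 19/18 columns before the cysteine, but in ungapped loop
  sequences the spacing compresses to 11–15 residues depending on the
  subclade, so the pair is searched over offsets −20..−11.
* A34: a tryptophan eight residues and an arginine fifteen residues
  N-terminal to the anchor (each with ±1 tolerance for loop-boundary
  jitter).
* A34β subclades additionally carry a second conserved ECL2 cysteine.

When ECL2 contains several cysteines (as the A34β ECL2 legitimately does),
every cysteine is evaluated as a candidate anchor and the best-supported
anchor is kept.

## Subclade classification

Classification is two-stage. Stage 1 votes for a clade from the anchored
diagnostics (`PxGxDxP` → A2, `WPDG` at +4 → A24, W at −8 → A34). A single
unambiguous vote restricts stage 2 to that clade's subclades; none or
several votes evaluate the whole library. Stage 2 scores each candidate
subclade as

```
combined = 0.7 * ecl2_score + 0.3 * ecl3_score
```

with the ECL3 weight folded into ECL2 when the library has no ECL3 pattern
for a subclade or the receptor's ECL3 is empty. A receptor is `classified`
when the best combined score is at least 0.70 and leads the runner-up by at
least 0.05; `ambiguous` (top two reported) when the threshold is met
without the margin; `unclassified` otherwise. The source material states no
numeric rule; these defaults were set so that noiseless motif realizations
classify perfectly while single-clade cross-matches stay below threshold,
and all three numbers are configurable. Because the stage 1 vote is a
heuristic restriction (a spurious cysteine can occasionally misdirect it),
a restricted evaluation that fails to produce a confident call falls back
to the full library.

Two robustness details matter in practice. First, ECL2/ECL3 windows are
widened by 5 residues into their flanking TM intervals before matching
(`loop_pad`); predicted loop boundaries jitter by a few residues, and a
clipped motif otherwise cannot fit. Second, all positional evidence is
anchor-relative, so it is insensitive to where exactly the loop was cut.

The signature scan reports the canonical Class A motifs at their expected
topological windows — E/DRY at the TMM3/ICL2 boundary (with the `xRx`
variant such as `GRF` reported verbatim when the acidic position is
substituted), `TxP` in TMM2, `CWxP` plus a downstream phenylalanine in
TMM6, `NPxxY` near the TMM7/C-terminus boundary, and `[YH]xWxF`/`xWxF` in
ECL1. The ECL2 anchor's disulfide partner is reported descriptively (the
nearest TM cysteine) rather than asserted, since the helix it bridges to is
described differently in different parts of the source material.

## CHH-superfamily peptide typing

Mature CHH-family peptides carry six conserved cysteines forming three
disulfide bridges. The framework locator records all cysteine positions;
exactly six constitute a valid framework, paired by the family-canonical
connectivity C1–C5, C2–C4, C3–C6 — a convention inferred from the known
bridge assignments, not a structure prediction. Type II peptides (MIH, GIH,
MOIH) carry a glycine inserted at the fifth position after the first
cysteine (Gly12 in the canonical numbering where C1 is Cys7); the rule is
applied relative to C1 so it transfers to peptides whose N-terminal
trimming differs, and both the relative and absolute positions are
reported. Type I precursors (CHH, ITP) are signal peptide +
precursor-related peptide + `KR` cleavage site + mature peptide; the mature
span starts after the *last* `KR` whose downstream sequence contains a
valid framework, matching the stated precursor architecture. Inputs without
any `KR` are treated as already mature (the Type II convention). C-terminal
basic extensions (such as the CHH `RKKK`) are retained for typing and
flagged. Identity against the packaged brachyuran MIH/CHH consensus
patterns is computed ungapped, anchored at the first cysteine, over the
consensus' conserved sites.

## Consensus and logo statistics

Column profiles report, per alignment column, each residue's proportion
among non-gap entries, with the gap fraction tracked separately — so logo
stack heights reflect residue usage among sequences present at a site, and
heavily gapped columns are not artificially flattened. The logo is drawn as
proportional stacked columns without information-content scaling.

Consensus emission uses three thresholds (all configurable): a site is
written as its top residue when that residue's proportion is ≥ θ = 0.7; as
a two-residue bracket `[R1R2]` when the top two each reach π = 0.4 without
either dominating (residues in near-equal proportions; at exact ties the
bracket members are ordered alphabetically — bracket content is a set); and
a gap fraction ≥ γ = 0.2 adds the indel marker (`[R-]`, `[x-]`). The
source material publishes consensus outputs but not thresholds; these
defaults make the two documented bracket cases (equal-proportion pairs and
indel sites) reproducible, and the zero-noise round trip — realize
sequences from a pattern, rebuild the consensus, recover every conserved
site — succeeds for all 22 packaged patterns.

## The synthetic benchmark

Every stage is testable without downloads via a seeded generator that
emulates the statistical structure the pipeline assumes:

* **Receptors.** Hydrophilic N-terminus, seven 21-residue TM blocks drawn
  from `{L,I,V,F,A,M}` alternating with hydrophilic loops, ECL2/ECL3
  carrying realized subclade motifs (wildcards uniform over the 20 amino
  acids; gap-allowed sites deleted with probability 0.5), mutated at a
  configurable per-site rate that never touches the anchor cysteine —
  anchor loss is a distinct failure mode, generated separately via decoys.
  Paired O/M/I labels, planted coordinates and a hit row (e-value
  log-uniform over a range straddling the screening threshold, so the
  filter is exercised on both sides) are emitted.
* **Decoys.** Non-GPCR hydrophilic sequences, 5-TM receptors, fragments
  from exempt and non-exempt taxa (exercising both exemption outcomes,
  each in its own species so redundancy removal is not entangled), and
  same-species near-duplicates (2% mutation, slightly truncated) of
  receptors that pass the e-value screen.
* **Peptides.** Realized from the packaged family consensus; wildcards
  sample non-cysteine residues and mutations never create a cysteine, so
  the six-cysteine framework is preserved by construction; a spurious
  dibasic site upstream of C1 is resampled away so precursor wrapping and
  mature extraction are exactly inverse.

The generator does **not** emulate evolution along a phylogeny, indels
outside bracketed sites, compositional biases of real membrane proteins, or
fragmentary/low-quality transcriptome artifacts beyond the explicit decoy
classes. Passing tests therefore demonstrate the pipeline's correctness
under its stated assumptions, not its performance on raw transcriptome
data.

Default study conditions: 5 receptors per subclade for recovery checks
(55 receptors), 19 per subclade (209) per mutation rate for the
accuracy-vs-noise curve over rates {0, 0.05, 0.1, 0.2}, 100 seeded bundles
of 11 receptors plus decoys for the curation partition invariant, and
1,000 random regions against all 22 patterns for the matcher/oracle
equivalence. These sizes keep the full suite in the minutes range on one
CPU while leaving each property statistically meaningful.

## Worked example

```{r example}
lib <- default_motif_library()
set.seed(42)
rec <- generate_receptor("A34β2", synthetic_spec(mutation_rate = 0.05), lib,
                         id = "demo")
regions <- assign_regions(rec$seq$residues, labels = rec$labels)
call <- classify_subclade(regions, rec$seq$residues, lib)
call[c("clade", "subclade", "combined_score", "status")]
```

```{r peptide}
ref <- chh_reference_set()
mih <- ref$peptides$residues[ref$peptides$id == "Gl-MIH"]
cys_framework(mih)
classify_type(mih)
```

## Known limitations

* The hydropathy fallback is a single-scale sliding-window method; it is
  deliberately simple and is superseded by external per-residue topology
  labels whenever they are provided. Re-entrant or ambiguous membrane
  segments are not modeled.
* The redundancy filter is a reproducible proxy for a manual curation step;
  its 0.95 identity threshold is a design choice, not a published value.
* Classification thresholds (0.70 call, 0.05 margin, 0.7/0.3 weights) are
  package defaults calibrated on noiseless synthetic data, exposed for
  tuning against real curated sets.
* The completeness criterion for "complete or nearly complete" sequences is
  unquantified in the source material and is represented only by the
  fragment flag consumed by the exemption logic.
* Whether ECL3 motifs contributed to the original subclade assignments is
  unstated; here they contribute 30% of the combined score and their
  absence is handled by weight folding.
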