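---
title: "Models and methods behind orfannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orfannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfannot)
```

`orfannot` annotates prokaryotic genomes by transferring function from a
protein reference database onto predicted open reading frames.  This
vignette explains the model the package implements, the parameters that
matter and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## ORF model

A coding gene is modelled as a single-exon, in-frame span from a start
codon to the next stop codon on one of six reading frames, with the stop
codon included in the genomic interval.  Internally every interval is
0-based half-open on the forward strand regardless of feature strand; the
1-based inclusive coordinates with `complement()` of EMBL files exist only
at (de)serialization time.  Using one arithmetic convention everywhere
keeps the overlap geometry (truncation, re-anchoring, fraction
computations) free of off-by-one special cases.

Prediction is a single pass per frame: outside an ORF, the first start
codon of a stop-delimited segment opens a candidate; the next in-frame
stop closes it.  One ORF per stop segment is deliberate — nested starts
sharing a stop are not enumerated, because the downstream resize step
revisits alternative starts against the selected database subject, which
is better evidence than enumeration.  Candidates opening at a valine or
leucine initiator are moved to the first in-frame `ATG` when the
Met-to-stop span still reaches the minimum length, reflecting the strong
prior for methionine initiation.

Two deliberate choices here:

* **Start-codon set.**  The default alternative initiators are `GTG`,
  `TTG` and `CTG` — the common bacterial Val/Leu starts.  The full Val/Leu
  codon sets are available via `genetic_code(full_alt_starts = TRUE)` for
  users who want the permissive behaviour; the permissive set produces
  many more spurious candidates on random sequence, which is why it is not
  the default.
* **Minimum length, 60 nt.**  Applied to the span from the (possibly
  Met-adjusted) start through the stop codon inclusive.  Shorter spans are
  too unspecific to search usefully.  The Met-preference rule only fires
  when the adjusted ORF still satisfies this floor — promoting a start may
  never push an ORF below the minimum it was admitted under.

Codons containing `N` are opaque: they never match a start or a stop and
translate to `X`.  This is the only deterministic treatment of ambiguity
that neither invents nor destroys ORFs.

## Scoring

Hits are scored with the composite accuracy

$$ACC = ID \cdot \frac{ML}{SL} \cdot \frac{ML}{OL}$$

with identity fraction $ID$, alignment columns $ML$, subject length $SL$
and ORF length $OL$, all lengths in amino acids.  $OL$ counts codons
excluding the stop, which is the only unit in which $ML/OL$ is
dimensionless against $ML$ and the full-match identity $ACC = ID$ holds
exactly.  All scores are stored as fractions in $[0,1]$ and rendered as
percentages only in reports.

The alignment engine is Smith–Waterman (Biostrings) with BLOSUM62 and gap
open 11 / extend 1 — the BLAST-family convention.  Identity is identical
columns over alignment columns.  For gapped alignments $ML$ is the column
count and the aligned spans on query and subject are each at most $ML$;
the gapless model is the common case and degrades gracefully.

Start-site extension is validated with the Levenshtein similarity
$S = (L - D)/L$ between equal-length strings.  Only equal lengths are
compared — the gate compares a proposed extension with a subject region of
exactly the same length, so unequal inputs indicate a caller bug and raise
an error rather than being normalised away.

## Start-site resize

Two cases, both anchored at the stop codon (strand, frame and stop never
change; stop disagreements are only flagged, never repaired):

* **Shrink** (subject fully matched, query longer): among in-frame
  alternative starts downstream of the current start that do not cut into
  the aligned query span, pick the one whose resulting length is closest
  to the subject length — and only move if that is strictly closer than
  the current length.  Equidistant candidates keep the longer ORF
  (conservative: retain sequence).
* **Extend** (query fully matched, subject longer): search upstream starts
  within $SL - OL$ plus a 10-codon slack (a bounded search keeps the
  operation deterministic and fast).  A candidate is accepted only when
  the extension contains no in-frame stop and its translation is at least
  90% similar to the subject region of equal length immediately upstream
  of the matched span.  The comparison region is that adjacent subject
  region by default (`region = "adjacent"`); comparing against the
  subject's literal prefix is available (`region = "prefix"`) and the two
  coincide in the typical case where the query aligns to the subject's
  suffix.  An accepted extension counts its tail as aligned — that is
  precisely what the similarity gate establishes — so the match span grows
  with the ORF while the identity is carried over unchanged.  The carried
  identity is an approximation (the tail was validated at ≥ 90%
  similarity, not re-aligned), accepted to avoid a second database search
  per extension.

The aligned-span constraint for shrinking is anchored on the coordinates
the ORF had when it was searched (`orig_start`/`orig_end` on the object),
so repeated application is a no-op rather than a slow crawl across
alternative starts.

## Annotation strategy

Candidates are processed from a queue ordered by decreasing nucleotide
length: long ORFs are the most likely genes, and confirming them first
lets their overlaps prune the queue before those ORFs are ever searched.
Entry selection applies, in order: a tolerance band (entries within 2% of
the best accuracy survive), gene acronym, characterized over hypothetical,
higher accuracy, shorter match, input order.  "Hypothetical" is detected
as a product name containing *hypothetical* or *uncharacterized*
case-insensitively — a heuristic over database naming conventions, and the
only place the package interprets free-text product names.

A characterized head with accuracy ≥ 90% cleans its overlaps: blasted
ORFs under 80% accuracy are removed; never-blasted ORFs are truncated to
the first alternative start clearing the overlap when the pair geometry
admits one (same-strand stop ordering, or opposite strands with the other
ORF's stop outside the head), removed when no start exists or the
remainder drops below 60 nt, and otherwise removed when the overlap
exceeds 50% of their length.  Overlaps of 3 nt or less are ignored as
routine stop/start sharing (`min_overlap_nt = 4`) — overlapping stop and
start codons are common in operons and pruning them would be wrong.
Hypothetical or low-accuracy heads clean nothing, so the ORFs they overlap
still get searched later; an ORF resized below the next queue head is
reinserted by its new length and, already carrying its hits, is never
searched twice.

Termination is structural: every iteration either consumes an unsearched
ORF or pops an already-searched one, and reinsertion happens at most once
per ORF.

## Pre-curation filters

Fixed order: low-accuracy filter, overlap filter, intergenic reduction.
The low-accuracy cutoff defaults to 80%.  The overlap filter first tries
to dissolve a pair by swapping one member to an alternative entry (within
the 2% tolerance of its best candidate) whose shorter subject removes the
overlap after re-resize; members are tried one at a time, greedily —
swapping both simultaneously would square the search space for marginal
benefit.  Unresolved pairs fall through ordered removal criteria: an
accuracy difference beyond the tolerance removes the weaker member (the
only reading under which the criterion discriminates at all); otherwise
gene acronym, then characterized status decide; an uncharacterized feature
bridging two others is removed.  A pair no criterion resolves is flagged
`overlap_unresolved` and kept — silently hiding a conflict would defeat
curation.

Intergenic reduction swaps a feature to an alternative entry of equivalent
characteristics — same gene/characterized class and accuracy within the
global 2% tolerance, reusing that knob rather than inventing a second one —
whose longer subject extends the ORF into a flanking gap without creating
any overlap (checked by an exhaustive pair scan) and without dropping the
feature's accuracy below its best candidate minus the tolerance.  Total
intergenic length is therefore non-increasing and the overlap count
unchanged.

## RNA annotation

tRNA and rRNA features are called by plain local alignment of reference
sequences against both strands, gated on identity ≥ 0.9 over ≥ 0.9 of the
reference length; matched regions are masked and the search repeated so
multiple copies are recovered.  Gating on both identity and coverage is
deliberate: either alone admits short spurious matches.  Covariance-model
search (the method real tRNA scanners use) is explicitly out of scope;
with curated reference sets, alignment recovers exact and near-exact
copies, which is the use case here.  RNA features never participate in CDS
overlap cleaning and are appended to the EMBL output.

## Synthetic data generator

`synth_protein_db()` and `synth_genome()` define the validation
conditions: random proteins (uniform residue usage, methionine first),
back-translated with uniform synonymous codons onto random strands,
separated by random spacers of 60–150 nt.  Each gene is sandwiched
between 9 nt stop walls (`TAA` repeats in the gene frame), which pin the
state machine's start choice to the true `ATG`, making ground-truth
coordinates exact.  Spacers are scrubbed by writing in-frame stop codons
into any accidental ≥ 60 nt ORF that touches editable spacer positions;
decoy ORFs overlapping genes in shifted frames are planted only on request
(`overlap_spec`).  `mutation_rate` introduces per-residue nonsynonymous
changes in the genomic copies only, so the expected top-hit identity is
$1 -$ rate — the knob behind the identity-gradient checks.

What the generator does *not* emulate: realistic codon usage or GC
content, operonic gene density, paralogous families, frameshifts,
pseudogenes, or partial homology between database entries.  Passing the
recovery tests therefore demonstrates that the machinery is correct under
unambiguous conditions — exact planted truth, a database containing the
true proteins — not that real-genome accuracy will match; on real data the
quality is bounded by the reference database, as for any homology-transfer
annotator.

Test and validation problem sizes — 30 planted genes against a 40-protein
database for end-to-end recovery, 100 random 2 kb sequences for the
ORF-finder cross-check, 500 engineered fixtures for the resize invariants,
1000 random pairs for the edit-distance check — were chosen as the
smallest sizes at which every code path is exercised repeatedly.

## Known limitations

* Circular contigs are accepted but treated as linear; origin-spanning
  features are not modelled.
* `join()` (multi-exon) locations are rejected on import rather than
  flattened — explicit failure beats corruption for a prokaryotic CDS
  model.  Re-annotation lists and skips them with a warning.
* The extension gate carries identity over the validated tail rather than
  re-aligning, slightly overstating identity for imperfect tails.
* Search is sequential over the database per query; there is no
  concurrency in the provider (a provider-level hook is the intended
  extension point).
* GFF3 and GenBank output are not provided; EMBL is the export format.
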