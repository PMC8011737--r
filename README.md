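# orfannot

Prokaryotic ORF prediction and homology-based annotation in R.

`orfannot` is aimed at people who annotate bacterial and archaeal genomes —
or curate annotations produced elsewhere — and want the whole loop (gene
calling, database transfer, start-site refinement, overlap resolution,
filtering, EMBL export) to run headlessly and reproducibly.  It takes a
genome FASTA and a protein reference database as minimum input, or an
existing EMBL/GenBank feature table for re-annotation, and produces a
curated EMBL file plus a project folder with every similarity hit retained
for later review.

## The method

**ORF prediction.**  A finite state machine scans each contig once per
frame on both strands.  Inside every stop-delimited segment the first start
codon — methionine (`ATG`) or one of the common valine/leucine alternative
initiators (`GTG`, `TTG`, `CTG`) — opens a candidate ORF, which closes at
the next in-frame stop.  ORFs shorter than 60 nt are discarded; an ORF that
opens on a Val/Leu codon is moved to its first in-frame methionine whenever
the Met-to-stop span still reaches 60 nt.

**Scoring.**  Each translated ORF (the *query*, length `OL` in amino acids)
is searched against the reference database with Smith–Waterman local
alignment (BLOSUM62, affine gaps).  Every hit against a subject of length
`SL`, aligned over `ML` columns with identity fraction `ID`, is scored with
the composite accuracy

```
ACC = ID * (ML / SL) * (ML / OL)
```

so that identity is discounted by how much of both subject and query the
alignment actually covers; when query and subject match end to end
(`ML = SL = OL`), `ACC = ID`.  Tails produced by start-site extension are
validated without a second database search using the Levenshtein similarity
`S = (L - D) / L` between two equal-length amino-acid strings (`D` = edit
distance).

**Annotation strategy.**  Candidate ORFs wait in a queue ordered by
decreasing length.  The head is searched, each hit is scored with its
eventual resized ORF length, and the best entry is chosen by ordered
criteria (accuracy within a 2% tolerance band, then gene acronym, then
characterized over hypothetical, then accuracy, then shorter match).  A
characterized head with accuracy ≥ 90% cleans the ORFs overlapping it:
blasted ORFs under 80% accuracy are removed, unblasted ones are truncated
to an alternative start clearing the overlap or removed.  Three
pre-curation passes follow: a low-accuracy filter (default 80%), a
two-step overlap filter (alternative-entry swap, then ordered removal),
and an intergenic-region reduction that swaps equivalent entries with
longer subjects when the extension closes gaps without creating overlaps.
tRNA/rRNA features are annotated by local alignment against reference
sequence sets and appended to the EMBL output.

## Worked example

Everything below runs offline: the synthetic generator plants ground-truthed
genes back-translated from a generated protein database.

```r
library(orfannot)

db <- synth_protein_db(40, seed = 7)          # 40 reference proteins
truth <- synth_genome(db, 30, seed = 3)       # 30 planted genes, one contig
writeLines(c(">ctg1", truth$genome[[1]]$sequence), "genome.fa")
write_protein_db(db, "db.fa")

project <- run_annotate("genome.fa", "db.fa", out_dir = "proj")
report(project)
```

```
Annotation report
  CDS features:        30
  tRNA features:       0
  rRNA features:       0
  with gene acronym:   9
  hypothetical:        4
  mean accuracy:       100.00%
```

All 30 planted genes are recovered at their exact coordinates
(`count_overlaps(project$features)` is `0`), every product is transferred
from the correct database entry, and the mean accuracy of 100.00% reflects
perfect identity and full mutual coverage.  `proj/` now contains
`annotation.embl`, a `config.yaml` snapshot, and one JSON file per ORF
under `orfs/` with the complete hit list.

The same workflow is available from a shell via the thin CLI:

```sh
Rscript inst/cli/orfannot.R annotate genome.fa --db db.fa -o proj
Rscript inst/cli/orfannot.R filter proj --low-acc 0.8 --overlaps --intergenic
Rscript inst/cli/orfannot.R report proj
```

Re-annotation of an existing EMBL or GenBank file uses
`run_reannotate(file, db_path, ...)`: imported CDS keep their coordinates
(start-site resize stays permitted), are re-searched and re-selected, and
CDS absent from the database are retained but flagged `no_hit`.

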