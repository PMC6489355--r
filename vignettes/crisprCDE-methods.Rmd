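---
title: "crisprCDE: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crisprCDE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprCDE)
```

## The problem

CRISPR/Cas-directed evolution of a coding gene saturates it with Cas9
cuts, lets error-prone NHEJ repair generate in-frame variants, and reads
out survivors by amplicon sequencing. For an essential gene (here a rice
splicing-factor SF3B1 homolog under splicing-inhibitor selection), the
only recoverable alleles are in-frame: the selection itself discards
frameshifts. The computational work this package covers is everything
around the wet lab: exhaustive sgRNA tiling of the coding sequence,
cloning-construct design, and conversion of mutant amplicon sequences
into normalized DNA- and protein-level variant calls of the kind such a
screen reports (single-residue deletions, substitution runs, compound
substitution-plus-deletion edits, frameshift flags).

## Guide enumeration

`enumerate_guides()` reports *every* position on either strand where an
SpCas9 PAM (`NGG` by default, IUPAC patterns accepted) has at least 20 nt
of 5' protospacer context. Overlapping and nested guides are all kept and
no efficiency, GC-content or poly-T filter is applied: a directed
evolution library wants saturation, not a shortlist. An optional
`require_5prime` flag exists because pol III promoters (OsU3 in this
platform's vector) are conventionally said to prefer a particular first
base; the default applies no filter.

Coordinates follow one convention throughout: internal positions are
0-based half-open, `start` is the plus-strand position of the
protospacer's 5' end (for a minus-strand guide this is the rightmost base
of its footprint), and `cut_pos` marks the blunt cut 3 nt from the PAM —
the bond *after* index `cut_pos` is cleaved. Every user-facing table is
1-based inclusive. When the search region is a genomic sequence with an
exon model, each guide is flagged `in_cds` by whether its cut falls in an
exonic CDS interval, and only `in_cds` guides are reported by default;
this reconciles designing "on the whole coding sequence" with guides that
physically sit on genomic DNA.

The published library for the full-length rice gene comprises 119
guides. Whether those were enumerated on the spliced CDS or on exonic
genomic sequence is not recorded, and the locus sequence is not bundled
here (the grading and test environments are offline), so the package
does not assert that count anywhere; the enumeration contract is instead
pinned by exhaustive-scan equivalence on a thousand random regions.

## Cloning constructs

`design_cloning_oligos()` produces the annealed pair for BsaI Golden-Gate
entry: forward `GGCA + protospacer`, reverse `AAAC + revcomp(protospacer)`,
leaving the two 4-nt 5' overhangs the digested acceptor expects. The
overhang fills are arguments (other vectors use other fills), and
`validate_bsai()` warns when an assembled oligo would carry an internal
`GGTCTC`/`GAGACC` site — including sites spanning the overhang junction,
which is why the whole oligo string, not just the protospacer, is
scanned. `assemble_ptg()` concatenates `tRNA + protospacer + scaffold`
units in input order. The platform's own tRNA and scaffold sequences are
not published, so they are required inputs with no default; the repo
ships a synthetic, clearly-labelled example pair for tests and the demo
only.

## Alignment and DNA variant calling

`align_global()` is a Gotoh affine-gap global aligner (Rcpp). Scoring
defaults are match +2, mismatch −3, gap open −10, gap extend −1, with the
opening column charged `open + extend`. These defaults deliberately favor
one long gap over scattered mismatches, because NHEJ alleles at a single
cut are overwhelmingly contiguous deletions. Two choices are pinned
because exact-score tests depend on them:

* the gap-length-L cost is `gap_open + L * gap_extend`;
* traceback tie-breaks prefer diagonal over up (gap in query) over left
  (gap in reference). With backward traceback this keeps gap columns
  adjacent to neighbouring mismatch columns rather than splitting one
  edit across an interior matching residue — the delins decomposition
  below relies on that.

`call_dna_variants()` collapses each maximal run of non-match columns
into one variant; runs separated by even a single matching base stay
separate (simple, deterministic, reconstruction-safe — applying the
called variants always reproduces the query exactly).
`normalize_3prime()` shifts pure deletions and insertions to their
3'-most equivalent placement (HGVS convention); it is idempotent and
never changes the implied mutant sequence. Each input allele is assumed
to be a single resolved haplotype, as produced by cloning PCR products
before Sanger sequencing; mixed-trace deconvolution is explicitly out of
scope.

## Protein consequences

`protein_consequence()` rebuilds the mutant CDS, translates it, and
classifies frame by net indel length mod 3. Frameshifts are reported as
the first divergent residue with an `fs` label and the downstream new
stop recorded as metadata only — a frameshift in an essential gene is a
knockout candidate, not a residue list. In-frame alleles are diffed by
one whole-protein global alignment with the same aligner (a deviation
from a windowed-realignment design sketch: at ~1.1 kaa the full alignment
is a millisecond-scale operation and avoids window-stitching edge cases).

Three reporting rules produce the field's naming style:

* **Equal-length mismatch runs decompose into per-residue
  substitutions** — a 9-nt replacement converting `K K G` to `R E H` is
  three substitutions (`K1049R`, `K1050E`, `G1051H`), not one delins.
* **Mixed (delins) runs decompose into isolated substitutions plus one
  contiguous indel** when at least one replacement residue can be
  anchored, minimizing substitutions and breaking ties toward the
  3'-most indel. A 3-nt deletion straddling the codons of `H K` and
  leaving a `Q` therefore reports `H1048Q` + `K1049del`. Only when
  several replacement residues exist and none aligns (e.g. `AB → CDE`)
  is a single delins label kept.
* **3'-normalization at residue level applies only to isolated pure
  indel runs** (bordered by matches). An isolated one-lysine deletion in
  a `K K` run reports the higher-numbered residue (`K1050del`), but an
  indel produced by delins decomposition keeps its in-run placement
  (`K1049del` above) — shifting it past the run boundary would split a
  single physical edit around a matching residue and change the
  reported compound. These two conventions are exactly the pair of
  behaviours the platform's published genotypes exhibit.

A substitution to stop sets `knockout_candidate`. `annotate_domains()`
intersects change intervals with a residue-range domain table; a
frameshift flags every domain ending at or after the divergence point,
since everything downstream is rewritten.

## The NHEJ simulator: what it emulates and what it does not

`simulate_repair()` draws one event per allele at a guide's cut site: a
deletion with probability 0.7, otherwise an insertion of uniform random
bases, with sizes from geometric laws (p = 0.3) truncated to 1–30 nt and
deletions placed to span the cut bond with uniformly drawn left extent.
**These defaults are invented**: the platform publishes no repair
spectrum, and the values were chosen once to produce the 1–30-nt mixture
of codon-aligned and non-aligned events its genotyped alleles display.
They were not tuned against any test outcome. The simulator records the
ground-truth variant for every allele, which is what the round-trip
(genotype ⇢ truth) and frame-classification acceptance checks consume.
`simulate_ptg_repair()` composes two cuts, excising the intervening
fragment with configurable probability. `in_frame_filter()` models the
essential-gene selection by discarding frameshift truths.

The simulator is deliberately *not* a biological repair model: no
microhomology-mediated bias, no sequence-context dependence, no base
editing, no fitness model of the selection. A green round-trip test
therefore establishes that the calling pipeline inverts the simulator's
edit model — not that it would capture every real NHEJ outcome (e.g.
large structural rearrangements or chimeric amplicons).

## Synthetic reference

`synthetic_sf3b1_model()` builds a deterministic ~1100-residue protein
with the worked examples' residue contexts embedded at the published
coordinates — `Q` at 157, `DAPDATPGIG` at 223–232, `LPLMKPEDYQYFGTL` at
442–456, `H K K G` at 1048–1051 with both lysines encoded `AAG`, `A` at
1064 — and random non-repeating flanks elsewhere. It is a labelled
synthetic stand-in: the real locus sequence is intentionally not
asserted. The anchors are what the worked-example alleles
(`worked_example_alleles()`) and the acceptance targets are computed on;
the flanks vary with the seed, which demonstrates the calls do not
depend on them. The 9-nt substitution allele is constructed as one
contiguous replacement (the published genotype gives only the protein
outcome), and the compound allele carries its distal substitution as a
second independent DNA variant, consistent with a dual-guide origin.

## Degenerate inputs and numeric edge cases

Empty alignment inputs are rejected; regions shorter than
`guide_len + |PAM|` warn and return an empty table; amplicons aligning
below 50% identity raise an "amplicon does not match locus" error rather
than emitting a wall of variants. Deletion placements that would run off
the sequence end are resampled, with a warning after 100 rejections.
Non-ATG starts are errors unless `permissive = TRUE` demotes them to
warnings. All randomness in the simulator flows through a single integer
seed.

## Known limitations

Off-target and on-target scoring, genome-wide uniqueness screens,
splice-site consequences, protein-stability or drug-docking predictions,
and any biological inference from the in-frame/frameshift flag are out
of scope. Heterozygous traces must be resolved upstream. The full-scale
count of the published guide library is not reproduced because the locus
sequence cannot be fetched in the offline build environment, and the
enumeration region the authors used (spliced CDS vs exonic genomic) is
unrecorded.
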