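---
title: "Proteogenomic re-annotation with proteoseed: models and methods"
author: "proteoseed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic re-annotation with proteoseed: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated structural annotation of bacterial genomes leaves a
characteristic residue of errors: genes missed entirely (often short or
lineage-specific), coding sequences called on the wrong strand or in the
wrong frame, start codons placed too far upstream (ab-initio callers
favour the longest open frame) or too far downstream, and single-base
sequencing errors that split one real gene across two apparent reading
frames. Shotgun proteomics sees the proteins a cell actually makes, and a
peptide that maps unambiguously onto the genome is hard evidence that the
surrounding frame is coding. proteoseed implements this proteogenomic
refinement loop for bacterial genomes, plus the "ortho" extension that
propagates validated corrections to related genomes through translated
homology.

The package is organised the way the analysis runs:

1. **Six-frame database.** Every maximal inter-stop segment of more than
   forty residues, in all three frames of both strands, becomes a search
   entry (`enumerate_orfs`, `build_search_db`). Replicon ends act as
   virtual stops; an alternate mode requires both bounding stops. A
   restricted second-pass database (`build_restricted_db`) unions the
   ORFs containing annotated CDSs with the ORFs hit in the first pass,
   mirroring the two-pass search strategy used with large six-frame
   databases.
2. **Evidence.** Peptide-spectrum matches arrive as a documented TSV
   (the search-engine stage itself is out of scope). Records are kept at
   rank 1 and identity p-value strictly below 0.005; a reversed-sequence
   decoy database estimates the false-discovery rate. Peptides are
   located in every database entry they occur in and converted to
   genomic coordinates; every placement is verified by re-translation.
   A protein is *validated* by at least two distinct unshared peptides;
   exactly one makes it a *one-hit wonder*.
3. **Refinement.** Validated ORFs absent from the annotation become
   novel-gene calls (no overlap with annotated CDSs), replacements of
   wrong CDSs (overlap only with undetected, homology-free annotations),
   or reported conflicts. One-hit wonders survive only below a stricter
   p-value (3.2e-5) and in isolation, and are promoted by transcription
   evidence. Strictly tryptic peptides upstream of an annotated start
   extend truncated genes; semi-tryptic N-terminal peptides confirm or
   correct start codons; collinear peptide groups in two frames trigger
   an exhaustive single-base edit search for sequencing errors.
4. **Clade extension.** Validated novel proteins are searched against the
   six-frame ORFs of related genomes (hits overlapping annotated CDSs
   are dropped, leaving only unannotated homologous regions), and
   certified N-termini are compared with the annotated starts of their
   homologs to confirm or correct them.

## Coordinate and sequence conventions

Coordinates are 1-based and inclusive throughout; a minus-strand feature
has `start_coord > stop_coord`, so published gene tables can be used
verbatim. Annotated CDS spans include the terminal stop codon, making the
span an exact multiple of three and `coords_to_length()` equal to the
protein length plus one. Translation uses the bacterial genetic code
(table 11); GTG and TTG initiators are rendered as methionine only at
position 1 of an annotated CDS, never inside six-frame entries. Ambiguity
codes translate to `X`, and peptides containing `X` can never match.
Isoleucine and leucine are kept distinct: all sequences derive from the
same database, so the mass ambiguity cannot arise internally.

Because the six-frame translation shows Val/Leu where a GTG/TTG initiator
is retained as Met in the real protein, peptide location includes a
dedicated initiator-Met mode: a semi-tryptic N-terminal peptide starting
with Met that has no exact database match is located by its tail and
anchored one residue upstream, provided the translation there is the
GTG/TTG product. This mirrors the special start-codon searches of engine
pipelines.

## Thresholds and parameters

| parameter | default | role |
|---|---|---|
| `min_orf_aa` | 41 aa | "more than forty residues" database rule |
| `psm_p_max` | 0.005 | identity threshold, strict `<`, rank 1 |
| `min_peptides_validate` | 2 | distinct unshared peptides per protein |
| `one_hit_p_max` | 3.2e-5 | single-peptide credibility (one-hit wonders **and** single-peptide frame-split members) |
| `canonical_starts` | ATG, GTG, TTG | admissible initiators |
| `frame_gap_max_nt` | 600 nt | max gap between frame-split peptide groups |
| `evalue_novel` | 1e-20 | translated-search cutoff, novel-gene propagation |
| `evalue_nterm` | 1e-30 | protein-search cutoff, N-terminus propagation |
| `max_missed` | 1 | trypsin missed cleavages |
| `pep_min_len`, `pep_max_len` | 6, 40 aa | MS-observable peptide window (simulator) |

All values live in `pipeline_config()` and are logged by the file-level
pipeline, so a run's thresholds are auditable.

## Design choices in the classifier

- **Overlap is one shared nucleotide on either strand.** Wrong-CDS cases
  include opposite-strand fakes, so the strictest reading is used, and
  the one-hit isolation rule tolerates zero overlap.
- **`choose_start` picks the nearest upstream canonical codon** covering
  the required residue, not the furthest: the longest-possible-sequence
  bias is precisely the error mode being corrected. When the region
  upstream of the evidence contains more than one canonical codon the
  choice is a declared convention, not an inference — peptides cannot
  distinguish them (a Met-Met N-terminus with an internal ATG is the
  canonical ambiguous case), and the residual exact-start error of the
  recovery benchmark traces entirely to this ambiguity. Homology-guided
  refinement is deliberately left to the clade stage.
- **Met-excision is not gated on the penultimate residue.** Both
  readings of a semi-tryptic N-terminal peptide (intact initiator vs
  excised Met) are evaluated; when both are chemically plausible the one
  consistent with the annotated start wins, which biases ties toward
  confirmation rather than spurious one-codon corrections.
- **Frame-split candidates** are pairs of peptide-bearing ORFs on the
  same strand in different frames, collinear, at most 600 nt apart
  (the real cases sit a few hundred nt apart). Three guards keep random
  matches from pairing healthy loci: shared peptides never count as
  support (the same parsimony rule that excludes them from validation);
  a member supported by a single peptide must pass the one-hit
  threshold; and the search interval must not cross an unrelated
  detected gene. Members that match a detected annotated CDS are never
  candidates.
- **Sequencing-error resolution tries deletions before insertions**
  because the observed error mode is an extra base in the reported
  sequence. A deletion is accepted iff re-translation places every
  supporting peptide in one stop-to-stop ORF. Equivalent deletions are
  collapsed into maximal intervals and extended through their
  homopolymer runs (deleting any base of a run yields a byte-identical
  genome, so the extension is exact). Where several non-equivalent
  intervals reconcile the frames — any gap base whose deletion creates
  no premature stop qualifies, since no peptide observes the junction —
  all are kept, ranked by corrected protein length, as one
  sequencing-error event.
- **Conflicts with detected genes** are attempted to be resolved by
  shortening the detected gene: a new start must still cover all of its
  own peptides and eliminate the overlap; otherwise the conflict stands
  and is reported, never silently dropped.

## The clade stage

The built-in translated search is a seeded Smith-Waterman: exact 3-mer
words (two-hit rule) prefilter candidates, batched affine-gap local
alignment under BLOSUM62 (open 11, extend 1) scores them, and E-values
follow the Karlin-Altschul form `E = K m n exp(-lambda S)` with the
published gapped parameters (K = 0.041, lambda = 0.267). These E-values
are approximate; the package asserts threshold behaviour on planted
homologs, never engine-exact values, and accepts standard 12-column
tabular hit files so real-genome runs can use an external search engine.
A subject start is *confirmed* when the alignment, extrapolated to the
query N-terminus, meets the subject's annotated start (offset 0);
otherwise a canonical codon at the implied position is required for a
*correction* (offsets signed, positive = subject annotated too long), and
a subject with no canonical codon there stays *undecidable* — a homolog
is never force-corrected.

## What the simulator emulates

`simulation_config()` defines a compact survey: one 60 kb replicon, 40
non-overlapping genes on both strands at 60% GC (the organism of interest
is GC-rich), initiator mix ATG 94% / GTG 5% / TTG 1%, protein lengths
90–300 aa, intergenic gaps 80–220 nt. The published (flawed) annotation
plants, per study, four missed genes, three overextended and three
truncated starts, three spurious overlapping CDSs, two single-base
insertions, and two one-hit-wonder genes (one transcribed). Planted
error genes are placed pairwise non-adjacent so the classes stay
separable, mirroring the isolated real loci.

Detection is gene-level and peptide-level Bernoulli (defaults 0.9 and
0.9) with negative-binomial spectral counts; semi-tryptic N-terminal
peptides are emitted for 70% of detected genes, Met-excised 70% of the
time (always for TTG starts). True-match p-values are log-uniform on
[1e-9, 1e-4] and random matches uniform around the identity threshold,
so both the 0.005 and the 3.2e-5 cutoffs are exercised; the decoy table
mirrors the random-match process against reversed sequences.

One modelling decision deserves emphasis: **genes carrying planted errors
always receive the diagnostic evidence that defines their error class**
(two peptides for a missed gene, a 5'-region peptide for a displaced
gene, the N-terminal peptide for a truncated start, a semi-tryptic
N-terminal peptide for an overextended start — planted only on genes
whose protein has an observable one — and flanking peptides at high
confidence around an insertion). This is survivorship by construction:
the real reported error cases are exactly those for which such evidence
was observed. Recovery benchmarks therefore measure the classifier's
logic, not detection luck; they say nothing about sensitivity on genes
whose evidence never made it into a spectrum.

Sister genomes are derived gene by gene at a configured amino-acid
divergence (default 10%, substitutions only — no indels) with resampled
codons, fresh intergenic sequence, 5% gene loss, and subject start errors
planted at 12% (70% overextended). The simulator does not model
retention-time or spectrum physics, post-translational modifications,
operons, mobile elements, paralogy, or real intergenic composition; a
pass on synthetic data shows the inference machinery is correct under the
stated evidence model, not that any particular real genome will yield the
same rates.

## Problem sizes and determinism

Every generator is deterministic given `seed`; the stages derive their
RNG state from fixed offsets of it, and the file-level pipeline caches
the database stage by input digest so a rerun reproduces byte-identical
call tables. The shipped benchmarks use 20 simulated studies of 40 genes
each for error recovery and 20 clade simulations of three subjects each
for the start-correction rate — sizes chosen to keep the full suite
runnable on a laptop in a few minutes while leaving binomial noise well
below the asserted margins.

## Known limitations

- Exact-start recovery is bounded by canonical-codon ambiguity near the
  true start (see `choose_start` above); the published analyses resolved
  such cases by manual homology curation, which is not reproduced.
- The headline counts of the original *R. pomeroyi* survey (validated
  proteins, non-redundant peptides, N-termini, clade corrections) depend
  on the original spectra and the 36 related draft genomes; the package
  reproduces the published coordinate arithmetic and the real-genome
  database/sequencing-error checks when the replicon FASTA files are
  supplied locally, and benchmarks everything else on synthetic ledgers.
- Functional annotation, operon inference and signal-peptide calling are
  out of scope; product descriptions pass through unchanged.
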