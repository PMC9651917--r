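---
title: "Correcting metatranscriptome assemblies with metagenome annotations"
author: "transcriptweld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting metatranscriptome assemblies with metagenome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcriptweld)
```

## The problem

De novo assembly of metatranscriptomic RNA-Seq reads from a microbial
community produces notoriously fragmented output. Coverage depth varies over
orders of magnitude between taxa and between genes, and homologous genes
from related strains collapse or tangle in the assembly graph. The typical
artifacts are: a transcript assembled in several overlapping pieces; a
transcript recovered only partially; both at once; and contigs that run past
the gene into intergenic sequence, sometimes across a whole operon.

When the same sample has also been sequenced at the DNA level, the
metagenomic assembly with its gene annotation is a natural scaffold for
repairing the RNA assembly. `transcriptweld` implements this repair: it takes
assembled transcript contigs, metagenomic contigs, a CDS annotation (GFF3,
in the dialect produced by prokaryotic annotators such as Prokka) and
transcript-to-genome alignments (PAF, e.g. from minimap2 with CIGAR
emission), and reconstructs one full-length transcript per sufficiently
covered coding region.

## The correction procedure

For every annotated coding region the package:

1. **Filters alignments** (`filterAlignments`): alignment blocks shorter
   than `minBlock` (default 100 nt — below a typical read length a block
   adds noise rather than evidence) and secondary alignments (`tp:A:S`) are
   dropped. Secondaries are excluded so that one transcript copy supports
   each locus; `primaryOnly = FALSE` re-admits them for paralog-rich
   communities.
2. **Projects alignments onto the CDS** (`projectToCds`): the alignment's
   target interval is intersected with the CDS interval and mapped back to
   query coordinates. With a `cg` CIGAR tag the mapping is base-accurate
   (positions inside transcript deletions map to zero-length query spans);
   without one, coordinates are interpolated linearly across the block —
   the standard coordinate-only approximation for unspliced prokaryotic
   alignments.
3. **Computes union coverage** (`computeCdsCoverage`) and **selects** CDS
   with at least `threshold` of their bases covered (default 0.5). The
   boundary is inclusive: a CDS at exactly 50% is selected.
4. **Builds a consensus** (`buildConsensus`): walking the CDS in genome
   coordinates, every position covered by transcript evidence takes the base
   of the winning alignment (provenance label `T`), so variants observed in
   the RNA — e.g. true strain variants absent from the assembled genome —
   are preserved over the genomic base. Uncovered positions are filled from
   the genome (label `G`). Minus-strand CDS are reverse complemented into
   coding sense at the end.

Operon splitting and intergenic trimming are emergent rather than special
cases: a contig overlapping *k* coding regions contributes evidence to all
*k* reconstructions (one output each), and since output length is locked to
the annotated CDS length, transcript bases mapping outside every CDS can
never appear in any output.

### Numerical and tie-break choices

* **Overlap winner.** Where several alignments cover one position, the base
  is taken from the alignment with the most matches, ties broken by higher
  mapping quality, then by lexicographically smallest transcript id (ranked
  in the C locale so the result is machine-independent). Applying segments
  worst-to-best and overwriting makes this deterministic regardless of
  input order.
* **Insertions.** A transcript insertion relative to the genome is dropped
  (and counted in `droppedInsertions`): emitting it would break the fixed
  reading frame that "one complete coding region per output" requires. This
  is a deliberate asymmetry — substitutions are preserved, insertions are
  not.
* **Deletions.** A position covered only by a transcript that carries a
  deletion there falls back to the next-best covering transcript's base,
  and to the genome base (label `G`) if none has one. Consequently the
  fraction of `T` labels can be slightly below the coverage fraction
  measured on target bases.
* **Degenerate inputs.** CDS with no alignment appear in `skippedCds` with
  fraction 0 rather than vanishing; zero selected CDS yields an empty but
  well-formed result.

## Unaligned transcripts

Transcripts that align nowhere in the metagenome (dietary mRNA in gut
samples, community members missing from the DNA assembly) are handled by a
separate path: `selectCoding` keeps contigs containing an ORF of at least
`minAa = 100` amino acids (six-frame scan, bacterial code, start codons
ATG/GTG/TTG, 3'-partial ORFs allowed — the conventional long-ORF screen),
and `clusterDedup` removes duplicates by greedy centroid clustering:
corrected transcripts are seeded as centroids, candidates are considered
longest-first and absorbed when they match a centroid at ≥ 95% identity
over ≥ 90% of the shorter sequence (both orientations are tried). The
identity/coverage defaults are our choice of conventional clustering
parameters. Every output record carries a binary `status=aligned|unaligned`
label, and the whole path can be disabled (`orphanEnabled = FALSE`).

## Evaluation metrics

`evaluateAssembly` scores an assembly against a reference transcript set:

* **Capture.** A reference is captured when a *single* alignment covers at
  least 95% of its bases (inclusive); unions of fragments never count, so
  fragmentation is penalised by construction.
* **Truth filter.** For simulated data, only references with TPM ≥ 1
  (inclusive) form the ground-truth set.
* **Misassemblies.** A contig whose split alignment parts hit different
  genomes (`inter_genome`), or the same genome at least 1000 bp apart
  (`intra_gap`, inclusive — the literal reading of "at least 1 kbp"), is
  called misassembled. Split parts overlapping a better part by more than
  90% on the query are collapsed first so supplementary hits are not double
  counted.
* **Completeness histogram.** Capture fractions binned over [0, 1],
  right-inclusive last bin.

For truth-known synthetic data the package derives evaluation alignments
analytically — `truthCdsAlignments` projects the generator's exact contig
placements onto the coding regions, and `exactMatchAlignments` locates
error-free reconstructions by exact substring search — so the evaluation
loop needs no external aligner. For real data, users supply minimap2 PAF.

## Quantification

`countFromAlignments` assigns each read a total weight of 1 split equally
among its best-scoring targets (maximal matches). Fractional multi-mapping
is the default because homologous genes are precisely where metatranscriptome
quantification is hard, and discarding multi-mappers biases whole homolog
families; a `unique` policy is available. `tpmFromCounts` converts counts to
TPM (`rate = count/length`, normalised to 10^6). There is no EM refinement:
ambiguity is spread, not resolved — a documented simplification relative to
likelihood-based quantifiers.

## The synthetic community generator

`generateSyntheticTruth` builds a fully ground-truthed community so that the
whole pipeline is testable without downloads:

* **Genomes and genes.** Uniform i.i.d. random DNA; `nCds` non-overlapping
  framed CDS per genome (start codon, stop-free body, in-frame stop; length
  divisible by 3 in `cdsLenRange`, random strand); optional cross-genome
  homolog pairs by copy-plus-mutate at a stated identity. Defaults (5
  genomes × 50 kb × 20 CDS of 300–1500 nt) are a deliberately desk-scale
  stand-in for communities of 7–32 bacterial genomes; they exercise every
  code path at a size where whole-suite runs take seconds.
* **Abundance and expression.** Genome abundances are log-normal(0, sigma)
  normalised to 1; per-gene expression is log-normal with a configurable
  fraction of silent genes. A gene's effective TPM is expression × species
  abundance, normalised to 10^6 — expression is only observable through the
  lens of how abundant its organism is. Log-normal is our distributional
  choice for "skewed like real communities"; sigma is exposed.
* **Artifacts.** Each expressed CDS draws a class from `mix` (default: the
  four classic artifact classes in equal proportion) and emits contigs with
  exact truth placements (`cg` CIGARs): overlapping fragments, a partial
  piece covering a fraction drawn from `partialRange` (default [0.5,
  0.95]), fragments with an internal gap, the full CDS with 50 bp flanks,
  an operon-spanning contig, a two-genome chimera, or an exact copy.
  Substitution errors can be injected at `errorRate`.
* **Reads.** Error-free fixed-length reads drawn proportionally to
  TPM × available start positions, uniform starts.

One global seed fans out to per-operation seeds (polynomial hash of the
operation name), so each generator is reproducible in isolation and adding
one does not shift the streams of the others.

What the generator does **not** emulate: sequencing errors with realistic
quality profiles, indels, rRNA contamination, GC bias, shared k-mer
structure between unrelated genomes, and real assembler behaviour. Passing
tests therefore demonstrate the correctness of the projection, consensus,
splitting, trimming, evaluation and quantification logic — not that any
particular real assembly will be repaired to the same degree.

## Problem sizes used in the tests

The test suite and the acceptance script run the full loop on 5 genomes ×
20 CDS (~100 genes, ~140 contigs), 1,000 randomised coverage instances, and
50,000 simulated reads — sizes chosen so the complete suite finishes in
about a minute on a single core while still exercising every artifact class
and the multi-mapping path.

## Known limitations

* Transcript evidence extending past the annotated stop codon (UTR-like
  sequence) is trimmed; boundaries are never extended beyond annotation.
* Spliced alignments and split/supplementary alignment chaining are not
  handled (prokaryotic transcripts are assumed unspliced).
* Insertion variants are not transferred into outputs (frame preservation).
* Inter-genome misassembly calls do not distinguish true chimeras from
  shared regions between closely related strains; for strain mixtures the
  call rate is an upper bound.
* The greedy clustering in the orphan path is quadratic in the number of
  centroids; it is intended for the thousands, not millions, of orphans.

## A minimal run

```{r example, eval = FALSE}
truth <- generateSyntheticTruth(seed = 1)
res <- correctAssembly(artifactContigs(truth), genomes(truth),
                       cdsTable(truth), truthPaf(truth))
res

trueTx <- trueCdsSequences(truth)
ev <- evaluateAssembly(correctedTranscripts(res), trueTx,
                       exactMatchAlignments(correctedTranscripts(res),
                                            trueTx))
ev
```
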