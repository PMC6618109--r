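---
title: "Resolving Symbiodiniaceae taxa from intragenomic ITS2 variation"
author: "divProfiler maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving Symbiodiniaceae taxa from intragenomic ITS2 variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The ITS2 region of the rDNA array is the workhorse marker for typing the
dinoflagellate symbionts of reef corals (family Symbiodiniaceae, the former
genus *Symbiodinium*, Clades A--I). The marker is multicopy: a single algal
genome carries hundreds to thousands of rDNA copies whose ITS2 sequences are
not identical. Amplicon sequencing of a coral sample therefore returns a
mixture of two very different signals: **intragenomic** variation (distinct
sequences from one genome's copies) and **intergenomic** variation (distinct
symbiont genotypes co-occurring in the host). Collapsing everything into
97%-similarity OTUs destroys the intragenomic signal -- closely related taxa
that share their most abundant ITS2 sequence become indistinguishable, even
though a single-base difference in that sequence can correspond to >10 My of
divergence.

divProfiler takes the opposite route. It treats the *combination* of
intragenomic sequences as the taxonomic fingerprint: sets of sequences that
re-occur together across samples are interpreted as the variant complement
of a single genotype. Each sequence in such a re-occurring set is a
**defining intragenomic variant (DIV)**, and an ordered set of DIVs with
characteristic relative-abundance ranges is an **ITS2 type profile** -- the
package's taxonomic unit. The central assumption: the probability that a
set of co-occurring sequences derives from one genome grows with the number
of samples in which the set re-occurs, because most hosts are dominated by
one genotype per genus.

## The pipeline

1. **Quality control** (`runSampleQC()`, `loadDataset()`). Paired reads are
   merged on their best ungapped overlap (mismatches resolved toward the
   higher-quality base), screened for ambiguous bases (`maxambig = 0`) and
   homopolymers (`maxhomop = 5`), assigned to a clade by local alignment
   against nine reference sequences (identity and query coverage at least
   80%, both orientations tried), dereplicated, filtered at per-sample
   abundance > 2, primer-trimmed (up to 2 mismatches per primer, IUPAC
   codes honoured, no indels), length-screened to 184--310 bp, and finally
   denoised by a simplified minimum-entropy decomposition (below). The
   result is one `CladeCollection` per sample and clade; a collection is
   **searchable** only when it holds more than 200 sequences, which guards
   the profile search against sequencing-depth artefacts.
2. **Profile discovery** (`runAnalysis()`). Searchable collections are
   reduced to **footprints** -- their sequences at >= 1% relative abundance
   -- and the engine greedily extracts the largest sequence set contained
   in at least `min_support = 3` not-yet-explained footprints. Supporters
   of each accepted set are then re-expanded to *every* collection whose
   footprint contains the set, because a profile is characterised by the
   DIV abundances "in all the samples it was found in"; this expansion is
   what lets a mixed two-genotype sample fall inside both constituent
   profiles' abundance ranges.
3. **Multimodal splitting** (`splitMultimodal()`). If a DIV occurs at two
   distinctly different abundance levels across supporters (e.g. the same
   variant complement at high and at low dosage in two host lineages), the
   supporter set is split by abundance mode, and the same DIV set yields
   two profiles with different ranges.
4. **Assignment** (`assignProfiles()`). A profile matches a collection only
   when every DIV is present *and* inside its characterised range.
   Overlapping matches resolve to the profile carrying the greatest summed
   DIV abundance; several disjoint same-clade profiles are retained only
   when each has been observed as the sole profile of some other sample.
   Unmatched searchable collections conservatively receive a fallback
   profile named after their most abundant sequence.
5. **Genus re-merging** (`mergeGenusOutputs()`). Clade-separated
   assignments are merged with abundances adjusted to the sample's
   pre-separation clade proportions.
6. **Outputs**. Absolute/relative sequence and profile count tables, a
   FASTA of all reported sequences, clade-separated Bray--Curtis and
   weighted-UniFrac distance matrices (samples and profiles) with PCoA
   coordinates, and a 97%-OTU baseline for comparison.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_collection_size` | 200 reads | searchability floor for a clade collection (strict >) |
| `footprint_rel_cutoff` | 0.01 | membership floor for the re-occurring-set search; must sit well below the ~5% abundances informative DIVs can take |
| `min_support` | 3 collections | how many samples make a set "re-occurring" |
| `abund_cutoff` | 2 reads | per-sample abundance filter (strict >) |
| `entropy_threshold` | 0.10 bits | column entropy below which decomposition stops splitting |
| `range_tolerance` | 0 | widening of characterised DIV ranges (strict observed min/max) |
| `otu_cutoff` | 0.03 | baseline OTU dissimilarity cutoff |

All live in a single validated `DivConfig` object (`divConfig()`).

## Numerical choices

* **Read-pair merging** scans every overlap length >= 30 bp, scores
  `matches - mismatches`, and accepts the best overlap only if its score
  reaches 80% of its length; overlap conflicts take the higher-quality
  base, ties the forward base. The method the pipeline standardises in
  place of an external contig maker is deliberately ungapped.
* **Clade screening** is specified as best local alignment (match +1,
  mismatch -1, gap -2) over both orientations of nine references with
  identity >= 80% and query coverage >= 80%. For speed, an 8-mer sharing
  prescreen shortlists the two most promising reference/orientation
  candidates per unique sequence, which are then verified by alignment;
  results are memoised per sequence. The bundled references cover the full
  primered amplicon so that untrimmed contigs meet the coverage threshold.
* **Entropy decomposition** is a simplified, internal stand-in for
  published minimum-entropy methods (the published parameters for this
  marker are not stated, so the decomposition is explicitly configurable
  and not a claimed re-creation): unique sequences are center-star
  aligned, each column's Shannon entropy (bits, count-weighted, gaps
  excluded) is computed, and the set splits recursively on the
  highest-entropy column while entropy exceeds 0.10 bits. Child nodes
  below `max(10 reads, 1% of parent)` merge into the nearest surviving
  node by edit distance. Counts are conserved exactly.
* **Multimodality** uses a Gaussian KDE with Silverman's bandwidth; two
  modes are declared when the deepest valley between the two highest local
  maxima drops below 85% of the lower maximum *and* the modes are at least
  0.05 apart in relative abundance. The separation guard was added because
  multinomial noise at realistic depths (~2000 reads) can produce closely
  spaced spurious density maxima; "distinctly different abundances" is the
  operative phrase being implemented. A split any of whose sides would
  hold fewer than `min_support` supporters is dissolved.
* **Discovery determinism**: candidate sets are drawn from the
  intersection closure of the footprints (any maximal supported set is an
  intersection of its supporters' footprints, so the closure is complete);
  ties break by cardinality, then supporter count, then summed abundance,
  then lexicographically by sorted UID. The unit tests verify equality
  with exhaustive subset enumeration.
* **Alignment**: an internal center-star aligner (pairwise global
  alignments, match +1/mismatch -1/gap -2, merged center-gap profile)
  replaces external aligners; ungapping any row reproduces its input
  exactly. For the few-edit, same-clade sequences this package aligns,
  center-star is effectively exact. p-distances exclude positions in
  either sequence's terminal gap runs (the `countends = F` convention).
* **Trees and UniFrac**: neighbour joining via ape with negative branch
  estimates clamped to zero (deficit moved to the sibling edge); the
  weighted, normalised UniFrac branch sum runs on the NJ tree with branch
  lengths. The seeded 50% majority-rule bootstrap consensus
  (`bootstrapConsensus()`, 100 column-resampling replicates by default) is
  exposed separately because consensus topologies carry no branch lengths.
* **PCoA** is classical metric scaling; axes with non-positive
  eigenvalues are dropped but the eigenvalues are reported.
* **OTU baseline**: count-weighted average linkage (every read
  contributes, mirroring name-file semantics), merging while the minimum
  inter-cluster distance is <= 3%, ties by label order, merge heights
  recorded. Verified against hclust on the read-expanded matrix.
* **Genus re-merging**: per-clade assignment abundances are renormalised
  to sum to one before scaling by the clade's read fraction, so a fully
  assigned sample's merged abundances sum to exactly 1; `normalise =
  FALSE` exposes the raw DIV-count arithmetic instead. The renormalised
  form is what makes the mixed-community bookkeeping close.

## The synthetic world

`makeGenotype()` / `simulateSampleReads()` / `generateStudy()` emulate the
data-generating process the method assumes: a genotype is a base ITS2
sequence with intragenomic variants within 3 substitutions, at fixed,
strongly skewed proportions (geometric decay, ratio 0.55); samples draw
reads multinomially from genotype mixtures; amplicons carry the real
primer sites (so trimming is exercised); paired 250 bp reads overlap (so
merging is exercised); substitution errors occur per base at the stated
rate with reduced quality at error positions (so quality-aware conflict
resolution is exercised deterministically). Genotype bases derive from the
bundled clade reference interiors with substitutions in disjoint position
blocks, which keeps reads clade-assignable and makes the genotypes' DIV
sets provably disjoint. Everything is seed-deterministic at genotype,
sample and study level.

What the simulator does *not* model: chimeras, PCR bias, indel errors,
length polymorphism among variants, or clade-reference mismatch. A green
recovery test therefore establishes that the engine separates intra- from
intergenomic variation under multinomial sampling and substitution noise
-- not that it is robust to every real-world artefact. The bundled clade
references and named-variant catalogue are synthetic stand-ins (marked
`_synthetic` in their file names); canonical names such as "C3" attach to
those stand-in sequences only.

## Known limitations

* Profiles sharing DIVs in one sample are not abundance-partitioned; the
  strongest profile wins (the conservative published behaviour).
* "Super types" -- artefactual profiles merging two taxa's radiations that
  always co-occur -- are flagged (`flagSuperTypes()`, disconnected
  components in the <= 3-edit DIV similarity graph) but never split
  automatically.
* The assumption of one dominant genotype per genus per sample is load
  bearing; free-living/environmental communities violate it and are out
  of scope.
* Local persistence (`persistRun()`/`loadRun()`) replaces the remote
  multi-user database of the original platform; analyses still accrue
  resolving power by re-running over a growing local store.
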