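---
title: "Curating multiplexed venom-gland transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multiplexed venom-gland transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(venomtx)
```

## The problem

Venom-gland transcriptomes are routinely sequenced with several species
multiplexed in one run. Before the toxin repertoire of any one species can
be trusted, three classes of artifact have to be dealt with
computationally:

1. **cross-sample read contamination** ("index hopping"): a small fraction
   of reads carries the wrong sample barcode, so highly expressed toxins of
   one species appear at low level in every co-sequenced library;
2. **chimeric contigs**: de novo assemblers occasionally fuse fragments of
   two transcripts, visible afterwards as a sharp step in read-coverage
   depth at the false junction;
3. **isoform inflation**: clouds of near-identical isoforms and allelic
   variants inflate "unique toxin" counts unless clustered.

venomtx implements this curation as separable, individually tested
components, plus the downstream molecular-evolution analysis (dN/dS) that
such studies typically run on the curated toxin families — in elapid
venoms, the three-finger toxins (3FTx) in particular, which evolve under
strong positive selection. A synthetic-data module generates multiplexed
venom-gland-like data with complete ground truth so every stage can be
scored, not just run.

## Cross-contamination read filter

For a focal sample, every 57-mer of every read is counted in canonical
(strand-folded) form. A focal k-mer is *flagged* against another sample
when its count there is at least 1000-fold its focal count (inclusive);
a read is removed when flagged k-mers cover at least 25% of its bases.
Reads shorter than 75 bp are removed independently. All four thresholds
are configurable; `k = 57` is large enough that a flagged window is
essentially diagnostic of origin, and counting is canonical because
contamination is strand-agnostic.

Two details are worth making explicit:

* **Which k-mers can be flagged.** Only k-mers present in the focal
  spectrum are candidates — an absent k-mer cannot cover any focal read.
  Sequencing-error k-mers in contaminant reads are absent from the donor
  sample and are therefore never flagged; removal relies on the genuine
  donor k-mers a contaminant read carries.
* **The fold ratio is pinned by the contamination rate.** A contaminant
  k-mer's focal count is itself proportional to the donor's coverage times
  the per-donor contamination rate, so the other/focal count ratio
  concentrates around the *reciprocal of the rate*, independent of
  expression level. With two donor samples at a total spiked fraction of
  1%, that ratio is ≈ 200; a 1000-fold rule then flags almost nothing, and
  measured sensitivity on such a spike-in is close to zero while
  specificity is perfect. The rule's operating regime is the index-hopping
  regime (rates of 0.01–0.1%, ratios of 10³–10⁴), which is where the
  threshold combination is coherent. The package's spike-in tests report
  both numbers honestly at the 1% study conditions rather than moving the
  generator or the threshold toward each other, and a property test
  verifies that sensitivity exceeds 90% once the fold threshold is below
  the reciprocal rate.

Multi-sample lanes are handled by taking the union of flagged positions
across all other samples (the conservative reading; a per-sample mode is
provided). Windows containing `N` are skipped in counting and can never be
flagged, but `N` positions count in the denominator of the coverage
fraction.

## ORF discovery and toxin annotation

Complete ORFs (ATG … in-frame stop, no internal stop) of at least 50 sense
codons are enumerated on all six frames; incomplete ORFs are discarded —
completeness is the binding quality rule, replacing any coding-likelihood
model. 50 codons is deliberately small: 3FTx precursors are under 100
amino acids. When several ATGs share a stop codon the longest ORF is
reported (a flag emits all nested starts). Coordinates are 0-based
half-open on the forward strand, whatever the ORF's strand.

Annotation is Smith–Waterman local alignment (BLOSUM62, gap open 11,
extend 1) of each ORF's protein against a labelled reference database
(`refid|FAMILY|taxon` headers). Hits are ranked by score, then percent
identity, then reference id; the best hit meeting both a score and an
identity threshold (defaults 50 and 30%) sets the family, otherwise the
ORF is `unclassified`. Raw score plus identity thresholds replace E-values
on purpose: E-value calibration depends on database size, which is
meaningless for the small curated toxin sets used here.

## Mapping, chimera screen, species assignment

The built-in mapper is seed-and-verify (exact 31-mer seeds, full
verification by mismatch count on both strands, all tied-best placements
reported), substitution-only, adequate for desk-scale synthetic data; SAM
import is provided for real alignments. Multi-mapped reads are assigned
fractionally (1/n to each of n tied placements) so isoform clusters do not
double-count read mass.

The chimera screen compares windowed medians (default 25 nt) of depth on
either side of every interior position; a breakpoint requires a
high/low median ratio of at least 10 with the high side at least 10 deep.
Medians rather than single-base ratios resist Poisson noise. Because a
full-containment mapper cannot cover the final read length at each end of
a reference, depth ramps to zero there; the `margin` parameter (set to the
read length by the pipeline) excludes those flanks from breakpoint calling.
A contig is removed when every sample with informative depth shows a
discontinuity — the conservative reading of "discontinuities across all
species"; a per-sample mode is a configuration switch. Note that a
junction's depth ratio equals the expression ratio of the two fused
transcripts, so chimeras between similarly expressed transcripts are below
any fold threshold by construction; the screen targets the
dominant-by-minor fusions that distort expression tables most. For the
same reason the detection tests plant parents at a 20-fold expression
difference: planting exactly at the 10-fold detection threshold would
measure tie-breaking on sampling noise, not detection.

Species of origin is decided by three indicators, mirroring curation
practice for multiplexed runs of distantly related species: (i) the sample
whose TPM exceeds all others at least 5-fold ("significantly higher
expression" made concrete as a fold rule — at genuine contamination
asymmetries of ~100–1000-fold a statistical test adds nothing); (ii) the
taxon of the best reference hit; (iii) the sample whose coverage is
full-length (≥ 80% of bases) while others are sparse (≤ 50%). A contig is
assigned when at least two non-equivocal indicators agree, and never to a
species without read support; otherwise it is ambiguous.

## Isoform clustering

Greedy incremental clustering with the semantics of the standard tool's
accurate mode: sequences sorted by length (ties by id), each joins the
highest-identity centroid at or above the 99% threshold or founds a new
cluster, clusters finally sorted by member count. Identity is computed
over the shorter sequence (matches divided by the shorter length, the
denominator convention implied by the tool's options), with the shorter
sequence aligned end-to-end inside the longer. Forward strands only, as
the pipeline clusters oriented CDSs. For thresholds ≥ 0.95 a shared-8-mer
prescreen skips alignments that cannot reach the threshold; at ≥ 99%
identity a sequence must retain well over half of its 8-mers, so the 0.5
prescreen cutoff is lossless by a wide margin for the divergences the
tests plant (≤ 1% within families, ≥ 5% between).

## Expression and family summaries

TPM is the plain length-normalized formula
TPM_i = 10⁶ (r_i/ℓ_i) / Σ_j (r_j/ℓ_j) with effective length equal to
contig length — no fragment-length correction, following venom
transcriptomics convention. Counts may be fractional (multi-mapping).
Family summaries report per-family TPM totals, proportions and
unique-contig counts (cluster representatives), and list families above a
1% proportion cutoff. Proportions are over the toxin-annotated rows
supplied to the summary — the "percent of total" convention in venom-gland
reports is percent of toxin expression; passing the unclassified rows in
changes the denominator to the whole transcriptome.

## Selection analysis

Coding sequences are trimmed to the mature protein (the signal/propeptide
codon count is supplied by the user; prediction is out of scope) and
compared by the Nei–Gojobori (1986) counting method: synonymous site
counts are the per-position fractions of synonymous one-step changes
(changes into stop codons count as nonsynonymous, so sites sum to exactly
3 per codon), averaged over the two sequences; multi-position codon
differences average synonymous/nonsynonymous step counts over all minimal
pathways with equal weight, excluding pathways through stop codons.
Proportions are Jukes–Cantor corrected, d = −(3/4)·ln(1 − 4p/3). A
proportion at or above 3/4 is flagged as saturated; dS = 0 leaves ω
undefined rather than erroring, and a saturated dS with dN = 0 yields
ω = 0 (the synonymous distance exceeds any finite value). Gapped or
ambiguous codon columns are dropped pairwise, not listwise, to keep
signal in small clades.

Clade-level ω pools ΣN_diff/ΣN_sites and ΣS_diff/ΣS_sites over all pairs
before correction — pooling counts rather than averaging per-pair ratios
keeps short, weakly diverged pairs from dominating. This counting
estimator deliberately replaces a maximum-likelihood codon-model fit; its
point estimates on real alignments will differ from ML values, which is
why recovery is demonstrated on simulation rather than asserted against
published numbers.

The simulator used for those recovery tests evolves codons along a star
(or supplied) tree under an MG94-flavoured process: single-nucleotide
codon changes at rate 1, × κ for transitions, × ω for nonsynonymous
changes, rate 0 into stops, scaled so branch length is expected
substitutions per codon at the ancestral composition. κ defaults to 1
because the counting estimator assumes no transition bias; recovery runs
use 20 taxa × 100 codons at root-to-tip branch length 0.15 (pairwise ≈ 0.1
substitutions per nucleotide site — moderate divergence typical of
within-clade toxin comparisons, safely below Jukes–Cantor saturation),
10 replicates per regime at ω ∈ {0.2, 1.0, 2.4}, the upper value matching
the strength of positive selection reported for elapid 3FTx clades. At
these settings the estimator's multiple-hit compression is a few percent;
at twice the divergence it grows toward 15% at ω = 2.4, which is why
divergence is kept moderate.

Tree utilities wrap ape (Newick I/O, clade extraction with an explicit
monophyly check that names intruding leaves) and phangorn (midpoint
rooting); midpoint rooting is the presentation-only rooting choice for
toxin trees without a trustworthy outgroup, and the tests verify the two
deepest root-to-leaf distances agree within 10⁻⁹ and bisect the
brute-force tree diameter.

## The synthetic study and what it does (not) show

`synthetic_study()` pins the package's reference conditions: 3 species ×
20 transcripts (family profile 3FTx 0.6, kunitz 0.25, PLA2 0.1, CRiSP
0.05 — a few dominant families, as in real venom glands), 100,000 × 150 nt
reads per sample, 1% substitution error, 1% cross-contamination, contigs
equal to the truth transcripts (assembly is an external hand-off) plus two
planted in-frame chimeras per species fusing a dominant with a minor
transcript at a codon boundary. Family weight enters both repertoire size
and expression (members of dominant families are both more numerous and
more expressed, matching the descending-order-in-both observation for
real venom glands); per-transcript expression is log-normal (σ = 1.5) on
top of the family weight. Quality strings are constant Phred 40 — quality
trimming is out of scope, so quality is cosmetic by design.

What the generator does **not** model, and tests therefore cannot show:
indels and empirical error profiles, PCR duplicates, paired-end inserts,
strandedness, real homology between species' toxins (prototypes are
independent random sequences, so cross-species similarity votes are easier
than in nature), assembly errors other than planted chimeras, and
incomplete transcripts. Passing the end-to-end test demonstrates the
plumbing and the decision rules under known ground truth, not performance
on real libraries.

Ground-truth labels (read provenance, chimera breakpoints) live in
sidecar tables and in-memory fields only; they are never written into the
sequence data the pipeline consumes.

## Numerical and degenerate-input choices

* All thresholds are inclusive (≥) where the workflow's wording is "or
  more" / "or higher".
* TPM of an all-zero count vector is all zeros (no 0/0); a single contig
  gets exactly 10⁶.
* `detect_chimera` on a contig shorter than twice the window returns
  `indeterminate`; a zero low-side median is floored at 0.5 for the
  reported fold change.
* Duplicate CDSs recovered from several contigs are collapsed before
  mapping so that identical catalog entries do not split read weight.
* Annotation tie-breaks are deterministic (score, identity, reference id),
  and greedy clustering breaks length ties by id, so every pipeline stage
  is order-independent and a fixed config + seed reproduces reports
  byte-identically.
* Chimera construction allows `breakpoint = length(a)` with an empty
  suffix (degenerate join equals the first parent); the simulator rejects
  ancestors containing stop codons anywhere.

## Problem sizes used by the test-suite and acceptance runs

Spike-in filtering and the end-to-end run use the full reference study
(3 × ~101k reads); oracle-equivalence checks use 100 reads (k-mers), 1000
random 300-nt contigs (ORFs), 50 random 10-residue peptide pairs
(Smith–Waterman), 200 random placements (coverage) and 100 random
100-codon pairs (NG86); clustering recovery plants 20 families of 3–8
isoforms; the chimera screen is scored on 50 planted chimeras and 50
uniform contigs; dN/dS recovery uses 10 replicates per ω regime; midpoint
rooting is checked on 100 random trees of 5–50 leaves.

## Known limitations

The mapper has no indel support and no quality awareness; the filter holds
all spectra of a lane in memory (fine for tens of millions of distinct
k-mers, not for hundreds); greedy clustering is quadratic in the number of
centroids; NG86 underestimates strong selection as divergence grows and
ignores transition bias and codon frequencies; and the species-assignment
coverage vote is a breadth heuristic, not a mixture model. Each limitation
is deliberate: the components stay small, exactly testable, and faithful
to the curation workflow they encode.
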