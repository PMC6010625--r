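---
title: "Sequence-based Y-STR analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based Y-STR analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrseq)
```

# The problem

Capillary electrophoresis (CE) types a short tandem repeat by fragment
length alone, so a Y-STR allele is a single number of repeat units. Massively
parallel sequencing reads the repeat array base by base and resolves three
extra layers of variation: repeat pattern variation (RPV; isometric alleles
whose block counts differ but sum to the same length), SNPs and indels inside
the array, and SNPs and indels in the flanking DNA. Because Y-STRs are
permanently linked on the male-specific Y, these variants can be read against
a SNP-based phylogeny of the sampled chromosomes: slow-mutating SNPs/indels
(~1e-8 per base per generation) should arise once (monophyletic), while
slippage-driven RPV (~1e-3 per array per generation) recurs (polyphyletic).

`ystrseq` implements that framework for the 23 PowerPlex Y23 (PPY23)
markers: repeat-array decomposition, CE-compatible and sequence-level
nomenclature, depth-aware allele calling, a read-depth-ratio test separating
constitutive duplications from somatic mutants, parsimony-based monophyly
classification, diversity summaries, and a phylogeny-aware simulator used to
validate every stage.

# The locus catalogue

Each locus is a grammar: an ordered list of repeat blocks (motif, legal copy
range, canonical copy number, counted flag), optional fixed spacers (the
42-nt interruption of DYS448, the 48-nt interruption of DYS389II), and
reference flanks. DYS385a and DYS385b share one definition on the b-copy
(forward-strand) convention because the kits cannot separate the two copies;
calls carry an a/b-unresolved flag, so the catalogue holds 22 definitions
covering 23 markers.

The packaged reference *flanking sequences are synthetic*: deterministic
sequences constrained so that no repeat motif of the locus touches the array
boundary and the 10-nt locate anchors are unique, with reference bases
pinned at the offsets of the documented flanking variants (e.g. C at DYS391
+50, A at DYS643 -7, AAA at DYS576 +3..+5). Real GRCh38 flanks can be
substituted via `load_catalog()` without touching code; all packaged
worked examples are self-consistent under the synthetic flanks because
variant calling is purely relative to the catalogue reference. Genomic
coordinates are anchored so that the documented variant positions (e.g.
DYS391 +50C>A at chrY:11,982,182) reproduce.

# Decomposition

`decompose()` locates the array between 10-nt flank anchors, then parses it
greedily left to right with maximal motif extension. On a mismatch it tries,
in order: the next block's motif (or the fixed spacer), a single
period-length *variant unit* differing from the local motif by exactly one
substitution (an internal SNP, written in bracketed style, e.g.
`GAAA[13]GGAA[1]`), and a sub-period *partial unit* (an internal indel
producing an intermediate allele, e.g. `GAAA[15]AA[1]GAAA[2]`, named 17.2).
At most one partial unit is accepted per allele; anything else is an
explicit decomposition error with position and context. Ties between
isometric re-interpretations resolve toward the catalogue's canonical block
order, which is what the greedy order implements.

Two properties are enforced by construction and by tests: the parse is a
pure function of (sequence, catalogue), and re-rendering the units
reproduces the input exactly. Property tests draw random catalogue-legal
block counts for all 22 definitions and check the round trip and the
block-count recovery.

Flank variants are called by ungapped outward comparison from each array
edge. A mismatch is resolved as a substitution if the remainder realigns;
otherwise an indel is sought within a 15-nt band, preferring the indel size
implied by the observed/reference length difference and requiring at least
4 nt of realignment evidence otherwise (this cleanly recovers the 13-bp
flanking insertion case at DYS533). Offsets use the +/- convention
(downstream/upstream), insertions are written `-48.1->SEQ`, deletions
`+3AAA>-`. When a variant falls inside a locate anchor (DYS439 +3A>T,
DYS576 +3 deletion, DYS643 -7A>G), that side's boundary is inferred by
maximal exact motif extension from the located side instead, and the
variant is recovered by the flank scan.

# Nomenclature

The CE-compatible name sums counted blocks plus period-length variant
units. Uncounted blocks — DYS19's `ccta`, DYS385's `AAGG[5-9]`, DYS481's
leading `CTG[0-2]`, DYS390's trailing `taga[1-3]` — are reported in the
designation but excluded from the count; their deviation from the canonical
copy number shifts the name, so compatibility with length-based
nomenclature is exact. One rule covers all four loci:

    name = sum(counted units) + sum(observed - canonical over uncounted blocks)

which yields, e.g., `AAGG[5]GAAA[16]` -> 15, `CTG[0]CTT[28]` -> 27,
`...CAGA[10]TAGA[1]` -> 24, and the DYS19 a+b-1 rule (`TCTA[13]ccta[0]` ->
12) as special cases. Partial units append the `.r` residue. The
length-based name (`length_based_name()`) is computed from array length
alone — it is what CE reports, and what isometric alleles collide on; on
every catalogue-legal allele it equals the structural CE name, which is the
compatibility requirement, and this is property-tested.

The full designation is `CE<name>_<bracketed units>[_<flank descriptors>]`,
with flank descriptors ordered by offset and ASCII signs. `parse_mps_name()`
inverts it by rendering and re-parsing, so parsed designations are always in
canonical form. One deliberate deviation from printed precedent: for the two
designations whose printed CE prefix reflects a CE mobility artefact rather
than array structure (the DYS533 14.1 flanking-insertion allele and the
DYS576 17.1 flanking-deletion allele), `ce_name()` reports the structural
name (11 and 18); the CE-measured values appear in the CE profile instead,
and surface through the concordance report as resolvable discordances.

# Allele calling

Reads for one sample x locus are grouped by identical decomposition; groups
under the analytical threshold (20x) are dropped; the deepest group is the
primary allele. A group whose CE length is one full repeat below a deeper
group sits in the -1 stutter position: at single-copy loci it is never
reported (the stutter-confusion rule), and its reads are re-attributed to
the parent group as the stutter-adjusted depth. At DYS385a,b a true second
allele may legitimately sit one repeat below the first, so there the mask
additionally requires the group to be within a stutter-plausible fraction
(default 1/3) of the deeper group's depth; the top two groups are reported,
doubled when homoallelic. Thresholding is monotone (raising it never adds a
call) and depth is conserved; both are tested.

# Duplication versus somatic mutation

An extra allele at a normally single-copy Y-STR is either a constitutive
duplication (two templates: roughly double read dose) or a somatic mutant in
part of the cells (a single dose split across two sequences). The test
compares stutter-adjusted depths against a similar-amplicon-size reference
locus: donors with single alleles at both loci give an empirical expected
ratio range (Tukey fences clipped to the observed extremes, which resist
depth outliers); the query's two allele ratios are summed. Verdicts:
duplication above the upper fence *and* at least 1.5x the range midpoint
(the guard stops mildly deep single alleles from being called duplications;
how close to double a double dose must be is not prescribed anywhere, so
1.5 is a design choice exposed as a parameter); somatic inside the range;
otherwise
ambiguous. The verdict is scale-invariant and deterministic.

With per-allele depth noise at 15% CV the summed-ratio distributions of the
two classes overlap slightly near the fences, so on a fixed simulated panel
an occasional extra allele is intrinsically ambiguous and can be assigned to
the wrong class even though the class counts are recovered; the tests assert
exact counts and allow isolated swaps, and the noise-free panel must be
recovered perfectly.

# Phylogenetic classification

Variants are binary presence/absence characters on a rooted, possibly
multifurcating sample tree (`ape::phylo`). `count_origins()` computes the
minimum number of state changes with gains and losses both allowed and the
root state free — unit-cost parsimony via dynamic programming over the two
states, which generalizes Fitch counting to polytomies exactly; tests
compare it against brute-force enumeration of all ancestral assignments on
trees of up to 12 leaves and check invariance to re-rooting.
`is_monophyletic()` is exact clade identity (the carriers equal one node's
leaf set); monophyly implies a single origin, not conversely. Variants with
one carrier keep a singleton flag rather than a monophyly claim, since a
single observation cannot distinguish a private variant from an unsampled
clade. Haplogroup association reports the carrier label set and an
exclusivity flag.

Variant records are extracted per distinct flanking variant, per distinct
internal variant/partial unit, and — for loci with at least two variable
blocks — per distinct block-count vector among alleles that belong to
isometric groups (the repeat-pattern variants). Variant units are excluded
from the block-count vector; they are SNP records, not repeat-pattern state.

# The synthetic panel

The simulator's defaults are the reference survey's conditions: 100 samples, 5
duplications, 6 somatic mutants, per-allele depths from a truncated
lognormal (median 1500x, truncation 251-11600x, CV 15%), stutter at 10% of
an allele's reads, 34 distinct branch-placed SNP/indel events, and
block-wise slippage at 0.05 per block per branch. The slippage and event
numbers are modelling choices: branches of a deep genealogy compress many
generations, and the rates are set so that a 100-sample panel carries
sequence diversity of the same order as the reference survey's (a few hundred distinct
alleles, tens of SNP/indel variants), with the five-orders-of-magnitude
process contrast preserved qualitatively by making slippage recurrent and
SNP/indel events unique. Trees are random-coalescent-shape (random pairwise
joins); haplogroup labels cut the tree into 10 clades.

Somatic mutants are injected at +1 repeat (never -1) so the calling rule's
stutter exclusion cannot hide them, with the primary keeping 55-75% of the
dose; duplications are placed at +2 with a full independent dose per allele.
Mutation events are verified recoverable at placement time by rendering and
re-parsing a carrier allele, and every event is recorded in a truth ledger
(branch, carriers, payload), so end-to-end recovery — alleles, variant
carrier sets, duplication/somatic verdicts — is asserted exactly on
noise-free runs.

What the simulator does not emulate: sequencing error beyond stutter,
quality scores, primer artefacts, realistic branch lengths, and
length-dependent slippage rates. Passing recovery tests therefore
demonstrates the correctness of the pipeline's logic under its stated
assumptions, not robustness to raw MiSeq noise — the upstream read
cleaning that real data would need is explicitly out of scope.

# Packaged worked examples

`fixture_designations()` carries the 60 published novel in-phase
designations plus a complementary set of previously reported alleles chosen
so that each locus's distinct length-based and sequence-based allele counts
match the published diversity table (totals 169 and 267, a 58% increase, 60
novel). `fixture_profile()` assigns them to 100 samples (2311 alleles
including 5 duplications and 6 somatic extras) following the published
carrier patterns on `fixture_tree()`: the canonical 7-block DYS635 RPV in
exactly the 15 superhaplogroup-P samples (the reference assembly carries
the P state, so non-P samples carry 5-block-family alleles), DYS389II
CAGA[6] confined to the 14 haplogroup-E samples with CAGA[4] polyphyletic
across T, O, N and sporadic carriers, the DYS391 +50C>A flanking SNP in all
nine B2 samples, CTG[0] DYS481 alleles in a B2b sub-clade, the
CTG[2]+CTT[20] combination confined to G2a, and the DYS393 first-unit SNP
in all four R1a samples. `fixture_ce_profile()` plants the four documented
CE/MPS discordances (one flanking indel, one rs368663163 mobility shift,
two primer-placement differences: 4/2311 = 0.17%).

# Numerical and interface choices

* Problem sizes in the test-suite: the property round-trips run 1000+
  random alleles; simulated panels use 100 samples; the exhaustive
  parsimony oracle runs 500+ random carrier sets on trees of up to 12
  leaves (2^11 ancestral assignments).
* All intermediates are TSV; trees are newick; the catalogue is JSON. Reads
  are accepted as aggregated (sample, locus, sequence, count) tables, which
  is also what the simulator emits; reads are assumed pre-oriented to the
  reporting strand.
* `run_pipeline()` orchestrates decompose -> name -> call -> ratio test ->
  classify -> summarize with a report-only `validate_inputs()`; a thin
  CLI wrapper (`inst/exec/ystrseq`) exposes `simulate`, `validate` and
  `all` subcommands over the same functions.
* Unicode minus signs in printed designations are normalized to ASCII.
* DYS389II is treated as its own full-span definition; subtracting the
  DYS389I span from a combined amplicon is supported in principle by the
  catalogue but not enabled by default, since inputs here are per-locus.

# Known limitations

* The parser accepts exactly one partial unit; two internal indels in one
  array are reported as unparseable rather than guessed.
* Flank variants inside the 10-nt locate anchors are recovered through the
  boundary-inference fallback, which requires the other side's anchor to be
  intact; variants in both anchors simultaneously are not locatable.
* The known-variant catalogue matching is exact-string (with flank-agnostic
  wildcards); fuzzy matching against heterogeneous literature nomenclature
  is out of scope.
* Haplogroup labels are flat strings; nested haplogroup hierarchies are
  expressed through the tree itself rather than a separate ontology.
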