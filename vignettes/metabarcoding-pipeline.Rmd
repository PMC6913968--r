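---
title: "MOTU filtering, taxonomic assignment and morphology comparison for macroinvertebrate metabarcoding"
author: "MetabarComp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOTU filtering, taxonomic assignment and morphology comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetabarComp)
```

## Scope and model

MetabarComp implements the identification side of a DNA-metabarcoding
workflow for freshwater macroinvertebrate bulk samples of the kind collected
under the EU Water Framework Directive (WFD), and the direct comparison of
the resulting DNA-based taxon lists against conventional morphological
assessments. The setting it targets is a monitoring design in which each
sampling location's bulk sample is sorted into six coarse taxon groups --
Annelida (ANNE), Crustacea (CRUS), Heteroptera/Coleoptera (HECO), Mollusca
(MOLL), Trichoptera/Odonata/Ephemeroptera (TOE) and a rest group of mostly
Diptera (REST) -- each extracted and amplified separately (two PCR
replicates), alongside a per-location pool of the six extracts amplified as
one sample. COI amplicons are clustered into molecular operational taxonomic
units (MOTUs) and identified against a curated national reference database
plus a general reference library.

The package covers five concerns:

1. **MOTU-table quality control.** A relative-abundance filter per PCR
   replicate, with the threshold derived from an artificial internal control
   (AIC); replicate-level depth filtering; additive combination of
   replicates.
2. **Taxonomic assignment.** Direct reference hits resolved through an
   ordered rule engine, with a genus-capped lowest-common-ancestor (LCA)
   fallback and dual-database contaminant screening.
3. **Taxonomic backbone.** Register/synonym matching, lineage queries and
   redundancy removal over a fixed rank ladder
   (order, family, genus, species, subspecies).
4. **Concordance analysis.** A six-category classification of the combined
   morphology/DNA taxon lists, overlap fractions, per-group summaries,
   richness statistics and rarefaction.
5. **A synthetic study generator** with complete ground truth, used to
   validate the pipeline end to end.

Upstream read processing (pair merging, primer trimming) and downstream
ecological quality ratio (EQR) scoring are out of scope; for the latter the
package exports presence/absence tables in a register-compatible naming so
external scoring tools can be applied.

## The contamination-derived MOTU threshold

Each PCR plate carries control wells amplifying only a synthetic AIC
construct. Two kinds of cross-contamination are informative: AIC reads
appearing in regular samples, and foreign reads appearing in control wells.
`contaminationThreshold()` returns the smallest relative-abundance cutoff
`t` such that zeroing, within each replicate, every MOTU at relative
abundance `<= t` removes both kinds of carry-over completely; this is simply
the maximum observed offending relative abundance. `filterLowAbundance()`
then applies a threshold per replicate, computing relative abundances
against the replicate total *before* filtering, since the threshold was
derived from raw contamination proportions. The pipeline default threshold
is 0.025% (0.00025), the operational value for this assay family; the
control-derived value is reported alongside and a warning is raised if it
ever exceeds the configured one.

Boundary semantics are literal throughout: *above* 0.025% retained means
strictly above, so a MOTU at exactly the threshold is removed; replicates
with *fewer than* 4,000 reads are discarded, so 4,000 exactly survives; the
read-length window of 313-319 bp is inclusive on both ends. Surviving
replicates of a sample are combined additively (counts summed over the
union of MOTUs, regardless of how many replicates a MOTU occurred in),
which favours taxon recovery over per-replicate reproducibility. Samples
that lose all replicates are recorded as failed and excluded downstream.

## Assignment: direct hits, rules, and the genus-capped LCA

Hits are BLAST-style tabular records (identity, query coverage, bit-score)
against two references: a curated national barcode database
(`wfd_custom`) and a general library (`genbank`) used only for screening.

A MOTU with at least one *direct* hit -- identity strictly above 98% at
100% coverage -- is resolved on the accumulated direct-hit names through
seven ordered rules: (1) names not on the national species register are
dropped; (2) synonyms are resolved to their canonical names; (3) subspecies
are collapsed to species; (4) a genus-level name is dropped when species of
that genus are also among the names; (5) blocklisted names (an explicit,
versioned stand-in for expert curation of known reference-database errors)
are removed; (6) if one species' best identity exceeds every other's by at
least a configurable margin (default 0.5 percentage points) it wins; (7)
otherwise all remaining names are kept as an unresolvable species complex,
written `"A/B"`. If every name is eliminated the MOTU falls through to the
LCA path -- the two paths are mutually exclusive per MOTU.

The LCA path filters hits to identity and coverage of at least 80% and
bit-score strictly above 170, then keeps the *top 5%* band: hits whose
bit-score is at least 95% of the best candidate's. We interpret the
top-percent filter in the MEGAN sense (a band below the best bit-score)
rather than as "the best 5 of 100 retrieved hits"; the band definition is
configurable. The lowest common ancestor of the candidate taxa is computed
on the fixed rank ladder and clipped at genus, so even a single-species
candidate set yields its genus -- species-level claims are reserved for the
direct path. Assignments shallower than order are discarded.

Screening is deliberately simple and register-driven: a MOTU is discarded
as non-target when its best general-library hit outscores its best curated
hit *and* that hit's order is not on the register. This removes, for
example, human or endosymbiont sequences that contaminate public reference
records, without hard-coding any taxon list. When both databases tie, the
curated assignment is preferred and the MOTU kept.

## Redundancy removal and the six categories

Before comparison, both taxon lists are matched to the register
(`matchNames()`: exact, synonym, or trinomial-to-binomial collapse;
unmatched names are flagged and reported, never silently dropped) and made
non-redundant: an entry whose taxon is a strict ancestor of another entry
on the same list is removed. The classical statement of this rule concerns
a genus entry co-occurring with a congeneric species entry; we generalise
it along the whole lineage (a family entry is removed when a contained
genus or species is present), since its purpose is to exclude uncertain or
duplicate identifications. Because the generalisation is a design choice,
`removeRedundant(mode = "genus")` provides the narrow variant, and both can
be compared on any list.

`classifyComparison()` then partitions the combined lists deterministically,
in priority order: exact matches (category 1, *found*; a species complex
containing the morphology species counts); cross-rank lineage matches
(category 2, *identified at a different level*); congeneric species pairs
(category 3, *putative misidentification*), paired alphabetically when a
genus has several unmatched members, with leftovers cascading onward;
morphology-only species absent from the reference database (category 4,
*missing in reference*); remaining morphology-only entries (category 5,
*not found*); and DNA-only entries (category 6, *extra*). Every occurrence
on either list lands in exactly one entry. Overlap fractions group
categories 1-3 as found-by-both and count category 4 towards the
morphology-only fraction; the three fractions sum to one per comparison
unit and are averaged unweighted across units, matching the mean-and-range
reporting style used in this field.

Morphology entries from samples that failed to amplify can only inflate
the morphology-only fraction, so `excludeFailed()` removes them before the
sorted-sample comparisons; the pooled comparison uses the full
morphological list for locations whose pool amplified.

`richnessStats()` reports the Pearson correlation between paired
morphological and DNA richness and *both* ratio conventions -- the mean of
per-sample DNA/morphology ratios and the ratio of means -- because "x times
as many taxa" summaries are ambiguous between the two; published values
computed one way can differ noticeably from the other on the same data.

## Rarefaction

To compare richness at equal sequencing effort, pooled samples are rarefied
to 15,000 reads and sorted samples to 2,500 reads (one sixth, reflecting
that a pool typically merges six group extracts). Rarefaction is a uniform
subsample without replacement (multivariate hypergeometric), delegated to
`vegan::rrarefy()` behind `rarefyCounts()`, and is deterministic under the
supplied seed; samples below the target depth are skipped and reported
rather than extrapolated.

## The synthetic study generator

`simulateStudy()` emulates the monitoring design so that every pipeline
stage can be tested against known truth. Its defaults are the study
conditions: 25 locations, six sorted groups plus a pool per location, two
PCR replicates per sample, and dedicated AIC control replicates.

* **Taxonomy and register.** Per group, a regional species pool (85 ANNE to
  300 REST species) structured into genera, families and orders; a few
  percent of synonym rows, subspecies rows and non-register congeners
  exercise the name-resolution rules.
* **Reference coverage.** Per-group fractions of species with reference
  sequences; defaults 63.5% for annelids and 96.5% for the TOE group (the
  extremes reported for the Dutch WFD list), around 90-95% elsewhere so
  that roughly 93-94% of morphologically recorded species are covered.
  Covered species yield direct hits at 98.6-100% identity; uncovered
  species yield only congeneric (85-95%) or confamilial (80-88%) hits,
  driving genus- or family-level LCA assignments.
* **Read counts.** Per-species reads follow lognormal biomass (sigma 2.0)
  times a per-species amplification factor (sigma 1.5), multinomially
  sampled at a lognormal replicate depth (median 28,000, truncated at
  4,200-70,000). Pools additionally multiply a per-(location, group)
  amplification factor (sigma 2.0, the *dominance* dial), reproducing the
  group-level preferential amplification that lets single taxa dominate
  pooled reads and drives taxon dropout -- the central mechanism separating
  sorted from pooled recovery. These sigmas are set so that pooled samples
  frequently have one group, and often one taxon, above half the reads,
  as observed in the study this design emulates.
* **MOTU structure.** Species split into one or more haplotype MOTUs
  (geometric weights), with a 15% chance of an additional low-abundance
  pseudogene MOTU (1% relative weight) that carries degraded (90-96%)
  self-hits and therefore ends at genus level via the LCA -- mirroring the
  observed excess of read-poor genus-level MOTUs.
* **Noise processes.** AIC carry-over into regular replicates and foreign
  reads into controls, both at relative abundances drawn strictly below
  0.025% (the study's filtering level was chosen to clear exactly this
  kind of contamination); non-target contaminant MOTUs (human,
  endosymbiont, fungal) with strong general-library hits; per-group
  amplification failure (54% for molluscs, 16% annelids, 12% HECO, 4%
  crustaceans and TOE); and morphology noise -- congeneric
  misidentifications (5%), genus-level resolution limits (10%), overlooked
  taxa (15%), occasional synonym or subspecies spellings.

Identity values in hit tables are drawn from the stated bands rather than
simulated from sequences; sequence-level simulation is exercised separately
on the clustering kernel. What the generator deliberately does *not* model:
COI sequence evolution, chimeras, quality scores, or taxon-specific primer
mismatch structure. Passing tests therefore demonstrate the correctness of
the decision logic (filtering, assignment, classification) under the
study's statistical structure, not the behaviour of wet-lab or
alignment-level artefacts on real reads.

`truthEvaluate()` closes the loop: false taxa, per-location species
recovery by origin, whether each injected congeneric swap that survives
filtering surfaces as a putative misidentification (credited within the
swap's genus, since alphabetical pairing may couple partners to other
congeners), the categories received by uncovered species, and the
disposition of spiked contaminant MOTUs.

## Numerical and design choices

* Greedy clustering (`greedyCluster()`) is an abundance-descending,
  first-match centroid algorithm with identity = matches / global-alignment
  length -- a desk-scale analogue of standard OTU pickers, not a
  re-implementation of their heuristics. Alignment uses match/mismatch
  +1/-1 with gap opening 4 and extension 2.
* Dereplication keeps groups with abundance at least 2 and orders by
  abundance with ties broken by first occurrence, so clustering input is
  deterministic.
* The LCA over an empty candidate set, or candidates sharing no order,
  yields no assignment; single-taxon sets are clipped to the rank cap.
  LCA is order-independent and idempotent by construction.
* Ties between the two databases in screening keep the MOTU (curated
  assignment preferred).
* Rule 6 operationalises "matched consistently higher" as a best-identity
  margin because the original decision was expert judgment; the margin is
  configurable and the blocklist of rule 5 is empty by default.
* Comparison units with no entries report `NA` fractions and are excluded
  from averages rather than counted as zero.
* All randomness (simulation and rarefaction) flows from the single
  configured seed; reruns are bit-identical.

## Problem sizes

The default simulated study (25 locations, roughly 150 sorted samples plus
25 pools and controls, around 1,100 MOTUs) runs the full pipeline in a few
seconds. The validation suite uses 5-6 location studies for most
properties, 1,000 random subsets for the LCA oracle, and 20 independent
seeds at the default study size for the sorted-versus-pooled recovery
trend; these sizes give stable results while keeping a full test run in the
low minutes on one CPU.

## Known limitations

* The classifier's alphabetical pairing for surplus congeners is a
  deterministic convention; manual matching could pair differently, though
  category counts are unaffected.
* Assignment treats hit tables as given; BLAST itself, reference-database
  construction and curation are upstream of the package.
* The generator's coverage gaps are sampled per species uniformly within a
  group, whereas real gaps cluster phylogenetically.
* EQR scoring is external; only the presence/absence export is provided.
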