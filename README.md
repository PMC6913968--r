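# MetabarComp

Tools for DNA metabarcoding of freshwater macroinvertebrate bulk samples,
and for comparing the resulting DNA-based taxon lists against conventional
morphological assessments, as practised in Water Framework Directive (WFD)
biomonitoring.

## The problem and who it is for

Monitoring agencies identify macroinvertebrate bulk samples morphologically
— a slow, expertise-bound process with known between-assessor variation.
COI metabarcoding offers an alternative, but complex bulk samples suffer
from uneven biomass, preferential amplification (a single dominant taxon
can swallow most reads of a pooled extract), reference-database gaps and
cross-contamination. A practical mitigation is *taxonomic sorting*: split
each sample into six coarse groups — Annelida (ANNE), Crustacea (CRUS),
Heteroptera/Coleoptera (HECO), Mollusca (MOLL),
Trichoptera/Odonata/Ephemeroptera (TOE), Diptera and the rest (REST) —
and amplify each separately alongside a per-location pool.

MetabarComp implements the identification and comparison machinery for this
design, for bioinformaticians and ecologists who need a tested, seedable
pipeline rather than a collection of ad hoc scripts:

* **MOTU-table QC** — a per-replicate relative-abundance filter whose
  threshold is the maximum cross-contamination observed via an artificial
  internal control (AIC): the smallest `t` such that zeroing MOTUs with
  relative abundance ≤ `t` removes all AIC reads from regular replicates
  and all foreign reads from controls. Replicates with < 4,000 reads are
  discarded; survivors are combined additively.
* **Taxonomic assignment** — direct hits (identity > 98%, coverage 100%)
  resolved through an ordered seven-rule engine (register membership,
  synonyms, subspecies collapse, genus-vs-species, blocklist, consistency
  margin, species complexes); otherwise a lowest-common-ancestor (LCA)
  assignment over hits with identity ≥ 80%, coverage ≥ 80%, bit-score
  > 170, restricted to the top-5%-of-best-bit-score band and capped at
  genus rank. A second reference library screens out non-target MOTUs
  (e.g. human or endosymbiont contamination of reference records).
* **Concordance analysis** — register matching, lineage-wide redundancy
  removal, and a deterministic six-category classification of the combined
  morphology/DNA lists: *found*, *different level*, *putative
  misidentification*, *missing in reference*, *not found*, *extra*.
  Categories 1–3 count as overlap; category 4 counts toward
  morphology-only. Overlap fractions, per-group summaries, richness
  correlations and rarefaction (pools to 15,000 reads, sorted samples to
  2,500) round out the statistics.
* **A synthetic study generator** (`simulateStudy()`) with complete ground
  truth — haplotype splitting, pseudogene MOTUs, coverage gaps, AIC
  carry-over, amplification failures, congeneric misidentifications and
  group-level dominance in the pools — used to validate every stage.

## Worked example

Simulate the default 25-location study and run the full pipeline:

```r
library(MetabarComp)
run <- runPipeline(simConfig(seed = 1))
s <- run$summary
```

With seed 1 this prints (via the summary fields shown):

```
derived contamination threshold: 0.02273%
retained MOTUs: 1014 | failed samples: 18
mean DNA richness: sorted 42.4 vs pooled 29.0 (gain 46.4%)
mean overlap with morphology: sorted 78.1%, pooled 53.5%
within-overlap shares: found 80.7%, different level 15.1%, putative misid 4.2%
richness correlation (morphology vs DNA): sorted r = 0.531, pooled r = 0.106
rarefied sorted/pooled ratios: MOTUs 1.48, taxa 1.41
```

Reading this: cross-contamination measured from the internal controls tops
out just below the 0.025% filtering level, so the filter clears it
completely. Sorting before amplification recovers ~46% more taxa per
location than pooling — the pools lose taxa to group-level preferential
amplification — and agrees better with the morphological lists. Within the
overlapping entries, most are exact species matches; the rest differ in
rank (reference gaps, coarse morphology) or are congeneric pairs flagged
as putative misidentifications. The rarefied ratios show the sorted
advantage is not merely sequencing depth.

Ground truth makes the run auditable:

```r
ev <- truthEvaluate(run)
nrow(ev$false_taxa)        # 0  — no species asserted that is not truly present
ev$screening               # all spiked contaminant MOTUs discarded, no target lost
```

`runPipeline(..., outDir = "out")` additionally writes comparison entries,
per-unit fractions, group summaries, the assignment table, a
presence/absence export for external EQR tools, and a JSON run manifest.

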