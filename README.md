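# wppina

Weighted protein–protein interaction network analysis with experimental
integration.

## What problem this package addresses

Literature-curated protein–protein interaction (PPI) databases are rich
but noisy: the same interaction is reported redundantly across databases,
much of the evidence is unreplicated, and affinity-purification mass
spectrometry (APMS) drags in sticky contaminants. High-throughput
experiments such as protein microarrays have the opposite problem — broad,
hypothesis-free coverage with no independent replication at all. `wppina`
is for systems biologists who want to combine the two: build a
confidence-weighted literature network around a set of *seed* proteins,
call microarray binding hits rigorously, and use each network to vet the
other.

The pipeline was built around the human ROCO protein family (DAPK1,
LRRK1, LRRK2, MASL1/MFHAS1) as seeds, but every constant is configuration
and any seed set works.

## The scoring model

Evidence for each seed–partner pair is aggregated from merged,
deduplicated PSI-MI TAB 2.5 records (deduplication key: unordered pair ×
publication × grouped detection method) after removal of non-protein,
unreviewed and non-human interactors. Three additive components give the
confidence score:

* **MS** (method score): 1 if one grouped detection method supports the
  pair, 2 if several;
* **PS** (publication score): 1 if one publication, 2 if several;
* **CS** (CRAPome score): a contaminant penalty for APMS-derived preys,
  from the fraction *f* of negative-control APMS datasets containing the
  prey — `−1` if *f* > 50 % and APMS is the only evidence; `−0.5` if
  *f* > 50 % with additional non-APMS evidence, or *f* ∈ [30 %, 50 %]
  with APMS-only evidence; `0` otherwise (and always 0 without APMS
  evidence).

`total = MS + PS + CS ∈ [1, 4]`. Pairs must exceed the threshold
(default 2) to enter the literature network, which enforces independent
replication by method and/or publication.

Microarray binding strength is a Z-score — background standard deviations
above the array background — averaged over duplicate spots; hits require
`Z > 3` (strict) and survive subtraction of the GFP negative-control hit
set. Integration classifies proteins present in both networks as
category **i** (same seed in both), **ii** (both networks, different
seeds) or **iii** (sub-threshold literature pairs *rescued* because the
array replicates them: one extra non-APMS method plus one extra
publication lifts the re-scored total over the threshold). Common-core
pairs are then screened for tissue co-expression (both genes ≥ 3 RPKM in
a tissue) and tested for GO biological-process over-representation with
a one-tailed hypergeometric test, Benjamini–Hochberg corrected, grouped
into semantic classes and functional blocks.

## Worked example

No external data is needed — the package generates its own inputs with
planted ground truth:

```r
library(wppina)
generate_fixture(fixture_spec(seed = 1), "demo")
res <- run_pipeline(read_run_config("demo/run.yaml"))
writeLines(res$report)
```

```
## Literature network
- scored pairs: 628; retained at total > 2: 167
- DAPK1: 57 reported, 38 retained (66.7%)
- LRRK1: 85 reported, 14 retained (16.5%)
- LRRK2: 481 reported, 113 retained (23.5%)
- MASL1: 7 reported, 4 retained (57.1%)
- seed-seed dimer edges: 5

## Experimental network
- positives per bait: DAPK1=87, LRRK1=51, LRRK2=78, MASL1=87
- 303 interactions across 226 nodes
- nodes shared by >=2 baits: 23.5%; >=3: 8.4%; all 4: 2.2%

## Common core
- thresholded-literature / array common interactors: 14
- non-thresholded overlap: 48
- rescued sub-threshold pairs: 20
- common-core interactors: 34 (category i: 10, ii: 4, iii: 20)

## Co-expression
- pairs scored: 37 (not found in matrix: 1)
- mean co-expressed tissues per pair: 9.5
- top tissues: reproductive_apparatus=100%, brain=100%, intestine=100%

## Functional enrichment
- significant BP terms: 1
- top block: response to stimulus (best p = 6.28e-13)
```

Reading the output: of the 57 interactions reported for the DAPK1-like
seed, 38 are independently replicated and survive thresholding (66.7 %
retention); the array screen calls 303 positive interactions over 226
distinct proteins, 2.2 % of which bind all four baits; 14 proteins are
cross-supported by the thresholded literature, and 20 sub-threshold
literature pairs are rescued by array replication. The planted enriched
GO term surfaces as the top functional block. Every number equals the
generator's answer key (`demo/answer_key.yaml`), which is computed from
the construction plan, not by the pipeline.

Stage outputs (SIF/GraphML networks, score and rejection tables,
co-expression and enrichment TSVs, `report.md`) land in `demo/results/`.

## Acceptance script

`scripts/acceptance.R` recomputes the confidence-score component
constants from scratch — it builds the stipulated evidence sets through
the package's record aggregation and scores them — and writes the values
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
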