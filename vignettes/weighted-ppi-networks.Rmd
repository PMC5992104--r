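---
title: "Weighted PPI networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted PPI networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic world does and
does not emulate, and the design decisions taken where more than one
reasonable reading existed.

## The literature-evidence model

A *seed* protein is a protein of interest; its interactome is the set of
proteins reported to bind it directly. Literature evidence arrives as
PSI-MI TAB 2.5 records from several source databases. The same
experiment is frequently annotated in more than one database, so records
are deduplicated on the key *(unordered protein pair, publication,
grouped detection method)*. The grouped method — not the raw PSI-MI term
— is part of the key because two terms of the same family (say, two
variants of the two-hybrid assay) are not independent evidence, and the
method score below must not count them twice. Conversely, using the raw
term would merge records that the method score needs to keep apart, and
using the publication alone would silently merge genuinely distinct
evidence from one paper. This is the most conservative key that never
merges distinct evidence.

Before scoring, records pass four pure per-record filters: non-protein
interactors (chemicals, RNA, complexes), partners without a reviewed
annotation (TrEMBL-style automatic entries), non-human interactors
(including orthologs of the seeds themselves), and isoform/transcript
suffixes are collapsed to the canonical parent accession (`P12345-2` is
evidence about `P12345`). Because each filter is a predicate on a single
record, the retained set is independent of filter order, and the
rejection logs plus the retained set partition the input — both
properties are tested.

### Confidence score

Per seed–partner pair, with `M` the set of grouped methods and `P` the
set of publications:

* method score `MS = 1` if `|M| = 1`, else `2`;
* publication score `PS = 1` if `|P| = 1`, else `2`;
* CRAPome score `CS ∈ {0, −0.5, −1}`: a contaminant penalty evaluated on
  the *partner* (the prey — contaminant repositories profile preys of
  APMS runs, not baits), applied only when the pair has APMS evidence.
  With `f` the fraction of negative-control datasets containing the
  partner: `f > 0.5` with APMS-only evidence gives −1; `f > 0.5` with
  additional non-APMS evidence, or `f ∈ [0.3, 0.5]` with APMS-only
  evidence, gives −0.5; everything else gives 0.

Two boundary readings deserve a note. First, the published bracket
descriptions (">50 %", "30–50 %", "<30 %", "<50 %") leave `f = 0.5` and
`f = 0.3` formally ambiguous; we assign both to the closed middle
bracket, the penalty-lighter-than-−1 reading, and test the boundaries
explicitly. Second, the bracket list does not enumerate
`f ∈ [0.3, 0.5]` with mixed (APMS + other) evidence; we score it 0, the
least punitive reading consistent with the listed brackets, since the
non-APMS replication already argues against a pure contaminant.

### Threshold direction

The retention rule as usually printed ("interactions that scored < 2
were retained") contradicts its own stated purpose: a single-method,
single-publication, penalty-free pair scores exactly 2 and is precisely
the *unreplicated* case the threshold exists to remove, while every
replicated pair scores ≥ 3. We therefore retain `total > threshold`
with threshold 2 — the replication-enforcing direction — and expose both
the threshold and its strictness in configuration rather than silently
hard-coding either. The invariant "no retained pair has one method, one
publication and `CS = 0`" is tested.

Retention percentages are reported to one decimal with half-up rounding
(38/57 → 66.7 %), matching the convention of the quantities they
reproduce; R's default banker's rounding would differ on exact halves.

## The microarray model

Binding strength is a Z-score: background standard deviations above the
array background. Each array protein is spotted in duplicate; the
per-spot Z values are averaged (averaging Z of spots, not re-scoring
averaged intensities — identical when background parameters are shared,
but the spot-level form is the stated one and keeps the estimator linear
in the spots). A protein is a hit when its averaged Z strictly exceeds
the threshold (default 3; `Z = 3.0` exactly is not a hit). Hits of a
seed bait that are also hits of the GFP negative-control bait are
removed as non-specific binders — a set subtraction, not a Z difference.

Vendor software normally supplies the background model. To stay
reproducible without proprietary tools, background mean and SD are
explicit per-array inputs, with a fallback robust estimator
(median/MAD over designated background or buffer spots). Whether a real
scan would be backgrounded per array or per print block is a
configuration question, not something this package asserts.

Degenerate inputs: a non-positive background SD is a fatal configuration
error; a bait with no spots is an error; proteins on the array but
absent from the protein dictionary keep their array identifier and
simply cannot cross-reference into the literature network.

## Integration and rescue

Non-seed proteins present in both networks fall into three categories:
(i) same seed supported in both, (ii) both networks but disjoint seed
sets, (iii) sub-threshold literature pairs rescued by the array. Rescue
re-scores a discarded pair after adding one grouped method ("protein
array", non-APMS) and one publication (the present study): a
single-method single-publication pair (total 2) becomes MS 2 + PS 2 = 4,
and even a fully penalized APMS-only pair (total 1) becomes
2 + 2 − 0.5 = 3.5, because the array evidence breaks APMS-only status.
Rescue therefore never demotes — tested as an invariant.

A node can satisfy different categories for different seeds; all
(seed, category) assignments are kept, and summary counts report each
node once under its strongest category, ordered i > iii > ii (direct
same-seed cross-support beats rescued support beats cross-seed support).
Seed–seed dimer edges are reported separately and never counted as
common-core interactors.

## Co-expression screen

A pair is co-expressed in a tissue when both genes reach the RPKM
threshold (default 3, read as ≥ 3 — "a threshold of three" includes
three; strictness is a config knob). This is deliberately a crude joint
threshold: temporal expression, isoforms and subcellular localization
are not modeled, and no correlation statistic is computed. The 13
default tissues are coarse organ groups; the summary always reports the
tissue list used. Per-tissue percentages are over pairs whose genes are
present in the matrix and are reported to the nearest integer; a tissue
in which no seed reaches the threshold necessarily shows 0 %.

## Enrichment

One-tailed over-representation: for a query of `n` proteins from a
universe of `N`, a term annotating `K` with query overlap `k`,
`p = P(X ≥ k)` hypergeometric — equal, by construction, to the one-tailed
Fisher exact test on the 2×2 table. `k = 0` gives `p = 1`. Tests verify
the implementation against exhaustive subset enumeration on small
universes, which is the only fully assumption-free oracle.

Public enrichment portals apply proprietary multiple-testing
corrections; these are not reproduced. Benjamini–Hochberg is the default
and Bonferroni is selectable — the cross-portal robustness such analyses
show in practice justifies tolerance to the correction choice. No
hierarchical parent-term filtering is applied: annotations are taken as
given, and GO DAG propagation, if wanted, belongs offline. Significant
terms are grouped by a curated term → semantic class → functional block
dictionary; the dictionary is an editable input (a small example ships
with the package), not an assertion, and unmatched terms land in an
explicit "unassigned" block.

## The synthetic world

`generate_fixture()` emits every input the pipeline consumes, with an
answer key computed from the construction plan — per-pattern score
constants, planted binder lists, planted tissue counts — never by
calling the pipeline. Its defaults are the stated world the package was
built around:

* per-seed literature interactors 57/38, 85/14, 481/113 and 7/4
  reported/retained, realized by cycling fixed evidence patterns
  (two-methods, two-publications, both, contaminated-but-replicated for
  retained; single-evidence and APMS-only contaminant patterns for
  discarded), with homo-/heterodimer seed–seed edges and shared
  interactors planted among the retained set;
* six source databases with a 0.3 duplicate-annotation rate;
* 400 array proteins standing in for a full 9480-protein array
  (identical logic, smaller index space), background mean 500/SD 50
  (arbitrary fluorescence units), planted binders at Z ≈ 5, sticky
  GFP-binding proteins at Z ≈ 6, non-binders bounded below Z 2;
  per-bait positives 87/51/78/87 arranged so the union is 226 nodes
  with 173/34/14/5 nodes bound by exactly 1/2/3/4 baits;
* a literature/array overlap of 48 proteins of which 14 survive
  literature thresholding (10 same-seed, 4 cross-seed) and 20 are
  rescuable sub-threshold pairs;
* 13 tissues with seeds expressed in 12 (skeletal muscle silent, so its
  co-expression is structurally 0 %), partner tissue counts drawn from
  5–12 with the ten same-seed cross-supported interactors fixed at 12,
  tissues filled in a fixed preference order so per-tissue percentages
  decline monotonically; one common-core protein deliberately absent
  from the matrix to exercise the not-found path;
* one GO term planted to cover ten common-core proteins out of fifteen
  annotated, against ~40 random terms and a universe-wide root term.

Spot intensities are background plus Z × SD with small uniform jitter;
background spots are log-normal (strictly positive fluorescence with a
right tail). Publication identifiers are opaque synthetic tokens.

What a green test on this world establishes: the pipeline's
arithmetic, filtering, thresholding, set operations and bookkeeping are
exact. What it does not establish: robustness to the messiness of real
inputs — malformed MITAB dialects beyond the cases tested, partial
dictionary coverage, arrays with spatially structured background,
expression matrices with missing tissues — nor, of course, any
biological claim about real interactomes, whose membership depends on
database snapshots and raw scans this package does not ship.

## Known limitations

* The method-group map is a flat table, not an ontology traversal; an
  ontology-derived map can be generated offline and dropped in.
* Identifier normalization trusts the supplied dictionary; ambiguous
  one-to-many accession mappings cannot be represented in it and are
  rejected rather than guessed.
* Rescue treats the whole array screen as one publication-equivalent,
  which is the intended reading of "independent replication" but means
  two array hits for the same pair add nothing further.
* Co-expression is binary joint thresholding; it screens for
  plausibility, not for co-regulation.
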