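---
title: "Filtering and analysing eDNA metabarcoding surveys with ednapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering and analysing eDNA metabarcoding surveys with ednapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednapipe)
```

## The problem

Metabarcoding of environmental DNA (eDNA) amplifies a short taxonomically
informative locus (here, a ~106-bp fragment of the vertebrate mitochondrial
12S rRNA gene) from water samples and sequences it in bulk. The raw output is
noisy in specific, well-understood ways: sequencing and PCR errors, tag
jumping between multiplexed samples, reagent- and handling-borne
contamination, misannotation against incomplete reference databases, and
stochastic dropout of rare templates. `ednapipe` implements an auditable
pipeline that carries tagged amplicon reads to a filtered taxon-by-replicate
table, separating true positives from low-confidence and spurious detections
using the survey's own controls, and then computes the community statistics
an ecologist needs to compare habitats and to benchmark eDNA against
conventional visual surveys.

The package is organised around one central object, the `taxon_table`: a
matrix of read counts (taxa x replicates) plus replicate metadata (site,
habitat, distance from shore, and a role — field sample, positive control or
negative control) and per-taxon lineages. Field samples and controls travel
together so that every filtering decision that uses a control is explicit
and reproducible.

## The filtering decision tree

`run_filter_pipeline()` applies four steps in a fixed order after deriving
the low-frequency noise threshold:

1. **Threshold derivation** (`derive_noise_threshold`). Positive controls
   have known composition (mock communities of fish DNA, single-species
   tissue extracts). Any taxon observed in a positive control that is not an
   intended member is spurious by construction; the noise threshold is the
   largest relative abundance such a spurious taxon reaches in any control.
   Clean controls give a threshold of 0.
2. **Low-frequency noise filter** (`apply_noise_filter`). Per field
   replicate, any taxon strictly below the threshold (count / replicate
   total) is zeroed. The boundary is inclusive-keep: a taxon exactly at the
   threshold survives. Denominators are the replicate totals at the time the
   step runs.
3. **Replicate-consistency rule** (`replicate_consistency_filter`). A taxon
   detected at a site in fewer than 2 of that site's 3 filter replicates is
   zeroed across the whole site; one-replicate detections are more likely
   PCR/sequencing artefacts than true rare signal. The rule is applied per
   site; a taxon counts as "removed" in the ledger only when it survives at
   no site.
4. **Negative-control subtraction** (`subtract_negative_controls`). Each
   field count is reduced by the paired negative control's count for that
   taxon, floored at zero. By default negatives are pooled by their
   element-wise maximum — the most conservative reading of "the respective
   negative control" when a one-to-one pairing between field samples and
   blanks is not recorded; an explicit pairing map is accepted via
   `filter_config(control_pairing = ...)`.
5. **Geographic filter** (`geographic_filter`). Detections are checked
   against an occurrence list of genera, families and suborders credibly
   present in the survey region. Genera on the list are kept; genera absent
   from the list whose family is present are *reassigned to the family
   level* (their counts merge into a family row — these are typically
   misannotations among close relatives); everything else is removed as
   exotic. Family- and suborder-level rows are judged at their own rank.

Every step logs reads and taxa removed into a `filter_report`, and the
ledger reconciles exactly: input field reads = output reads + the sum of
per-step removals. Each taxon receives exactly one final classification
(`true_positive_class1` for listed genera, `class2` for listed
family/suborder rows, `class3` for family rows created by reassignment,
`low_confidence_threshold`, `low_confidence_replicate`,
`spurious_negative_control`, `spurious_exotic`, `reassigned_to_family`).

**Order sensitivity is deliberate.** Subtracting negatives before the
replicate rule can change the outcome (a taxon knocked down to one replicate
by subtraction would then be removed entirely); the pipeline fixes the order
above and a property test documents the sensitivity rather than hiding it.

## Upstream: reads to annotated taxa

* **Quality filtering** keeps reads with expected errors
  (sum of per-base `10^(-Q/10)`) at most 0.5 and length at least 154,
  both boundaries inclusive.
* **Demultiplexing** accepts a read only when the same 6-nt sample tag is
  found at both the 5' end and (reverse-complemented) the 3' end, after a
  3-nt pad. Mismatched tag pairs are the signature of tag jumping and
  chimeras and are dropped. `design_tags()` builds tag sets by greedy
  selection over a seeded shuffle of all 4^6 candidates, guaranteeing
  pairwise Hamming distance >= 3 and no homopolymer runs over 3 nt (a
  conservative cap so tags cannot interact with the read-level homopolymer
  filter).
* **Primer trimming** anchors the forward primer at the 5' end and the
  reverse-complemented reverse primer at the 3' end, allowing 2 mismatches
  per primer with IUPAC degeneracy honoured.
* **Homopolymer filter** drops inserts with single-base runs longer than 7.
* **Dereplication** groups identical inserts and removes groups below 2
  total copies (singletons). Output order is abundance-descending with
  lexicographic tie-break, which makes the downstream clustering
  deterministic.
* **OTU clustering** is greedy centroid clustering at >= 99% identity:
  sequences are scanned in abundance order and join the first centroid
  within the radius, else found a new OTU. Identity is matching columns /
  alignment columns of a global alignment with match +1, mismatch −1,
  gap −2. Clustering tools differ in their internal identity definitions
  (gap and terminal-gap handling vary between implementations), so this
  scoring is fixed here as the module's contract and used consistently for
  clustering and reference search.
* **Taxonomy assignment** aligns each centroid against every reference
  (exhaustive search — reference sets at this amplicon size are thousands of
  sequences, so no heuristic seeding is needed), keeps hits with identity
  >= 98% and score >= `min_score` (default 90 on the scoring above: a
  perfect 106-bp match scores 106 and passes; a 90%-identity match scores
  about 84 and fails), retains hits within 2% of the best score (boundary
  inclusive), and assigns the lowest common ancestor of the retained hits'
  taxonomy nodes. OTUs with no hits go to an unassigned side table rather
  than being silently dropped.

## Community statistics

Counts are normalized by median-of-ratios size factors (the reference is the
per-taxon geometric mean over replicates, computed over taxa observed
everywhere; with no such taxon the geometric means fall back to positive
entries, with a warning). Only the size-factor normalization of the
negative-binomial framework is used — the pipeline compares communities, not
per-taxon differential abundance, so no dispersion estimation is needed.

Bray-Curtis dissimilarity, PERMANOVA (via `vegan::adonis2`, sequential sums
of squares, free permutation by default with optional strata, p-values
including the observed statistic so p is never 0), per-taxon Kruskal-Wallis
tests with Bonferroni correction (family = taxa tested in the call),
NMDS (Kruskal stress-1 via `vegan::metaMDS`, 20 random restarts by default,
seed required for reproducibility), UPGMA clustering with newick output, and
per-replicate/per-site richness complete the statistics layer. A direct
Gower-centred sums-of-squares oracle cross-checks the PERMANOVA partition in
the test suite, and R² terms are verified to add to 1 within 1e-9.

## eDNA vs visual surveys

Visual dive surveys record abundance in four log10 categories — single (1),
few (2–10), many (11–100), common (101–1000) — which are encoded numerically
as the medians of their integer ranges: 1, 6, 55.5, 550.5. Detection overlap
is computed rank-aware through the taxonomy (a family-level visual record is
matched by any eDNA genus within that family), with the false-negative rate
defined as the fraction of visually observed taxa missed by eDNA. Spatial
concordance uses a two-sample Kolmogorov-Smirnov statistic on
count-weighted distance-from-shore distributions; because read counts are
not independent observations, effective sample sizes for the asymptotic
p-value are capped at 10 per site (a deliberately conservative choice — the
construction the original analysis used is not described).

## What the synthetic generator emulates

`simulate_study()` generates the statistical structure the analysis assumes,
so every stage is testable without any external download:

* **Layout.** 12 sites in 5 habitat types along a 2.5-km transect, 3 filter
  replicates per site (36 field libraries), 5 positive controls (2 ten-fish
  mock communities, one equimolar and one with linearly increasing input,
  plus 3 single-species tissue controls) and 13 blank negative controls —
  54 tagged libraries in all.
* **Communities.** 22 vertebrate genera (rockfish, greenlings, surfperch,
  flatfish, anchovies, pinnipeds, sea otter, cormorant, ...) with
  habitat-affinity weights; expected site composition is the
  habitat-normalized affinity vector. A per-site lognormal multiplier
  (`microhabitat_sd`, default 0.5) differentiates sites within a habitat
  type, reproducing the observed pattern that between-site differences
  dominate community variance while within-habitat and replicate-level
  fractions stay small.
* **Counts.** Dirichlet-multinomial draws around the site composition
  (`replicate_dispersion`, default 0.005 — filter replicates of a shared
  3-L water sample are highly consistent). Dispersion 0 gives a plain
  multinomial.
* **Contamination.** Per-taxon expected relative abundances with a scope:
  reagent contamination (default: Gallus at 0.02%) hits every library
  including positive controls — which is exactly what makes the noise
  threshold derivable — while handling contamination (default: Homo at 28%
  expected relative abundance, matching the scale of human contamination a
  field survey can carry) hits field samples and blanks but not
  tissue-derived positives. Contaminant reads displace community reads so
  each library sums exactly to the nominal depth before tag jumping.
* **Noise channels.** Spurious annotation relabels reads uniformly onto a
  pool of off-community taxa (some with locally present families, some
  exotic, so both branches of the geographic filter are exercised); tag
  jumping moves reads uniformly to any other library in the run. Both
  conserve the grand total.
* **Depth.** Default 20,000 reads per replicate — a desk-scale choice that
  keeps the full simulate-filter-analyse loop under a couple of seconds
  while leaving the 0.02%-scale threshold resolvable (4 expected reads per
  library).
* **Reads.** `simulate_reads()` emits the exact read-level image of a count
  table (pad + tag + primer + taxon insert + reverse-complemented primer,
  tag, pad) so the full cascade from FASTQ-shaped input can be tested;
  `taxon_reference_sequences()` draws well-separated 106-bp reference
  inserts per taxon.

What it does **not** emulate: chimera formation (the OTU clustering here
does not re-implement chimera detection), base-calling error profiles and
quality-score structure (emitted reads have uniform quality; the
expected-error filter is tested against constructed quality strings
instead), paired-end merging, eDNA transport/degradation between sites, and
amplification bias between taxa. Passing the recovery tests therefore
demonstrates the correctness of the bookkeeping and the filtering logic
under the model's assumptions, not robustness to every artefact of a real
sequencing run.

## A worked run

```{r pipeline}
design <- transect_design()
sim <- simulate_study(design, noise_model(seed = 42),
                      total_reads_per_replicate = 20000)
cfg <- filter_config(default_occurrence_list(),
                     mock_compositions = default_mock_compositions())
res <- run_filter_pipeline(sim$table, cfg)
res$report
```

```{r stats}
vals <- normalize_counts(res$table$counts)
d <- bray_curtis(vals)
meta <- data.frame(habitat = res$table$meta$habitat,
                   site = res$table$meta$site_id,
                   row.names = res$table$meta$replicate_id)
permanova(d, meta, terms = c("habitat", "site"),
          n_permutations = 200, seed = 1)
```

## Numerical and design choices

* Tie-breaking is fixed everywhere as (abundance descending, sequence
  lexicographic); re-running any stage on its own output changes nothing.
* The LCA retention window and the noise threshold comparison are boundary
  inclusive; the noise filter's removal test is strict (`<`).
* All randomness flows from explicit integer seeds; a simulation is
  byte-identical under the same (design, noise model, seed).
* Reads are assumed already merged and in forward orientation;
  reverse-orientation rescue is not attempted.
* Whether the original analysis pooled negatives or paired them per batch is
  not recorded, and whether noise-filter denominators should include reads
  later removed by other steps is likewise open; both choices are exposed in
  `filter_config` (pooled-max pairing and at-time-of-step denominators are
  the defaults).
* PERMANOVA uses sequential (Type I) sums of squares, so term order matters
  and is the caller's statement of the model; strata-restricted permutation
  is available for nested designs.

## Limitations

Occupancy modelling (imperfect detection across replicates) is out of scope,
as is qPCR-style single-species confirmation. The geographic filter is only
as good as its occurrence list: a genuinely present taxon missing from the
regional register will be discarded as exotic. Abundance comparisons are
within-taxon across sites; cross-taxon abundance comparison from read counts
is unreliable because amplification efficiency differs between taxa — the
community-level statistics that unavoidably mix taxa should be interpreted
with that caveat, and the presence/absence variant (`to_presence_absence`)
is provided for exactly that reason.
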