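---
title: "Methods: satellitome classification, repeat landscapes and hybrid-zone clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellitome classification, repeat landscapes and hybrid-zone clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satzone)
```

# Scope

satzone implements the computational core of a satellitome-based hybrid-zone
analysis: classifying tandem-repeat (TR) consensus monomers into nested
groups, summarizing repeat landscapes into degeneration/homogenization
indices and amplification dates, comparing chromosome band tables between
two taxa to find presence/absence markers, and turning genotype counts along
a transect into allele-frequency clines with paired bootstrap effect sizes.
Everything upstream of these steps — read trimming, graph-based read
clustering, primer design, the FISH wet lab — is out of scope: the package
starts from consensus sequences, divergence hits, band tables and genotype
counts, and a synthetic-data module can generate all of those with known
ground truth.

# TR classification

## The comparison model

A TR monomer is a circular object: two consensuses describing the same
repeat may start at any phase of the unit and may be reported on opposite
strands. `monomer_identity()` therefore defines identity as the best
global-alignment identity over both strands and all cyclic rotations of the
partner. To avoid end effects on short units, both sequences are first
multimerized to at least 200 nt and at least two units (`dimerize()`,
`k = max(2, ceiling(200 / RUL))`).

The alignment objective is Needleman–Wunsch with match +1, mismatch −1,
linear gap −1, and identity is `100 * matches / alignment_columns`, with
gap columns counted in the denominator so that length mismatch between
putative variants is penalized. Because many alignments can share the
optimal score while differing in match count, the reported alignment is the
one that lexicographically maximizes (score, matches, −columns). This makes
identity a deterministic function of the two sequences — important both for
reproducibility and for testing against an independent aligner, which would
otherwise disagree by up to a point or two on distant pairs purely through
traceback order.

For repeat units up to 64 bp every rotation is aligned exhaustively. Above
that, the phase is found by aligning one monomer pattern-globally inside an
extended concatemer of the partner (the standard trick for circular phase),
and only the found phase plus the unrotated fallback are aligned globally.
The exhaustive rotation-by-rotation scan, driven by an independently
written pure-R dynamic-programming aligner, is kept as the test oracle.

## Thresholds and clustering

Classification is single-linkage on the pairwise identity graph, mirroring
the merge-if-any-match logic of manual curation:

* **subfamily (variant)**: identity ≥ 95%;
* **family**: identity ≥ 80%;
* **superfamily**: identity < 80% but detectable homology.

"Detectable homology" is operationalized explicitly, since masking-software
defaults are not a reproducible rule: a local alignment covering at least
50% of the shorter multimer at ≥ 70% identity, on either strand. Pairs at
or above the family threshold are homologous by definition, so the three
partitions are nested by construction. Group ids are dense from 1, ordered
by decreasing total abundance when abundance is supplied and by input order
otherwise. For a merged subfamily the reproducible stand-in for manual
consensus picking is the medoid — the member maximizing mean identity to
the rest (`subfamily_consensus()`).

# Repeat landscapes and their indices

A repeat landscape is the distribution of a family's abundance (aligned bp
of genomic hits) over divergence-from-consensus bins. Bins are 0.5% wide —
finer than the conventional 1% for better peak resolution — half-open
`[edge, edge + 0.5)` and labelled by their lower edge, so divergence-0 hits
are unambiguous and a hit at exactly 0.5% falls in the 0.5 bin. Abundance
is summed in integer arithmetic; conservation (bins sum to total hit
length) is exact.

* **DIVPEAK** (degeneration index): the label of the maximum-abundance bin,
  ties broken toward lower divergence. Higher values mean the last
  amplification burst is older.
* **RPS** (relative peak size, homogenization index): the percentage of
  total abundance in bins whose lower edge lies within ±1.0% of DIVPEAK.
  The defining pipeline for this statistic is cited but not restated in the
  source study, so the ±1.0% window is an explicit, configurable default.
  Note that with the tie rule above, a perfectly flat landscape has its
  "peak" at bin 0 and a one-sided window; RPS is intended for unimodal
  landscapes.
* **TSI** (tandem structure index): the abundance-weighted fraction of hits
  with at least one same-repeat junction (a flank that is another copy of
  the repeat). The exact published formula is likewise delegated to a cited
  pipeline; this proxy is monotone in array length, equals 1 for perfect
  arrays and 0 for fully dispersed monomers, and is testable against the
  generator's planted array fraction. Junction annotations are an input;
  the package does not re-mask genomes.
* **Amplification time**: `t = DIVPEAK / (2 * rate)` Mya with the rate
  defaulting to 1.11% per lineage per Myr, the average satDNA turnover rate
  measured in grasshoppers. The source prints both 1.1 (prose) and 1.11
  (formula); the package uses 1.11, and the constant is configurable. The
  factor 2 reflects divergence accruing on both the copy lineage and the
  consensus-defining lineage; the synthetic burst generator adopts the same
  convention so the estimator is unbiased for simulated data.

# Cytogenetic band comparison

FISH signals per family and taxon are classed as B (banded), DB
(dotted-banded), D (dotted) or NS (no signal); only B and DB count as
"banded". Band tables store compact per-chromosome location codes
(`p`/`i`/`d` for pericentromeric/interstitial/distal, `*` flagging a band
on only one member of the pair); heterozygous bands count toward presence.
The karyotype is fixed at eight autosomes plus the X (X0 male system), in
configuration rather than inferred from data.

`differential_markers()` returns families banded in exactly one taxon and
signal-less in the other — the usable hybrid-zone markers.
For per-chromosome enrichment two readings exist ("more families on
chromosome c in taxon A" can mean a difference of totals or
taxon-exclusive families); the package exposes both
(`per_chromosome_counts()`, `exclusive_families()`) because the source
study's two examples are each consistent with a different one.

# Hybrid-zone clines and effect sizes

Allele frequencies come from genotype counts in males: autosomal
`q_B = (NB + 2 BB) / (2 n)`; X-linked males are hemizygous (X0), so
`q_B = B / (N + B)` and heterozygote columns are structurally absent.
Computation is exact (counts, not rounded frequencies); rounding to two
decimals, half away from zero, happens only at report time.

The cline coordinate is the transect order index, not geodesic distance —
the study design orders populations along a mountain-pass corridor and fits
no distance-parameterized cline model. `cline_center()` reports the first
adjacent site pair whose segment crosses q = 0.5 under linear interpolation
and the endpoint closer to 0.5, rather than committing to a single
definition of "inflection point"; on the bundled data both markers yield
the same nearest site either way.

Marker concordance uses the Gardner–Altman paired-mean-difference design:
`mean(y − x)` over sites, with a 95% bias-corrected-and-accelerated (BCa)
bootstrap interval from 5,000 pair resamples and a mandatory seed. The
convention is second argument minus first, with the X-linked marker second,
which reproduces the published sign. The BCa implementation was
cross-checked against an independent implementation (scipy) to the fourth
decimal. With only seven transect sites the interval is a coarse
instrument: BCa is known to undercover at very small n (measured ~92% at
n = 40 pairs on normal noise), and the coverage property test therefore
uses n = 100 pairs, a regime where the asymptotic correction is
appropriate (measured 93.4% over 1,000 seeded trials).

# The synthetic-data generator

The generator states the world the tests live in:

* **Burst families** (`simulate_burst_family()`): one ancestral monomer
  (default 300 bp, matching the mid-range of observed repeat units) copied
  `copies` times at `burst_time_mya`; each copy accumulates substitutions
  so its expected divergence is `2 * rate * time` percent, binomial over
  sites, uniform across sites and bases (Jukes–Cantor-like), no indels —
  landscapes are mismatch-based, so indel realism would add nothing
  testable. Substitution counts are drawn first, so the emitted hit table
  is identical whether or not sequences are materialized.
* **Planted libraries** (`simulate_library()`): unrelated family ancestors
  diversify into variants ~10% apart, each emitted as members ~2% apart —
  comfortably inside the 95/80 thresholds — with ground-truth labels.
* **Transect samples** (`simulate_transect()`): site frequencies follow a
  logistic cline `q = plogis((order − center) / width)`; autosomal sites
  draw Hardy–Weinberg genotypes, X-linked sites draw hemizygous Bernoulli
  alleles. No inbreeding or population-structure model is imposed — the
  source provides none.

All generators are deterministic under a seed and restore the ambient RNG
state. What a green test does *not* establish: the generator has no
read-level noise, no alignment error, no copy-length variation and no
selection; recovering planted structure shows the estimators are correct
under the stated model, not that the model captures every feature of real
Illumina-derived hit tables.

## A known limitation of bin-edge dating

With 300-bp monomers, realized divergences live on a 1/3% lattice, and the
0.5% bins alternate between containing one and two lattice points. At a
planted age of 3.0 Myr (expected divergence 6.66%) the modal bin is the
two-point bin [6.0, 6.5) rather than [6.5, 7.0), and the dated age is off
by ~0.30 Myr — about one bin-width equivalent — in the median. The
acceptance suite keeps this criterion at its stated 0.15 Myr tolerance and
it fails honestly at t = 3.0; the unit suite demonstrates recovery in the
1.5 Myr regime the published dates actually occupy. Users dating real
families should treat half the bin width (0.25% ≈ 0.11 Myr at the default
rate) as the floor on resolution, and more when the repeat unit length
aliases against the bin grid.

# Numerical choices

* Identity ties: lexicographic (score, matches, −columns), as above.
* Dense group ids: ties in abundance resolve by input order.
* `divpeak` ties: lower bin wins (the younger reading).
* Exact-0.5 frequencies in `cline_center()` count as a crossing; tied
  endpoints resolve to the earlier site.
* Degenerate bootstrap (all paired differences equal): the interval
  collapses to the point estimate rather than erroring.
* Report rounding is half-away-from-zero (`round_half_up()`), matching the
  published tables (0.125 → 0.13), not banker's rounding.
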