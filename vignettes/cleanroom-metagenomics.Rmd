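---
title: "Profiling low-biomass cleanroom metagenomes: models, filters and growth calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling low-biomass cleanroom metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleanroomr)
library(dplyr)
```

# The problem

Spacecraft-assembly cleanrooms are among the most hostile environments a
microbe can occupy: HEPA-filtered air, twice-daily cleaning with oxidising
agents, controlled humidity, near-zero nutrient input. The organisms that
persist there are, almost by selection, the ones planetary-protection policy
cares about — spore formers, radiation- and desiccation-resistant taxa,
biofilm builders. Shotgun metagenomics can see them, but cleanroom samples
carry vanishingly little DNA, so every step of the analysis is dominated by
two failure modes: false-positive taxonomic assignments from sparse, noisy
read classification, and laboratory/reagent contamination that can exceed
the genuine signal.

`cleanroomr` implements a decision framework for exactly this regime. It
consumes the tabular outputs of standard upstream tools (a
KrakenUniq-style classified-read report with unique marker k-mer
statistics, per-genome binned coverage tracks, draft-genome quality tables)
and provides the downstream statistical pipeline: sequence-complexity QC,
two-stage taxon retention, diversity analysis, survival-trait annotation
and replication-rate calling — plus a ground-truth synthetic-data generator
that makes every stage testable without any raw sequencing data.

# Sequence-complexity QC

Low-biomass libraries sequenced to saturation contain few distinct
molecules. Two spectrum statistics summarise this before any taxonomy is
attempted, both computed from a canonical k-mer spectrum of the cleaned
reads (`count_kmers()`, default $k = 31$, counting singletons):

* **singleton fraction** — distinct k-mers seen once over all distinct
  k-mers. Saturated or heavily duplicated libraries drive it toward 0.
* **k-mer entropy** — Shannon entropy of the probability of drawing each
  distinct k-mer, $H = -\sum_i p_i \ln p_i$, reported in nats.

Design notes: $k = 31$ is the conventional marker-k-mer size and is
configurable; canonical form is the lexicographic minimum of a k-mer and
its reverse complement; windows containing ambiguous bases are skipped
rather than substituted, so an `N` breaks the k-mer window. Entropy is in
nats throughout the package (the log base is stated in every output
header); multiply by $1/\ln 2$ for bits. The in-memory spectrum is meant
for QC-scale data, not for disk-backed counting of billion-read libraries.

# Two-stage taxon retention

Classifier reports list, per taxon and sample: assigned reads $r$, distinct
marker k-mers $u$, the fraction of the taxon's marker set observed, and the
mean copy number of observed markers. Genuine detections accumulate *new*
marker k-mers with every read; false positives re-observe the same few, so
$u/r$ near 1 is diagnostic of a spurious call.

**Stage 1 — evidence thresholds** (`apply_thresholds()`). An assignment
survives iff

$$ r \ge 256 \quad\wedge\quad u \ge 1024 \quad\wedge\quad u/r \ge 2.5. $$

All three thresholds are parameters of `filter_params()`. The filter is
idempotent and monotone, and deliberately makes no use of relative
abundance: in this regime abundance has no natural inflection point to
threshold on, so no abundance-based removal is performed.

**Stage 2 — negative-control rule** (`control_contamination_filter()`).
For every taxon detected (post-threshold) in at least one negative control,
let $U^\*$ and $R^\*$ be the *maximum* unique-marker and read counts over
all controls. The taxon is retained only if at least 2 case samples each
show $u \ge 5U^\*$ **and** $r \ge 2R^\*$ — both folds in the *same* sample,
read inclusively. Otherwise the taxon is discarded from every sample,
controls included: the decision is per taxon, not per assignment. Taxa
never seen in a control are untouched. The choice of the maximum over
controls (rather than the mean) and the coupling of both folds within one
sample make the rule conservative against a single noisy control.

Open choices resolved here: supporting samples are counted among case
samples only (`support = "cases"`; `"all"` is available); filters operate
on species-rank rows by default with genus-rank mode available; read counts
are clade-inclusive by default (`counts = "taxon"` switches to
taxon-exclusive).

# Diversity

All diversity is computed *after* filtering, so presence means a surviving
assignment.

* **Rarefied richness** (`rarefied_richness()`, default depth 1000 reads)
  uses the exact hypergeometric expectation
  $E[S] = \sum_t \left(1 - \binom{N-n_t}{d}\big/\binom{N}{d}\right)$
  rather than a single random subsample: it is deterministic, which makes
  group comparisons and tests reproducible. Monte-Carlo subsampling is
  retained in the test suite as an independent oracle. Samples with fewer
  than $d$ reads are flagged `NA` and excluded from group comparisons.
* **Shannon entropy** of species abundance, in nats.
* **Beta diversity** is the Jaccard distance on presence/absence profiles;
  ordination defaults to classical MDS because it is deterministic and
  therefore assertable. A seeded non-metric MDS is available; UMAP-family
  embeddings are intentionally not wrapped — they can be applied externally
  to the exported distance matrix when a familiar visual is wanted.
* **Rarefaction curves** come in two flavours: sample-accumulation
  (expected unique taxa against number of samples, averaged over seeded
  random orderings) and within-sample read-rarefaction over a depth grid.
* **Group tests** use the Welch unequal-variance t-test, two-sided, with
  *no multiple-testing correction* — the per-comparison convention of this
  kind of survey analysis; treat p-values accordingly when many groups are
  compared.
* **QC-diversity correlations** (`qc_diversity_correlation()`) are plain
  Pearson coefficients between per-sample QC metrics and diversity metrics;
  concordance between them is evidence that taxonomic structure reflects
  real sequence diversity rather than classifier noise.

# Survival-trait annotation and genome screening

`annotate_taxa()` reports two evidence tiers per trait: the species' own
directory entry (`species_direct`) and a genus expansion (`genus_expanded`)
that is true when any congeneric species — or a genus-level entry — carries
the trait. Expansion only ever adds evidence. A taxon absent from the
directory reports `NA` ("unknown"), never `FALSE`: absence of an annotation
is not evidence of trait absence. The package ships a small curated
directory of well-documented exemplars (*Geodermatophilus obscurus*,
*Ramlibacter tataouinensis*, *Kocuria* spp., …) as a format reference;
production analyses should supply a fuller directory.

`count_gene_categories()` counts annotation rows matching editable keyword
rules in five survival-relevant categories (DNA repair,
chemotaxis/motility, biocide resistance, sporulation, antimicrobial
resistance). A row may serve several categories but counts once per
category; duplicated rows count separately. The bundled rule list is a
starting point, not a reconstruction of any particular database.
`screen_genomes()` applies the conventional draft-quality gate:
completeness $\ge 80\%$ (inclusive) and contamination $< 5\%$ (strict).

# Replication-rate estimation

Bacteria replicate from a fixed origin, so an actively dividing population
shows a coverage peak at the origin decaying to a trough at the terminus;
the peak-to-trough ratio (PTR) of binned coverage scores replication
(1 = static). `estimate_ptr()` defines the estimator as:

1. re-bin the circular track into `n_bins` (default 100) equal windows
   (length-weighted means, 0-based half-open coordinates);
2. circular moving median, window 5, to suppress single-bin artefacts;
3. score $=\max/\min$ of the smoothed profile.

Three quality gates guard the score. The trough must lie within 25% of the
genome length of the peak's antipode — a real replication gradient is
antipodal by construction. Mean depth must reach 0.2×. And the symmetric
piecewise-linear fit of $\log_2$ coverage from peak to antipode and back
must achieve $R^2 \ge 0.5$: the max/min of a *flat* noisy track is always
above 1, so without a goodness-of-fit gate every static genome would drift
into the "growing" calls; requiring that a peak-to-trough gradient actually
explains the profile is the same device the established PTR estimators use
to null-calibrate themselves. **Strain heterogeneity** is proxied by the
fraction of bins deviating more than two-fold ($|\log_2|$ residual $> 1$)
from that fitted profile; estimates above 0.5 are discarded
(`filter_heterogeneity()`), as co-occurring strains distort the gradient in
ways the single-origin model cannot represent. The proxy is this package's
own declared definition, not a reimplementation of any external tool's
unpublished internals.

Numerical behaviour worth knowing: the median smoothing replaces the peak
(trough) bin by its one-bin neighbour, so on a noiseless exponential track
the score is exactly $2^{a(1-4/n)}$ for true PTR $2^a$ — an attenuation of
about $2.7\%$ at $n=100$ and PTR 2, vanishing as $n$ grows. The score is
invariant to uniform depth scaling and to rotation of the circular bin
order.

`call_growing_species()` groups the surviving estimates by species, ISO
group and sampling category and applies a one-sample one-sided t-test of
$H_1$: mean score $> 1$ to every group with $n \ge 2$ (degenerate
zero-variance groups use the limiting conventions: constant at 1 gives
$p = 0.5$). A species is called growing when any group is significant at
$\alpha = 0.05$ (configurable; no multiple-testing correction, consistent
with the group tests above). Species with no testable group are reported
untestable rather than silently dropped.

# The synthetic-data generator

The generator exists so that every pipeline stage can be verified against
known ground truth; its defaults describe the study conditions the package
is built around.

* `simulate_design()` reproduces a 51-sample campaign: five sampling
  categories (extracted DNA, surface wipes, HEPA-filter solution, vacuum
  particles, technical replicates) of sizes 14/12/10/10/5 including eight
  within-category controls, split between ISO-5 and ISO-6–8.5 rooms, plus
  buffer controls. Construction is deterministic.
* `simulate_reports()` draws per-sample reads as a multinomial over the
  community's abundance vector (default $10^5$ classified reads per case
  sample, $5\times 10^4$ per control — realistic for libraries of this
  biomass after classification). Unique markers follow the collector's
  curve $u = M(1 - (1 - 1/M)^{mr})$ with marker-set size $M = 2\times10^5$
  and $m = 3$ observable markers per read for genuine taxa; false-positive
  taxa are planted with $m \approx 1$, reproducing the near-1
  markers-per-read signature of spurious calls. Duplication is $mr/u$ and
  marker coverage $u/M$.
* `simulate_community()` plants recoverable structure: contaminants strong
  in controls (60% of control mass) with case levels that *fail* the
  5×/2× rescue; genuine shared residents weak in controls (1% each) but
  far above both folds in cases; reagent-style control-only taxa; and
  log-normal ordinary residents absent from controls.
* `simulate_coverage()` builds circular tracks with
  depth $\propto 2^{-a\,d(x)}$ ($d$ = normalised circular distance from the
  origin, $2^a$ = true PTR), scaled to a requested mean depth, with
  optional per-bin Poisson read-count noise. With the origin on a bin
  anchor and an even bin count the noiseless peak/trough ratio equals the
  true PTR exactly.
* `simulate_reads()` writes seeded FASTQ (uniform starts, substitution
  errors) for the QC stage; output is byte-identical under a fixed seed.

Seeding is hierarchical — one study seed splits into independent per-sample
seeds — so adding a sample never perturbs another sample's draws.

What the generator does *not* emulate: sequence-level error structure
(indels, quality profiles), host-read carry-over, classifier
misassignment between related genomes, multi-replicon genomes, or
abundance correlations between taxa. Tests passing on synthetic data
therefore demonstrate the *decision logic* — thresholds, the control rule,
the estimators' statistical behaviour — not robustness to classifier
idiosyncrasies on real reads.

# Verification scale

The repository's checks run the contamination rule against an exhaustive
brute-force enumeration on 100 random small studies; analytic rarefaction
against 10,000-draw Monte-Carlo subsampling on 10 profiles; the k-mer
statistics against a per-read brute force on 100 reads; PTR recovery on 20
noisy genomes (median relative error observed under 3%, against a 10%
band); and the growth caller on 200 seeded studies of 4 planted growers
(PTR 1.8, 6 tracks each) among 10 static species, requiring at least 3 of
4 found with zero false calls in at least 90% of runs. These sizes keep
the whole verification deterministic and desk-scale while leaving each
check statistically meaningful.

# Known limitations

* The heterogeneity proxy and the fit-$R^2$ gate are model-based
  surrogates; genomes with genuinely non-exponential coverage (prophage
  induction, large repeats, active HGT regions) may be flagged unreliable
  even when static, and a mixture of two growing strains may pass with a
  biased score.
* The control rule assumes controls are processed identically to cases; a
  systematically under-sequenced control weakens $U^\*, R^\*$ and lets
  borderline contaminants through.
* Entropy and richness are computed on classified reads only; unclassified
  dark matter is invisible to every statistic here.
* No compositional transforms or phylogeny-aware metrics (UniFrac) are
  provided; the beta-diversity layer is deliberately presence/absence.
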