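---
title: "Simulating and analysing unmethylated-CpG enrichment sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing unmethylated-CpG enrichment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umeseq)
```

## The assay and its generative model

Enzymatic unmethylated-CpG enrichment assays profile the *unmethylome*:
the fraction of a genome's CpG sites that carry no cytosine modification.
A CpG-targeting methyltransferase transfers an azide-bearing tag onto
every unmodified CpG it encounters; tagged fragments are click-labelled
with an affinity handle, captured on streptavidin beads, eluted and
sequenced.  The enriched library therefore over-represents DNA in
proportion to its density of unmodified CpGs, and the unbound fraction
holds the methylated and CpG-free remainder.

`umeseq` models this workflow generatively, molecule by molecule:

1. **Fragmentation** (`fragmentize`): uniform fragment starts, truncated
   normal lengths (mean 180 bp, the usual sonication target; SD 20 bp,
   since sonication yields a tight, roughly 10% CV distribution; minimum
   50 bp).  For each fragment the catalog CpGs wholly inside it are
   counted, and each site's molecule-level state is drawn
   Bernoulli($1-\beta$): $\beta$ is a *population* methylation frequency,
   a fragment is a single molecule.  Site states are drawn independently;
   real molecules show co-methylation along a fragment, which this model
   omits (see *Limitations*).
2. **Tagging** (`tag_fragments`): each unmodified site is tagged
   independently with probability $\tau$ (default 0.95, near-complete
   labelling).
3. **Capture** (`enrich`): a fragment with $k>0$ tags binds with
   probability $b(k) = b_{\max}\,(1-(1-p_b)^k)$ and, if bound, elutes
   with probability $r$.  The saturating independent-site curve is the
   simplest form that rises with tag count at low CpG density and then
   plateaus, which is how measured binding behaves.  Untagged fragments
   bind non-specifically with probability $q_{ns}$ and elute with
   probability $r_{ns}$.  Enriched and unbound outputs partition the
   input exactly.
4. **Duplicates** (`add_duplicates`/`dedup`): duplicate records reference
   their source row, so deduplication is an exact inverse.

### Default calibration

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.95 | per-site tagging probability |
| `p_b` | 0.55 | per-tag incremental binding probability |
| `b_max` | 0.95 | binding plateau |
| `r` | 0.90 | elution probability, specific |
| `q_ns` | 0.056 | non-specific binding probability |
| `r_ns` | 0.05 | elution probability, non-specific |
| `dup_rate` | 0.12 | duplicate-read fraction |

The calibration is anchored to three assay-level operating points:
single-site specific capture
$\tau \cdot b(1) \cdot r = 0.95 \times 0.52 \times 0.90 \approx 0.45$
against a non-specific floor $q_{ns} r_{ns} = 0.0028$, i.e. roughly
160-fold single-site specificity; under 5% of non-specifically bound
material eluting (`r_ns` = 0.05 — we keep this physical constraint and
let `q_ns` absorb the remaining calibration freedom); and overall
recovery of tagged multi-CpG fragments in the 60–80% range with ~12%
duplicates.  `capture_probability()` gives the closed-form capture
probability marginalised over tagging and is the independent check used
against the Monte-Carlo workflow in the tests.

## The synthetic genome and methylome

`build_genome` lays out a CpG landscape with four ingredients:

* **background sites** from a homogeneous point process (default spacing
  70 bp — denser than the human genome-wide average, chosen so that
  spontaneous CpG-free runs of ≥ 1 kb are vanishingly rare and the
  background-region class is exactly the designed one);
* **islands**: fixed-length (1 kb) runs of sites every 10 bp.  When the
  island count is not given it is solved from the target island-site
  fraction (default 25%), counting the background sites that fall inside
  islands;
* **guaranteed isolated sites**: carved-in sites whose neighbourhood
  (± 251 bp) is cleared, so the "no other CpG within 250 bp" rule always
  finds at least the requested number;
* **guaranteed CpG-free gaps** of configurable length (default 2 kb,
  minimum 1 kb).

Carved features sit at deterministic, evenly spaced positions with a
fixed jitter so their window-grid offsets are spread uniformly — evenly
spaced centres would otherwise all share one offset modulo the window
width and bias windowed statistics at those sites.

`synth_methylation` assigns $\beta$ per site and condition: islands
unmethylated ($\beta=0$), background methylated (Beta-distributed around
0.85), guaranteed isolated sites exactly 0.  This bimodal default puts
the genome-wide unmethylated-site fraction ($\beta < 0.5$) in the
20–30% band expected of a somatic methylome; the fraction is monotone in
the island-coverage parameter and checked with a warning.  The shape of
the $\beta$ distribution between the two modes is a modelling choice,
not data-derived.

Two refinements matter for the enrichment-fold statistic.  First, sites
within 300 bp of a carved gap ("shores") are fully methylated in every
condition: kb-scale CpG-free regions in somatic genomes sit inside
heavily methylated, CpG-poor territory, and without methylated shores
the background signal is dominated by shoulder coverage from fragments
that straddle a region boundary and carry a partially methylated flank
site, rather than by the assay's non-specific floor.  Second, planted
hypermethylated regions raise island $\beta$ to 0.98, not 0.9: because
binding saturates with tag count, a dense island whose molecules still
carry ~10% unmethylated sites continues to capture efficiently, so only
near-complete methylation silences the signal.

Planted truth — cell-type marker blocks (runs of ≥ 3 adjacent CpGs
unmethylated in exactly one cell type), hypermethylated islands, and
broad PMD-like hypomethylated domains (toy scale 20–50 kb, $\beta$
reduced by 10–30%) — is recorded in `truth_markers`/`truth_dmrs` for
benchmarking.

## Coverage, region classes and enrichment statistics

Fragments are assigned to fixed-width windows by **midpoint** — this
keeps counts additive, so segment counts and window counts partition
identically.  Normalisations: RPGC (counts scaled to genome-wide mean 1)
and RPKM ($10^9 / (\text{window} \times \text{total})$).  Tracks with no
fragments are returned raw and flagged rather than normalised.

The two site classes of the enrichment-fold statistic follow the site
catalog rules exactly: *isolated unmethylated sites* have $\beta \le$
`max_beta` (default 0) and no catalog neighbour within 250 bp on either
side, with a neighbour at exactly 250 bp disqualifying (the conservative,
inclusive reading); *CpG-free regions* are maximal intervals with no CG
dinucleotide, at least 1 kb long, with contig termini included by
default (configurable).  `enrichment_fold` is the ratio of set-level
mean signals and is invariant to track rescaling.  Note that windowed
midpoint coverage dilutes a single-site signal by the fraction of
window-assigned fragments that actually contain the site (about 0.95 at
the default length distribution); the measured end-to-end fold is
therefore expected a little below the idealised per-molecule ratio.

`beta_bin_log2ratio` bins sites by $\beta$ (width 0.1, left-closed, last
bin closed — ten bars) and contrasts enriched against unenriched signal
at site-containing windows.  `saturation_curve` subsamples nested
fractions of the library (shared permutation, so the curve is
non-decreasing by construction) and counts distinct non-empty 100 bp
windows — a proxy for the saturating quantity that avoids restating any
particular library-complexity estimator — interpolating the depth at 90%
of the full-depth value.  `spearman_matrix` computes rank correlations
over all windows (1 kb RPGC tracks are the conventional input) and flags
constant tracks as undefined.

## DMR calling

The differential pipeline follows the segmentation-count-test recipe:

1. **Per-base log2 fold change** of library-size-scaled condition mean
   coverages, $y_i = \log_2\frac{c^A_i + \varepsilon}{c^B_i +
   \varepsilon}$ with $\varepsilon = 1$ on the per-million scale (the
   pseudocount also defines $y = 0$ on empty territory).
2. **Change-point segmentation** by exact penalised least squares:
   boundaries minimise $\sum_s \mathrm{SSE}(s) + \lambda\,(|s|-1)$, via
   PELT (pruned optimal partitioning — identical solution to the full
   dynamic program, verified against exhaustive enumeration in the
   tests; ties broken toward fewer segments).  The default penalty is
   $\lambda = 2\hat\sigma^2 \ell \log(n/\ell)$ with $\hat\sigma$ a
   median-absolute-deviation noise estimate taken at lag $2\ell$ and
   $\ell = 200$ bp the noise correlation length: per-base coverage is
   serially correlated over about one fragment length, so a run of
   $\ell$ bases carries roughly one independent observation and the
   uncorrelated BIC-style penalty ($2\hat\sigma^2\log n$) over-segments
   drastically.  The pipeline searches boundaries on the profile
   aggregated to 20 bp means (PELT's pruning weakens on long flat
   stretches, making exact per-base search on multi-Mb contigs
   impractical); `resolution = 1` restores the exact per-base search.
   Segments shorter than `min_segment_len` (200 bp) are disallowed
   within the search itself.
3. **Per-segment counts** by fragment-midpoint containment (a midpoint
   on a boundary belongs to the right-hand, half-open segment); column
   sums equal each sample's in-territory fragment count.
4. **Negative-binomial Wald test**: median-of-ratios size factors;
   $\log_2\mathrm{FC} = \log_2\frac{\mu_A + 0.5}{\mu_B + 0.5}$ on
   normalised condition means; method-of-moments dispersion
   $\hat\alpha = \max(0, (s^2-\mu)/\mu^2)$ shrunk toward a robust trend
   (the median of $\hat\alpha$ over segments with mean normalised count
   ≥ 10 — a mean would be inflated by the wild moment estimates of
   low-count segments); delta-method standard error with the model
   variance evaluated at the pseudocounted mean, so a zero-count group
   retains a variance floor instead of claiming certainty; two-sided
   normal p.  Segments with all-zero counts, or with mean normalised
   count below 10 (independent filtering — the normal approximation
   needs moderate counts, and near-empty slivers otherwise produce
   confidently wrong calls), are excluded from testing.  This is a
   minimal native pipeline: calibration (type-I error near nominal on a
   Poisson null) and planted-effect recovery are its contracts, not
   numeric parity with any particular count-model package — though its
   fold changes track DESeq2 closely on planted data, which one test
   verifies.
5. **BH adjustment** and thresholding: a DMR needs adjusted p < 0.05 and
   $|\log_2\mathrm{FC}| > 0.58$ (a ~1.5-fold effect floor, $2^{0.58}
   \approx 1.49$).  Direction is defined on the enrichment signal with
   the tumor-like condition in the numerator: lower unmethylated signal
   in tumor ⇒ `hyper`, higher ⇒ `hypo`.  Swapping condition labels maps
   the two calls onto each other exactly.

## Marker scoring and tumor-informed cfDNA scoring

`marker_matrix` counts deduplicated fragments per labelled marker region,
normalises to counts per million, and Z-scores each row with the sample
standard deviation (constant rows map to zero and are flagged).  With
planted cell-type markers, within-type Z exceeds between-type Z in every
type — the block structure of a marker heatmap.

Patient plasma is modelled as a $\beta$-mixture of the healthy and tumor
profiles at a configurable tumor fraction (`mix_profiles`), with plasma
depths reduced relative to tissue to emulate low cfDNA inputs.
`blood_informative_filter` keeps DMRs whose cohort-mean signal ratio in
blood exceeds ±1.5-fold; the ratio-of-cohort-means reading was chosen
over per-patient fold averaging and is exposed through the returned
per-DMR fold.  At a plasma tumor fraction of 0.2 the expected blood fold
of a tissue hypo-DMR sits near the 1.5 threshold, so the filter is
genuinely selective — most tissue DMRs fail it, as they do in practice.
`sample_score` averages a sample's region means over a DMR set
(region-mean-of-means; whether to average over regions or windows was
open, and region means weight each DMR equally), and
`cohort_separation` reports the exact Mann–Whitney statistic, two-sided
p, and the case-control score gap.

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state.  Multi-stage simulations derive named sub-streams
from one master seed (`derive_seed`), so adding a stage never perturbs
earlier stages' draws, and a run is fully determined by its
configuration plus one integer.  `run_config` serialises the whole
parameter set to YAML; reading rejects unknown keys so a misspelled
parameter can never fall back silently to a default.

## Benchmark problem sizes

The standard tumor/normal benchmark pair (`simulate_tumor_normal`) uses
a 2 Mb single-contig genome, 3 + 3 replicates, six planted
hypermethylated islands (~1 kb) and six hypomethylated domains
(20–50 kb, $\beta$ drop 0.3 — sized so the planted signal effect is at
least 2-fold), and 5 × 10^5 input fragments per sample, which yields
roughly 30 sequenced enriched fragments per kb per sample.  The
enrichment-fold benchmark uses a 10 Mb genome with 400 guaranteed
isolated sites, 100 guaranteed 4 kb gaps and a few million fragments —
enough Monte-Carlo resolution that the background mean rests on a few
hundred non-specific reads.  The spike-in experiment uses 10^4 copies
per oligo class against 3 × 10^5 genomic background fragments.

## What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume —
CpG islands, isolated sites, CpG-free gaps, a 20–30% unmethylome,
marker blocks, hyper/hypo differentials, saturating capture, spike-in
classes — but not real sequence composition, repeats, SNPs, chromatin
state, GC amplification bias, sequencing error, or co-methylation of
neighbouring sites on one molecule.  Independence of site states means
partially methylated dense regions capture more efficiently than real
molecules with correlated methylation would; the hyper-DMR default
compensates (see above), but quantitative capture at intermediate
$\beta$ in dense regions is optimistic.  Fragment intervals stand in for
aligned reads, so mappability, MAPQ filtering and alignment artefacts
are outside the model.  Passing the planted-DMR benchmark shows the
statistical machinery recovers effects of the planted kind at the stated
depth; it does not certify performance on real tissue, where dispersion
between biological replicates is larger than the technical-replicate
noise simulated here.
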