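---
title: "Simulating and measuring phosphorothioate optical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring phosphorothioate optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptomap)
```

## The problem

Phosphorothioate (PT) modification replaces a nonbridging oxygen of the DNA
backbone with sulfur at short consensus motifs. Two families exist: Dnd
systems install PT on both strands of a duplex consensus (e.g.
5'-G~PS~AAC-3' / 5'-G~PS~TTC-3'), while Ssp systems install it on one
strand only (e.g. 5'-C~PS~CA-3', whose complement TGG carries no PT).
Unlike methylation-based epigenetics, PT occupancy is partial: only on the
order of 10–15% of genome-wide consensus sites carry PT at population
level, and different molecules of the same genome carry different subsets.
Single-molecule optical mapping makes this heterogeneity directly visible:
modified sites are converted to fluorescent labels, molecules are stretched
by molecular combing, and distances between resolvable spots are measured
in physical units and converted to kilobases.

`ptomap` implements that entire chain as testable code: a forward
simulator from genome sequence to resolvable spots, and the measurement
procedure that turns spot tables back into calibrated spacing statistics
and occupancy estimates. Because every stage is explicit, each claim about
PT spacing and molecule-to-molecule heterogeneity can be exercised on
synthetic data whose ground truth is known.

## Model overview

The pipeline is a composition of small probabilistic stages:

1. **Motif scanning** (`scan_motifs`). All overlapping matches of the
   consensus on both strands. Coordinates are 0-based half-open (BED
   convention); the PT linkage is projected onto the forward strand as
   `start + offset` on `+` sites and `start + length − offset` on `−`
   sites, so a site's labeling coordinate is unambiguous. Windows
   containing N never match, since assembly gaps carry no evidence of a
   motif. For bistranded motifs each match is one duplex locus; a
   palindromic recognition (e.g. GGCC) is reported once per locus.

2. **Molecule sampling** (`sample_molecules`). Either identical full-length
   molecules of a linear genome (the design used with the 48,502 bp phage
   lambda standard, whose left terminus makes a molecule eligible for the
   orientation end label) or random fragments with lognormal lengths,
   uniform starts and truncation at the contig end (extracted genomic
   DNA).

3. **Occupancy** (`place_modifications`). Default is i.i.d. Bernoulli
   occupancy at fraction `f = 0.12`, the middle of the reported 10–15%
   population range. A first-order Markov "clustered" mode with
   persistence `rho` (transitions `P(mod|mod) = rho + (1−rho)f`,
   `P(mod|unmod) = (1−rho)f`) keeps the stationary occupancy at `f` while
   adding spatial correlation; `rho = 0` reduces exactly to the i.i.d.
   model under common random numbers. Duplex sites are modified
   all-or-none with a single draw, since hemi-modified bistranded sites
   have not been described. Molecules are independent, which is the null
   model of molecule-to-molecule heterogeneity; the probability that two
   i.i.d. molecules share a pattern over `m` sites,
   `(f^2 + (1−f)^2)^m` (`pattern_identity_probability`), is astronomically
   small at genome scale.

4. **Chemistry**. Single-stranded PT: iodine cleaves each modified linkage
   into a strand-specific nick. Cleavage is modeled as certain and all
   losses are lumped into one labeling probability `p_label_nick`
   (default 0.8): a single lumped efficiency is identifiable from spot
   counts, separate cleavage and fill-in yields are not. Residual nicks
   that survive the polymerase/ddNTP blocking step enter as a per-strand
   Poisson background (`bg_nick_rate`, default 1e-6 per bp — a
   placeholder, as no residual rate is published). Two opposite-strand
   nicks closer than `d_break` (default 500 bp) destabilize the duplex and
   break it at the floored midpoint; each nick joins at most one break and
   pairs resolve left to right, which makes the rule deterministic given
   the nicks. Consumed nicks surface as `break_end` labels on the new
   extremities — the mechanism behind labels observed at fragment ends —
   and fragment lengths always sum exactly to the molecule length.
   Bistranded PT: covalent tagging followed by quantum-dot attachment
   labels each modified duplex with probability `p_label_qd = 0.92`, the
   measured coupling yield of the reagent on a one-PT oligonucleotide, and
   causes no breakage.

5. **Optics** (`comb`, `collapse_spots`). Combing draws one stretch factor
   per molecule from a normal with mean 0.942 and sd 0.02, truncated to
   (0, 1.1]; every bp coordinate maps affinely through
   0.34 nm/bp × stretch. A single per-molecule scalar matches how the
   assay is calibrated (one average stretch from lambda standards);
   intramolecular stretch variation is not identifiable from spacing data
   and is omitted. Diffraction-limited merging is single-linkage 1D
   clustering at `resolution_nm = 300`: chains of labels with consecutive
   gaps under the resolution fuse into one spot at their mean with summed
   multiplicity. Single linkage was chosen over fixed-radius seeding
   because it is parameter-free and order-independent, and an exact
   O(n^2) transitive-closure oracle keeps it honest in the tests. The
   300 nm default corresponds to roughly 0.9 kb at the calibrated
   stretch, consistent with the smallest reporting bin edge of 1.5 kb.
   Spot centers then receive Gaussian localization jitter
   (`localization_sd_nm = 50`, clamped to the backbone). `comb` itself is
   noise-free so that physical spacings remain exactly
   Δbp × 0.34 × stretch; jitter enters at the spot stage.
   `observe_fragments` is a vectorized bulk path that lays fragments
   end-to-end with super-resolution gaps so that one clustering pass
   reproduces the per-fragment result exactly (verified in tests with
   noise disabled).

6. **Measurement** (`calibrate`, `select_molecules`,
   `neighbor_spacings`). The µm→kb conversion comes from combed standards
   of known size: `kb_per_um = size_kb / mean(lengths)`, and the realized
   stretch is `mean(lengths) / (size_bp × 0.34 nm)`. Molecules enter the
   analysis if (A) they carry the orientation end label, are full length
   within `length_tol` (default 5% — "full length" is published without a
   tolerance, so it is an exposed parameter) and have ≥1 PT spot, or (B)
   they have ≥2 resolvable PT spots. Criterion-A molecules are oriented
   from the end-labeled extremity and contribute positional maps;
   criterion-B molecules contribute spacings only, which are
   orientation-invariant. Spots on fragment extremities are included in
   spacings, since break-end labels are genuine PT-derived signals.

7. **Statistics** (`spacing_histogram`, `estimate_density`,
   `spots_per_molecule`, `pattern_dissimilarity`). Spacings are reported
   over half-open bins with edges 0, 1.5, 4, 10, 20, ∞ kb; the explicit
   sub-1.5 kb bin keeps resolution censoring visible instead of silent.
   Heterogeneity is summarized by the spots-per-molecule distribution and
   by the mean Jaccard distance between occupied 2-kb position bins of
   oriented molecule pairs. No hypothesis tests are performed — the
   module reports descriptive statistics and resampling intervals only.

## The occupancy-density estimator

When the consensus spacing (tens of bp) is far below the optical
resolution (~1 kb), labeled sites along a molecule are locally Poisson
with an effective rate λ per kb, and a resolvable gap behaves as
`resolution + Exponential(λ)`. `estimate_density` inverts the mean:
`λ = 1 / (mean(gap) − r)`, and converts to a per-site occupancy via the
motif density and labeling efficiency,
`f_hat = λ / (motif_density_per_kb × p_label)`, clipped to [0, 1]. A
percentile bootstrap over gaps (fixed seed, `B = 0` for the point estimate
alone) gives the interval. A mean gap at or below the resolution means the
label density is saturated and the rate is unidentifiable; this is an
error, not a number.

Two caveats are built into the tests rather than hidden. First, in the
`r → 0`, full-labeling limit the estimator recovers the true occupancy
(verified at `f = 0.12` over 10⁴ sites spaced 30 bp). Second, on finite
molecules long gaps are censored — a gap `g` can only be observed with
probability proportional to `W − g` on a molecule of length `W` — so on
48.5-kb molecules at λ = 0.2/kb the moment estimator converges to the
size-biased value `1 / ((W·E[g] − E[g²])/(W − E[g]) − r)` rather than to
λ. The test suite asserts exactly that, and the uncensored recovery to
within 10% on gaps drawn from the model itself.

## What the generator emulates — and what it does not

Emulated: partial and clustered per-molecule occupancy; independence
across molecules; nick conversion with background nicks and
double-strand-break artifacts at proximate opposing nicks; end-labeling
eligibility restricted to the genome's native left terminus; per-molecule
stretch variation; diffraction-limited merging with multiplicities;
localization jitter; the full measurement chain including standards-based
calibration.

Not emulated: sequence-context preference in site selection (unknown
biology); hemi-modified duplex sites; iodine concentration/temperature
dependence of cleavage; multiple tag attachment per site; photobleaching,
blinking, or quantum-dot size effects on combing; 2D image formation
(1D intensity profiles stand in for line scans). Passing tests therefore
demonstrate the internal consistency of the measurement procedure under
this generative model, not the fidelity of any particular laboratory
image.

A consequence worth stating: with the population-level occupancy
`f = 0.12` applied to *all* CCA sites of a dense consensus (one site per
~32 bp on random sequence), nick spacing falls well below `d_break` and
the model predicts heavy fragmentation and near-saturated labeling. The
published single-molecule observations (full-length lambda genomes with
one to twelve resolvable spots) are only compatible with a much sparser
*effective* labeled-site density; the simulator makes this tension
explicit and measurable rather than resolving it by assumption. The
bistranded quantum-dot mode, which causes no breakage, retains full-length
molecules at any occupancy.

## Numerical and reproducibility choices

- Coordinates 0-based half-open throughout; the linkage coordinate is the
  phosphate position projected to the forward strand.
- Break positions round down at half-bp midpoints (determinism).
- Spot collapse at `resolution = 0` is the identity; multiplicities are
  conserved by construction and checked on every simulation.
- One master seed drives named substreams
  (`derive_seed(seed, stage)`), so changing one stage's parameters never
  perturbs another stage's draws, and identical config + seed give
  byte-identical tabular outputs.
- Stretch draws are truncated by redraw, not clamping, to avoid a point
  mass at the boundary.
- Empty inputs return typed empty results (empty site tables, empty
  spacing sets, zero-count histograms with no fractions) rather than NA
  propagation; degenerate statistics (pairwise dissimilarity of a single
  molecule) are reported absent.

Default problem sizes — 500 molecules per pipeline run, 100 calibration
standards, 10⁴ sites or gaps for recovery checks, 1 Mb scan fixtures —
were chosen so each check resolves its target at 3-standard-error
precision while a full run of suite plus acceptance script stays in the
minutes range on a single core.

## Worked example

```{r example, eval = FALSE}
library(ptomap)

cfg <- default_config()          # 48.5-kb linear genome, CCA, f = 0.12
cfg$seed <- 1
res <- run_pipeline(cfg, "ptomap-out")

res$calibration$stretch_fraction # ~0.942 recovered from 100 standards
res$histogram$fractions          # spacing fractions over 1.5/4/10/20 kb bins
res$density$f_hat                # occupancy implied by spacings
```

The same functions consume real measurements: a tab-separated spot table
with columns `molecule_id`, `backbone_um`, `end_labeled`,
`spot_position_um`, `channel` (plus optional `multiplicity`) goes through
`molecule_records()`, `select_molecules()` and `neighbor_spacings()`
identically to simulated data.

## Known limitations

- The background nick rate and the break-distance threshold are exposed
  parameters with placeholder defaults; neither is published.
- The density estimator assumes local Poisson labels and is biased on
  molecules short relative to the mean gap (quantified above).
- Orientation requires the end label; criterion-B molecules contribute no
  positional information, so positional occupancy maps are conditional on
  end-label efficiency.
- IUPAC-degenerate motifs are not supported; scanning is exact-match over
  A/C/G/T with N treated as never matching.
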