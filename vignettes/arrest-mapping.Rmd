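---
title: "Mapping cell-cycle arrest architectures with arrestmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cell-cycle arrest architectures with arrestmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`arrestmap` reconstructs the branching structure of cell-cycle arrest from
hyperplexed immunofluorescence (4i) single-cell feature tables. This
vignette is the package's account of the underlying models: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
method's known limits lie.

## The data model

A feature table is a tibble with one row per cell: `cell_id`, `condition`,
`replicate`, optional ground-truth columns (synthetic data only), and
numeric feature columns named by marker, compartment and statistic
(`pcna_nucleus_median`, `cell_area`, ...). All downstream stages operate on
this one shape, so every user-facing function takes the table first and
returns a tibble, and results chain with the pipe.

## Integration normalization

Two normalizations, applied per feature:

* **Matched-control z-normalization.** Every cell's value becomes
  `(x - mu_ctrl) / sigma_ctrl`, where the statistics come from the matched
  control condition only (sample standard deviation, n - 1). Because the
  same affine map is applied to treated cells, relative fold-changes induced
  by treatment are preserved on the z scale. Features with zero control
  variance are excluded (reported, never silently dropped); missing values
  propagate and never enter the fits.
* **Bimodal peak normalization.** Features whose biology pins two modes --
  DNA content (2C/4C) and the phospho/total-RB ratio (hypo-/hyper-
  phosphorylated) -- are instead mapped affinely so the two density modes
  land on fixed anchors: (2, 4) and (0, 1) respectively. The map is exact at
  the anchors, strictly increasing, and invertible by swapping anchors and
  targets.

Mode detection (`detect_bimodal_peaks()`) works in two passes. A Gaussian
KDE with Silverman (`nrd0`) bandwidth proposes candidate modes; the two
dominant modes must be separated by at least 20% of the data range --
measured robustly as the 1%-99% quantile span, since raw min/max is
dominated by stray polyploid tails -- and the minor/major height ratio must
exceed 10%, otherwise the sample is declared unimodal with an explicit
error (never a silent guess). Each mode is then *refined* on its own side of
the antimode using the half-sample mode estimator within a window around
the first-pass peak. The refinement matters: a single global bandwidth on a
bimodal sample is dominated by the between-mode spread, and a one-sided
shoulder (the S-phase continuum abutting the 4C peak) drags a kernel mode
by several percent, while the half-sample mode is robust to exactly this
kind of asymmetric contamination.

## Phase and arrest calls

Arrest is called first: cells with normalized phospho/total-RB ratio below
the threshold 0.7 are arrested (G0), at or above are cycling. The boundary
is assigned to cycling because the hyperphosphorylated mode sits at 1 after
peak normalization, so 0.7 lies in the upper mode's basin; both the
threshold and the boundary rule are configurable (`arrest_params()`).

Cycling cells then get G1/S/G2/M from a four-component Gaussian mixture
(full covariance) over nine features: median nuclear PCNA, CDH1, SKP2,
cyclin A, E2F1, cyclin B1 and phospho-p27, plus nuclear area and DNA
content. Two design choices deserve explanation:

* **Anchored EM.** The likelihood surface of an unconstrained 4-component
  mixture on these data prefers splitting the large, internally graded G1
  population and absorbing the ~3% mitotic population into G2 -- components
  then stop corresponding to phases. We therefore initialize EM from a
  coarse marker-logic partition (PCNA separates S; DNA content separates G1
  from G2/M; cyclin B1 and nuclear area separate M from G2) and run EM with
  a conjugate prior regularizing the covariances. On degenerate input
  (noiseless simulations, where within-phase covariances are singular) the
  fit falls back to ridge-regularized per-component Gaussians around the
  same partition. Fits are deterministic given the seed.
* **Automated component-phase mapping.** Components are mapped to phases by
  marker ordering -- lowest-DNA component is G1; among the rest, the
  component with the highest cyclin B1 rank and smallest nuclear-area rank
  is M; the higher-cyclin-A remainder is G2; the last is S (sanity-checked
  for high PCNA). Rank-based comparisons keep the mapping valid on raw and
  z-normalized scales alike. This replaces manual annotation of components,
  which would not be testable.

Arrested cells are G0 regardless of the mixture posterior. Ploidy is banded
on the normalized DNA scale: 2C below 3, 4C in [3, 6), 8C at or above 6 --
midpoints between C-states on the anchored scale.

## The cell cycle map

The embedding is a diffusion-geometry method implemented in full:

1. **Kernel.** `K_ij = (exp(-(d_ij/s_i)^a) + exp(-(d_ij/s_j)^a)) / 2`, with
   Euclidean `d` on the selected features and `s_i` the distance from cell
   `i` to its knn-th neighbor. The decay exponent defaults to 40 (the
   canonical alpha-decay choice) for map building; `K_ii = 1`; duplicate
   points fall back to the smallest positive neighbor distance.
2. **Diffusion operator.** `P = D^-1 K`, rows summing to 1; isolated cells
   are an error naming the cell.
3. **Potential distances.** `P^t` by binary exponentiation; potentials
   `-log(P^t + eps)` for gamma = 1 or the power transform
   `2/(1-gamma) (P^t + eps)^((1-gamma)/2)` otherwise, with a
   machine-epsilon floor; distances are Euclidean between potential rows.
4. **Embedding.** Classical MDS initialization followed by SMACOF stress
   majorization (stress is non-increasing by construction; iteration stops
   at relative improvement below 1e-7). Deterministic given the input.

Map-building parameter sets follow the published convention for this kind
of data (knn = 150, t = 20, gamma = 1 for a ~10-25k-cell map); all are
configurable per analysis. Everything is exact and dense -- no landmarking
or approximate neighbors -- which is comfortable up to a few thousand cells
per analysis and is how all shipped analyses run.

## Diffusion pseudotime and branches

With stationary distribution `pi` proportional to the kernel row sums, the
accumulated transition matrix is `M = (I - (P - 1 pi'))^-1 - I` (the
closed form of the series `sum_s (P^s - 1 pi')`), and the
diffusion-pseudotime distance between cells is the Euclidean distance
between their rows of `M`. Pseudotime is the distance from a root cell,
rescaled to [0, 1]. The root defaults to an early-G1 anchor: the cycling
G1 cell with minimal DNA content and maximal phospho/total RB.

Two practical choices differ from the map-building defaults, deliberately:

* **Kernel sharpness.** For pseudotime we use a Gaussian-type kernel
  (decay exponent 2) with knn = 30. An exponent of 40 is effectively
  binary -- neighbors inside the adaptive bandwidth get weight ~1, everyone
  else ~0 -- which leaves near-disconnected diffusion islands wherever the
  data have sharp transitions, and knn above the size of a small branch
  erases that branch's internal ordering. The source formulation of
  diffusion pseudotime itself uses Gaussian kernels.
* **Per-condition analyses.** Pseudotime is computed per stress condition
  (control; serum-starved; replication-stress), each with its own
  population and root, mirroring how per-condition maps are built with
  their own parameter sets. On a single unified population containing the
  full four-deep chain (4C arrest, mitotic skipping, senescence, 8C), the
  root-distance field of this formula is *not* monotone along the deep
  chain: across several density bottlenecks the distances become dominated
  by local trapping norms rather than by progression along the chain. This
  is a known limitation (below); the deep states are characterized instead
  by the senescence score and ploidy banding.

**Branch assignment** is anchor-supervised: each cell joins the branch of
its nearest anchor in the diffusion-pseudotime metric; ties break to the
first-listed branch; anchors always belong to their own branch. A branch
may contribute *several* anchors, and the shipped analyses place anchors
along each arm at depth quantiles (0.2 ... 1.0). This matters: with a
single tip anchor per arm, cells far from every anchor are decided by the
anchors' own local trapping norms rather than by arm membership, and
junction-adjacent cells drift to whichever arm protrudes least. Anchors
along the arm make the decision local. Coincident anchors of different
branches are an error; coincident anchors of the same branch are redundant
and harmless.

**Trajectory profiles** cut pseudotime into `n_bins = 50` equal-width bins
(configurable), restrict to one branch, and average each feature per bin.
Bins with fewer than 15 cells are excluded from the profile -- the 15-cell
rule -- and the exclusion is exact, not approximate. Features are displayed
in the leaf order of an average-linkage hierarchical clustering under
correlation distance `1 - r`, with a deterministic rotation: at every
merge, the subtree whose features peak at the earlier pseudotime goes
first. Zero-variance profiles cannot enter a correlation and are placed
last, with a message.

**Senescence score** = mean over the signature of direction x z-value;
linear by construction, zero for a cell at the control means. The default
signature (GSK3beta, phospho-T157-p27, p27, CDK4, cyclin D1, cyclin E,
cell area positive; DNA:cytoplasm ratio negative) is a stand-in mean-z
form for a previously trained multivariate signature whose exact
coefficients are not public; it is flagged as such and fully configurable.

**Fate fractions** turn label counts into whole percentages that sum to
exactly 100: round half away from zero, then assign the residual to the
largest label. The tracked-cell worked example (40 G2-arrested, 32
completing mitosis) gives 56% / 44%.

## Time-lapse biosensor analysis

CDK2 activity is the ratio of background-corrected median intensities:
cytoplasm over nucleus, with the cytoplasmic signal taken in a 15-pixel
ring outside the segmented nucleus separated by a 2-pixel gap. Ring
membership uses Chebyshev (chessboard) distance to the mask --
gap-exclusive, width-inclusive -- implemented by box-brush morphological
dilation, with pixel centers at integer coordinates. A background-corrected
nuclear denominator at or below a small guard flags the measurement
unreliable (`NA` plus a warning) rather than returning a wild ratio.

S phases are maximal runs of PCNA-foci counts at or above 3, merged across
single-frame dropouts (foci flicker at S-phase margins). Mitoses are
single-frame DNA-proxy drops of at least 40%.

Fate classification applies ordered rules on the running-median-smoothed
(window 5) CDK2 and p21 channels, with thresholds CDK2 low/high = 0.5/1.0
(the conventional cut-offs for this sensor family), minimum arrest duration
6 h, p21-rise level 50 a.u. within 2 frames of the CDK2 collapse, and a
minimum S-interval duration of 0.5 h for the endoreduplication rule (so a
stray foci spike cannot masquerade as replication):

1. *Endoreduplication*: an arrest episode, CDK2 recovery above high, a
   subsequent S interval, and no mitosis between arrest onset and that
   S phase.
2. *G2 arrest (4C)*: collapse from above high to sustained low until trace
   end, no subsequent mitosis, p21 rising at the collapse. With cyclin A/B1
   channels present and collapsed without mitosis, refined to *mitotic
   skipping into senescence*.
3. *Post-mitotic arrest (2C)*: a mitosis, then sustained low CDK2 to trace
   end with the p21 rise after division.
4. Otherwise *proliferative*.

The ordering encodes the biology: the p21-timing window is what separates a
G2 arrest (p21 rises with the collapse) from a post-mitotic arrest (p21
rises after division), which is exactly the discriminator seen in live
cells. The arrest-duration and p21 conventions are package conventions, not
published constants, and are all configurable via `fate_thresholds()`.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions every
recovery test runs under.

**Population model.** A cycling cell sits at `theta ~ U[0, 1)` with phase
boundaries G1 [0, 0.45), S [0.45, 0.75), G2 [0.75, 0.97), M [0.97, 1)
(approximate human somatic phase proportions). Marker means are piecewise
functions of `theta` encoding the canonical dynamics (DNA 2C to 4C across
S; cyclin A accumulating to G2 and degraded at M; cyclin B1 peaking at M;
cyclin D1 rising in late G2 and staying up through M; CDH1 high in G1;
PCNA/SKP2 marking S; E2F1/cyclin E peaking at G1/S; nuclear area growing
until mitotic rounding). Arrested cells sit on one of eight branches at
arrest depth `s ~ U`, with means interpolating from an anchor profile (the
cycle position of exit, or the parent branch's terminus for the chained
mitotic-skip, senescent and 8C states) to a terminal profile. The
phospho/total-RB ratio drops abruptly on every arrest branch (0.95 cycling;
`0.45 - 0.35 s` arrested) -- arrest is RB-switch-like by construction.

Noise is multiplicative log-normal, median-anchored (`x = m exp(sigma z)`,
`sigma^2 = log(1 + cv^2)`), default `noise_cv = 0.15`; at cv = 0 every
value equals its mean function exactly. Ratio statistics (phospho/total RB,
DNA:cytoplasm) and integrated DNA content use cv/2: ratios cancel shared
illumination and size fluctuations, and integrated DNA stain is the classic
low-CV cytometry measurement -- with full cv on DNA the 4C histogram mode
would dissolve into the S-phase continuum, which real ploidy histograms do
not do.

Three dynamic-range choices are deliberately structural, because the real
data's trajectories are visibly distinct on the published maps and a
generator whose branches fuse would be a poor emulation:

* Stress-response markers (p21, phospho-H2AX, p53, phospho-CHK1) follow a
  saturating immediate-early curve in `s` (rate-2 exponential): damage
  signaling precedes the arrest it causes. The hypomitogenic global decline
  (factor 0.4 on nearly every protein, p27 excepted and rising) is also
  early -- translation inhibition is rapid after serum withdrawal.
* The 2C and 4C replication-stress branches are differentiated by
  checkpoint route: strong phospho-CHK1 on the G2-exit (4C) branch, p53/
  phospho-H2AX emphasis on the post-mitotic (2C) branch, cyclins A/B1
  retained on the 4C branch until mitotic skipping degrades them.
* The default state mix mirrors the reported architecture: among
  replication-stress arrests, 56% 4C vs 44% 2C; ~2% endoreduplicated 8C;
  small mitotic-skip and senescent compartments.

`depth_range` narrows the arrest-depth distribution; `c(0.1, 1)` emulates a
snapshot taken after every arrested cell has committed to its trajectory
(as in multi-day treatments). The branch-assignment validation uses this,
because at `s = 0` all 2C-anchored arms coincide by construction and an arm
label there is not meaningful ground truth.

**Traces.** 10-min frames, 72 h default duration, 24-h cycle (G1 9 h, S
8 h, G2 6 h, M 1 h). CDK2 rises 0.45 to 1.35 across the cycle and resets at
division; the DNA proxy doubles across S and halves in one frame at
mitosis (an unambiguous detection target); foci count 20 during S.
Endoreduplication dwells 15-30 h before CDK2 re-rise and a second S phase
reaching a DNA proxy of 8. p21 induction crosses its detection level within
about a frame of arrest onset (G2 arrest) or one hour after division
(post-mitotic arrest) -- the live-cell discriminator. Per-channel noise is
additive Gaussian (plus Poisson background foci), and the default fate mix
mirrors the 56/44 bifurcation with ~5% endoreduplication.

**What passing tests do and do not show.** The generator produces smooth,
log-normal, piecewise-linear manifolds with independent per-feature noise.
Real 4i data add segmentation errors, staining batch effects, cell-cell
contact artifacts, fat-tailed outliers, and correlated noise; none of these
are emulated, so ground-truth recovery here validates the *algorithms*, not
performance guarantees on any particular real dataset.

## Problem sizes and numerical choices

Shipped analyses and tests run at: phase recovery n = 5,000 (the full
8-state mix); replication-stress pseudotime n = 5,000; hypomitogenic
pseudotime n = 3,000; Y-shaped branch assignment n = 2,000; trace
classification 500 traces; oracle equivalence n <= 50 against brute-force
double loops and a 500-term truncated series. Exact dense linear algebra
throughout; `eps = .Machine$double.eps` inside the potential log; SMACOF
tolerance 1e-7; mixture covariance ridge `max(mean diag x 1e-6, 1e-10)` on
the degenerate fallback path. All stochastic stages are bit-reproducible
under a fixed seed.

## Known limitations

* The diffusion-pseudotime root-distance is not monotone across long
  multi-bottleneck chains (the 4C-to-8C progression on a unified map);
  per-condition analyses and score/ploidy characterization of the deep
  states are the supported route.
* Anchor-based branch assignment needs anchors along each arm; single tip
  anchors misassign cells near the branch point.
* Peak normalization requires a genuinely bimodal sample; at high noise
  (cv >= ~0.25) the DNA 4C mode dissolves and the stage errors out -- by
  design, rather than normalizing to a fictitious mode.
* Dense exact computation bounds a single analysis to a few thousand cells
  on a laptop-class machine; no approximate-neighbor or landmark paths are
  provided.
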