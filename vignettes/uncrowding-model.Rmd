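---
title: "A grouping and segmentation account of vernier uncrowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grouping and segmentation account of vernier uncrowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncrowdr)
```

## The problem

In peripheral vision, discriminating the offset direction of a vernier (two
nearly collinear vertical bars) deteriorates sharply when flanking lines are
placed beside it — *crowding*. Counter-intuitively, making the flankers much
longer than the target *improves* performance again — *uncrowding* — even
though more flanker "signal" is added. Local pooling accounts cannot explain
this; a two-stage account can: elements are first grouped into objects, and
interference then occurs within the perceived group. When the flankers form
their own group, a segmentation process can strip them away from the
representation used for the vernier decision.

`uncrowdr` implements this account as a compact, fully deterministic
pipeline and runs it on eight stimulus configurations: the vernier alone,
with equal-length flankers, with long (8.5°) flankers, with gapped long
flankers, and the gapped/long flankers combined with four "Pacman" disks
(inward- or outward-facing mouths) that were designed, in the study this
package models, to induce an illusory occluding bar. The package also
contains the statistical machinery for the accompanying subjective-rating
experiment: an exact Wilcoxon signed-rank test, rating summaries, a
within-person consistency metric, and a seeded ordinal-rating generator so
that every analysis stage is testable without human data.

## Stimulus geometry

All geometry is declarative and in visual degrees, taken from the printed
experimental parameters: vernier length 1.8°, width 210 arcsec, offset 0.2°;
three flankers per side spaced 0.4° apart; long flankers 8.5° tall; gaps of
1.25° aligned with the vernier's top and bottom; Pacman radius 1.125° at
3.33° horizontal distance, mouth height equal to the gap; background at 75%
luminance, elements at 25%. The default raster resolution is 10 px/°
(component counts are resolution-invariant over 8–16 px/°, which the tests
check).

Geometric choices the source text left open, decided once here:

* **Gapped flankers** are read as three stacked collinear segments (two
  gaps), the middle segment spanning the vernier's 1.8° extent, because the
  stimuli are described elsewhere as "three separate short gratings stacked
  vertically".
* **Gaps abut** the vernier's top and bottom exactly (rather than being
  centred on them).
* The **vernier halves abut** with no vertical gap, each half the total
  length — the conventional construction.
* **Pacman centres** sit on the gap-row centres (±1.525°).
* Coordinates are measured from the stimulus centre; the 10.5° eccentricity
  is metadata (the fixation point lies outside the simulated patch).
* **Pixel rounding** is half-away-from-zero, and sub-pixel-wide bars snap
  toward the pixel column nearest their centre-facing edge. The snap rule
  matters only at coarse resolutions: a naive nearest-centre snap places the
  0.2°-offset lower vernier segment in the column adjacent to the nearest
  flanker at 8 px/°, spuriously fusing the two elements. The inner-edge rule
  is exactly mirror-symmetric, which makes left-offset renders bit-exact
  mirrors of right-offset renders — the foundation of the evidence
  antisymmetry checked below.

## Boundary dynamics

`oriented_response()` converts the luminance image into four
orientation-channel energy maps using quadrature pairs of Gaussian-derivative
kernels (odd = first cross-derivative, even = second cross-derivative;
support ≈ 0.3°). Energy is contrast-polarity invariant and exactly zero on
uniform input; along the body of a vertical bar only the vertical channel
responds, with horizontal responses confined to the terminators — the
property the grouping stage relies on. Diagonal channels are computed but
carry no weight in the decision; they matter only for the Pacman contours.

The source model uses integrate-and-fire neurons but prints no equations, so
a deterministic rate dynamic is substituted: every unit rises toward its
static drive with τ≈20 ms from stimulus onset (20 ms) and decays with
τ≈60 ms after offset (140 ms; 120 ms presentation). The two printed temporal
landmarks anchor the constants: responses reach ≥ 90% of asymptote by
100 ms, and activity persists well past stimulus offset. Because all units
share the time constants, activity factorizes into a static map times a
scalar temporal profile; `accumulate()` reports trailing 20-ms window sums,
the deterministic analogue of accumulated spike counts.

## Grouping and segmentation

`build_graph()` extracts boundary nodes (per-channel non-maximum suppression
across the contour plus a half-maximum threshold, one node per pixel with
its dominant orientation) and connects them with

* **local 8-adjacency** (any orientation — a physical contour stays
  connected across its own corners and terminators), and
* **bipole-style grouping links** between collinear, like-oriented nodes
  across gaps of up to `max_bridge_deg` (default 0.8°) with a lateral
  tolerance of 0.1°.

The 0.8° default is the model-critical free parameter. The source
constrains only the interval: links must span the 0.4° flanker spacing
(terminator-to-terminator grouping between neighbouring lines is part of the
account of crowding with equal flankers) but must not span the 1.25° gap
(gapped flanker segments group as separate objects). Any value strictly
between those bounds gives the same qualitative behaviour.

Non-maximum suppression uses a non-strict rule on both sides so that exact
two-pixel plateaus (which terminator responses produce) survive; the
dominance rule then assigns each pixel to one channel. The symmetric rule is
what keeps node extraction exactly mirror-safe.

`place_selection()` positions two top-down selection disks (radius 1.5°)
over the tops of the left and right flanker triplets — "roughly covering"
them, as the source figure shows — excluding nodes on the vernier columns so
that the selection targets the flankers, never the target itself.
`spread()` models segmentation as constant-speed geodesic growth on the
boundary graph, starting at stimulus offset at 0.1°/ms: Layer 1 at time *t*
is the graph ball of radius *v·(t − offset)* around the seeds. This replaces
the published diffusive circuit with an equivalent-order process whose speed
is tuned to the printed "takes almost 100 ms" landmark; with the default
speed the 8.5° flanker contour completes in ~70–90 ms (the seed disks
already cover the top ~1.3° of the contour, which shortens the nominal 85 ms
path slightly). Membership is monotone and nodes unreachable from the seeds
stay in Layer 0 forever.

The mechanism then plays out by geometry alone:

* **Long flankers:** the vernier's terminators do not align with any flanker
  feature, so the vernier forms its own component; the selection sweeps the
  entire flanker group into Layer 1 and the vernier remains nearly alone in
  Layer 0 → uncrowding.
* **Equal flankers:** vernier and flanker terminators align, horizontal
  grouping links fuse everything into one component, and the selection
  cannot separate target from flankers → crowding.
* **Gapped flankers:** the middle segments group with the vernier (aligned
  terminators) but the 1.25° gaps exceed the bridge length, so the selection
  spreads only over the top segments; the middles stay beside the vernier in
  Layer 0 → crowding.
* **Pacmen:** their closed contours satisfy the collinearity rule nowhere
  near the line terminators (the nearest mouth edge is ~1.0° from the
  outermost flanker column, beyond the bridge length), so they form isolated
  components, are never seeded, and cannot change segmentation → the
  inducers leave the evidence untouched, matching the reported null effect
  of the inducers on performance.

## Decision

`build_templates()` constructs right/left vernier templates from the
vertical-channel energy of an isolated right-offset vernier, blurred by a
0.1° tolerance kernel, cropped to a square support of 1.5× the vernier
length and normalized to unit energy; the left template is the exact
horizontal mirror. The support admits the flanker columns (0.4–1.2°) but
excludes the Pacmen (≥ 2.2°) — the decision pools whatever ungrouped
activity remains near the target, which is precisely how flankers hurt it.

Per readout window (trailing 20-ms windows from offset to 300 ms), the
evidence is

$$ E_w = \frac{\langle A_w, T_R\rangle - \langle A_w, T_L\rangle}{\lVert A_w\rVert}, $$

where \(A_w\) is the accumulated vertical-channel activity at **Layer-0
nodes** inside the support. The reported evidence is the mean over windows.
Three consequences follow directly:

* Flanker activity left in Layer 0 is mirror-symmetric about the vernier
  column, so it cancels in the numerator but inflates the norm — crowding is
  pure match dilution.
* Removing flankers into Layer 1 restores the match — uncrowding is
  produced by segmentation, not geometry (ablating the spread stage
  collapses the LONG advantage to a few percent; the tests assert < 10%).
* Mirroring the stimulus negates the evidence exactly (the tests assert a
  relative error below 1e-9; in practice it is at the level of float
  reassociation, ~1e-16).

Evidence is deliberately not mapped to proportion correct: no psychometric
link is printed in the source, so the battery reports the raw score, and
`correlate_with_empirical()` accepts a user-supplied per-condition accuracy
table for a Pearson correlation. A window with no Layer-0 node in the
support contributes 0 with a warning (this happens legitimately for the
equal-flanker condition late in the trial, when everything has been
recruited).

## Rating analysis

Ratings are long-format records (participant, condition A–F, side,
repetition, Likert 1–5); a complete dataset has 4 ratings per participant ×
condition, 24 judgments per participant. `wilcoxon_signed_rank()` computes
midranks of the absolute paired differences, discards zeros by default
(Pratt handling available), reports the smaller signed-rank sum — the
convention is printed with every result, since the source reports only "sum
of the ranks" — and computes the exact p-value from the full distribution of
sign assignments (via the shift algorithm, identical to 2^n enumeration) for
n ≤ 25, else a tie-corrected normal approximation with continuity
correction. The default pairing unit for the long-vs-gapped-inward
comparison is the per-participant condition mean (n = 15), since the source
figure plots participant means; per-trial pairing is available. The
within-person consistency metric — whose exact formula the source does not
print — is defined as the mean absolute pairwise difference among a cell's
ratings, averaged over cells then participants.

## The synthetic rating generator

`generate_ratings()` draws from a thresholded-Gaussian (cumulative-link)
latent model: latent = condition mean + participant effect (SD 0.5) + trial
noise (SD 1.7), cut at (1.5, 2.5, 3.5, 4.5) so integer latent means map to
their own rating. The default condition means are **two-level**: the gapped
conditions B, D, F and the long-with-inward-inducers condition C at latent
4 ("three separate gratings"), the long conditions A and E at latent 2 —
the qualitative pattern of the reported ratings, in which all gapped
conditions average "about 4" and C received the same average rating as D.
The ties are part of the stated world: rank-order recovery is therefore
defined over pairs whose latent means differ. The large trial SD emulates
the reported within-person inconsistency of roughly two rating points
between repeats of the same condition; after discretization the realized
mean trial difference is somewhat smaller (~1.4), and reproducing the
printed value exactly is out of scope since the human data are not
published.

What a green test does and does not establish: the generator reproduces the
design (counts, balance, seeding) and the assumed latent structure; it does
not model eye movements, learning across trials, response times, or any
systematic left/right asymmetry, and the generator's condition means are
illustrative, not fitted. Monte-Carlo tests (type-I error of the exact test
in [0.03, 0.07] on 2000 null replicates; recovery of the latent order in ≥
95% of 200 replicates) validate the analysis chain on this stated world
only.

## Numerical choices and degenerate inputs

* All pipeline stages are deterministic; the only randomness in the package
  is the rating generator, which isolates and restores the global RNG state.
* A numerically blank channel map (peak ≤ 1e-12) yields an empty graph
  rather than thresholding noise.
* All-zero paired differences give the degenerate Wilcoxon result (p = 1,
  n = 0) with a warning; singleton rating cells are excluded from the
  consistency metric with a count.
* Image export is plain-text PGM (no binary formats); stimulus specs and
  generator parameters serialize to JSON.

## Known limitations

The pipeline is a minimal re-expression of a much larger laminar cortical
circuit: no spiking, no retina/LGN stages, no cortical magnification, no
learned selection placement, at most two segmentation layers, and no
illusory-surface filling-in (deliberately — the package's empirical point is
that occlusion completion is not needed to reproduce the pattern). The
evidence score is qualitative: orderings and null effects are meaningful,
absolute values are not, and the printed human quantities (rank sum 12.5,
p = 0.001, mean trial difference 1.94, r = 0.77 against empirical
accuracies) are not reproducible without the unpublished human data.
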