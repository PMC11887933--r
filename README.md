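# uncrowdr

A grouping/segmentation model of visual **uncrowding**, plus the statistical
toolkit for a subjective-rating experiment on the same stimuli.

## The scientific problem

Peripheral vernier-offset discrimination (was the lower bar offset left or
right of the upper bar?) deteriorates when flanking lines are added —
*crowding* — yet recovers when the flankers are made much longer than the
target — *uncrowding*. Local pooling cannot explain this; a mid-level
account can: oriented boundary signals **group** along collinear contours
(bipole/illusory-contour links), top-down selection **spreads** along the
grouped contours and shifts them into a separate segmentation layer, and the
vernier decision reads out only the default layer. Whether flankers hurt
therefore depends on whether they can be segmented away from the target —
which is determined by the grouping topology of the display, not by local
energy.

`uncrowdr` implements that account end to end for eight configurations:
vernier alone, equal-length flankers, long (8.5°) flankers, gapped long
flankers, and gapped/long flankers with four Pacman inducers (inward or
outward mouths). The decision variable is a template difference

E = (⟨A, T_R⟩ − ⟨A, T_L⟩) / ‖A‖,

the normalized difference between the match of Layer-0 vertical-channel
activity *A* to a right-offset and a left-offset vernier template, averaged
over post-offset 20-ms windows. The package also provides the rating-side
analysis: an exact Wilcoxon signed-rank test (full enumeration, midranks,
discard/Pratt zero policies), Likert summaries, a within-person consistency
metric, and a seeded cumulative-link rating generator with the study design
(15 participants × 6 conditions × 2 sides × 2 repetitions).

See `vignettes/uncrowding-model.Rmd` for the model description, parameter
rationale and limitations.

## Worked example

```r
library(uncrowdr)

bat <- run_battery()          # all 8 conditions, right offset, ~2 s
print(bat[, c("condition", "evidence")])
#>        condition   evidence
#> 1   VERNIER_ONLY 0.30284570
#> 2 EQUAL_FLANKERS 0.02112027
#> 3           LONG 0.17685204
#> 4         GAPPED 0.04188661
#> 5  GAPPED_INWARD 0.04188661
#> 6 GAPPED_OUTWARD 0.04188661
#> 7    LONG_INWARD 0.17685204
#> 8   LONG_OUTWARD 0.17685204
```

Reading: the unflanked vernier gives the strongest right-offset evidence
(0.303). Equal-length flankers crowd it (0.021): their terminators align
with the vernier's, grouping everything into one object that selection
cannot split. Long flankers uncrowd (0.177): they form their own group,
selection sweeps them into Layer 1, and the vernier is read out nearly
alone. Gapping the long flankers reinstates crowding (0.042): the middle
segments group with the vernier while the 1.25° gaps block the selection
spread. Adding Pacman inducers changes *nothing* (identical evidence to the
digit): their contours never link to the lines, so the model predicts the
inducers should not affect performance — the crowding/uncrowding pattern
arises without any occlusion or surface-completion machinery.

Rating side:

```r
d <- generate_ratings(rating_model_params(seed = 1))
rep <- analyze_ratings(d, test_pair = c("A", "D"))
print(rep$wilcoxon)
#> Wilcoxon signed-rank test (exact_enumeration, zeros: discard)
#>   statistic (smaller signed-rank sum) = 1  n = 15
#>   two-sided p = 0.0001221
```

A = long flankers, D = gapped flankers with inward Pacmen; under the
generator's defaults (gapped conditions rated ≈ 4 "three separate
gratings", long conditions ≈ 2) the exact test separates them decisively —
the same qualitative outcome as the human ratings the design emulates.

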