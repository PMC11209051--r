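---
title: "Quantifying testicular maturation from ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying testicular maturation from ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotestis)
```

## The measurement problem

Computer-assisted echotexture analysis turns a B-mode ultrasound frame into a
handful of numbers: the mean grayscale intensity (GI, 0 = anechoic black,
255 = hyperechoic white) of a region of interest, and its variability. In the
maturing dog testis these numbers track puberty: parenchymal GI rises from
hypoechoic levels to medium echogenicity and settles after the first
spermatozoa appear in the ejaculate; textural heterogeneity (the pixel SD)
rises past 19 by the onset of fertility; the mediastinum testis exceeds GI
190 and the capsule settles between 210 and 220; and colour-Doppler flow
progresses from absent to a visible vessel course in over 80 % of testes.
`echotestis` implements the measurement operators, the vascularity scoring,
the semen and volume arithmetic, and the rank-based statistics that connect
them, plus a synthetic generator of the whole longitudinal study.

## Echotexture operators

Two region-of-interest conventions are implemented, and deliberately kept
distinct:

- **Spot-meter**: nine square 2 mm² spots inside the parenchyma. The pixel
  side is `round(sqrt(2 mm^2) / mm_per_pixel)` (14 px at 0.1 mm/px). Mean GI
  is the mean of the nine spot means; "heterogeneity" is the SD of the nine
  spot means. Spot placement is deterministic: target centres on a 3×3 grid
  over the bounding box of the effective mask, each spot snapping to the
  nearest position fully inside the parenchyma, fully outside the
  mediastinum, and non-overlapping, in row-major order. An operator placing
  spots by hand would introduce irreproducibility for no statistical gain;
  artefact exclusion is handled by the masks supplied with the frame.
- **Region-area**: all pixels of the outlined parenchyma with the mediastinum
  excluded; mean and pixel SD. The pixel SD is the headline heterogeneity
  measure, since averaging spot means smooths exactly the variability of
  interest.

Both SDs use the n−1 denominator. On a uniform region both heterogeneities
are zero; on homogeneous speckle the two mean-GI estimates agree within a
couple of grayscale units (a property the test suite checks on 60 seeded
frames). The spot-meter fails — by design, with an explicit error — when nine
standard-area spots cannot fit, which happens in the smallest (youngest)
testes; downstream code records these frames as spot-infeasible rather than
silently shrinking the spots.

Percent echogenicity is `reference / parenchyma × 100` with the capsule as
the standard reference and the mediastinum as the modified variant. The ratio
direction follows the defining formula; note that a bright capsule over a
dark immature parenchyma gives ratios *above* 200 %, and maturation pulls the
ratio below 200 % as the parenchyma catches up — hence its negative
correlation with every growth and semen parameter. Echogenicity categories
are low 0–85, moderate 86–170, high 171–255, with non-integer means rounded
half-up before classification (so 85.4 is low and 85.5 is moderate); inputs
outside [0, 255] are errors, not clamped.

## Doppler scoring

Flow overlays are reduced to 8-connected components (8-connectivity keeps
thin, angled vessels in one piece). Components below `min_pixels = 5` are
speckle noise and dropped. The ordinal score is then:

| score | rule |
|---|---|
| 0 | no components |
| 1 | only sub-distinct components (below `distinct_pixels = 10`) |
| 2 | 1–3 distinct components |
| 3 | > 3 distinct components |
| 4 | any component with elongation ≥ 4 or principal-axis chord ≥ 30 px |

Course visibility (score 4) dominates counting: a single long vessel scores
4. The size and elongation thresholds are stated conventions — the original
scale is defined visually — and are exposed as arguments. Elongation is the
major/minor axis ratio of the component's coordinate covariance (with a
1/12-pixel quantization term so single pixels are well-defined); the chord
length along the principal axis is a cheap, monotone proxy for skeleton
length that is accurate for thin curved structures.

## Volumes, semen, staging

Calliper volumes use the ellipsoid constant 0.5236; ultrasonographic volumes
use 0.71. Haemocytometer concentration is the mean chamber count × 10⁶ per
mL — the dilution and chamber geometry are folded into that single printed
factor, so the 1:100 dilution is metadata, not part of the formula (users
with other counting protocols should convert before calling). Total sperm is
concentration × ejaculate volume, and fertility requires *strictly* more than
200 × 10⁶ spermatozoa. Viability targets 300 counted cells and flags smaller
counts instead of refusing them.

Age periods partition the week grid at the milestones: pre-pubertal through
the first-ejaculate week (default 28), pubertal until the fertile week,
post-pubertal from the fertile week (default 36) on. Milestones can be
cohort-level defaults or per-dog.

## Statistics

All inference is rank-based, matching the small-n longitudinal design:
Spearman correlations (average ranks for ties, t-approximation p-values),
Kruskal–Wallis with tie correction across structures and periods, Wilcoxon
signed-rank for the left–right comparison. No multiple-testing correction is
applied by default (raw p-values are reported; Holm is available). Lagged
correlations pool dogs, testes and semen-bearing weeks, pairing the GI at
week *w* with total sperm at *w* + lag.

The GI slope over the rising phase (defaults: weeks 6–30 parenchyma, 8–36
mediastinum, in GI units per week) is plain OLS on all testis-level points.
Its reported standard error is a dog-clustered CR1 sandwich estimate: the
points are repeated measures with dog-level and exam-level correlation, and
the i.i.d. OLS standard error understates the slope's sampling variability by
roughly 70 % on the synthetic cohort. The i.i.d. value is returned alongside
as `se_ols`. Plateau detection is a successive-median rule — the earliest
week from which every later biweekly change in the weekly medians stays
within tolerance (2 GI units; 5 % relative for volumes). The rule is simple
and transparent; it is also the least stable element of the maturity panel
(see limitations).

## The synthetic cohort

The generator is first-class, tested code that defines the study conditions:
8 dogs × 2 testes, biweekly exams at weeks 4–40, one master seed from which
every per-dog and per-frame seed is derived by a fixed hash (so extending a
cohort never perturbs existing records).

**Trajectories.** Grayscale targets are piecewise linear: parenchyma starts
at GI 55 (week 6, after a 3-unit dip from week 4), rises at 2.525 GI
units/week to the plateau week (30), then drifts at 0.45 units/week. The
plateau is deliberately *approximate*: biweekly median steps of ~0.9 units
remain well inside the 2-unit plateau tolerance (detection still returns
week 30, and the trajectory reads as constant at measurement precision), but
an exactly flat plateau would make the pooled same-day GI–sperm rank
correlation mathematically incapable of reaching the values the analysis is
designed to exhibit — with GI flat after week 30, GI ranks over the fertile
window are noise, capping pooled Spearman near 0.55. The mediastinum appears
at week 8 at GI 80 and rises at 4.251 units/week until the fertile week
(199 at week 36); the capsule rises from 140 to a 215 plateau after week 32;
heterogeneity rises linearly 8 → 22 by week 36. Growth follows logistic
fractions of adult values (weight 12 kg, height 38 cm, US testis volume
9.5 cm³) anchored to percent-of-maturity milestones (weight 86 %/95 % and
height 95 %/99 % at the first-sperm/fertile weeks; volume 0.2 cm³ at week 4,
~96 % of adult at week 36). Slope units are per week of age; the printed
convention could also be read per exam interval, so the parameter is
explicit in the profile.

**Noise and coupling.** Exam-level GI noise (`noise_sd = 1.5` grayscale
units) splits into a persistent dog factor (sd 1.0), an AR(1) exam latent
(sd 1.2, autocorrelation 0.5 per biweekly step) and per-testis noise
(sd 0.8). Left and right testes share the dog-week latent, which is what
makes them exchangeable. The same dog factor and exam latent load (×0.05 and
×0.18) onto log₁₀ total sperm with residual sd 0.05, producing the monotone
GI–sperm coupling: strong same-day correlation decaying over +2 and +4 week
lags as the AR(1) latent decorrelates. The median sperm curve is anchored to
the milestones (0 at first ejaculate, 10 × 10⁶ at first sperm, crossing the
200 × 10⁶ fertility threshold exactly at the fertile week). All constants
were fixed by design simulation before the acceptance suite existed and are
not tuned thereafter.

**Frames.** The testis is an ellipse (length from the volume trajectory,
width 0.6 × length) with a 3-px capsule rim, a central mediastinum band from
the onset week, and parenchyma filled with multiplicative gamma speckle whose
mask mean and SD equal the trajectory targets. The gamma's upper clip at 255
would bias bright regions dark, so the pre-clip mean is moment-matched using
the closed-form clipped-gamma mean (four fixed-point iterations); with
region means ≤ 215 and SDs ≤ 22 the residual bias is far below the sampling
error. `noise_sd = 0` is the analytic limit: uniform fills, exact trajectory
values, zero heterogeneity — used by the exactness tests. Doppler overlays
are rendered class-conditionally (blob sizes straddling the distinct
threshold, a traced vessel path for score 4), which is what makes the
classifier round-trip testable; week-level class assignment apportions the
reference proportion table to the testes examined by largest remainder, so
at the default 16 testes the counts are exact (13/16 = 81 % score 4 at week
36), not i.i.d. draws.

**What the generator does not emulate.** No acoustic physics: speckle is
i.i.d. gamma, not correlated interference; no attenuation, shadowing,
focal-zone or gain artefacts; masks are exact rather than operator-traced;
anatomy is a clean ellipse with no epididymis or scrotal tissue. Passing
tests therefore validate the *measurement and analysis operators* and the
internal consistency of the workflow — not segmentation robustness or
performance on clinical images, where masks are inputs supplied by the user.

## Problem sizes and determinism

The default analyses use the full design: 8 dogs × 2 testes × 19 weeks = 304
frames of 192 × 192 px at 0.2 mm/px (the frame comfortably contains the
largest ~3.3 cm testis; nine 7-px spots stop fitting below roughly week 12,
reproducing the small-testis limitation of the spot-meter). The acceptance
script regenerates and measures the whole cohort in well under a minute.
Identical configuration and seeds give bit-identical tables, frames and
reports; the RNG state of the caller is never disturbed.

## Known limitations

- The volume-plateau indicator of the maturity panel inherits the
  successive-median rule's sensitivity: late biweekly median steps are ~1–2 %
  while their sampling noise under the designed dimension noise is ~3–4 %,
  so this one indicator flips in a sizeable minority of seeds. The verdict
  is robust (the five threshold indicators are stable), but the panel should
  be read as indicators-plus-verdict, not six independent certainties.
- Pooling all testis-weeks inflates nominal significance of the Spearman
  matrix (repeated measures); p-values are reported raw by convention, and
  only the slope fit gets a cluster-robust SE. A mixed-effects treatment is
  out of scope by design — the workflow is rank-based end to end.
- The distinct-size and course thresholds of the Doppler scorer are
  operational conventions for a visually defined scale; on real scanners
  they should be calibrated to the colour-pixel footprint of the machine.
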