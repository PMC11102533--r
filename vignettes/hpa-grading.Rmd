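---
title: "Automated HPA grading of glaucomatous visual field defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated HPA grading of glaucomatous visual field defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpagrade)
library(dplyr)
```

## The problem

Staging glaucomatous visual field loss from Humphrey perimetry printouts is
done clinically with the Hodapp-Parrish-Anderson (HPA) criteria, which read
three things off a printout: the mean deviation (MD), the four central
5-degree sensitivities on the global plot, and the pattern-deviation
probability plot. Applying the criteria by hand is slow and error-prone
enough that in practice clinicians often fall back on subjective judgement.
`hpagrade` automates the whole procedure: a deterministic rule engine for
the criteria, and an interpretable computer-vision parser that turns a
raster image of the pattern-deviation plot into the per-locus significance
matrix the rules need. Everything else in the package exists to certify
that pipeline: a synthetic printout renderer with known ground truth, and
the agreement statistics used to report validation results.

## The rule engine

Each criterion maps its input to one of four ordered grades
(none < mild < moderate < severe), and the overall stage is the most severe
of the per-criterion grades:

* **Mean deviation** (dB, more negative = worse): `>= -1` none, `>= -6`
  mild, `>= -12` moderate, below that severe. Band floors are inclusive, so
  `md = -6` is mild.
* **Central points**: a point is *depressed* when strictly below 15 dB.
  No depressed points: none. Depressed points confined to one hemifield:
  moderate. Depressed points in both hemifields, or any point at (or,
  defensively, below) 0 dB: severe.
* **Pattern deviation, P < 5%**: the proportion of loci depressed at P < 5%
  or worse. Zero: none; up to 25% inclusive: mild; up to 50% inclusive:
  moderate; above: severe.
* **Pattern deviation, P < 1%**: zero: none; strictly below 10/76: mild;
  below 20/76: moderate; at or above 20/76: severe.

Proportions rather than absolute counts are used because the denominator
differs between test patterns (54 loci on 24-2, 76 on 30-2). All proportion
comparisons are integer cross-multiplications, never floating point, so
band boundaries are bit-stable: `19/76` is *exactly* the mild boundary and
`7/54 < 10/76` is decided exactly.

```{r rules}
grade_md(c(0, -6, -12.5))
grade_pd1(c(9, 10, 20), 76)

rec <- field_record("right", md = -3, central = c(20, 20, 20, 20),
                    pd = pd_matrix("30-2", c(rep("P1", 20), rep("NS", 56))))
grade_field(rec)
```

The thresholds live in a configurable `hpa_thresholds()` object, so the
scheme can be adapted (a stricter MD cut-off, a different depressed-point
definition) without touching the engine. The defaults are the standard HPA
values above.

Two readings of the criteria are genuinely ambiguous in the sources this
package follows, and were fixed as design choices: a central point is
depressed iff *strictly* below 15 dB, and the P < 1% moderate band is
`[10/76, 20/76)` — the only choice that makes the four bands exhaustive and
mutually exclusive. The per-criterion bands otherwise follow the printed
inclusive `>=` signs. The "no defect" outcome is an explicit grade rather
than an absent one, so confusion matrices generalise to datasets that do
contain healthy fields.

## The plot parser

The parser mirrors how a human reads the plot, and every intermediate is
inspectable (no learned components):

1. **Binarise** with a global Otsu threshold. Printouts are near-bilevel,
   so one global threshold suffices; colour images are first reduced to
   luminance.
2. **Locate the panel**: the rectangular frame is found as the outermost
   long horizontal/vertical ink runs (a run must span at least half the
   image, which no row of symbols can). Without a frame, the tight bounding
   box of symbol mass dilated by half a cell gives a first estimate.
   Frame pixels are then erased from the ink mask so they can never bleed
   into a sampling window — at small cell sizes the outermost loci sit only
   a few pixels from the frame.
3. **Refine the grid**: per-locus ink centroids are regressed on the
   canonical grid coordinates (3 iterations), re-estimating origin and
   scale. Every locus carries ink (the not-significant symbol is a visible
   dot), so all loci inform the fit. This step is what makes the frameless
   path exact: the bounding-box estimate alone cannot recover scale because
   glyph extent varies by category.
4. **Superimpose the canonical grid**: 24-2 and 30-2 layouts are built in
   (6-degree pitch, 3-degree meridian offset, the two extra nasal loci of
   the 24-2); left-eye charts are the x-mirror of right-eye charts.
5. **Classify each symbol** by the dark-pixel fraction in a square window
   of 0.8x the grid pitch, against a calibration table of the five symbol
   densities, with the symbol bounding box as a secondary feature. The five
   glyphs are monotonically ordered in ink density, so a 1-D feature is
   sufficient and interpretable. Samples near a calibration boundary
   resolve toward the *less* significant category and are flagged
   low-confidence — conservative against false severity inflation, and
   listed for human review in the parse diagnostics.

```{r parse}
pd_true <- pd_matrix("24-2", sample(pd_categories(), 54, replace = TRUE))
rp <- render_pattern_plot(pd_true, "right", render_style(cell_px = 32), seed = 1)
parsed <- parse_pattern_plot(rp$image, "24-2", "right")
identical(as.character(parsed$category), as.character(pd_true$category))
count_depressed(parsed, "p5")
```

Numeric values (MD, central sensitivities) are *not* extracted from images
— there is no OCR. They are user-supplied numbers, mirroring the
three-input design of the deployed application this package re-implements.

### Calibration and scale

Ink fraction is nearly scale-invariant, so one calibration table rendered
at a canonical 48 px pitch serves all plot sizes; `symbol_calibration()`
can re-derive it at another pitch or from a rendered legend strip. The
nearest-reference decision rule (log scale) with both glyph families in the
table means the classifier tolerates symbol sets whose densities differ by
tens of percent from its own.

## The synthetic validation set

No public corpus of graded pattern-deviation plots exists, so validation
uses synthetic records with known ground truth. `sample_field()` draws MD,
central sensitivities and pattern-deviation counts band-wise so the overall
grade equals a requested target (verified by re-running the rule engine —
rejection sampling), and `render_pattern_plot()` draws the matrix as a
Humphrey-style panel. The defaults emulate the validation conditions of the
study this package re-implements: 168 fields, none of them defect-free,
with a 0.4/0.3/0.3 mild/moderate/severe mixture typical of a glaucoma
clinic; the mixture is a parameter, so the undefined-specificity edge case
(below) can be reproduced or avoided at will. Rendering defaults are a
framed panel at 32 px per cell with jitter and noise off; robustness suites
turn margins, rescaling, frameless rendering, the second glyph family and
jitter on explicitly.

What the generator deliberately does **not** model: spatial correlation of
real scotomata (arcuate defects, nasal steps, respect of the horizontal
meridian), test-retest variability, reliability indices, or the rest of a
full printout. Counts and categories are what the rules and the parser
consume, so passing tests certify the *mechanism* (rules correctly applied,
symbols correctly read) — they say nothing about how well HPA itself stages
real disease, and a parser validated here could still fail on printout
styles outside the rendered families (e.g. heavily compressed JPEGs or
scanned paper with skew, neither of which is emulated).

```{r dataset}
ds <- make_validation_set(n = 20, seed = 42)
count(ds, true_grade)
```

## Validation statistics

`validate_dataset()` runs the full image-to-grade pipeline on every record
and scores it against the numeric ground truth: confusion matrix,
unweighted Cohen's kappa, and positive-vs-rest binary metrics for both
severe detection and any-defect detection.

```{r validate}
v <- validate_dataset(ds)
glance(v)
```

Undefined values are first-class: a metric whose denominator is empty is
reported as `NA` with a `*_defined` flag (and serialised as the string
`"undefined"`), never as 0 or 1. With the default class mixture there are
no defect-free fields, hence no true negatives for any-defect detection,
and its specificity is undefined — an edge case the reporting preserves
rather than hides.

The appraisal-duration comparison is a two-sample t-test from summary
statistics. Welch's form is the default because the two workflows have
very unequal spreads (a tool-assisted workflow is far more uniform than
free-form manual appraisal); with equal group sizes the t statistic equals
the pooled-variance form, and both are exposed. Group sizes enter as an
explicit argument — `n = 20` per arm reproduces the published timing
comparison from its printed means and SDs:

```{r ttest}
t_test_summary(26.5, 3.3, 20, 48.6, 28.4, 20)
```

## Numerical choices and degenerate inputs

* Proportion bands: exact integer cross-multiplication (see above).
* Kappa returns `NA` when expected agreement is 1 (single occupied margin).
* Both-SDs-zero with equal means gives an undefined t statistic.
* Blank images raise "no plot found"; images with more than one plausible
  panel raise an ambiguity error listing the candidates; a geometry whose
  loci fall outside the image is an error rather than a clipped sample.
* Symbol ties at a calibration boundary resolve to the less significant
  category with a warning.
* All randomness (field sampling, jitter, noise) flows from explicit seeds;
  datasets are bit-reproducible from `(n, class_mix, seed, style)`.

## Problem sizes used in the checks

The shipped checks run the full pipeline at the study scale — one
168-record set for the headline agreement statistics (about 40 s) — plus a
200-case parser round-trip sweep across both patterns, both eyes, three
cell sizes, two glyph families, margins up to 20 px and rescaling in
[0.75, 1.5]. Band-boundary checks sweep every count for both denominators
exhaustively.

## Limitations

* Single-field staging only: no progression analysis, no visual-field
  index, no total-deviation computation.
* One cropped pattern-deviation panel per image; full single-field-analysis
  printouts are not segmented.
* HPA only (thresholds configurable; other schemes are out of scope).
* The clinical fidelity caveats of the synthetic generator above.
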