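# hpagrade

Automated Hodapp-Parrish-Anderson (HPA) staging of glaucomatous visual
field defects from Humphrey-style perimetry results.

Interpreting visual fields is central to glaucoma diagnosis, staging and
prognostication, but manual application of standardised criteria is slow,
so day-to-day grading is often subjective. `hpagrade` re-implements an
automatic HPA grader for clinicians and vision researchers: it takes the
three inputs a human grader reads off a printout — the mean deviation
(MD), the four central 5° global-plot sensitivities, and the
pattern-deviation probability plot (as numbers *or* as a PNG/JPEG/TIFF
image) — and returns the HPA stage with a full per-criterion breakdown.

## The criteria

Each criterion yields a grade in none < mild < moderate < severe; the
overall stage is the **maximum** (most severe wins):

| Criterion | none | mild | moderate | severe |
|---|---|---|---|---|
| Mean deviation (dB) | ≥ −1 | ≥ −6 | ≥ −12 | < −12 |
| Central 5° points | all > 15 dB | — | depressed (< 15 dB) in one hemifield | both hemifields, or any point = 0 dB |
| Loci at *P* < 5% | 0 | ≤ 25% | ≤ 50% | > 50% |
| Loci at *P* < 1% | 0 | < 10/76 | < 20/76 | ≥ 20/76 |

Proportions are used (not counts) so the rules transfer between the
54-locus 24-2 and 76-locus 30-2 patterns; all band comparisons are exact
integer cross-multiplications. Thresholds are configurable via
`hpa_thresholds()`.

The pattern-deviation plot image is parsed by an explicitly coded (not
machine-learned) vision pipeline: global Otsu binarisation → panel frame
detection (or symbol-mass bounding box plus grid refinement when no frame
is present) → superposition of the canonical test-locus grid → per-locus
symbol classification by ink density against a calibration table, with
near-boundary cells flagged for review. Every intermediate is available
for inspection (`plot_overlay()` draws the superimposed grid).

## Worked example

```r
library(hpagrade)

# a field with 20 of 76 loci depressed below P < 1%, mild MD
rec <- field_record("right", md = -3, central = c(20, 20, 20, 20),
                    pd = pd_matrix("30-2", c(rep("P1", 20), rep("NS", 56))))
grade_field(rec)
#> <graded_field> overall: severe
#>   MD: mild | central: none | P<5% (20/76): mild | P<1% (20/76): severe
```

The 1% criterion (20/76 ≥ 20/76) dominates the mild MD: the field is
staged severe. From an image instead:

```r
rp <- render_pattern_plot(rec$pd, "right", render_style(cell_px = 32), seed = 1)
pd <- parse_pattern_plot(rp$image, "30-2", "right")
count_depressed(pd, "p1")
#> $count
#> [1] 20
#>
#> $total
#> [1] 76
```

End-to-end validation against known ground truth:

```r
ds <- make_validation_set(n = 168, seed = 42)   # synthetic clinic case mix
v  <- validate_dataset(ds)                      # image -> matrix -> rules
v
#> <hpa_validation> n = 168 (0 parse failures)
#>   kappa = 1.00, accuracy = 100.0%
#>   severe-vs-rest: sensitivity 100.0%, specificity 100.0%, F1 100.0%
#>   any-defect: sensitivity 100.0%, specificity undefined
```

κ is Cohen's unweighted kappa between pipeline grades and ground truth;
the any-defect specificity is *undefined* (not 0) because the clinic-style
mixture contains no defect-free fields, so there are no true negatives —
undefined metrics are first-class throughout. The timing comparison of the
original validation (tool-assisted vs manual grading) is reproducible from
its summary statistics:

```r
t_test_summary(26.5, 3.3, 20, 48.6, 28.4, 20)
#>   estimate statistic parameter p_value method
#> 1    -22.1     -3.46      19.5 0.00259 Welch two-sample t-test
```

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gfdc.R", package="hpagrade"))') \
  grade --md -21 --central 20,20,20,20 --image plot.png --eye right
```

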