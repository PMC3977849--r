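---
title: "pombetrack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pombetrack: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombetrack)
```

# The measurement problem

Fission yeast (*Schizosaccharomyces pombe*) grown as a dense monolayer in a
microfluidic microchemostat can be followed for days, yielding tens of
thousands of cell cycles per experiment. The chambers are subdivided by
wall structures ("highways") into lanes that guide the rod-shaped cells
toward the outlet; imaging slightly out of focus renders cell contours
dark and division septa bright on a mid-gray background, so no fluorescent
marker is needed. `pombetrack` implements the full analysis chain for such
movies:

1. **lane splitting** — each frame is cut into the 5 lanes defined by the
   highway walls (`split_lanes()`, `detect_lanes()`);
2. **segmentation** — per-lane thresholding and outlining, feature
   extraction, non-cell rejection, and triage of contours into *single* /
   *too large* (> 20 px = 4.6 µm across) / *too long* (> 13 µm), with
   refinement of the latter two (`segment_movie()`, `refine_contour()`);
3. **tracking** — greedy local frame-to-frame matching with strict gates,
   backed by a global linear-assignment tracker (`track_movie()`);
4. **division detection** — Mexican-hat (Ricker) filtering of lengthwise
   intensity profiles to follow the septum (`detect_divisions()`);
5. **lineage reconstruction** — tracks plus divisions assembled into
   binary forests with census and completeness metrics (`build_forest()`,
   `census()`, `completeness()`);
6. **growth statistics** — per-cycle parameters and population summaries
   (`records_from_tracks()`, `summarize_records()`, and friends).

A synthetic movie generator (`simulate_colony()`) states a miniature
version of this world with full ground truth, so every stage is testable
at desk scale without external data.

# The growth model

Each cell cycle is described by six parameters: **birth length**
$L_b$, **division length** $L_d$ (the plateau at the end of the
elongation phase), **fission length** $L_f$ (a short, sharp terminal peak
caused by the reshaping just before the two daughters separate),
**elongation time** $T_e$, **septation time** $T_s$, and **elongation
rate** $r$. The doubling time is the identity

$$T_d = T_e + T_s,$$

which the extraction code preserves *exactly* for every emitted record.
Because of the terminal peak, daughters are born at half the fission
length, not half the division length:

$$L_b' = L_f / 2 .$$

The generator grows each cell linearly from $L_b$ to $L_d$ over $T_e$,
holds $L_d$ for $T_s$ (the plateau), switches to $L_f$ for the final
`fission_snap` (2 min), and then splits it symmetrically (a configurable
asymmetry SD is available). Division lengths follow the size-control law

$$L_d = \bar L_d + s\,(L_b - \bar L_b) + \varepsilon,$$

with `size_control_slope` $s$ (default 0.61, the steady-state value
measured on chip; $s = 0$ gives a pure sizer) and Gaussian noise
$\varepsilon$ scaled by `cv_lengths`.

## Generator defaults: the stated world

| parameter | default | unit | rationale |
|---|---|---|---|
| pixel size | 0.2304 | µm/px | 50 px = 11.52 µm on the reference setup |
| frame interval | 1 | min | the acquisition rate used for tracking |
| division length | 12.9 | µm | steady-state mean at 30 °C |
| fission length | 14.2 | µm | steady-state mean at 30 °C |
| birth length | 7.1 | µm | = fission/2 (the printed 7.3 µm is a measured value; the generator keeps its own invariant exact) |
| elongation time | 94.3 | min | 73% of a 129.3-min doubling time |
| septation time | 35 | min | the remaining 27% |
| `cv_lengths` | 0.10 | — | length distributions have ~10% CV |
| `cv_times` | 0.18 | — | elongation-time CV is 18% (septation 16%; one knob covers both) |
| septum appearance | 50% of plateau | — | the filtered septum signal appears around half of the growth plateau |
| `septum_peak_delay` | 14 | min | appearance → peak on the reference timeline (appearance 16 min, peak 30 min after a pre-septum frame) |
| `septum_fall_time` | 4 | min | bright septum → complete disappearance |
| lanes | 5 × 24 px × 1500 px | — | five highways; length chosen so a confluent chamber yields ~300 divisions in 6 h, the scale of the desk-size benchmark |
| advection | 0 → 1.5 px/frame | linear in x | cells near the sieve move slower than cells near the outlet |
| noise | σ = 3 | 8-bit units | frame-averaged camera noise; border/background contrast is ~90 units |
| rendering | axis-aligned capsules, dark 2-px contour, bright Gaussian septum band (σ = 2 px, peak +90) | | highway geometry constrains orientation; band width/contrast are not published and are exposed as parameters |

Cells never overlap: the pairwise exclusion constraints along a lane
reduce to a running maximum and are resolved before rendering (hard-core
displacement). Cells are eluted once fully past the outlet.

**What the generator does *not* emulate:** bent or tilted cells, focus
drift and illumination gradients, texture inside cells, mechanical
bending forces, partial monolayer failures, and fluorescence. A green
test therefore establishes that the *algorithms* are correct under the
stated geometry and noise, not that the pipeline is robust to every
artifact of a real microscope.

# Segmentation choices

* **Threshold** — per-lane Otsu by default (`seg_config(threshold=)`
  overrides); the published description says only "thresholding and
  outlining".
* **Outlining** — dark pixels are the contour tracery; every enclosed
  bright component is a candidate cell interior. Components touching the
  lane boundary are ambient background or partially imaged cells and are
  dropped, which automatically removes highway-wall artifacts (a wall is
  a line, never an enclosure).
* **Non-cell filters** — minimum area (30 px²; anything below 4 px² is
  always rejected), minimum transverse extent, and a bounding-box fill
  ratio. The published pipeline names "contours and textures" without
  formulas; these are the geometry-only equivalents that suffice in the
  synthetic world.
* **Length calibration** — length is the extent of the interior pixel
  cloud along its principal axis plus `2 * border_halfwidth` (the cell
  edge runs through the middle of the dark line) plus an
  orientation-dependent lattice gap, `|cosθ| − |sinθ|` px. The gap term
  is an empirical calibration: pixel centres undershoot a region
  boundary by ~1 px for lattice-aligned rods but much less for oblique
  ones. With it, rods measured at 0° and 30° agree within 2% and the
  mean error over 6–15 µm rods is below 0.25 µm. A medial-axis skeleton
  would handle bent rods but adds bias and cost for the straight
  capsules the highway geometry enforces.
* **Triage** — `too_large` means *transverse extent* above 20 px
  (4.6 µm): at ~2.3 µm cell radius that is exactly a double row of
  cells, which is what the category exists to catch. Whether the
  published "20 pixels" means width, diameter or area is not stated;
  width is this package's reading and is configurable. `too_large`
  takes precedence over `too_long`.
* **Refinement** — merged chains are cut at dark valleys of the
  lengthwise profile (prominence ≥ `valley_depth`), never producing
  pieces under 2 µm; a `too_large` object is also tried along its
  transverse profile. A genuinely long pre-division cell shows a
  *bright* septum, not a dark valley, and is correctly returned unsplit
  (flagged) — essential, because every cell exceeds the 13-µm triage
  bound during its fission peak (14.2 µm).

# Tracking choices

The local score between observations in consecutive frames is

$$S_{local} = w_1\,d + w_2\,|dx| + w_3\,|dy| +
  w_4\,\frac{|A_1-A_2|}{\max(A_1,A_2)} + w_5\,\Delta\theta,$$

infinite beyond one cell length (50 px = 11.52 µm). A pair is accepted
only if $S < 65$, the contours overlap, and the areas differ by ≤ 40%;
everything else stays unpaired — unpaired is cheaper than wrong. The
global tracker scores

$$S_{global} = v_1\,|L_1-L_2| + v_2\,\frac{|A_1-A_2|}{\max(A_1,A_2)} +
  v_3\,d$$

and solves a square linear-assignment problem with a per-cell no-match
alternative (a frame-by-frame reduction of the standard LAP-tracking
formulation). It runs only when the local pass leaves more than 30 cells
unpaired or the mean displacement exceeds 8 px (1.85 µm).

Decisions where the published text is not explicit:

* **Score coefficients** — the equations' coefficients are not legible in
  the source text; only the gates (65, 40%, 50 px, > 30, 8 px, every 50
  frames) are printed. Defaults are chosen so each term is in
  pixel-equivalent units (`local_weights = c(1, 1, 1, 20, 0.5)`), which
  puts true pairs of slowly drifting cells at scores ≈ 5–25, far below
  the printed gate of 65. All weights sit in `tracker_config()`.
* **Angular difference** — the acute angle between orientations, in
  [0°, 90°].
* **Area normalisation** — $|A_1-A_2|/\max(A_1,A_2)$ for both the 40%
  gate and the score terms, consistent with the global score's stated
  normalisation.
* **Overlap gate** — nonempty bounding-box intersection. For axis-aligned
  rods in lanes this equals the filled-contour intersection up to
  quantization and avoids storing pixel sets for whole movies.
* **Tie-breaking** — greedy selection orders by score, then smaller
  displacement, then lower observation ids; fully deterministic.
* **Minimal displacements** — a linear ramp from 0 px at the sieve to
  `min_disp_max` (3 px) at the outlet, applied only in the global pass;
  "too few cells paired" (the re-run trigger, no printed count) defaults
  to under half the cells, and the re-run doubles the ramp, once.
* **Track initiation** — any observation without an accepted predecessor
  starts a fresh track immediately. Daughter tracks must exist at the
  division frame for the lineage phase to link them, so initiation
  cannot wait for the periodic reseed; `reseed_interval` (50 frames)
  remains as the bookkeeping cadence reported in the diagnostics log.

# Division detection

For each cell a lengthwise intensity profile is convolved with a Ricker
(Mexican-hat) kernel whose scale matches the septum band width
(`kernel_width`, 3 px; the published material gives no width). The kernel
is forced to exact zero mean, so a flat profile gives exactly zero
response. Per track, the maximum response and its position form the
septum trace, smoothed with a 3-frame running median (at 1 frame/min the
4-min septum fall spans several frames, so a single-frame glitch is never
evidence).

A division is called when one — and only one — episode satisfies: response
above `baseline + 5·MAD` *and* an absolute floor (20 intensity units),
maximum within ±0.2 of mid-cell, concurrent length plateau, for at least
3 frames. The baseline comes from sub-floor frames only, so a septum
episode spanning most of a truncated track cannot contaminate its own
reference. The fission frame is the first frame whose response returns to
baseline (septum fully disappeared); if the parent contour splits first —
the usual case, since the septum vanishes at separation — the track ends
and the fission frame is the first frame after it. Ambiguous double-peak
traces are dropped (conservative), as are calls without two identifiable
daughters.

Daughters are the tracks starting within 2 frames of the fission whose
first contour genuinely overlaps the parent's final contour, one on each
side of the septum position; simultaneous divisions of neighbouring cells
are processed in frame order and cannot claim each other's daughters.
Whether the published pipeline calls division at the septum peak or at its
disappearance is implied but not stated; the disappearance convention is
used here, and the daughters' birth frame is the fission frame, which
avoids the linked-newborn length artifact at cycle starts.

# Lineage metrics

Trees are rooted at tracks without detected parents. With the root at
generation 1, a `g`-generation lineage is a root-anchored path with `g`
observed division cycles, and **completeness** of a tree evaluated at
`g` generations is (observed nodes at generation `g+1`) / $2^g$. The
worked example — both daughters observed, three of four granddaughters,
two great-granddaughters — is 75% complete as a 2-generation tree and 25%
complete as a 3-generation tree; `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` recompute exactly these numbers. `census()`
reports, per `g`, the number of lineages, the number of complete trees,
and mean completeness over trees reaching that depth.

# Growth-parameter extraction

* **Plateau detection** — an exact two-segment least-squares changepoint
  (linear ramp + flat plateau) over the length series, excluding the
  first 3 frames (linked-newborn artifact) and the last 3 (fission
  snap). A sliding-window slope threshold — the obvious alternative —
  detects the breakpoint ~3 frames late on average, a 3% bias on a
  94-min elongation phase that would exceed the 2% recovery requirement;
  the changepoint fit is unbiased for the stated piecewise growth model.
  Ties resolve to the earliest changepoint (growth "ceases" at the first
  flat frame).
* **Division length** — mean of the plateau segment; **fission length**
  — maximum over the last 10 frames; **elongation rate** — OLS slope of
  the ramp frames.
* **Septation time** starts at plateau onset (the non-elongating phase
  encompasses septation); whether it should instead start at septum
  appearance is ambiguous in the source and the plateau-onset convention
  is used throughout.
* **Complete cycles only** — records lacking an observed birth division
  or terminal division (founders, reseeds, eluted cells) are excluded
  from all summaries, for unbiased steady-state statistics.
* **Shift alignment** — `align_to_shift()` assigns each record the
  fraction of its cycle spent after the shift, clipped to [0, 1], with
  moving mean/SD series (30-min window by default; the published
  window is not stated).
* **Regression and sisters** — `birth_division_regression()` restricts
  to 6–10 µm birth lengths by default (0.5-µm bins for the distribution
  table); `sister_table()` pairs daughters that both completed a cycle,
  with the mother's division length and Pearson correlations.

# Validation against ground truth

`validate_against_truth()` plays the role of the manual-annotation
comparison used to estimate the original pipeline's accuracy, with the
simulator's truth replacing the annotator. Observations map to truth
cells by nearest same-frame centroid. Division recall is computed over
*observable* divisions — both daughters fully inside the imaged lane for
at least 3 frames — because a division whose products are immediately
eluted past the outlet is invisible to any in-frame method (a manual
annotator could not see it either). Growth-parameter recovery compares
measured means with the generator's ground truth *for the same cells that
were measured*, isolating measurement accuracy from the sampling noise of
which cycles happen to complete on screen; the nominal configured values
are reported alongside.

On the seeded default benchmark (5 lanes, 360 frames, ~300 divisions)
the suite requires and achieves: division recall ≥ 95% with no false
calls, false-link rate ≤ 1%, all growth-parameter means within 2%, and
the doubling-time identity exact for every record.

# Numerical and engineering notes

* No TIFF or raster-image package is available in the target
  environment, so the package carries a minimal multi-page uncompressed
  grayscale TIFF reader/writer (`write_tiff()`, `read_tiff()`),
  cross-checked against an independent Python implementation in the test
  suite. Likewise the Hungarian/shortest-augmenting-path LAP solver
  (`solve_lap()`) is implemented in-package and tested against exhaustive
  enumeration.
* Connected components use run-length encoding with union-find; all
  pixel work is vectorised base R, keeping the full benchmark (simulate,
  segment, track, divide, summarise 360 frames) under 5 minutes on one
  CPU.
* Coordinates are 1-based (R convention) with `(x = column, y = row)`;
  orientations are degrees in [−90, 90) with rows growing downward.
* Optional figure outputs are deliberately not produced; all results are
  plain tables (CSV) plus Newick/text lineages, which is what the tests
  can verify.

# Known limitations

* Segmentation assumes enclosed dark contours; heavily broken borders
  (very high noise, strong defocus drift) degrade it in ways the
  synthetic world does not probe.
* The tracker links frame to frame only; there is no multi-frame
  gap-closing, by design (the original pipeline is also frame-by-frame).
* Division detection needs the septum episode visible within a track;
  divisions during long segmentation dropouts are recovered only as new
  roots after reseeding, not as lineage links.
* Real-data headline numbers (e.g. 107 103 one-generation tracks, 19
  ten-generation lineages) require the original 50-hour movies and are
  out of scope; the corresponding quantities here are computed on
  synthetic data only.
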