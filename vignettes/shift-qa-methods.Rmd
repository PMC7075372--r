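---
title: "Couch-shift automation and user-origin QA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Couch-shift automation and user-origin QA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtshift)
```

## The problem

At CT simulation, three radiopaque markers (two lateral, one on the anterior
or posterior surface) are taped to the patient at the skin marks. The planner
then sets the plan's *user origin* at the intersection of those markers. If
the treatment isocenter is placed away from the user origin, therapists must
shift the patient from the marks to the isocenter at the first treatment.
Two well-known error pathways feed incident-learning databases here: shift
instructions that are miscalculated or mistranscribed (wrong sign, wrong
axis, wrong unit), and a user origin that was never actually set at the
marks, which silently corrupts every shift computed from it.

`rtshift` automates both defenses: it computes and renders the shift
instructions (the "Treat Sheet"), and it independently re-derives the user
origin from the marker contours and flags plans that disagree beyond a
tolerance.

## Coordinate model

All geometry lives in one of two frames, carried explicitly on every vector
(`vec3()`), and mixing frames is a hard error — the bug class being
eliminated is precisely a frame/sign confusion:

* **DICOM patient frame (LPS)**: $+x$ toward patient left, $+y$ posterior,
  $+z$ superior, in millimeters.
* **IEC 61217 fixed frame**: $+X$ toward the observer's right facing the
  gantry, $+Y$ toward the gantry, $+Z$ up.

For each of the eight standard patient position codes the map between the
frames is the unique proper rotation consistent with the pose. Writing the
patient axes $L, P, S$ in room coordinates (head-first poses point $S$ at
the gantry, the surface lain on fixes "down", and $L = P \times S$ by the
right-handedness of LPS), the matrix columns are those axis vectors:

| code | $(x,y,z) \mapsto (X,Y,Z)$ |
|------|---------------------------|
| HFS  | $(x, z, -y)$  |
| HFP  | $(-x, z, y)$  |
| FFS  | $(-x, -z, -y)$ |
| FFP  | $(x, -z, y)$  |
| HFDR | $(y, z, x)$   |
| HFDL | $(-y, z, -x)$ |
| FFDR | $(-y, -z, x)$ |
| FFDL | $(y, -z, -x)$ |

Each is a signed permutation with determinant $+1$; the test suite rebuilds
the whole table from the axis-composition argument above and verifies
orthogonality, determinant, and the group relations (e.g. HFS and HFP
differ by a 180° rotation about IEC $Y$). Oblique/non-standard orientations
and the gantry/collimator/couch-rotation sub-frames of IEC 61217 are out of
scope.

## The shift instruction

The shift is $\Delta = \text{isocenter} - \text{user origin}$ in the patient
frame, labeled per axis with anatomical direction words ($+x \to$ Left,
$+y \to$ Posterior, $+z \to$ Superior; magnitudes are absolute values), and
additionally reported as IEC fixed-frame components. Both vocabularies are
emitted on the sheet because clinical usage mixes them; emitting both
removes the ambiguity.

Numerical choices:

* **Units are hardcoded to centimeters.** Wrong units (cm vs mm) are a
  classic transcription error; every rendered shift line carries `cm` and
  the renderer never emits `mm` on a shift line. Not configurable by
  design.
* **Rounding**: mm/10, round-half-even to 2 decimals — unbiased and
  reproducible. Pre-rounding values are retained in the instruction object
  (`dicom_mm`, `iec_mm`) so nothing is lost.
* **Zero threshold**: components under 0.5 mm print as "No shift
  (0.00 cm)"; 0.5 mm is below couch-positioning resolution. Configurable
  per call (`zero_mm`).

Plan-to-plan shifts ($\Delta = \text{iso}_B - \text{iso}_A$) are only
defined for plans on the same CT scan: the frame-of-reference UIDs must
match and the patient position must be identical, otherwise the operation
errors out.

Manual overrides are supported (in-room setups, e.g. electrons) but
audited: the operator id is mandatory, the original computed values are
retained in the override record, and every render — text, JSON, PDF —
carries a MANUAL OVERRIDE banner. A sheet whose instruction claims
`OVERRIDDEN` without a record (or vice versa) refuses to render at all,
which is deliberately stricter than rendering without the banner.

## The user-origin check

The marker intersection is computed exactly as the clinical rule states:
$y$ and $z$ are the means over the two lateral markers; $x$ comes from the
anterior/posterior marker alone. The AP marker's $y$ and $z$ are ignored
even though averaging $z$ over all three markers might seem natural — the
check re-implements the stated rule, not an "improved" one. When both an
anterior and a posterior marker are contoured, their $x$ coordinates are
averaged; this is our reading of the under-specified "average anterior and
posterior coordinate" behavior, adopted as a design decision.

Each marker is reduced to the centroid (per-axis mean) of its contour
vertices — the markers are BBs a few millimeters across, so the centroid is
the natural point estimate and is invariant under vertex reordering.

* **Matching**: ROI names are matched with case-insensitive globs; defaults
  cover `BB`/`MARKER` with `LT/LEFT`, `RT/RIGHT`, `ANT/POST` tokens and are
  configurable, since the naming convention itself is site-specific.
  Exactly one ROI must match per role. A missing role makes the check
  **NOT-EVALUABLE** — a distinct outcome (CLI exit 3) that is never
  conflated with PASS: a safety check must fail loudly. Multiple matches
  are an ambiguity error, likewise not evaluable.
* **Geometric fallback** (opt-in): with exactly three unlabeled contours,
  the two with extreme $x$ are the laterals and the middle one is the AP
  marker. The layout is refused as ambiguous when the lateral $x$-span is
  under 20 mm (real lateral markers sit decimeters apart) or the AP
  marker's $x$ falls outside the central half of the lateral interval;
  the thresholds are a design choice where the field gives none.
* **Deviation metric**: the flag fires when the *Euclidean norm* of
  (expected − actual) strictly exceeds the tolerance. The norm is
  rotation-invariant and conservative; per-axis deltas are always reported
  alongside so the reviewer sees which axis drifted.
* **Tolerance default 2.0 mm.** The clinical record this tool re-enacts
  caught offsets from 2.7 mm up; the default must sit below that smallest
  real error yet above contouring noise (sub-millimeter). Configurable in
  the config file and on the CLI.

## What the synthetic generator emulates — and what it does not

`fixture_spec()`/`generate_bundle()` write complete DICOM bundles (one
16×16 CT slice with correct geometry tags, an RT Structure Set with the
three marker rings, one RT Plan per isocenter) on a shared frame of
reference, plus a ground-truth record. The stated world:

* lateral markers ≈ ±115 mm off midline, an anterior surface marker at
  $y \approx -92$ mm — a thorax-scale setup;
* marker contours are planar 8-vertex rings of 2 mm radius (realistic BB
  contour scale, exercises centroid averaging);
* per-vertex jitter uniform within ±0.05 mm per coordinate, seeded, and
  **mean-centered per ring**, so centroids (and therefore ground truth)
  are exact while the vertices still wobble;
* exported coordinates follow the common TPS convention of placing the
  user origin at the DICOM origin; an injected `origin_offset` therefore
  shows up as the marker intersection sitting at $-\text{offset}$;
* the default isocenter offset (15, 0, −42) mm is the package's worked
  example (Left 1.50 cm / Inferior 4.20 cm under HFS);
* coordinates are serialized as DICOM decimal strings with six decimals,
  quantizing geometry at $5\times10^{-7}$ mm — inside every stated
  $10^{-6}$ mm recovery tolerance.

A green test on these bundles establishes that the pipeline recovers known
geometry through real DICOM encode/decode for all eight positions and that
verdicts match construction. It does **not** establish robustness to the
mess of clinical data: multi-slice CTs, contour resampling, vendor-private
tags, oblique image orientations, >3-marker setups, or TPSs whose exports
do not place the user origin at the DICOM origin (for those, pass the
origin explicitly).

## DICOM subset

No DICOM toolkit is assumed: the package carries a minimal Part-10
reader/writer restricted to explicit VR little endian — the only transfer
syntax accepted; anything else is a parse error, never a silent guess. The
reader handles defined- and undefined-length sequences and is tested
against byte-level fixtures assembled independently of the writer. Plans
must expose exactly one isocenter: beams whose isocenters differ by more
than 0.01 mm are rejected ("multi-isocenter plan unsupported") because a
single shift instruction is only well-defined for one isocenter.

## Known limitations

* Config files are JSON only (no YAML parser in the supported dependency
  set).
* The PDF render is a plain single-page monospaced sheet, not a replica of
  any clinical form layout.
* The user-origin default (DICOM origin) is an export convention, not a
  DICOM-standard fact; sites whose TPS exports differently must supply
  `--origin`.
* Decubitus positions are supported in the transform and the generator,
  but marker-role inference assumes the markers were placed in the usual
  supine/prone arrangement at simulation.
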