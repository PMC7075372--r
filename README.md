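# rtshift

Automation for two of the most common radiotherapy setup-error pathways:
**wrong couch-shift instructions** and **an incorrectly set user origin**.

At CT simulation, three radiopaque markers (two lateral, one anterior or
posterior) mark the setup point on the patient. The planner sets the plan's
*user origin* at the intersection of those markers; if the isocenter is
elsewhere, therapists shift the patient from the marks to the isocenter at
the first treatment. `rtshift` provides, vendor-neutrally:

* **Treat Sheet** — computes the shift $\Delta = \text{isocenter} -
  \text{user origin}$ in the DICOM patient (LPS) frame, transforms it into
  the IEC 61217 fixed frame with the proper rotation for the patient
  position (all eight codes: HFS, HFP, FFS, FFP, HFDR, HFDL, FFDR, FFDL),
  labels it with anatomical direction words, and renders a printable sheet
  (text / JSON / PDF) with values **hardcoded to centimeters**. Plan-to-plan
  shifts are supported for plans on the same CT scan. Manual overrides are
  allowed but audited: operator id required, original values retained, and
  a MANUAL OVERRIDE banner on every render.
* **Origin check** — re-derives the user origin from the marker contours
  (y and z: mean of the two lateral markers; x: from the anterior/posterior
  marker) and flags the plan when it differs from the plan's user origin by
  more than a tolerance (default 2.0 mm, Euclidean). A missing or ambiguous
  marker makes the check NOT-EVALUABLE — loudly distinct from PASS.
* A minimal DICOM reader/writer (explicit VR little endian; CT / RT Plan /
  RT Structure Set geometry only) and a **synthetic fixture generator**
  that emits complete DICOM bundles with known ground truth, so everything
  is testable without clinical data.

## Worked example

```r
library(rtshift)

# a synthetic bundle: HFS, isocenter 15 mm left / 42 mm inferior of the
# marks, and a deliberately mis-set user origin 2.7 mm off the markers
spec <- perturb_origin(fixture_spec(seed = 42), c(2.7, 0, 0))
b    <- generate_bundle(spec)

run_origin_check(b$rtstruct, rtplan_file = b$rtplan[1])
#> User origin check: FLAG
#>   expected (marker intersection): (-2.700, 0.000, -0.000) mm
#>   actual (plan user origin):      (0.000, 0.000, 0.000) mm
#>   deviation: (-2.700, 0.000, -0.000) mm, |delta| = 2.700 mm (tolerance 2.00 mm)
#>   ** User origin is NOT at the intersection of the simulation markers **

cat(render_treat_sheet(treat_sheet(read_plan_geometry(b$rtplan[1])), "text"))
#> ==============================================
#>                  TREAT SHEET
#> ==============================================
#> Patient ID:       SYN-000001
#> Plan:             PLAN1
#> Patient position: HFS
#>
#> Shifts from setup marks (user origin) to isocenter:
#> Lateral (left/right):    Left 1.50 cm
#> Vertical (ant/post):     No shift (0.00 cm)
#> Longitudinal (sup/inf):  Inferior 4.20 cm
#> IEC 61217 fixed frame [X, Y, Z]: +1.50, -4.20, +0.00 cm
#> ...
```

The check FLAGs because the 2.7 mm injected origin error exceeds the 2.0 mm
tolerance; the sheet reads the plan's isocenter (15, 0, −42) mm and prints
it as Left 1.50 cm / Inferior 4.20 cm (LPS: +x left, −z inferior), with the
IEC fixed-frame components as a second vocabulary.

## Command line

```sh
exec/rtshift gen-fixture --position HFS --offset 0,10,0 --seed 9 --out /tmp/fx
exec/rtshift origin-check /tmp/fx/rs.dcm --rtplan /tmp/fx/rp1.dcm --json
exec/rtshift treat-sheet /tmp/fx/rp1.dcm --format pdf --out sheet.pdf
```

Exit codes are the machine contract: `0` success/PASS, `1` usage or parse
error, `2` FLAG, `3` check not evaluable. Configuration (naming patterns,
tolerance, default format, origin override) is a JSON file passed with
`--config`.

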