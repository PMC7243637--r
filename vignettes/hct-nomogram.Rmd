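---
title: "Hematocrit mass balance and the alignment-chart nomogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hematocrit mass balance and the alignment-chart nomogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hctnomo)
```

## The model and its assumptions

The package treats circulating blood as two conserved tallies — red-cell
volume (RBC, ml) and plasma — with hematocrit always the derived ratio
`Hct = RBC / BV × 100`. Blood volume is taken as weight-proportional,
`BV = w × bv_per_kg`, with `bv_per_kg = 75` ml/kg by default. Three
assumptions do all the work:

1. **Weight-proportional blood volume.** 75 ml/kg holds from about one
   month after term delivery through most of adulthood. It *underestimates*
   BV in premature neonates (85–100 ml/kg) and *overestimates* it in the
   elderly and obese (~70 ml/kg). Both cases are handled by overriding
   `bv_per_kg` on the `patient_profile`; the package never switches the
   rule automatically from the `age_class` label, because the choice is a
   clinical judgment, not a deterministic function of age.
2. **Red-cell conservation under fluid shifts.** Crystalloid infusion,
   urinary and insensible losses, and dehydration change the denominator
   only. Whole-blood loss removes red cells at the hematocrit of the blood
   actually leaving the body — the *current* state's hematocrit when the
   event occurs mid-sequence.
3. **Equilibration.** The closed form for hematocrit after hemorrhage,
   `Hct_f = Hct_i (BV_i − V)/BV_i`, assumes the blood volume is restored to
   its pre-loss value by RBC-free fluid (interstitial recruitment, plasma,
   or crystalloid). Its accuracy in practice depends entirely on that
   restoration having happened; the event engine expresses partial
   restoration explicitly (`blood_loss` followed by a `crystalloid_in` of
   any size) for when it has not.

The closed forms (`hct_after_blood_loss`, `hct_after_infusion`,
`hct_after_dehydration`) are each the limit of the same two-compartment
bookkeeping, and the test suite checks them against an independently coded
tally simulation on a thousand random states.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `bv_per_kg` | ml/kg | 75 | the weight-to-blood-volume rule; override to 85–100 (premature) or 70 (elderly/obese) |
| `packed_rbc_hct` | fraction | 0.65 | hematocrit of a packed red-cell unit; each ml transfused credits 0.65 ml RBC |
| `donor_hct` | percent | patient's initial Hct | whole-blood transfusion is modelled as negative blood loss unless the donor unit's Hct is given |
| `lb_per_kg` | — | 2.20462 | display-only pound labels on the chart |

Hct is **percent at every public interface** and a fraction only inside
formulas. Volumes are unrounded real ml everywhere in the engine; rounding
(0.1% for Hct, 1 ml for volumes, 0.1 L for deficits) happens only at the
CLI/print layer, which is why `--json` output is exact.

## Event semantics and edge cases

- Losing the entire blood volume is rejected rather than returning 0%: the
  restoration assumption is meaningless at total exsanguination.
- Negative volumes are rejected everywhere; a transfusion is an event kind,
  not a negative loss.
- Dehydration may remove at most the plasma volume; the boundary case
  (hematocrit exactly 100%) is allowed, one drop more is an error.
- Packed red cells add their **full unit volume** to BV and `0.65 × V` to
  RBC. Adding the carrier volume keeps `0 ≤ Hct ≤ 100` invariant and
  conserves volume; crediting only the red-cell mass to a separate tally
  would let the ratio exceed 100% in corner cases.
- Event order is physically meaningful: `[blood_loss, crystalloid_in]`
  removes red cells at the undiluted hematocrit, the reverse order at the
  diluted one. The worked operating-room scenario uses the loss-first
  order, and a regression test pins both.
- Insensible losses are always user-supplied volumes. Estimating them needs
  operative context and experience; no heuristic is built in.

## The inverse estimators

`estimate_blood_loss` inverts the equilibrated-loss formula:
`V = BV (Hct_pre − Hct_post)/Hct_pre` — the red-cell volume lost divided by
the pre-loss hematocrit as a decimal. `estimate_fluid_deficit` uses
red-cell conservation to recover the pre-dehydration weight from the
current weight and hematocrit plus a baseline hematocrit, and reports the
weight difference as a water deficit at the fixed equivalence 1 kg = 1 L.
A baseline above the current hematocrit means net fluid *gain*; the
negative deficit is returned with an explicit `fluid_gain = TRUE` flag
instead of an error, since the arithmetic is equally valid in that
direction.

The dehydration worked example assumes a pre-dehydration hematocrit of 35%
(`FIG5_BASELINE_HCT`). That number is a clinical-judgment input, not model
output; it is a named constant so nobody mistakes it for physiology.

## Chart construction

All three axes are **logarithmic**. The governing relation is
multiplicative, and in logs it is additive,
`log RBC = log BV + log Hct − 2`, which the classical parallel-scale
construction realizes exactly: outer axes at `x = 0` and `x = D` with
moduli `m1`, `m2` (mm per decade), middle axis at `x = D·m1/(m1+m2)` with
modulus `m1·m2/(m1+m2)` and intercept chosen so the three scale points of
any valid `(BV, Hct, RBC)` triple are collinear. A linear-scale chart could
only approximate this relation, so the scale type is a load-bearing design
choice, not a styling preference.

Numerical choices, stated once:

- Chart coordinates are mm, y increasing **upward**, origin at the
  bottom-left of the drawing area; larger values always sit higher.
- Outer moduli are equal by default (middle axis centered); the largest
  moduli that keep both outer scales inside the drawing height are used, and
  each outer scale is centered vertically on its log-midpoint.
  `modulus_ratio` supports asymmetric layouts; the alignment property is
  preserved for any ratio and the tests sweep one.
- Default ranges: pediatric weight 1–20 kg, adult 30–150 kg, hematocrit
  10–70% for both. These cover the worked scenarios plus physiologic
  extremes; the published charts' actual ranges and scale types are not
  machine-readable, so these are engineering defaults, all overridable.
- The red-cell axis range is derived as
  `[BV_min·Hct_min, BV_max·Hct_max]/100`, so no in-range alignment can run
  off the middle scale.
- "Subtract the blood loss on the BV scale" is arithmetic on the *value*
  before mapping to the scale — exactly how a clinician uses the printed
  chart — not graphical subtraction of lengths.
- The virtual straight-edge (`isopleth_read`) is exact analytic geometry:
  a line through two axis points intersected with the third axis, inverted
  through the scale map. The 1e-6 relative agreement tolerance against the
  algebraic engine covers floating point only.
- `collinearity_residual` measures, on the middle-axis line, the distance
  between the true RBC scale point and the isopleth's intersection; it is
  ~1e-13 mm across a 50×50 grid for a correct geometry and visibly nonzero
  when a modulus is deliberately corrupted by 1%, which the tests use as a
  negative control.

## Rendering and CLI

SVG output is assembled as plain text with fixed 3-decimal formatting and
no timestamps, so identical inputs are byte-identical — a property the
tests assert and that a graphics-device route would not give. Ticks follow
a 1-2-5-per-decade major pattern with integer-mantissa minors; the left
axis carries dual labels, with the weight tick `w` kg placed at exactly the
height of the BV tick `75·w` ml. Pound labels (display-only) and a
four-line usage summary are opt-in.

The CLI (`hct_cli()`, wrapped by `inst/cli/hctnomo.R`) exposes the whole
toolkit with stable exit codes (0 success, 2 validation, 1 unexpected) and
a stable JSON schema; `--verbose` echoes the per-event audit trail.

## What the tests do and do not establish

The test fixtures are the four worked clinical scenarios plus seeded random
draws from physiologic ranges (BV 50–10 000 ml, Hct 5–65%). Green tests
establish internal consistency: closed forms agree with independent
bookkeeping, inverse estimators undo forward models, and the chart agrees
with the algebra to floating-point accuracy. They do **not** establish
clinical validity — the 75 ml/kg rule's error in any given patient, the
accuracy of estimated blood loss in the field, or the equilibration
assumption's realism on any time scale. No compartment kinetics, infusion
rates, coagulation effects, or hemoglobin conversion are modelled.
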