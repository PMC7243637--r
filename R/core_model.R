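# Core mass-balance algebra relating body weight, blood volume (BV),
# red-cell volume (RBC), and hematocrit (Hct).
#
# Conventions used throughout the package:
#   - Hct is a PERCENT at every public interface; it becomes a fraction only
#     transiently inside formulas.
#   - Volumes are real numbers in ml; nothing in the engine rounds. Rounding
#     to display precision happens only in the CLI / print methods.

#' Signal a validation error
#'
#' Validation failures carry the condition class `hctnomo_validation_error`
#' so callers (notably the CLI, which maps them to exit code 2) can tell
#' bad user input apart from internal faults.
#'
#' @param ... passed to [sprintf()] to build the message.
#' @keywords internal
abort_validation <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("hctnomo_validation_error", "error")))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("`%s` must be a single finite number, got %s",
                     name, deparse(substitute(x)))
  invisible(x)
}

#' Patient profile
#'
#' Bundles body weight with the per-kilogram blood-volume rule. The default
#' rule is 75 ml/kg, which holds from about one month after term delivery
#' through most of adult life. Premature neonates run higher (roughly
#' 85-100 ml/kg) and the elderly/obese lower (about 70 ml/kg); both are
#' expressed by overriding `bv_per_kg`, never auto-applied from `age_class`.
#'
#' @param weight body mass in kg; must be positive.
#' @param age_class one of `"infant"`, `"premature"`, `"adult"`. Descriptive
#'   only: it selects chart ranges downstream but never changes `bv_per_kg`.
#' @param bv_per_kg blood volume per unit mass, ml/kg (default 75).
#' @return an object of class `patient_profile`.
#' @examples
#' p <- patient_profile(12)
#' blood_volume(p)  # 900 ml
#' @export
patient_profile <- function(weight,
                            age_class = c("infant", "premature", "adult"),
                            bv_per_kg = 75) {
  age_class <- match.arg(age_class)
  check_scalar(weight, "weight")
  check_scalar(bv_per_kg, "bv_per_kg")
  if (weight <= 0)
    abort_validation("`weight` must be > 0 kg (got %g)", weight)
  if (bv_per_kg <= 0)
    abort_validation("`bv_per_kg` must be > 0 ml/kg (got %g)", bv_per_kg)
  structure(list(weight = weight, age_class = age_class,
                 bv_per_kg = bv_per_kg),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %g kg (%s), %g ml/kg -> BV %g ml\n",
              x$weight, x$age_class, x$bv_per_kg, blood_volume(x)))
  invisible(x)
}

#' Model constants
#'
#' @param packed_rbc_hct hematocrit of a packed red-cell unit as a fraction;
#'   default 0.65 (packed cells are approximately 65% red cells).
#' @param lb_per_kg pounds per kilogram, used only for display labels.
#' @param percent_tolerance relative tolerance for round-trip identities.
#' @return an object of class `model_config`.
#' @export
model_config <- function(packed_rbc_hct = 0.65,
                         lb_per_kg = 2.20462,
                         percent_tolerance = 1e-9) {
  check_scalar(packed_rbc_hct, "packed_rbc_hct")
  if (packed_rbc_hct <= 0 || packed_rbc_hct >= 1)
    abort_validation("`packed_rbc_hct` must lie in (0, 1) (got %g)",
                     packed_rbc_hct)
  structure(list(packed_rbc_hct = packed_rbc_hct,
                 lb_per_kg = lb_per_kg,
                 percent_tolerance = percent_tolerance),
            class = "model_config")
}

#' Blood state
#'
#' Whole-blood volume and red-cell volume; hematocrit is always derived as
#' `rbc / bv * 100`, never stored independently.
#'
#' @param bv whole-blood volume in ml, > 0.
#' @param rbc red-cell volume in ml, with `0 <= rbc <= bv`.
#' @return an object of class `blood_state` with elements `bv`, `rbc`, and
#'   the derived `hct` (percent).
#' @export
blood_state <- function(bv, rbc) {
  check_scalar(bv, "bv")
  check_scalar(rbc, "rbc")
  if (bv <= 0) abort_validation("`bv` must be > 0 ml (got %g)", bv)
  if (rbc < 0) abort_validation("`rbc` must be >= 0 ml (got %g)", rbc)
  if (rbc > bv)
    abort_validation("`rbc` (%g ml) cannot exceed `bv` (%g ml)", rbc, bv)
  structure(list(bv = bv, rbc = rbc, hct = rbc / bv * 100),
            class = "blood_state")
}

#' @export
print.blood_state <- function(x, ...) {
  cat(sprintf("<blood_state> BV %.0f ml, RBC %.0f ml, Hct %.1f%%\n",
              x$bv, x$rbc, x$hct))
  invisible(x)
}

#' Blood volume from body weight
#'
#' `BV = weight * bv_per_kg`. With the 75 ml/kg default this is the left
#' axis of the nomogram: the BV read opposite the body weight.
#'
#' @param profile a [patient_profile()].
#' @return blood volume in ml.
#' @export
blood_volume <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  profile$weight * profile$bv_per_kg
}

#' Red-cell volume from blood volume and hematocrit
#'
#' @param bv whole-blood volume in ml, > 0.
#' @param hct hematocrit in percent, within \[0, 100\].
#' @return red-cell volume in ml: `bv * hct / 100`.
#' @export
rbc_volume <- function(bv, hct) {
  check_scalar(bv, "bv"); check_scalar(hct, "hct")
  if (bv <= 0) abort_validation("`bv` must be > 0 ml (got %g)", bv)
  if (hct < 0 || hct > 100)
    abort_validation("`hct` must lie in [0, 100] percent (got %g)", hct)
  bv * hct / 100
}

#' Hematocrit from red-cell and whole-blood volume
#'
#' The defining ratio `Hct = RBC / BV * 100`; exact inverse of
#' [rbc_volume()].
#'
#' @param rbc red-cell volume in ml, `0 <= rbc <= bv`.
#' @param bv whole-blood volume in ml, > 0.
#' @return hematocrit in percent.
#' @export
hct_of <- function(rbc, bv) {
  check_scalar(rbc, "rbc"); check_scalar(bv, "bv")
  if (bv <= 0) abort_validation("`bv` must be > 0 ml (got %g)", bv)
  if (rbc < 0) abort_validation("`rbc` must be >= 0 ml (got %g)", rbc)
  if (rbc > bv)
    abort_validation("`rbc` (%g ml) cannot exceed `bv` (%g ml)", rbc, bv)
  rbc / bv * 100
}

#' Hematocrit after blood loss with volume restoration
#'
#' Models loss of `v_lost` ml of whole blood at the initial hematocrit,
#' followed by restoration of the blood volume to its initial value by
#' red-cell-free fluid (interstitial recruitment, plasma, or crystalloid):
#' `Hct_f = Hct_i * (BV_i - BV_lost) / BV_i`.
#'
#' Loss of the entire blood volume is rejected: the restoration assumption
#' is meaningless at total exsanguination. Negative `v_lost` is rejected
#' too; transfusion is a distinct event, not negative loss.
#'
#' @param hct_i initial hematocrit, percent.
#' @param bv_i initial blood volume, ml.
#' @param v_lost whole-blood volume lost, ml, with `0 <= v_lost < bv_i`.
#' @return final hematocrit in percent.
#' @examples
#' hct_after_blood_loss(35, 900, 200)  # 27.22...
#' @export
hct_after_blood_loss <- function(hct_i, bv_i, v_lost) {
  check_scalar(hct_i, "hct_i"); check_scalar(bv_i, "bv_i")
  check_scalar(v_lost, "v_lost")
  if (bv_i <= 0) abort_validation("`bv_i` must be > 0 ml (got %g)", bv_i)
  if (hct_i < 0 || hct_i > 100)
    abort_validation("`hct_i` must lie in [0, 100] percent (got %g)", hct_i)
  if (v_lost < 0)
    abort_validation(
      "`v_lost` must be >= 0 ml (got %g); model transfusion as an event, not negative loss",
      v_lost)
  if (v_lost >= bv_i)
    abort_validation(
      "`v_lost` (%g ml) must be smaller than `bv_i` (%g ml): total exsanguination is not modelled",
      v_lost, bv_i)
  hct_i * (bv_i - v_lost) / bv_i
}

#' Hematocrit after infusion of red-cell-free fluid
#'
#' Red-cell volume is conserved while the denominator grows:
#' `Hct_f = Hct_i * BV_i / (BV_i + v_in)`.
#'
#' @param hct_i initial hematocrit, percent.
#' @param bv_i initial blood volume, ml.
#' @param v_in infused volume, ml, >= 0.
#' @return final hematocrit in percent.
#' @examples
#' hct_after_infusion(35, 450, 200)  # 24.23...
#' @export
hct_after_infusion <- function(hct_i, bv_i, v_in) {
  check_scalar(hct_i, "hct_i"); check_scalar(bv_i, "bv_i")
  check_scalar(v_in, "v_in")
  if (bv_i <= 0) abort_validation("`bv_i` must be > 0 ml (got %g)", bv_i)
  if (hct_i < 0 || hct_i > 100)
    abort_validation("`hct_i` must lie in [0, 100] percent (got %g)", hct_i)
  if (v_in < 0)
    abort_validation("`v_in` must be >= 0 ml (got %g)", v_in)
  hct_i * bv_i / (bv_i + v_in)
}

#' Hematocrit after loss of red-cell-free water
#'
#' Forward model of dehydration (urinary and gastrointestinal water loss):
#' red cells are conserved while the blood volume shrinks,
#' `Hct_f = Hct_i * BV_i / (BV_i - v_water_lost)`. This is the exact
#' inverse of [hct_after_infusion()]. At most the plasma volume
#' `bv_i * (1 - hct_i/100)` can be removed; at that boundary the
#' hematocrit reaches exactly 100%.
#'
#' @param hct_i initial hematocrit, percent.
#' @param bv_i initial blood volume, ml.
#' @param v_water_lost water volume lost from the circulation, ml.
#' @return final hematocrit in percent.
#' @export
hct_after_dehydration <- function(hct_i, bv_i, v_water_lost) {
  check_scalar(hct_i, "hct_i"); check_scalar(bv_i, "bv_i")
  check_scalar(v_water_lost, "v_water_lost")
  if (bv_i <= 0) abort_validation("`bv_i` must be > 0 ml (got %g)", bv_i)
  if (hct_i < 0 || hct_i > 100)
    abort_validation("`hct_i` must lie in [0, 100] percent (got %g)", hct_i)
  if (v_water_lost < 0)
    abort_validation("`v_water_lost` must be >= 0 ml (got %g)", v_water_lost)
  plasma <- bv_i * (1 - hct_i / 100)
  if (v_water_lost > plasma)
    abort_validation(
      "`v_water_lost` (%g ml) exceeds the plasma volume (%g ml): hematocrit would exceed 100%%",
      v_water_lost, plasma)
  hct_i * bv_i / (bv_i - v_water_lost)
}

#' Red-cell volume contributed by a packed red-cell unit
#'
#' Packed red cells have a hematocrit of approximately 65%, so a unit of
#' `v_packed` ml carries `v_packed * 0.65` ml of red cells (with the
#' default [model_config()]).
#'
#' @param v_packed packed red-cell volume transfused, ml, >= 0.
#' @param config a [model_config()]; supplies `packed_rbc_hct`.
#' @return red-cell volume in ml.
#' @examples
#' packed_rbc_to_rbc(100)  # 65
#' @export
packed_rbc_to_rbc <- function(v_packed, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  check_scalar(v_packed, "v_packed")
  if (v_packed < 0)
    abort_validation("`v_packed` must be >= 0 ml (got %g)", v_packed)
  v_packed * config$packed_rbc_hct
}
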