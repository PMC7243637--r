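# Event-sequence engine: applies an ordered list of fluid events to a
# patient's blood state, with a per-event audit trail, plus the two inverse
# estimators (blood loss from hematocrit; water deficit from weight and
# hematocrit) and the four worked-example fixtures.

EVENT_KINDS <- c("blood_loss", "crystalloid_in", "urine_out",
                 "insensible_out", "whole_blood_in", "packed_rbc_in",
                 "dehydration", "equilibrate_to_baseline")

#' Fluid event
#'
#' One typed change in intravascular volume. Semantics (applied to the
#' running state, in list order):
#' \describe{
#'   \item{blood_loss}{removes whole blood at the *current* hematocrit:
#'     `rbc -= hct/100 * volume`, `bv -= volume`.}
#'   \item{crystalloid_in}{adds red-cell-free fluid: `bv += volume`.}
#'   \item{urine_out, insensible_out, dehydration}{remove red-cell-free
#'     water: `bv -= volume`.}
#'   \item{whole_blood_in}{adds whole blood: `bv += volume`,
#'     `rbc += donor_hct/100 * volume`. `donor_hct` defaults to the
#'     patient's initial hematocrit, matching the view of whole-blood
#'     transfusion as negative blood loss.}
#'   \item{packed_rbc_in}{adds the unit volume and its red cells:
#'     `bv += volume`, `rbc += packed_rbc_hct * volume`.}
#'   \item{equilibrate_to_baseline}{restores `bv` to the profile's
#'     weight-predicted blood volume with red-cell-free fluid (`rbc`
#'     unchanged); `volume` is ignored and may be 0.}
#' }
#'
#' @param kind one of `"blood_loss"`, `"crystalloid_in"`, `"urine_out"`,
#'   `"insensible_out"`, `"whole_blood_in"`, `"packed_rbc_in"`,
#'   `"dehydration"`, `"equilibrate_to_baseline"`.
#' @param volume volume in ml, >= 0 (ignored for
#'   `equilibrate_to_baseline`).
#' @param donor_hct donor hematocrit in percent; only meaningful for
#'   `whole_blood_in`. `NULL` means "use the patient's initial Hct".
#' @return an object of class `fluid_event`.
#' @export
fluid_event <- function(kind, volume = 0, donor_hct = NULL) {
  kind <- match.arg(kind, EVENT_KINDS)
  check_scalar(volume, "volume")
  if (volume < 0)
    abort_validation("event `%s`: volume must be >= 0 ml (got %g)",
                     kind, volume)
  if (!is.null(donor_hct)) {
    check_scalar(donor_hct, "donor_hct")
    if (donor_hct < 0 || donor_hct > 100)
      abort_validation("`donor_hct` must lie in [0, 100] percent (got %g)",
                       donor_hct)
  }
  structure(list(kind = kind, volume = volume, donor_hct = donor_hct),
            class = "fluid_event")
}

#' @export
print.fluid_event <- function(x, ...) {
  extra <- if (!is.null(x$donor_hct))
    sprintf(" (donor Hct %.1f%%)", x$donor_hct) else ""
  cat(sprintf("<fluid_event> %s %g ml%s\n", x$kind, x$volume, extra))
  invisible(x)
}

#' Apply a sequence of fluid events
#'
#' Starts from the profile's weight-predicted blood volume at the given
#' initial hematocrit and applies each event in order, tracking whole-blood
#' and red-cell volume separately. Any event that would drive `bv <= 0`,
#' `rbc < 0`, or `rbc > bv` raises a validation error naming the offending
#' event index.
#'
#' @param profile a [patient_profile()].
#' @param hct_i initial hematocrit, percent.
#' @param events list of [fluid_event()] objects (possibly empty).
#' @param config a [model_config()].
#' @return an object of class `scenario_result` with elements:
#'   \describe{
#'     \item{initial}{the starting [blood_state()].}
#'     \item{trajectory}{list of [blood_state()] after each event (same
#'       length as `events`).}
#'     \item{final}{the last state (equals `initial` for empty `events`).}
#'     \item{final_hct}{final hematocrit, percent.}
#'     \item{audit}{data frame with one row per event: kind, volume, and
#'       the bv/rbc deltas and post-event values.}
#'   }
#' @examples
#' p <- patient_profile(12)
#' r <- apply_events(p, 35, list(fluid_event("blood_loss", 200),
#'                               fluid_event("equilibrate_to_baseline")))
#' r$final_hct  # 27.22...
#' @export
apply_events <- function(profile, hct_i, events, config = model_config()) {
  stopifnot(inherits(profile, "patient_profile"),
            inherits(config, "model_config"))
  check_scalar(hct_i, "hct_i")
  if (hct_i < 0 || hct_i > 100)
    abort_validation("`hct_i` must lie in [0, 100] percent (got %g)", hct_i)
  if (inherits(events, "fluid_event")) events <- list(events)
  if (!is.list(events) ||
      !all(vapply(events, inherits, logical(1), "fluid_event")))
    abort_validation("`events` must be a list of fluid_event objects")

  bv0 <- blood_volume(profile)
  state <- blood_state(bv0, rbc_volume(bv0, hct_i))
  trajectory <- vector("list", length(events))
  audit <- data.frame(event = integer(0), kind = character(0),
                      volume_ml = numeric(0), d_bv = numeric(0),
                      d_rbc = numeric(0), bv = numeric(0),
                      rbc = numeric(0), hct = numeric(0))

  for (i in seq_along(events)) {
    e <- events[[i]]
    bv <- state$bv; rbc <- state$rbc
    hct_cur <- state$hct
    switch(e$kind,
      blood_loss = {
        rbc <- rbc - hct_cur / 100 * e$volume
        bv <- bv - e$volume
      },
      crystalloid_in = bv <- bv + e$volume,
      urine_out = bv <- bv - e$volume,
      insensible_out = bv <- bv - e$volume,
      dehydration = bv <- bv - e$volume,
      whole_blood_in = {
        dh <- if (is.null(e$donor_hct)) hct_i else e$donor_hct
        bv <- bv + e$volume
        rbc <- rbc + dh / 100 * e$volume
      },
      packed_rbc_in = {
        bv <- bv + e$volume
        rbc <- rbc + config$packed_rbc_hct * e$volume
      },
      equilibrate_to_baseline = bv <- bv0
    )
    if (bv <= 0)
      abort_validation("event %d (%s, %g ml) drives blood volume to %g ml (must stay > 0)",
                       i, e$kind, e$volume, bv)
    if (rbc < 0)
      abort_validation("event %d (%s, %g ml) drives red-cell volume to %g ml (must stay >= 0)",
                       i, e$kind, e$volume, rbc)
    if (rbc > bv)
      abort_validation("event %d (%s, %g ml) drives red-cell volume (%g ml) above blood volume (%g ml)",
                       i, e$kind, e$volume, rbc, bv)
    new_state <- blood_state(bv, rbc)
    audit <- rbind(audit, data.frame(
      event = i, kind = e$kind, volume_ml = e$volume,
      d_bv = bv - state$bv, d_rbc = rbc - state$rbc,
      bv = bv, rbc = rbc, hct = new_state$hct))
    state <- new_state
    trajectory[[i]] <- state
  }

  structure(list(initial = blood_state(bv0, rbc_volume(bv0, hct_i)),
                 trajectory = trajectory,
                 final = state,
                 final_hct = state$hct,
                 audit = audit),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d event(s); final Hct %.1f%% (BV %.0f ml, RBC %.0f ml)\n",
              nrow(x$audit), x$final_hct, x$final$bv, x$final$rbc))
  if (nrow(x$audit)) print(x$audit, row.names = FALSE)
  invisible(x)
}

#' Estimate unmeasured blood loss from a hematocrit drop
#'
#' Back-calculation: the red-cell volume lost is
#' `BV * (hct_pre - hct_post) / 100`; dividing by the pre-loss hematocrit
#' taken as a decimal gives the whole-blood volume lost,
#' `BV * (hct_pre - hct_post) / hct_pre`. Exact inverse of
#' [hct_after_blood_loss()] under the volume-restoration assumption.
#'
#' @param profile a [patient_profile()].
#' @param hct_pre pre-loss hematocrit, percent, > 0.
#' @param hct_post post-loss (equilibrated) hematocrit, percent, with
#'   `hct_post <= hct_pre`.
#' @return estimated whole-blood loss in ml.
#' @examples
#' estimate_blood_loss(patient_profile(12), 35, 35 * 700 / 900)  # 200
#' @export
estimate_blood_loss <- function(profile, hct_pre, hct_post) {
  stopifnot(inherits(profile, "patient_profile"))
  check_scalar(hct_pre, "hct_pre"); check_scalar(hct_post, "hct_post")
  if (hct_pre <= 0 || hct_pre > 100)
    abort_validation("`hct_pre` must lie in (0, 100] percent (got %g)", hct_pre)
  if (hct_post <= 0 || hct_post > 100)
    abort_validation("`hct_post` must lie in (0, 100] percent (got %g)", hct_post)
  if (hct_post > hct_pre)
    abort_validation("`hct_post` (%g%%) exceeds `hct_pre` (%g%%): no blood loss is consistent with a hematocrit rise",
                     hct_post, hct_pre)
  blood_volume(profile) * (hct_pre - hct_post) / hct_pre
}

#' Estimate a total-body-water deficit from weight and hematocrit
#'
#' Given the current (dehydrated) weight and hematocrit and a baseline
#' hematocrit judged present before the losses, recovers the pre-loss
#' weight from the conserved red-cell volume and reports the weight
#' difference as a water deficit at 1 kg = 1 L:
#' `rbc = hct_now/100 * bv_per_kg * weight_now`;
#' `weight_pre = rbc / (hct_baseline/100) / bv_per_kg`;
#' `deficit = weight_pre - weight_now`.
#'
#' If `hct_baseline > hct_now` the patient has gained fluid relative to
#' baseline; the (negative) deficit is returned with `fluid_gain = TRUE`
#' rather than raising an error.
#'
#' @param weight_now current body weight, kg, > 0.
#' @param hct_now current hematocrit, percent, > 0.
#' @param hct_baseline baseline hematocrit, percent, > 0.
#' @param bv_per_kg blood volume rule, ml/kg (default 75).
#' @return list with `deficit_l` (liters), `weight_pre_kg`, `rbc_ml`, and
#'   logical `fluid_gain`.
#' @examples
#' estimate_fluid_deficit(6, 50, 35)  # deficit ~2.571 L
#' @export
estimate_fluid_deficit <- function(weight_now, hct_now, hct_baseline,
                                   bv_per_kg = 75) {
  check_scalar(weight_now, "weight_now")
  check_scalar(hct_now, "hct_now")
  check_scalar(hct_baseline, "hct_baseline")
  check_scalar(bv_per_kg, "bv_per_kg")
  if (weight_now <= 0)
    abort_validation("`weight_now` must be > 0 kg (got %g)", weight_now)
  if (bv_per_kg <= 0)
    abort_validation("`bv_per_kg` must be > 0 ml/kg (got %g)", bv_per_kg)
  if (hct_now <= 0 || hct_now > 100)
    abort_validation("`hct_now` must lie in (0, 100] percent (got %g)", hct_now)
  if (hct_baseline <= 0 || hct_baseline > 100)
    abort_validation("`hct_baseline` must lie in (0, 100] percent (got %g)",
                     hct_baseline)
  rbc <- hct_now / 100 * bv_per_kg * weight_now
  bv_pre <- rbc / (hct_baseline / 100)
  weight_pre <- bv_pre / bv_per_kg
  deficit <- weight_pre - weight_now  # 1 kg of water == 1 L
  list(deficit_l = deficit, weight_pre_kg = weight_pre, rbc_ml = rbc,
       fluid_gain = deficit < 0)
}

# Baseline Hct assumed for the dehydration worked example; the source
# procedure leaves the pre-dehydration Hct to clinical judgment.
FIG5_BASELINE_HCT <- 35

#' Worked-example fixtures
#'
#' The four canonical chart procedures as structured scenarios, with
#' expected outputs computed by the algebraic engine at call time:
#' \enumerate{
#'   \item 12-kg infant, Hct 35%, loses 200 ml of blood, equilibrated.
#'   \item 6-kg infant, Hct 35%, receives 200 ml of fluid, no blood loss.
#'   \item 12-kg infant, Hct 35%, 200 ml blood loss plus 400 ml
#'     crystalloid (operating-room combination).
#'   \item 6-kg dehydrated infant presenting at Hct 50%; water deficit
#'     back-calculated against an assumed baseline Hct of 35%.
#' }
#'
#' @return named list of four scenario descriptions. Each has `name`,
#'   `procedure` (one of `"blood_loss_equilibrated"`, `"infusion"`,
#'   `"combined"`, `"dehydration"`), the inputs, and `expected` (final Hct
#'   in percent, or deficit in liters for the dehydration case).
#' @export
figure_fixtures <- function() {
  f1 <- list(
    name = "blood_loss_equilibrated",
    procedure = "blood_loss_equilibrated",
    weight_kg = 12, initial_hct_pct = 35, loss_ml = 200,
    expected = hct_after_blood_loss(35, 900, 200))
  f2 <- list(
    name = "infusion",
    procedure = "infusion",
    weight_kg = 6, initial_hct_pct = 35, infusion_ml = 200,
    expected = hct_after_infusion(35, 450, 200))
  p3 <- patient_profile(12)
  f3 <- list(
    name = "combined",
    procedure = "combined",
    weight_kg = 12, initial_hct_pct = 35, loss_ml = 200, infusion_ml = 400,
    expected = apply_events(p3, 35, list(
      fluid_event("blood_loss", 200),
      fluid_event("crystalloid_in", 400)))$final_hct)
  f4 <- list(
    name = "dehydration",
    procedure = "dehydration",
    weight_kg = 6, current_hct_pct = 50,
    baseline_hct_pct = FIG5_BASELINE_HCT,
    expected = estimate_fluid_deficit(6, 50, FIG5_BASELINE_HCT)$deficit_l)
  list(blood_loss_equilibrated = f1, infusion = f2, combined = f3,
       dehydration = f4)
}

# ---- scenario JSON interchange ------------------------------------------

#' Read a scenario description from JSON
#'
#' Schema: `{"weight_kg": num, "initial_hct_pct": num, "events":`
#' `[{"kind": str, "volume_ml": num, "donor_hct_pct": num?}]}`, with an
#' optional `"bv_per_kg"`.
#'
#' @param path path to a JSON file.
#' @return list with `profile` ([patient_profile()]), `hct_i`, and
#'   `events` (list of [fluid_event()]).
#' @export
read_scenario_json <- function(path) {
  if (!file.exists(path))
    abort_validation("scenario file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e)
                    abort_validation("scenario file is not valid JSON: %s",
                                     conditionMessage(e)))
  for (field in c("weight_kg", "initial_hct_pct"))
    if (is.null(doc[[field]]) || !is.numeric(doc[[field]]))
      abort_validation("scenario file missing numeric field `%s`", field)
  bv_per_kg <- if (is.null(doc$bv_per_kg)) 75 else doc$bv_per_kg
  events <- lapply(seq_along(doc$events), function(i) {
    e <- doc$events[[i]]
    if (is.null(e$kind))
      abort_validation("scenario event %d has no `kind`", i)
    if (!e$kind %in% EVENT_KINDS)
      abort_validation("scenario event %d has unknown kind `%s` (valid: %s)",
                       i, e$kind, paste(EVENT_KINDS, collapse = ", "))
    fluid_event(e$kind,
                volume = if (is.null(e$volume_ml)) 0 else e$volume_ml,
                donor_hct = e$donor_hct_pct)
  })
  list(profile = patient_profile(doc$weight_kg, bv_per_kg = bv_per_kg),
       hct_i = doc$initial_hct_pct, events = events)
}

#' Serialize a scenario result to the JSON result schema
#'
#' @param result a `scenario_result` from [apply_events()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
scenario_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  out <- list(
    final_hct_pct = result$final_hct,
    bv_ml = result$final$bv,
    rbc_ml = result$final$rbc,
    trajectory = lapply(result$trajectory, function(s)
      list(bv_ml = s$bv, rbc_ml = s$rbc, hct_pct = s$hct)))
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
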