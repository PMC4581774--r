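# Easement and land-purchase cost schedule.
#
# Transaction costs for placing an easement on a parcel have a fixed part
# (legal and financial advice, registration, a stewardship endowment, the
# holder's legal cost) and three size-dependent parts (ecological baseline
# study, appraisal, land survey), each a saturating curve
#   cost = intercept + slope * ln(area in acres)
# that is never allowed to fall below a stated minimum. Monitoring and staff
# time recur annually. Land purchase costs the assessed value plus a
# fraction placed in a stewardship trust. All values are present-day CAD;
# no discounting is applied anywhere in the model.

#' Size-dependent cost curve
#'
#' A saturating cost curve of the form
#' `max(minimum, intercept + slope * ln(area_acres))`, used for easement
#' transaction components whose cost grows with parcel size.
#'
#' @param intercept Intercept in CAD.
#' @param slope Slope in CAD per log-acre.
#' @param minimum Floor in CAD; the evaluated cost never falls below this.
#' @return An object of class `cost_curve`.
#' @seealso [variable_cost()]
#' @export
cost_curve <- function(intercept, slope, minimum) {
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(slope, "slope")
  assert_scalar_number(minimum, "minimum", lower = 0)
  structure(list(intercept = intercept, slope = slope, minimum = minimum),
            class = "cost_curve")
}

#' Easement cost schedule
#'
#' Default constants are the compiled estimates from two regional land
#' trusts: five fixed components (landowner legal 300, financial advice 300,
#' registration 200, endowment 10,000, holder legal 4,000 CAD), three
#' size-scaled curves (ecological baseline, appraisal, land survey; all with
#' slope 1,957 CAD per log-acre) and two recurring annual costs (monitoring
#' 758, staff 151.6 CAD/yr).
#'
#' @param fixed_landowner_legal,fixed_landowner_financial,fixed_registration,fixed_endowment,fixed_holder_legal
#'   Fixed one-time components, CAD.
#' @param curve_ecological_baseline,curve_appraisal,curve_land_survey
#'   [cost_curve()] objects for the size-scaled components.
#' @param recurring_monitoring,recurring_staff Annual recurring costs, CAD/yr.
#' @return An object of class `easement_cost_schedule`.
#' @export
easement_cost_schedule <- function(fixed_landowner_legal = 300,
                                   fixed_landowner_financial = 300,
                                   fixed_registration = 200,
                                   fixed_endowment = 10000,
                                   fixed_holder_legal = 4000,
                                   curve_ecological_baseline = cost_curve(2185, 1957, 1000),
                                   curve_appraisal = cost_curve(0, 1957, 1500),
                                   curve_land_survey = cost_curve(300, 1957, 1000),
                                   recurring_monitoring = 758,
                                   recurring_staff = 151.6) {
  fixed <- c(fixed_landowner_legal, fixed_landowner_financial,
             fixed_registration, fixed_endowment, fixed_holder_legal)
  for (i in seq_along(fixed)) assert_scalar_number(fixed[i], "fixed cost", lower = 0)
  assert_scalar_number(recurring_monitoring, "recurring_monitoring", lower = 0)
  assert_scalar_number(recurring_staff, "recurring_staff", lower = 0)
  stopifnot(inherits(curve_ecological_baseline, "cost_curve"),
            inherits(curve_appraisal, "cost_curve"),
            inherits(curve_land_survey, "cost_curve"))
  structure(list(
    fixed_landowner_legal = fixed_landowner_legal,
    fixed_landowner_financial = fixed_landowner_financial,
    fixed_registration = fixed_registration,
    fixed_endowment = fixed_endowment,
    fixed_holder_legal = fixed_holder_legal,
    curve_ecological_baseline = curve_ecological_baseline,
    curve_appraisal = curve_appraisal,
    curve_land_survey = curve_land_survey,
    recurring_monitoring = recurring_monitoring,
    recurring_staff = recurring_staff
  ), class = "easement_cost_schedule")
}

#' Land-purchase cost model
#'
#' Fee-simple purchase at assessed value plus a stewardship endowment equal
#' to `trust_fraction` of the purchase price (regional land trusts raise 15%
#' of purchase value into trust at acquisition).
#'
#' @param trust_fraction Non-negative fraction of purchase price endowed.
#' @return An object of class `purchase_cost_model`.
#' @export
purchase_cost_model <- function(trust_fraction = 0.15) {
  assert_scalar_number(trust_fraction, "trust_fraction", lower = 0)
  structure(list(trust_fraction = trust_fraction), class = "purchase_cost_model")
}

#' Purchase cost of one or more parcels
#'
#' @param assessed_value Numeric vector of assessed values, CAD.
#' @param model A [purchase_cost_model()].
#' @return `assessed_value * (1 + trust_fraction)`, vectorised.
#' @export
purchase_cost <- function(assessed_value, model = purchase_cost_model()) {
  stopifnot(inherits(model, "purchase_cost_model"))
  if (any(!is.finite(assessed_value)) || any(assessed_value < 0)) {
    stop_input("assessed_value must be finite and non-negative")
  }
  assessed_value * (1 + model$trust_fraction)
}

#' Evaluate a size-dependent cost curve
#'
#' `max(minimum, intercept + slope * ln(area_acres))`; natural logarithm.
#'
#' @param curve A [cost_curve()].
#' @param area_acres Positive numeric vector of parcel areas in acres.
#' @return Cost in CAD, vectorised over `area_acres`.
#' @export
variable_cost <- function(curve, area_acres) {
  stopifnot(inherits(curve, "cost_curve"))
  if (any(!is.finite(area_acres)) || any(area_acres <= 0)) {
    stop_input("area_acres must be finite and > 0")
  }
  pmax(curve$minimum, curve$intercept + curve$slope * log(area_acres))
}

#' One-time easement setup cost
#'
#' Sum of the five fixed components (14,800 CAD with defaults) and the three
#' size-scaled curves evaluated at the parcel area.
#'
#' @param area_acres Positive numeric vector of areas, acres.
#' @param schedule An [easement_cost_schedule()].
#' @return Setup cost in CAD, vectorised over `area_acres`.
#' @export
easement_setup_cost <- function(area_acres, schedule = easement_cost_schedule()) {
  stopifnot(inherits(schedule, "easement_cost_schedule"))
  fixed <- schedule$fixed_landowner_legal + schedule$fixed_landowner_financial +
    schedule$fixed_registration + schedule$fixed_endowment +
    schedule$fixed_holder_legal
  fixed +
    variable_cost(schedule$curve_ecological_baseline, area_acres) +
    variable_cost(schedule$curve_appraisal, area_acres) +
    variable_cost(schedule$curve_land_survey, area_acres)
}

#' Annual recurring easement cost
#'
#' Monitoring plus staff time; independent of parcel area
#' (909.6 CAD/yr with defaults).
#'
#' @param schedule An [easement_cost_schedule()].
#' @return Recurring cost in CAD per year.
#' @export
easement_recurring_annual <- function(schedule = easement_cost_schedule()) {
  stopifnot(inherits(schedule, "easement_cost_schedule"))
  schedule$recurring_monitoring + schedule$recurring_staff
}
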