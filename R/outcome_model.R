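# Scale a net per-person daily calorie reduction into annual disease-case,
# QALY and cost changes for England.

#' Configuration for outcome scaling
#'
#' The reference outcome model is a UK-level, 20-year projection of the
#' effect of a sustained 20 kcal/person/day reduction. Scaling a duty's net
#' kcal change onto it therefore needs three constants: the pro-rata
#' reference (20 kcal/day), the horizon used to annualise the 20-year deltas,
#' and the England share of the UK reference population. The default
#' `population_factor` of 0.836 back-calculates consistently (to within
#' 0.001) from all four published England-level outcome rows and agrees with
#' the England/UK mid-2010 population ratio (about 0.84); see the vignette.
#'
#' @param population_factor England share of the UK reference population,
#'   in `(0, 1]`.
#' @param reference_kcal Reference calorie reduction (kcal/person/day).
#' @param horizon_years Projection horizon the reference deltas span.
#' @return An object of class `ssb_scaling_config` (a list).
#' @export
scaling_config <- function(population_factor = 0.836,
                           reference_kcal = 20,
                           horizon_years = 20) {
  stopifnot(population_factor > 0, population_factor <= 1,
            horizon_years > 0)
  structure(
    list(population_factor = population_factor,
         reference_kcal = reference_kcal,
         horizon_years = horizon_years),
    class = "ssb_scaling_config"
  )
}

#' Scale a net calorie reduction to annual outcome changes
#'
#' Pro-rata scaling: each outcome's 20-year reference delta (scenario 2,
#' the 20 kcal/day reduction) is multiplied by `net_kcal / reference_kcal`,
#' rescaled from UK to England by `population_factor`, and annualised by
#' dividing by `horizon_years`. The mapping is strictly linear in
#' `net_kcal`: disease deltas are negative (cases averted) and the QALY
#' delta positive for any positive calorie reduction.
#'
#' @param net_kcal Net per-person daily calorie reduction (kcal/day).
#' @param ref Outcome reference table, see [ssb_outcome_reference()].
#' @param cfg A [scaling_config()].
#' @return A tibble (`outcome`, `annual_change`): cases/year for the three
#'   disease outcomes, QALYs/year for `qalys`.
#' @examples
#' scale_outcomes(6.5)
#' @export
scale_outcomes <- function(net_kcal,
                           ref = ssb_outcome_reference(),
                           cfg = scaling_config()) {
  stopifnot(is.numeric(net_kcal), length(net_kcal) == 1, is.finite(net_kcal))
  if (any(ref$reference_kcal == 0) || cfg$reference_kcal == 0) {
    stop("reference calorie reduction must be non-zero", call. = FALSE)
  }
  tibble::tibble(
    outcome = ref$outcome,
    annual_change = ref$scenario2_reduction * (net_kcal / cfg$reference_kcal) *
      cfg$population_factor / cfg$horizon_years
  )
}

#' Annual healthcare cost savings from averted cases
#'
#' Values each disease outcome's annual case change at its average annual
#' treatment cost and sums the absolute savings. QALYs are not monetised
#' and are excluded.
#'
#' @param delta Outcome delta tibble from [scale_outcomes()].
#' @param costs Unit-cost table, see [ssb_costs()].
#' @return Total cost savings in GBP/year (a single number, >= 0 for
#'   case reductions).
#' @export
cost_savings <- function(delta, costs = ssb_costs()) {
  diseases <- delta[delta$outcome != "qalys", ]
  merged <- dplyr::left_join(diseases, costs, by = "outcome")
  if (anyNA(merged$unit_cost)) {
    missing <- merged$outcome[is.na(merged$unit_cost)]
    stop("no unit cost for disease outcome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(abs(merged$annual_change) * merged$unit_cost)
}

#' Rescale a 20%-duty result to another duty rate
#'
#' The duty's effect is linear in the duty rate (within reasonable ranges),
#' so a 30% duty produces 1.5x the 20% result and a 10% duty half of it.
#' Multiplies every outcome delta (and cost column, if present) by
#' `new_duty / baseline_duty`.
#'
#' @param delta Outcome delta tibble (as from [scale_outcomes()]), optionally
#'   with additional numeric impact columns.
#' @param new_duty Target duty rate (fraction, >= 0).
#' @param baseline_duty Duty rate the input was computed at (default 0.20).
#' @return The rescaled tibble.
#' @examples
#' duty_scaling(scale_outcomes(6.5), 0.30) # 1.5x every outcome
#' @export
duty_scaling <- function(delta, new_duty, baseline_duty = 0.20) {
  if (!is.numeric(new_duty) || new_duty < 0) {
    stop("`new_duty` must be a non-negative fraction", call. = FALSE)
  }
  stopifnot(baseline_duty > 0)
  k <- new_duty / baseline_duty
  num <- vapply(delta, is.numeric, logical(1))
  delta[num] <- lapply(delta[num], function(col) col * k)
  delta
}
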