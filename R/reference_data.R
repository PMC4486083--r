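# Published model parameters, embedded as code so the pipeline is
# self-contained and the values are version-controlled alongside it.

# Manufacturer sales data imply roughly 3.1x the SSB volume reported in the
# NDNS (478 vs 156 ml/day); the high-estimate kcal column is the NDNS column
# scaled by exactly this factor.
MANUFACTURER_SCALE <- 3.1

#' Age bands and genders used throughout the model
#'
#' The model stratifies consumption into eight demographic groups:
#' two genders crossed with four categorical age bands. Band labels are
#' treated as categories; no arithmetic is performed on ages.
#'
#' @return Character vector of the four age-band labels, or the two genders.
#' @export
ssb_age_bands <- function() c("4-10", "11-18", "19-64", "65+")

#' @rdname ssb_age_bands
#' @export
ssb_genders <- function() c("male", "female")

# adult bands drive outcome allocation; children still shape consumption
adult_bands <- function() c("19-64", "65+")

#' SSB consumption by age and gender
#'
#' Average daily sugar-sweetened beverage consumption for England from the
#' National Diet and Nutrition Survey (NDNS) 2008-10, by gender and age band.
#' `kcal_low` is the NDNS survey estimate; `kcal_high` scales it by the
#' manufacturer-data factor of 3.1, reflecting survey under-reporting and
#' wastage. `pct_consumers` (the share of each group consuming any SSB) is
#' carried as optional metadata; it is descriptive only and no model
#' operation consumes it.
#'
#' @return A tibble with one row per demographic group: `gender`, `age_band`,
#'   `grams_per_day` (g/day), `kcal_low` and `kcal_high` (kcal/day),
#'   `pct_consumers`.
#' @examples
#' ssb_consumption()
#' @export
ssb_consumption <- function() {
  tbl <- tibble::tribble(
    ~gender,  ~age_band, ~grams_per_day, ~kcal_low, ~kcal_high,
    "male",   "4-10",    141,            44,        136,
    "male",   "11-18",   314,            98,        304,
    "male",   "19-64",   173,            54,        167,
    "male",   "65+",     48,             15,        46,
    "female", "4-10",    127,            40,        123,
    "female", "11-18",   247,            77,        239,
    "female", "19-64",   110,            34,        106,
    "female", "65+",     52,             16,        50
  )
  tbl$pct_consumers <- NA_real_

  # integrity check: the printed high column must be consistent with the
  # 3.1 manufacturer scaling (2% slack for printed-value rounding)
  ratio <- tbl$kcal_high / tbl$kcal_low
  if (any(abs(ratio / MANUFACTURER_SCALE - 1) > 0.02)) {
    stop("consumption table corrupted: high/low kcal ratio deviates from ",
         "the 3.1 manufacturer scaling by more than 2%", call. = FALSE)
  }
  if (any(tbl$grams_per_day < 0 | tbl$kcal_low < 0)) {
    stop("consumption table corrupted: negative quantities", call. = FALSE)
  }
  tbl
}

#' Reference obesity-scenario outcomes
#'
#' Twenty-year (2010-2030) UK changes in disease incidence and QALYs under
#' three obesity scenarios, from the comparative risk assessment model the
#' pipeline scales against. Scenario 2 -- a sustained net reduction of
#' 20 kcal/person/day, lowering mean BMI by about 1% -- is the reference the
#' duty effect is scaled pro rata against; scenarios 1 (recent trends
#' continue) and 3 (obesity back at 1990 levels) are carried for context.
#'
#' Disease rows are signed case counts (negative = fewer cases); the QALY row
#' is signed QALYs (positive = QALYs gained).
#'
#' @return A tibble with columns `outcome` (diabetes, chd_stroke, cancer,
#'   qalys), `scenario1_trend`, `scenario2_reduction`, `scenario3_1990`,
#'   `reference_kcal` (20 kcal/day) and `horizon_years` (20).
#' @export
ssb_outcome_reference <- function() {
  tbl <- tibble::tribble(
    ~outcome,     ~scenario1_trend, ~scenario2_reduction, ~scenario3_1990,
    "diabetes",   545000,           -179000,              -897000,
    "chd_stroke", 331000,           -122000,              -634000,
    "cancer",     87000,            -32000,               -177000,
    "qalys",      -2219000,         3011000,              7073000
  )
  tbl$reference_kcal <- 20
  tbl$horizon_years <- 20
  tbl
}

#' Annual treatment costs per disease case
#'
#' Average annual per-case treatment costs (GBP) used to value changes in
#' disease incidence: usual care for type 2 diabetes, hospital cost of a
#' cardiovascular event, and per-patient bowel-cancer cost (the most common
#' obesity-related cancer affecting both genders). QALYs are not monetised
#' and have no entry.
#'
#' @return A tibble with columns `outcome` and `unit_cost` (GBP per case per
#'   year).
#' @export
ssb_costs <- function() {
  tibble::tribble(
    ~outcome,     ~unit_cost,
    "diabetes",   1371,
    "chd_stroke", 4614,
    "cancer",     8808
  )
}

#' Uncertainty distributions for the Monte Carlo simulation
#'
#' Parameter set for probabilistic sensitivity analysis. The three sampled
#' parameters are fitted to independent normal distributions:
#' population SSB consumption ~ Normal(301, 91) ml/person/day, price
#' elasticity of demand ~ Normal(-0.691, 0.12), and substitution of calories
#' from other foods ~ Normal(1.78, 0.91) kcal/person/day. The elasticity SD
#' is stored as a positive magnitude.
#'
#' `energy_density` converts consumption volume to energy. The default
#' 0.199 kcal/ml is calibrated so that the mean-parameter scenario under a
#' 20% duty reproduces the model's mean net reduction of 6.5 kcal/day
#' (`(6.5 + 1.78) / (301 * 0.691 * 0.20)`); note NDNS intake tables imply a
#' somewhat higher density (about 0.31 kcal/g), so treat this value as a
#' model calibration, not a beverage property. See the package vignette.
#'
#' The narrative elasticity estimate of -0.46 (from the price-elasticity
#' literature used for the deterministic lookup) differs from the simulation
#' centre -0.691; pass `elasticity_mean = -0.46` to use it as an alternative.
#'
#' @param consumption_mean,consumption_sd Consumption distribution (ml/day).
#' @param elasticity_mean,elasticity_sd Elasticity distribution
#'   (dimensionless; mean must be <= 0, sd a positive magnitude).
#' @param substitution_mean,substitution_sd Substitution distribution
#'   (kcal/day).
#' @param energy_density Energy density of SSBs (kcal/ml).
#' @param duty_rate Ad valorem duty rate as a fraction (0.20 = 20%).
#' @param n_sims Number of Monte Carlo draws.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ssb_uncertainty`.
#' @export
ssb_uncertainty_params <- function(consumption_mean = 301,
                                   consumption_sd = 91,
                                   elasticity_mean = -0.691,
                                   elasticity_sd = 0.12,
                                   substitution_mean = 1.78,
                                   substitution_sd = 0.91,
                                   energy_density = 0.199,
                                   duty_rate = 0.20,
                                   n_sims = 10000,
                                   seed = NULL) {
  stopifnot(
    consumption_sd >= 0, elasticity_sd >= 0, substitution_sd >= 0,
    elasticity_mean <= 0, energy_density > 0, duty_rate >= 0,
    n_sims >= 1
  )
  structure(
    list(
      consumption_mean = consumption_mean, consumption_sd = consumption_sd,
      elasticity_mean = elasticity_mean, elasticity_sd = elasticity_sd,
      substitution_mean = substitution_mean, substitution_sd = substitution_sd,
      energy_density = energy_density, duty_rate = duty_rate,
      n_sims = as.integer(n_sims), seed = seed
    ),
    class = "ssb_uncertainty"
  )
}

#' @export
print.ssb_uncertainty <- function(x, ...) {
  cat("SSB duty uncertainty parameters\n")
  cat(sprintf("  consumption  ~ Normal(%g, %g) ml/day\n",
              x$consumption_mean, x$consumption_sd))
  cat(sprintf("  elasticity   ~ Normal(%g, %g)\n",
              x$elasticity_mean, x$elasticity_sd))
  cat(sprintf("  substitution ~ Normal(%g, %g) kcal/day\n",
              x$substitution_mean, x$substitution_sd))
  cat(sprintf("  energy density %g kcal/ml, duty %g%%, %d simulations\n",
              x$energy_density, 100 * x$duty_rate, x$n_sims))
  invisible(x)
}

#' Export the built-in parameter tables to CSV
#'
#' Writes the embedded fixtures to versioned CSV files so they can be
#' inspected or substituted with updated survey data:
#' `table1.csv` (consumption), `table2.csv` (outcome reference),
#' `table3.csv` (unit costs), `table4_params.csv` (uncertainty
#' distributions).
#'
#' @param dir Directory to write into (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("table1.csv", "table2.csv", "table3.csv",
                            "table4_params.csv"))
  readr::write_csv(ssb_consumption(), paths[1])
  readr::write_csv(ssb_outcome_reference(), paths[2])
  readr::write_csv(ssb_costs(), paths[3])
  p <- ssb_uncertainty_params()
  params_tbl <- tibble::tribble(
    ~parameter,           ~mean,                ~sd,                ~units,
    "consumption",        p$consumption_mean,   p$consumption_sd,   "ml/person/day",
    "elasticity",         p$elasticity_mean,    p$elasticity_sd,    "dimensionless",
    "substitution",       p$substitution_mean,  p$substitution_sd,  "kcal/person/day",
    "energy_density",     p$energy_density,     NA_real_,           "kcal/ml",
    "duty_rate",          p$duty_rate,          NA_real_,           "fraction"
  )
  readr::write_csv(params_tbl, paths[4])
  invisible(paths)
}
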