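# Disaggregate the England-level result to lower-tier local authorities,
# weighting by each area's age/gender structure.

#' Read and write local-authority population tables
#'
#' The population CSV has one row per area and demographic group, with
#' columns `area_code`, `area_name`, `gender` (`male`/`female`), `age_band`
#' (one of the four band labels, see [ssb_age_bands()]) and `count`
#' (head count, >= 0). Malformed rows are reported with their line numbers.
#'
#' @param path Path to a population CSV.
#' @return A tibble in the schema above.
#' @export
read_area_populations <- function(path) {
  pop <- readr::read_csv(path, col_types = readr::cols(
    area_code = readr::col_character(),
    area_name = readr::col_character(),
    gender = readr::col_character(),
    age_band = readr::col_character(),
    count = readr::col_double()
  ))
  required <- c("area_code", "area_name", "gender", "age_band", "count")
  missing <- setdiff(required, names(pop))
  if (length(missing)) {
    stop("population file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # +1 for the header row when reporting line numbers
  bad_band <- which(!pop$age_band %in% ssb_age_bands())
  if (length(bad_band)) {
    stop(sprintf("unknown age band label '%s' at line %d of %s",
                 pop$age_band[bad_band[1]], bad_band[1] + 1L, path),
         call. = FALSE)
  }
  bad_gender <- which(!pop$gender %in% ssb_genders())
  if (length(bad_gender)) {
    stop(sprintf("unknown gender label '%s' at line %d of %s",
                 pop$gender[bad_gender[1]], bad_gender[1] + 1L, path),
         call. = FALSE)
  }
  bad_count <- which(is.na(pop$count) | pop$count < 0)
  if (length(bad_count)) {
    stop(sprintf("missing or negative count at line %d of %s",
                 bad_count[1] + 1L, path), call. = FALSE)
  }
  pop[required]
}

#' @rdname read_area_populations
#' @param pop A population tibble in the schema above.
#' @export
write_area_populations <- function(pop, path) {
  readr::write_csv(pop, path)
  invisible(path)
}

validate_area_populations <- function(areas) {
  stopifnot(all(c("area_code", "gender", "age_band", "count") %in%
                  names(areas)))
  if (any(areas$count < 0)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  key <- paste(areas$area_code, areas$gender, areas$age_band)
  if (anyDuplicated(key)) {
    dup <- areas$area_code[duplicated(key)][1]
    stop("duplicate area/group rows for area code '", dup, "'",
         call. = FALSE)
  }
  adults <- areas |>
    dplyr::filter(.data$age_band %in% adult_bands()) |>
    dplyr::group_by(.data$area_code) |>
    dplyr::summarise(adults = sum(.data$count), .groups = "drop")
  no_adults <- union(
    adults$area_code[adults$adults <= 0],
    setdiff(unique(areas$area_code), adults$area_code)
  )
  if (length(no_adults)) {
    stop("area(s) with no adult population: ",
         paste(utils::head(no_adults, 3), collapse = ", "), call. = FALSE)
  }
  invisible(areas)
}

#' Consumption-weighted calorie intake of an area
#'
#' The demographic weight of an area: mean SSB calorie intake per person,
#' using the national per-group intake (low estimate) as relative weights
#' over the area's age/gender composition. Areas with young populations get
#' higher weights because 11-18 year olds are by far the heaviest SSB
#' consumers.
#'
#' @param pop Population rows for a single area (columns `gender`,
#'   `age_band`, `count`).
#' @param table Consumption table, see [ssb_consumption()].
#' @return Mean SSB kcal/day per person for the area's composition.
#' @export
area_consumption_weight <- function(pop, table = ssb_consumption()) {
  total <- sum(pop$count)
  if (total <= 0) {
    stop("area population is all zero", call. = FALSE)
  }
  merged <- dplyr::left_join(pop, table[c("gender", "age_band", "kcal_low")],
                             by = c("gender", "age_band"))
  if (anyNA(merged$kcal_low)) {
    stop("population contains groups missing from the consumption table",
         call. = FALSE)
  }
  sum(merged$count * merged$kcal_low) / total
}

#' Disaggregate the national result to local authorities
#'
#' Each area's per-person calorie reduction is the national net reduction
#' scaled by the ratio of the area's consumption weight to the
#' all-England (pooled) weight, so areas with younger, higher-consuming
#' populations see larger per-person reductions. Outcome totals (cases,
#' QALYs, costs) are allocated proportionally to each area's adult
#' population times its relative weight, normalised so that area totals sum
#' exactly to the national totals. Children shape an area's consumption
#' weight but totals are spread over adults only, matching the 41-million
#' adult modelled population.
#'
#' @param national A national result: either an `ssb_national` object from
#'   [run_national()] or a list with elements `net_kcal` (single number or
#'   named vector whose first element is used), `outcomes` (tibble
#'   `outcome`/`annual_change`) and `cost_savings`.
#' @param areas Long population tibble (schema of
#'   [read_area_populations()]).
#' @param table Consumption table used for weighting.
#' @return A tibble with one row per area: `area_code`, `area_name`,
#'   `adults`, `per_person_kcal`, one column per outcome (`diabetes`,
#'   `chd_stroke`, `cancer`, `qalys`; annual changes) and `cost_savings`
#'   (GBP/year).
#' @export
disaggregate <- function(national, areas, table = ssb_consumption()) {
  validate_area_populations(areas)
  net_kcal <- unname(national$net_kcal[1])
  outcomes <- national$outcomes
  total_cost <- national$cost_savings

  w_england <- area_consumption_weight(areas, table)

  per_area <- areas |>
    dplyr::group_by(.data$area_code, .data$area_name) |>
    dplyr::summarise(
      adults = sum(.data$count[.data$age_band %in% adult_bands()]),
      weight = area_consumption_weight(
        dplyr::pick(dplyr::everything()), table
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$area_code)

  per_area$per_person_kcal <- net_kcal * per_area$weight / w_england
  alloc <- per_area$adults * per_area$weight
  share <- alloc / sum(alloc)

  for (i in seq_len(nrow(outcomes))) {
    per_area[[outcomes$outcome[i]]] <- outcomes$annual_change[i] * share
  }
  per_area$cost_savings <- total_cost * share
  per_area$weight <- NULL
  per_area
}

#' Rank areas by an impact metric
#'
#' Stable descending sort on the chosen metric, ties broken by area code,
#' with a `rank` column added. The default metric is annual QALYs gained.
#' Disease-case metrics are negative (cases averted), so a descending sort
#' on them puts the least-impacted areas first; sort on their absolute
#' value externally if impact ordering is wanted.
#'
#' @param results Area results from [disaggregate()].
#' @param metric Name of a numeric column of `results`.
#' @return `results` sorted, with a `rank` column prepended.
#' @export
rank_areas <- function(results, metric = "qalys") {
  if (!metric %in% names(results) || !is.numeric(results[[metric]])) {
    stop("unknown metric: ", metric, call. = FALSE)
  }
  out <- results |>
    dplyr::arrange(dplyr::desc(.data[[metric]]), .data$area_code)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}
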