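# Synthetic local-authority population generator. Stands in for official
# area denominators so the full pipeline can run and be tested end to end
# without any data download; it does not reproduce any named authority.

#' Reference demographic shares for England
#'
#' Approximate England age/gender composition (population aged 4+) used as
#' the centre of the synthetic generator. The constants are round figures
#' chosen to reflect the broad structure of the mid-2010s population: about
#' 8% in each child band per gender pair, roughly 62% aged 19-64, and a
#' 65+ group where women outnumber men. Shares sum to 1.
#'
#' @param override Optional tibble (`gender`, `age_band`, `share`) replacing
#'   the defaults; shares are renormalised to sum to 1.
#' @return A tibble with `gender`, `age_band`, `share`.
#' @export
england_reference_shares <- function(override = NULL) {
  shares <- tibble::tribble(
    ~gender,  ~age_band, ~share,
    "male",   "4-10",    0.043,
    "male",   "11-18",   0.049,
    "male",   "19-64",   0.310,
    "male",   "65+",     0.090,
    "female", "4-10",    0.041,
    "female", "11-18",   0.047,
    "female", "19-64",   0.308,
    "female", "65+",     0.112
  )
  if (!is.null(override)) {
    stopifnot(all(c("gender", "age_band", "share") %in% names(override)),
              all(override$share >= 0), sum(override$share) > 0)
    shares <- override[c("gender", "age_band", "share")]
  }
  shares$share <- shares$share / sum(shares$share)
  shares
}

#' Synthetic population configuration
#'
#' Defaults emulate the modelled England population: 41 million adults
#' spread over 326 lower-tier local authorities. Area sizes are heavy-tailed
#' (log-normal; England's range spans Birmingham to the Isles of Scilly) and
#' compositions vary along a young-urban vs old-rural gradient.
#'
#' @param n_areas Number of areas.
#' @param total_adults Total adult (19+) head count, conserved exactly.
#' @param age_gradient Log-scale SD of the per-area young/old tilt; 0 gives
#'   every area the identical reference composition.
#' @param size_dispersion Log-scale SD of area sizes; the default 0.8 gives
#'   a max/min size ratio on the order of 100 across 326 areas.
#' @param reference_shares Demographic centre, see
#'   [england_reference_shares()].
#' @param seed Optional integer seed.
#' @return An object of class `ssb_synth_config`.
#' @export
synth_config <- function(n_areas = 326,
                         total_adults = 41000000,
                         age_gradient = 0.3,
                         size_dispersion = 0.8,
                         reference_shares = england_reference_shares(),
                         seed = NULL) {
  stopifnot(n_areas >= 1, age_gradient >= 0, size_dispersion >= 0)
  if (total_adults < n_areas) {
    stop("infeasible config: `total_adults` must be at least `n_areas`",
         call. = FALSE)
  }
  structure(
    list(n_areas = as.integer(n_areas),
         total_adults = as.integer(total_adults),
         age_gradient = age_gradient,
         size_dispersion = size_dispersion,
         reference_shares = reference_shares,
         seed = seed),
    class = "ssb_synth_config"
  )
}

# Round non-negative quotas to integers preserving their (integer) sum:
# floor everything, then hand the remaining units to the largest fractional
# parts (ties by index).
largest_remainder <- function(quota) {
  base <- floor(quota)
  short <- round(sum(quota) - sum(base))
  if (short > 0) {
    frac <- quota - base
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Generate a synthetic local-authority population table
#'
#' Draws area adult counts from a log-normal size distribution, rescaled by
#' largest-remainder rounding so they sum exactly to `total_adults`. Each
#' area's adult composition tilts around the reference shares: a per-area
#' tilt `t ~ Normal(0, age_gradient)` multiplies the 19-64 shares by
#' `exp(t)` and the 65+ shares by `exp(-t)` before renormalising, so shares
#' stay non-negative and sum to 1. Child counts ride along at fixed ratios
#' to the area's adults (the 11-18 ratio is tilted by `exp(t)` as well,
#' since teenagers belong to the young side of the gradient), so children
#' influence consumption weighting while outcome allocation remains
#' adult-only.
#'
#' @param config A [synth_config()].
#' @return A population tibble (schema of [read_area_populations()]):
#'   `n_areas x 8` rows with ONS-style synthetic area codes `S001`, ...
#' @examples
#' pop <- generate_population(synth_config(n_areas = 10,
#'                                         total_adults = 100000, seed = 1))
#' sum(pop$count[pop$age_band %in% c("19-64", "65+")]) # exactly 100000
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "ssb_synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_areas
  ref <- config$reference_shares

  raw <- stats::rlnorm(n, meanlog = 0, sdlog = config$size_dispersion)
  adults_per_area <- largest_remainder(config$total_adults * raw / sum(raw))

  tilt <- stats::rnorm(n, 0, config$age_gradient)

  get_share <- function(g, b) {
    ref$share[ref$gender == g & ref$age_band == b]
  }
  adult_ref <- c(m1964 = get_share("male", "19-64"),
                 f1964 = get_share("female", "19-64"),
                 m65 = get_share("male", "65+"),
                 f65 = get_share("female", "65+"))
  adult_total_share <- sum(adult_ref)
  # child-to-adult head-count ratios at the reference composition
  ratio_children <- c(m410 = get_share("male", "4-10"),
                      f410 = get_share("female", "4-10"),
                      m1118 = get_share("male", "11-18"),
                      f1118 = get_share("female", "11-18")) / adult_total_share

  rows <- lapply(seq_len(n), function(i) {
    t <- tilt[i]
    sh <- adult_ref * c(exp(t), exp(t), exp(-t), exp(-t))
    sh <- sh / sum(sh)
    adult_counts <- largest_remainder(adults_per_area[i] * sh)
    child_ratio <- ratio_children * c(1, 1, exp(t), exp(t))
    child_counts <- round(child_ratio * adults_per_area[i])
    tibble::tibble(
      area_code = sprintf("S%03d", i),
      area_name = sprintf("Synthetic Area %d", i),
      gender = c("male", "female", "male", "female",
                 "male", "female", "male", "female"),
      age_band = c("4-10", "4-10", "11-18", "11-18",
                   "19-64", "19-64", "65+", "65+"),
      count = c(child_counts[["m410"]], child_counts[["f410"]],
                child_counts[["m1118"]], child_counts[["f1118"]],
                adult_counts[1], adult_counts[2],
                adult_counts[3], adult_counts[4])
    )
  })
  dplyr::bind_rows(rows)
}
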