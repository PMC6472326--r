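# Model dimensions: index sets shared by every module.

#' Model dimensions
#'
#' Builds the index sets used throughout the framework: commodities (with
#' designated labels for palm cooking oil, other edible oils and the primary
#' crops), regional households (region x rural/urban composites), 13
#' five-year age bands (the last open-ended), genders, locations, annual
#' periods, biomarker strata and production factors.
#'
#' The `"desk"` scale (default) uses 10 commodities, 4 households and 20
#' annual periods; `"full"` uses full national-model dimensions
#' (49 commodities, 9 regional households, 7 primary crops, 2016--2035).
#'
#' @param scale `"desk"` or `"full"`, or `NULL` when supplying custom sets.
#' @param commodities character vector of commodity labels.
#' @param households character vector of household labels; each must be a
#'   `region_location` composite except `"bangkok"`, which is treated as
#'   urban.
#' @param crops labels of the primary crop commodities (first entry must be
#'   the oil-palm crop); at least three (oil palm plus two others).
#' @param palm_oil,other_oils,health_commodity designated commodity labels.
#' @param food_commodities labels of commodities carrying dietary energy.
#' @param periods integer vector of annual periods.
#' @param strata_count number of intra-household biomarker support points.
#' @return an object of class `model_dims`.
#' @examples
#' d <- model_dims()
#' d$n_commodities
#' @export
model_dims <- function(scale = "desk",
                       commodities = NULL,
                       households = NULL,
                       crops = NULL,
                       palm_oil = "palm_oil",
                       other_oils = "other_oils",
                       health_commodity = "health_services",
                       food_commodities = NULL,
                       periods = 2016:2035,
                       strata_count = 10L) {
  if (is.null(commodities)) {
    if (identical(scale, "full")) {
      crops <- c("oilpalm_crop", "rice_crop", "maize_crop", "cassava_crop",
                 "sugarcane_crop", "rubber_crop", "fruitveg_crop")
      staples <- c("palm_oil", "other_oils", crops, "meat_fish", "dairy",
                   "sugar_sweets", "beverages", "other_food",
                   "processed_food")
      nonfood <- c(sprintf("manufacturing_%02d", 1:20),
                   sprintf("services_%02d", 1:12), "energy",
                   "health_services")
      commodities <- c(staples, nonfood)
      stopifnot(length(commodities) == 49L)
      households <- c("bangkok",
                      "central_rural", "central_urban",
                      "north_rural", "north_urban",
                      "northeast_rural", "northeast_urban",
                      "south_rural", "south_urban")
      food_commodities <- staples
    } else {
      crops <- c("oilpalm_crop", "rice_crop", "maize_crop")
      commodities <- c("palm_oil", "other_oils", crops, "other_food",
                       "processed_food", "manufacturing", "services",
                       "health_services")
      households <- c("central_rural", "central_urban",
                      "south_rural", "south_urban")
      food_commodities <- c("palm_oil", "other_oils", "rice_crop",
                            "maize_crop", "other_food", "processed_food")
    }
  }
  if (is.null(crops)) stop("`crops` must be supplied with custom commodities",
                           call. = FALSE)
  if (is.null(food_commodities)) food_commodities <- crops
  age_starts <- seq(10L, 70L, by = 5L)
  age_groups <- c(paste(age_starts[-13L], age_starts[-13L] + 4L, sep = "-"),
                  "70+")
  hh_loc <- ifelse(grepl("rural", households), "rural", "urban")
  hh_reg <- sub("_(rural|urban)$", "", households)
  dims <- structure(list(
    commodities = commodities,
    households = households,
    household_region = stats::setNames(hh_reg, households),
    household_location = stats::setNames(hh_loc, households),
    regions = unique(hh_reg),
    locations = c("rural", "urban"),
    age_groups = age_groups,
    age_starts = age_starts,
    genders = c("male", "female"),
    periods = as.integer(periods),
    strata_count = as.integer(strata_count),
    factors = c("labour_unskilled", "labour_skilled", "capital", "land"),
    palm_oil = palm_oil,
    other_oils = other_oils,
    crops = crops,
    health_commodity = health_commodity,
    food_commodities = food_commodities,
    n_commodities = length(commodities),
    n_households = length(households),
    n_regions = length(unique(hh_reg)),
    n_periods = length(periods)
  ), class = "model_dims")
  validate_dims(dims)
  dims
}

#' @keywords internal
validate_dims <- function(dims) {
  if (!inherits(dims, "model_dims")) stop("not a model_dims object",
                                          call. = FALSE)
  if (dims$n_commodities < 6L) {
    stop("dimension error: at least 6 commodities required", call. = FALSE)
  }
  if (dims$n_households < 2L) {
    stop("dimension error: at least 2 households required", call. = FALSE)
  }
  if (length(dims$age_groups) != 13L) {
    stop("dimension error: exactly 13 five-year age bands required",
         call. = FALSE)
  }
  if (dims$strata_count < 2L) {
    stop("dimension error: strata_count must be >= 2", call. = FALSE)
  }
  if (dims$n_periods < 2L) {
    stop("dimension error: at least 2 periods required", call. = FALSE)
  }
  if (length(dims$crops) < 3L) {
    stop("dimension error: oil-palm crop plus >= 2 other primary crops ",
         "required", call. = FALSE)
  }
  need <- c(dims$palm_oil, dims$other_oils, dims$crops, dims$health_commodity)
  miss <- setdiff(need, dims$commodities)
  if (length(miss)) {
    stop("dimension error: designated commodities missing from commodity ",
         "list: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(dims)
}

#' @export
print.model_dims <- function(x, ...) {
  cat("<model_dims>", x$n_commodities, "commodities,", x$n_households,
      "households,", x$n_periods, "periods,", x$strata_count, "strata\n")
  invisible(x)
}
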