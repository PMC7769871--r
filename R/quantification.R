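#' Number of defined daily doses from an ingredient amount
#'
#' Core conversion of the DDDch metric: the prescribed mass of an active
#' ingredient divided by the defined daily dose (mg/kg) times the standard
#' weight (kg) of the treated age category,
#' `nDDDch = amount_mg / (dose_mg_per_kg * standard_weight_kg)`.
#' The result estimates the number of potential treatment days the amount
#' covers for one animal of standard weight.
#'
#' @param amount_mg Prescribed ingredient mass in mg (>= 0), vectorised.
#' @param dose_mg_per_kg DDDch in mg per kg bodyweight per day (> 0).
#' @param standard_weight_kg Standard weight of the age category in kg (> 0).
#' @return Numeric vector of nDDDch values.
#' @examples
#' record_ndddch(8000, 20, 12)   # 33.33 treatment days
#' record_ndddch(2200, 10, 220)  # exactly one sow daily dose
#' @export
record_ndddch <- function(amount_mg, dose_mg_per_kg, standard_weight_kg) {
  if (any(!is.finite(dose_mg_per_kg) | dose_mg_per_kg <= 0)) {
    stop("dose_mg_per_kg must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(standard_weight_kg) | standard_weight_kg <= 0)) {
    stop("standard_weight_kg must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(amount_mg) | amount_mg < 0)) {
    stop("amount_mg must be non-negative", call. = FALSE)
  }
  amount_mg / (dose_mg_per_kg * standard_weight_kg)
}

validate_usage_records <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("farm_id", "product_id", "quantity", "age_category")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("usage records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- which(!records$age_category %in% age_categories())
  if (length(bad_cat) > 0) {
    stop("usage record ", bad_cat[1], ": unknown age category '",
         records$age_category[bad_cat[1]], "'; valid categories are: ",
         paste(age_categories(), collapse = ", "),
         " (gilts and boars count as sows)", call. = FALSE)
  }
  bad_q <- which(!is.finite(records$quantity) | records$quantity < 0)
  if (length(bad_q) > 0) {
    stop("usage record ", bad_q[1], ": quantity must be non-negative",
         call. = FALSE)
  }
  records
}

#' Quantify antimicrobial usage records as ingredient mass and nDDDch
#'
#' Resolves each prescription into its active ingredient amounts, converts
#' every amount into nDDDch with the record's age-category standard weight
#' and the ingredient's (route-specific) DDDch, and accumulates mass and
#' nDDDch by farm, age category and antimicrobial class. The calculation is
#' performed separately per ingredient and the resulting numbers added up,
#' so combination products contribute one term per active ingredient.
#'
#' @param records Data frame of usage records with columns `farm_id`,
#'   `product_id`, `quantity` (dispensing units, >= 0), `age_category` and
#'   optionally `year`.
#' @param formulary A [new_formulary()] object.
#' @param year Optional calendar year; records from other years are dropped
#'   with a message stating how many were excluded.
#' @param on_error `"stop"` (default) fails on the first record whose
#'   product or DDDch key is unknown; `"exclude"` drops such records and
#'   attaches them as the `excluded` element of the result.
#' @return An object of class `amu_result` with element `by_class`, a tibble
#'   of `farm_id`, `age_category`, `class`, `mass_mg`, `ndddch`. Per-animal
#'   fields are filled in by [per_animal_year()].
#' @export
quantify <- function(records, formulary, year = NULL,
                     on_error = c("stop", "exclude")) {
  stopifnot(inherits(formulary, "formulary"))
  on_error <- match.arg(on_error)
  records <- validate_usage_records(records)

  if (!is.null(year)) {
    if (!"year" %in% names(records)) {
      stop("`year` filter requested but records have no year column",
           call. = FALSE)
    }
    keep <- records$year == year
    if (any(!keep)) {
      message(sum(!keep), " record(s) outside year ", year, " excluded")
    }
    records <- records[keep, , drop = FALSE]
  }
  records$.row <- seq_len(nrow(records))

  comp <- dplyr::inner_join(records, formulary$products, by = "product_id",
                            relationship = "many-to-many")
  unresolved <- setdiff(records$.row, comp$.row)
  excluded <- records[records$farm_id %in% character(0), , drop = FALSE]
  if (length(unresolved) > 0) {
    if (on_error == "stop") {
      r <- records[unresolved[1], ]
      stop("usage record ", unresolved[1], " (farm ", r$farm_id,
           "): unknown product_id '", r$product_id, "'", call. = FALSE)
    }
    excluded <- records[records$.row %in% unresolved, , drop = FALSE]
    message(length(unresolved), " record(s) with unknown products excluded")
    comp <- comp[!comp$.row %in% unresolved, , drop = FALSE]
  }

  comp <- dplyr::left_join(comp, formulary$dddch,
                           by = c("ingredient", "route"))
  no_dose <- which(is.na(comp$dose_mg_per_kg))
  if (length(no_dose) > 0) {
    if (on_error == "stop") {
      stop("usage record ", comp$.row[no_dose[1]], " (product ",
           comp$product_id[no_dose[1]], "): no DDDch entry for (",
           comp$ingredient[no_dose[1]], ", ", comp$route[no_dose[1]], ")",
           call. = FALSE)
    }
    bad_rows <- unique(comp$.row[no_dose])
    excluded <- dplyr::bind_rows(
      excluded, records[records$.row %in% bad_rows, , drop = FALSE])
    message(length(bad_rows), " record(s) without DDDch entry excluded")
    comp <- comp[!comp$.row %in% bad_rows, , drop = FALSE]
  }

  comp$amount_mg <- comp$concentration_mg_per_unit * comp$quantity
  comp$weight_kg <- unname(formulary$weights[comp$age_category])
  comp$ndddch <- record_ndddch(comp$amount_mg, comp$dose_mg_per_kg,
                               comp$weight_kg)

  by_class <- comp |>
    dplyr::group_by(.data$farm_id, .data$age_category, .data$class) |>
    dplyr::summarise(mass_mg = sum(.data$amount_mg),
                     ndddch = sum(.data$ndddch), .groups = "drop") |>
    dplyr::arrange(.data$farm_id,
                   factor(.data$age_category, levels = age_categories()),
                   .data$class)

  structure(
    list(by_class = by_class, per_animal = NULL, farm_totals = NULL,
         year = year,
         excluded = if (nrow(excluded) > 0) {
           excluded[setdiff(names(excluded), ".row")]
         } else NULL),
    class = "amu_result"
  )
}

#' @export
print.amu_result <- function(x, ...) {
  cat("<amu_result>\n")
  cat("  farms:", length(unique(x$by_class$farm_id)),
      " cells:", nrow(x$by_class),
      " total nDDDch:", format(sum(x$by_class$ndddch), digits = 6),
      " total mass (kg):", format(sum(x$by_class$mass_mg) / 1e6, digits = 4),
      "\n")
  if (!is.null(x$per_animal)) {
    cat("  per-animal values filled for",
        length(unique(x$per_animal$farm_id)), "farms\n")
  }
  invisible(x)
}

validate_census <- function(censuses) {
  censuses <- tibble::as_tibble(censuses)
  req <- c("farm_id", "age_category", "n_animals")
  miss <- setdiff(req, names(censuses))
  if (length(miss) > 0) {
    stop("census lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- which(!censuses$age_category %in% age_categories())
  if (length(bad_cat) > 0) {
    stop("census row ", bad_cat[1], ": unknown age category '",
         censuses$age_category[bad_cat[1]], "'", call. = FALSE)
  }
  if (any(!is.finite(censuses$n_animals) | censuses$n_animals < 0)) {
    stop("census counts must be non-negative", call. = FALSE)
  }
  full <- tidyr::expand_grid(farm_id = unique(censuses$farm_id),
                             age_category = age_categories())
  miss_cells <- dplyr::anti_join(full, censuses,
                                 by = c("farm_id", "age_category"))
  if (nrow(miss_cells) > 0) {
    stop("census incomplete: farm ", miss_cells$farm_id[1],
         " lacks category ", miss_cells$age_category[1], call. = FALSE)
  }
  censuses
}

#' Usage per animal and year
#'
#' Divides each farm-and-category nDDDch total by the number of animals in
#' the denominator for that category: sows are counted as animals kept,
#' piglets, weaners and fatteners as animals produced in the year. The farm
#' total is the plain sum of the four per-animal category values. Farms
#' present in the census but without any usage stay in the result with value
#' zero. A category with zero animals but non-zero usage is undefined and
#' reported as `NA` (never 0 or infinity), with a warning.
#'
#' @param amu_result Result of [quantify()].
#' @param censuses Long census tibble with columns `farm_id`, `age_category`,
#'   `n_animals`; see [read_census()]. Every farm with usage must be present.
#' @return The `amu_result` with `per_animal` (tibble: `farm_id`,
#'   `age_category`, `ndddch`, `n_animals`, `ndddch_per_animal_year`) and
#'   `farm_totals` (tibble: `farm_id`, `total_ndddch`,
#'   `total_ndddch_per_animal_year`) filled in.
#' @export
per_animal_year <- function(amu_result, censuses) {
  stopifnot(inherits(amu_result, "amu_result"))
  censuses <- validate_census(censuses)

  usage_farms <- unique(amu_result$by_class$farm_id)
  missing_farms <- setdiff(usage_farms, censuses$farm_id)
  if (length(missing_farms) > 0) {
    stop("no census for farm(s) with usage: ",
         paste(missing_farms, collapse = ", "), call. = FALSE)
  }

  cat_totals <- amu_result$by_class |>
    dplyr::group_by(.data$farm_id, .data$age_category) |>
    dplyr::summarise(ndddch = sum(.data$ndddch), .groups = "drop")

  per_animal <- censuses |>
    dplyr::left_join(cat_totals, by = c("farm_id", "age_category")) |>
    dplyr::mutate(ndddch = dplyr::coalesce(.data$ndddch, 0)) |>
    dplyr::mutate(ndddch_per_animal_year = dplyr::case_when(
      .data$n_animals > 0 ~ .data$ndddch / .data$n_animals,
      .data$ndddch == 0 ~ 0,
      TRUE ~ NA_real_
    )) |>
    dplyr::arrange(.data$farm_id,
                   factor(.data$age_category, levels = age_categories()))

  n_undef <- sum(is.na(per_animal$ndddch_per_animal_year))
  if (n_undef > 0) {
    warning(n_undef, " farm-category cell(s) have usage but zero animals; ",
            "per-animal value undefined (NA)", call. = FALSE)
  }

  farm_totals <- per_animal |>
    dplyr::group_by(.data$farm_id) |>
    dplyr::summarise(
      total_ndddch = sum(.data$ndddch),
      total_ndddch_per_animal_year = sum(.data$ndddch_per_animal_year),
      .groups = "drop")

  amu_result$per_animal <- per_animal
  amu_result$farm_totals <- farm_totals
  amu_result
}

#' Per-animal usage in wide (one row per farm) form
#'
#' Convenience reshaping used by the regression suite: one row per farm with
#' the four per-animal category values, the farm total and the sow count
#' (herd size).
#'
#' @param amu_result An `amu_result` after [per_animal_year()].
#' @return Tibble with columns `farm_id`, `piglet`, `weaner`, `fattener`,
#'   `sow`, `total`, `sows_kept`.
#' @export
per_animal_wide <- function(amu_result) {
  stopifnot(inherits(amu_result, "amu_result"))
  if (is.null(amu_result$per_animal)) {
    stop("per-animal values not filled; run per_animal_year() first",
         call. = FALSE)
  }
  wide <- amu_result$per_animal |>
    dplyr::select("farm_id", "age_category", "ndddch_per_animal_year") |>
    tidyr::pivot_wider(names_from = "age_category",
                       values_from = "ndddch_per_animal_year")
  sows <- amu_result$per_animal |>
    dplyr::filter(.data$age_category == "sow") |>
    dplyr::select("farm_id", sows_kept = "n_animals")
  wide |>
    dplyr::left_join(amu_result$farm_totals[
      c("farm_id", "total_ndddch_per_animal_year")], by = "farm_id") |>
    dplyr::rename(total = "total_ndddch_per_animal_year") |>
    dplyr::left_join(sows, by = "farm_id")
}
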