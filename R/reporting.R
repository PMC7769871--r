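#' Round half away from zero
#'
#' Display rounding used for the percentage tables: exact halves round away
#' from zero (so 2.5 -> 3), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

category_totals_from_df <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"age_category" %in% names(x) || !"ndddch" %in% names(x)) {
    stop("expected columns age_category and ndddch", call. = FALSE)
  }
  if ("mass_kg" %in% names(x)) {
    x$mass_mg <- x$mass_kg * 1e6
  }
  if (!"mass_mg" %in% names(x)) {
    stop("expected a mass_mg or mass_kg column", call. = FALSE)
  }
  x |>
    dplyr::group_by(.data$age_category) |>
    dplyr::summarise(ndddch = sum(.data$ndddch),
                     mass_mg = sum(.data$mass_mg), .groups = "drop")
}

#' Distribution of usage across age categories
#'
#' Totals and relative shares of antimicrobial consumption per age category
#' under both metrics: number of defined daily doses (nDDDch) and mass of
#' active ingredient (kg). Shares are computed on the unrounded totals and
#' kept unrounded; the `*_share_display` columns carry the half-up integer
#' rounding used for presentation. An `overall` row holds the totals.
#'
#' @param x An `amu_result`, or a data frame with columns `age_category`,
#'   `ndddch` and `mass_mg` (or `mass_kg`).
#' @return Tibble with one row per category plus `overall`: `ndddch_total`,
#'   `ndddch_share_pct`, `ndddch_share_display`, `mass_kg`,
#'   `mass_share_pct`, `mass_share_display`.
#' @export
category_distribution <- function(x) {
  UseMethod("category_distribution")
}

#' @export
category_distribution.amu_result <- function(x) {
  category_distribution(x$by_class)
}

#' @export
category_distribution.data.frame <- function(x) {
  tot <- category_totals_from_df(x)
  tot <- tot[order(match(tot$age_category, age_categories())), ]
  grand_n <- sum(tot$ndddch)
  grand_m <- sum(tot$mass_mg)
  share <- function(v, tot) if (tot > 0) 100 * v / tot else rep(0, length(v))
  out <- tibble::tibble(
    age_category = tot$age_category,
    ndddch_total = tot$ndddch,
    ndddch_share_pct = share(tot$ndddch, grand_n),
    mass_kg = tot$mass_mg / 1e6,
    mass_share_pct = share(tot$mass_mg, grand_m)
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    age_category = "overall", ndddch_total = grand_n,
    ndddch_share_pct = if (grand_n > 0) 100 else 0,
    mass_kg = grand_m / 1e6,
    mass_share_pct = if (grand_m > 0) 100 else 0))
  out$ndddch_share_display <- round_half_up(out$ndddch_share_pct)
  out$mass_share_display <- round_half_up(out$mass_share_pct)
  out[c("age_category", "ndddch_total", "ndddch_share_pct",
        "ndddch_share_display", "mass_kg", "mass_share_pct",
        "mass_share_display")]
}

#' Distribution of usage across antimicrobial classes
#'
#' Per-class totals and relative shares under one metric, either overall or
#' restricted to one age category.
#'
#' @param x An `amu_result`, or a data frame with columns `class` and
#'   `ndddch` / `mass_mg` (or `mass_kg`).
#' @param metric `"ndddch"` or `"mass"`.
#' @param category Optional age category to restrict to; default is the
#'   whole population.
#' @return Tibble with `class`, `total` (nDDDch, or kg for the mass metric),
#'   `share_pct` (unrounded) and `share_display` (half-up integer percent).
#' @export
class_distribution <- function(x, metric = c("ndddch", "mass"),
                               category = NULL) {
  UseMethod("class_distribution")
}

#' @export
class_distribution.amu_result <- function(x, metric = c("ndddch", "mass"),
                                          category = NULL) {
  class_distribution(x$by_class, metric = metric, category = category)
}

#' @export
class_distribution.data.frame <- function(x, metric = c("ndddch", "mass"),
                                          category = NULL) {
  metric <- match.arg(metric)
  x <- tibble::as_tibble(x)
  if (!"class" %in% names(x)) {
    stop("expected a class column", call. = FALSE)
  }
  if (!is.null(category)) {
    stopifnot(category %in% age_categories())
    x <- x[x$age_category == category, , drop = FALSE]
  }
  if (metric == "ndddch") {
    x$.value <- x$ndddch
    scale <- 1
  } else {
    if ("mass_kg" %in% names(x)) x$mass_mg <- x$mass_kg * 1e6
    x$.value <- x$mass_mg
    scale <- 1e6
  }
  tot <- x |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(total = sum(.data$.value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total))
  grand <- sum(tot$total)
  tot$share_pct <- if (grand > 0) 100 * tot$total / grand else 0
  tot$total <- tot$total / scale
  tot$share_display <- round_half_up(tot$share_pct)
  tot
}

#' Share of HPCIA classes in total usage
#'
#' Sums the class shares over the classes configured as highest priority
#' critically important antimicrobials.
#'
#' @inheritParams class_distribution
#' @param formulary A `formulary` supplying the HPCIA set, or `NULL` if
#'   `hpcia_classes` is given directly.
#' @param hpcia_classes Optional character vector overriding the
#'   formulary's HPCIA set.
#' @return Unrounded share in percent (scalar).
#' @export
hpcia_share <- function(x, formulary = NULL, metric = c("ndddch", "mass"),
                        category = NULL, hpcia_classes = NULL) {
  if (is.null(hpcia_classes)) {
    if (is.null(formulary)) {
      stop("supply either a formulary or hpcia_classes", call. = FALSE)
    }
    hpcia_classes <- formulary$hpcia_classes
  }
  dist <- class_distribution(x, metric = metric, category = category)
  sum(dist$share_pct[dist$class %in% hpcia_classes])
}

#' Descriptive statistics of a distribution
#'
#' The summary used for herd-size and per-animal usage tables: mean, median,
#' SD, extremes, quartiles and a t-based 95% confidence interval for the
#' mean, `mean +/- t(n-1, 0.975) * sd / sqrt(n)`. Quartiles use linear
#' interpolation between order statistics (type 7 by default; type 6
#' available via `quartile_type`). With n = 1 the SD and CI are reported as
#' `NA`.
#'
#' @param values Numeric vector, n >= 1; `NA`s are dropped with a warning.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (7 = linear interpolation default, 6 = SPSS-style).
#' @return One-row tibble: `n`, `mean`, `median`, `sd`, `min`, `max`,
#'   `q25`, `q75`, `ci95_low`, `ci95_high`.
#' @export
describe <- function(values, quartile_type = 7) {
  if (anyNA(values)) {
    warning(sum(is.na(values)), " NA value(s) dropped", call. = FALSE)
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  half <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  tibble::tibble(
    n = n, mean = m, median = q[2], sd = s,
    min = min(values), max = max(values), q25 = q[1], q75 = q[3],
    ci95_low = m - half, ci95_high = m + half
  )
}

#' Descriptive tables per age category
#'
#' Applies [describe()] to each age category (and the farm totals, as
#' `overall`) of a per-animal usage table or a census.
#'
#' @param values_by_category Tibble with columns `farm_id`, `age_category`
#'   and a value column.
#' @param value Name of the value column (string).
#' @param overall Optional numeric vector summarised as an `overall` row.
#' @inheritParams describe
#' @return Tibble with one row per category.
#' @export
describe_by_category <- function(values_by_category, value, overall = NULL,
                                 quartile_type = 7) {
  values_by_category <- tibble::as_tibble(values_by_category)
  out <- lapply(age_categories(), function(cat) {
    v <- values_by_category[[value]][values_by_category$age_category == cat]
    dplyr::bind_cols(tibble::tibble(age_category = cat), describe(v,
      quartile_type = quartile_type))
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(overall)) {
    out <- dplyr::bind_rows(out, dplyr::bind_cols(
      tibble::tibble(age_category = "overall"),
      describe(overall, quartile_type = quartile_type)))
  }
  out
}
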