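#' Age categories of a farrow-to-finish pig farm
#'
#' The four production stages used throughout the package: piglet (birth to
#' end of week 4 of life), weaner (weeks 5--12), fattener (week 13 to
#' slaughter) and sow (including gilts and boars from 7 months of age).
#' Every usage record and census entry is allocated to exactly one of them.
#'
#' @return Character vector of the four category labels, in age order.
#' @export
age_categories <- function() {
  c("piglet", "weaner", "fattener", "sow")
}

#' ESVAC standard weights per age category
#'
#' Standardised live weights (kg) used to convert an ingredient mass into a
#' number of defined daily doses: 4 kg for piglets, 12 kg for weaners,
#' 50 kg for fatteners and 220 kg for sows.
#'
#' @return Named numeric vector (kg), one entry per age category.
#' @export
default_standard_weights <- function() {
  c(piglet = 4, weaner = 12, fattener = 50, sow = 220)
}

#' Default HPCIA class set
#'
#' The WHO highest priority critically important antimicrobial classes
#' relevant to pig medicine: cephalosporins, fluoroquinolones, macrolides
#' and polypeptides (colistin).
#'
#' @return Character vector of class identifiers.
#' @export
default_hpcia_classes <- function() {
  c("cephalosporins", "fluoroquinolones", "macrolides", "polypeptides")
}

#' Administration routes/forms distinguished by the defined-dose registry
#' @return Character vector of valid route labels.
#' @export
dddch_routes <- function() {
  c("injectable", "oral_premix", "oral_other", "other")
}

#' Construct a validated formulary
#'
#' A formulary bundles all reference data the usage calculations depend on:
#' the standard weight per age category, the registry of defined daily doses
#' Switzerland (DDDch, mg active ingredient per kg bodyweight per day, keyed
#' by ingredient and route/form), the product compositions (mg of each active
#' ingredient per dispensing unit), and the set of antimicrobial classes
#' counted as HPCIA.
#'
#' DDDch values are national reference values and must be supplied by the
#' user; the registry shipped with the package (see [demo_formulary()]) is
#' illustrative only. Ingredients dosed in international units must be
#' entered already converted to mg/kg.
#'
#' @param weights Named numeric vector of standard weights in kg; one
#'   strictly positive entry per age category.
#' @param dddch Data frame with columns `ingredient`, `class`, `route`,
#'   `dose_mg_per_kg` and optionally logical `hpcia`. `(ingredient, route)`
#'   must be unique and doses strictly positive.
#' @param products Data frame with columns `product_id`, `ingredient`,
#'   `concentration_mg_per_unit`, `unit`, `route`; combination products carry
#'   one row per active ingredient, concentrations strictly positive.
#' @param hpcia_classes Character vector of class identifiers counted as
#'   HPCIA. Defaults to the classes flagged in `dddch$hpcia` when that column
#'   exists, otherwise to [default_hpcia_classes()].
#' @return An object of class `formulary`.
#' @export
new_formulary <- function(weights, dddch, products, hpcia_classes = NULL) {
  cats <- age_categories()
  if (!is.numeric(weights) || is.null(names(weights))) {
    stop("`weights` must be a named numeric vector", call. = FALSE)
  }
  missing_w <- setdiff(cats, names(weights))
  if (length(missing_w) > 0) {
    stop("standard weight missing for category: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  extra_w <- setdiff(names(weights), cats)
  if (length(extra_w) > 0) {
    stop("unknown age category in weights: ",
         paste(extra_w, collapse = ", "),
         "; valid categories are: ", paste(cats, collapse = ", "),
         call. = FALSE)
  }
  weights <- weights[cats]
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("standard weights must be strictly positive", call. = FALSE)
  }

  dddch <- tibble::as_tibble(dddch)
  req <- c("ingredient", "class", "route", "dose_mg_per_kg")
  miss <- setdiff(req, names(dddch))
  if (length(miss) > 0) {
    stop("dddch table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_route <- which(!dddch$route %in% dddch_routes())
  if (length(bad_route) > 0) {
    stop("dddch row ", bad_route[1], ": unknown route '",
         dddch$route[bad_route[1]], "'; valid routes are: ",
         paste(dddch_routes(), collapse = ", "), call. = FALSE)
  }
  bad_dose <- which(!is.finite(dddch$dose_mg_per_kg) | dddch$dose_mg_per_kg <= 0)
  if (length(bad_dose) > 0) {
    stop("dddch row ", bad_dose[1], " (", dddch$ingredient[bad_dose[1]],
         ", ", dddch$route[bad_dose[1]],
         "): dose_mg_per_kg must be strictly positive", call. = FALSE)
  }
  key <- paste(dddch$ingredient, dddch$route, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("dddch row ", dup[1], ": duplicate (ingredient, route) key (",
         dddch$ingredient[dup[1]], ", ", dddch$route[dup[1]], ")",
         call. = FALSE)
  }

  products <- tibble::as_tibble(products)
  reqp <- c("product_id", "ingredient", "concentration_mg_per_unit", "unit",
            "route")
  missp <- setdiff(reqp, names(products))
  if (length(missp) > 0) {
    stop("products table lacks column(s): ", paste(missp, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(products) > 0) {
    bad_conc <- which(!is.finite(products$concentration_mg_per_unit) |
                        products$concentration_mg_per_unit <= 0)
    if (length(bad_conc) > 0) {
      stop("products row ", bad_conc[1], " (", products$product_id[bad_conc[1]],
           "): concentration_mg_per_unit must be strictly positive",
           call. = FALSE)
    }
    dup_comp <- which(duplicated(products[c("product_id", "ingredient")]))
    if (length(dup_comp) > 0) {
      stop("products row ", dup_comp[1], ": duplicate component (",
           products$product_id[dup_comp[1]], ", ",
           products$ingredient[dup_comp[1]], ")", call. = FALSE)
    }
  }

  if (is.null(hpcia_classes)) {
    if ("hpcia" %in% names(dddch)) {
      hpcia_classes <- sort(unique(dddch$class[as.logical(dddch$hpcia)]))
    } else {
      hpcia_classes <- default_hpcia_classes()
    }
  }
  if (!"hpcia" %in% names(dddch)) {
    dddch$hpcia <- dddch$class %in% hpcia_classes
  }

  structure(
    list(weights = weights, dddch = dddch, products = products,
         hpcia_classes = as.character(hpcia_classes)),
    class = "formulary"
  )
}

#' @export
print.formulary <- function(x, ...) {
  cat("<formulary>\n")
  cat("  standard weights (kg):",
      paste(names(x$weights), x$weights, sep = "=", collapse = ", "), "\n")
  cat("  DDDch entries:", nrow(x$dddch), "(",
      length(unique(x$dddch$class)), "classes )\n")
  cat("  products:", length(unique(x$products$product_id)), "\n")
  cat("  HPCIA classes:", paste(x$hpcia_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Load a formulary from a directory of CSV files
#'
#' Expects three UTF-8 CSV files with header rows in `path`:
#' `weights.csv` (`category,weight_kg`), `dddch.csv`
#' (`ingredient,class,route,dose_mg_per_kg,hpcia`) and `products.csv`
#' (`product_id,ingredient,concentration_mg_per_unit,unit,route`). All
#' invariants are enforced at load time; violations raise an error naming
#' the offending row.
#'
#' @param path Directory containing the three CSV files.
#' @return A validated `formulary` object.
#' @seealso [write_formulary()], [demo_formulary()]
#' @export
load_formulary <- function(path) {
  files <- file.path(path, c("weights.csv", "dddch.csv", "products.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("formulary file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wtab <- readr::read_csv(files[1], col_types = readr::cols(
    category = readr::col_character(), weight_kg = readr::col_double()))
  weights <- stats::setNames(wtab$weight_kg, wtab$category)
  dddch <- readr::read_csv(files[2], col_types = readr::cols(
    ingredient = readr::col_character(), class = readr::col_character(),
    route = readr::col_character(), dose_mg_per_kg = readr::col_double(),
    hpcia = readr::col_logical()))
  products <- readr::read_csv(files[3], col_types = readr::cols(
    product_id = readr::col_character(), ingredient = readr::col_character(),
    concentration_mg_per_unit = readr::col_double(),
    unit = readr::col_character(), route = readr::col_character()))
  new_formulary(weights, dddch, products)
}

#' Write a formulary back to its CSV representation
#'
#' Inverse of [load_formulary()]; loading the written directory yields an
#' identical registry.
#'
#' @param formulary A `formulary` object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_formulary <- function(formulary, path) {
  stopifnot(inherits(formulary, "formulary"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble::tibble(category = names(formulary$weights),
                   weight_kg = unname(formulary$weights)),
    file.path(path, "weights.csv"))
  readr::write_csv(formulary$dddch, file.path(path, "dddch.csv"))
  readr::write_csv(formulary$products, file.path(path, "products.csv"))
  invisible(path)
}

#' Illustrative demo formulary
#'
#' A small synthetic formulary used by the examples, tests and the synthetic
#' cohort generator. Its DDDch values are plausible in magnitude but are NOT
#' the national reference values; any real analysis must load the official
#' registry via [load_formulary()].
#'
#' @return A `formulary` object.
#' @export
demo_formulary <- function() {
  load_formulary(system.file("extdata", "formulary_demo",
                             package = "pigamu", mustWork = TRUE))
}

#' Resolve a product prescription into ingredient amounts
#'
#' Multiplies the dispensed quantity by the concentration of each active
#' ingredient; a combination product yields one row per ingredient.
#'
#' @param formulary A `formulary`.
#' @param product_id Product identifier registered in the formulary.
#' @param quantity Dispensed quantity (in the product's dispensing unit),
#'   must be >= 0.
#' @return Tibble with columns `ingredient`, `amount_mg`, `route`.
#' @export
resolve_product <- function(formulary, product_id, quantity) {
  stopifnot(inherits(formulary, "formulary"))
  if (!is.numeric(quantity) || length(quantity) != 1 || !is.finite(quantity) ||
        quantity < 0) {
    stop("`quantity` must be a single non-negative number", call. = FALSE)
  }
  comp <- formulary$products[formulary$products$product_id == product_id, ]
  if (nrow(comp) == 0) {
    stop("unknown product_id '", product_id, "'; known products: ",
         paste(sort(unique(formulary$products$product_id)), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    ingredient = comp$ingredient,
    amount_mg = comp$concentration_mg_per_unit * quantity,
    route = comp$route
  )
}

#' Look up a defined daily dose
#'
#' Returns the registered DDDch (mg/kg) for an (ingredient, route) key.
#' There is no fallback across routes: national defined doses differ by
#' formulation, so a missing key is an error, never a silent substitution.
#'
#' @param formulary A `formulary`.
#' @param ingredient Active ingredient identifier.
#' @param route Route/form label, see [dddch_routes()].
#' @return The dose in mg per kg bodyweight per day (positive scalar).
#' @export
lookup_dddch <- function(formulary, ingredient, route) {
  stopifnot(inherits(formulary, "formulary"))
  hit <- formulary$dddch$ingredient == ingredient & formulary$dddch$route == route
  if (!any(hit)) {
    stop("no DDDch entry for (", ingredient, ", ", route, ")", call. = FALSE)
  }
  formulary$dddch$dose_mg_per_kg[which(hit)[1]]
}

#' Is an antimicrobial class an HPCIA?
#'
#' @param formulary A `formulary`.
#' @param antimicrobial_class Class identifier(s).
#' @return Logical vector: `TRUE` where the class is in the configured
#'   HPCIA set.
#' @export
is_hpcia <- function(formulary, antimicrobial_class) {
  stopifnot(inherits(formulary, "formulary"))
  antimicrobial_class %in% formulary$hpcia_classes
}
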