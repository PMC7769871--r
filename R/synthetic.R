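#' Default synthetic cohort configuration
#'
#' Parameters of the synthetic farrow-to-finish cohort generator. The
#' defaults describe a population of 71 farms with a right-skewed sow herd
#' size distribution (mean about 79 and SD about 43 sows, truncated to
#' 10--220), produced-animal counts proportional to the sow count (about 30
#' piglets, 26 weaners and 12 fatteners per sow and year, with 20%
#' lognormal noise), zero-inflated lognormal per-animal usage in every age
#' category (medians near 0.5, 0.7, 0.04 and 2.1 nDDDch/animal/year for
#' piglets, weaners, fatteners and sows, capped at the observed maxima),
#' a positive linear linkage of piglet usage to sow usage, and a
#' multiplicative herd-size effect on the farm-total usage. The linkage and
#' herd-size parameters are calibrated so that cohorts reproduce, in
#' expectation, an adjusted R-squared of about 0.19 for the piglet-on-sow
#' regression and about 0.06 for the total-usage-on-herd-size regression.
#'
#' @return A list of class `sim_config`.
#' @export
default_config <- function() {
  structure(list(
    n_farms = 71L,
    year = 2017L,
    herd = list(
      meanlog = log(70), sdlog = 0.55, min = 10, max = 220,
      ratios = c(piglet = 30.3, weaner = 26.1, fattener = 11.8),
      ratio_cv = 0.2
    ),
    usage = list(
      piglet = list(p_zero = 0.15, meanlog = -1.20, sdlog = 1.10, cap = 11.5),
      weaner = list(p_zero = 0.20, meanlog = 0.02, sdlog = 1.49, cap = 13.3),
      fattener = list(p_zero = 0.35, meanlog = -1.78, sdlog = 1.96, cap = 9.9),
      sow = list(p_zero = 0.10, meanlog = 0.80, sdlog = 1.04, cap = 13.8)
    ),
    linkage = list(slope = 0.10),
    herd_effect = list(gamma = 0.50, center = 70),
    class_mix = list(
      piglet = c(penicillins = 0.60, aminoglycosides = 0.10,
                 macrolides = 0.10, polypeptides = 0.10,
                 cephalosporins = 0.05, fluoroquinolones = 0.05),
      weaner = c(sulfonamides = 0.35, tetracyclines = 0.30,
                 penicillins = 0.20, polypeptides = 0.10, macrolides = 0.05),
      fattener = c(penicillins = 0.60, tetracyclines = 0.25,
                   macrolides = 0.15),
      sow = c(penicillins = 0.70, tetracyclines = 0.15, macrolides = 0.15)
    )
  ), class = "sim_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  if (config$n_farms < 3) stop("n_farms must be >= 3", call. = FALSE)
  for (cat in age_categories()) {
    u <- config$usage[[cat]]
    if (is.null(u)) stop("usage model missing for ", cat, call. = FALSE)
    if (u$p_zero < 0 || u$p_zero > 1) {
      stop("p_zero must be in [0, 1] for ", cat, call. = FALSE)
    }
    if (u$sdlog <= 0 || u$cap <= 0) {
      stop("sdlog and cap must be positive for ", cat, call. = FALSE)
    }
  }
  if (config$herd$sdlog <= 0 || config$herd$min <= 0 ||
        config$herd$max <= config$herd$min) {
    stop("invalid herd size model", call. = FALSE)
  }
  invisible(config)
}

# Truncated lognormal draw via inverse-CDF so the truncation is exact and
# the RNG stream length does not depend on the draws.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

# Zero-inflated lognormal per-animal usage draws for one category.
draw_usage <- function(n, model) {
  zero <- stats::runif(n) < model$p_zero
  value <- stats::rlnorm(n, model$meanlog, model$sdlog)
  ifelse(zero, 0, value)
}

#' Generate a synthetic farm cohort
#'
#' Draws a cohort of farrow-to-finish farms: a census (sows kept; piglets,
#' weaners and fatteners produced per year) and latent per-animal usage
#' targets (nDDDch/animal/year) per farm and age category. Sow herd sizes
#' come from a truncated lognormal; produced-animal counts scale the sow
#' count by category-specific ratios with lognormal noise; usage is
#' zero-inflated lognormal per category, with piglet usage linear in sow
#' usage plus noise, a multiplicative herd-size tilt
#' `(sows / center)^gamma` applied to all categories, and each category
#' capped at its configured maximum. Fully deterministic given
#' `(config, seed)`.
#'
#' @param config A `sim_config`, see [default_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `census` (long tibble
#'   `farm_id`, `age_category`, `n_animals`), `targets` (tibble `farm_id`,
#'   `age_category`, `target`, the latent nDDDch/animal/year), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = default_config(), seed) {
  validate_config(config)
  n <- config$n_farms
  withr::with_seed(seed, {
    sows <- pmin(pmax(round(rlnorm_trunc(
      n, config$herd$meanlog, config$herd$sdlog,
      config$herd$min, config$herd$max)), config$herd$min), config$herd$max)

    cv <- config$herd$ratio_cv
    sdl <- sqrt(log(1 + cv^2))
    produced <- sapply(c("piglet", "weaner", "fattener"), function(cat) {
      noise <- stats::rlnorm(n, -sdl^2 / 2, sdl)
      pmax(round(sows * config$herd$ratios[[cat]] * noise), 1)
    })

    u_sow <- draw_usage(n, config$usage$sow)
    u_weaner <- draw_usage(n, config$usage$weaner)
    u_fattener <- draw_usage(n, config$usage$fattener)
    eps_piglet <- draw_usage(n, config$usage$piglet)
    # the zero-inflation indicator of the piglet model switches off the
    # whole linked value, so piglet zeros occur regardless of sow usage
    u_piglet <- ifelse(eps_piglet > 0,
                       config$linkage$slope * u_sow + eps_piglet, 0)

    tilt <- (sows / config$herd_effect$center)^config$herd_effect$gamma
    u <- cbind(piglet = u_piglet, weaner = u_weaner,
               fattener = u_fattener, sow = u_sow) * tilt
    caps <- vapply(age_categories(), function(cat) config$usage[[cat]]$cap,
                   numeric(1))
    u <- pmin(u, rep(caps[colnames(u)], each = n))
  })

  farm_id <- sprintf("farm_%03d", seq_len(n))
  census <- tibble::tibble(
    farm_id = rep(farm_id, times = 4),
    age_category = rep(age_categories(), each = n),
    n_animals = c(produced[, "piglet"], produced[, "weaner"],
                  produced[, "fattener"], sows)
  )
  targets <- tibble::tibble(
    farm_id = rep(farm_id, times = 4),
    age_category = rep(age_categories(), each = n),
    target = c(u[, "piglet"], u[, "weaner"], u[, "fattener"], u[, "sow"])
  )
  structure(list(census = census, targets = targets, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_farms, " farms, seed ", x$seed,
      "\n", sep = "")
  cat("  median per-animal targets:",
      paste(age_categories(), vapply(age_categories(), function(cat) {
        format(stats::median(x$targets$target[x$targets$age_category == cat]),
               digits = 2)
      }, character(1)), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Single-ingredient products of the formulary with their class and dose,
# one representative product per antimicrobial class.
emission_catalog <- function(formulary) {
  p <- formulary$products
  single <- names(which(table(p$product_id) == 1))
  cat <- dplyr::inner_join(p[p$product_id %in% single, ], formulary$dddch,
                           by = c("ingredient", "route"))
  cat[!duplicated(cat$class), ]
}

#' Emit prescription records reproducing latent usage targets
#'
#' Inverse of the quantification formulas: for every farm and age category
#' with a positive latent target, draws an antimicrobial class mix
#' (weights from the configuration; penicillin-dominated except for
#' weaners, where premix classes dominate) and computes product quantities
#' such that [quantify()] followed by [per_animal_year()] reproduces the
#' target exactly: `quantity = nDDDch * dose * weight / concentration`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param formulary Formulary supplying products and doses (default
#'   [demo_formulary()]).
#' @param seed Integer seed for the class-mix draws.
#' @return Tibble of usage records: `farm_id`, `product_id`, `quantity`,
#'   `unit`, `age_category`, `year`.
#' @export
emit_usage_records <- function(cohort, formulary = demo_formulary(), seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  catalog <- emission_catalog(formulary)
  weights <- formulary$weights

  work <- dplyr::inner_join(cohort$targets, cohort$census,
                            by = c("farm_id", "age_category"))
  work <- work[work$target > 0 & work$n_animals > 0, , drop = FALSE]
  if (nrow(work) == 0) {
    return(tibble::tibble(farm_id = character(), product_id = character(),
                          quantity = double(), unit = character(),
                          age_category = character(), year = integer()))
  }
  work$total_ndddch <- work$target * work$n_animals

  mixes <- cohort$config$class_mix
  out <- withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(work)), function(i) {
      cat_i <- work$age_category[i]
      w <- mixes[[cat_i]]
      w <- w[names(w) %in% catalog$class]
      if (length(w) == 0) {
        stop("no emittable product for any class in the ", cat_i,
             " class mix", call. = FALSE)
      }
      k <- sample.int(min(3L, length(w)), 1)
      chosen <- if (length(w) == 1) names(w) else {
        sample(names(w), k, prob = w)
      }
      split <- w[chosen] / sum(w[chosen])
      prod <- catalog[match(chosen, catalog$class), ]
      ndd <- work$total_ndddch[i] * split
      qty <- ndd * prod$dose_mg_per_kg * weights[[cat_i]] /
        prod$concentration_mg_per_unit
      tibble::tibble(farm_id = work$farm_id[i], product_id = prod$product_id,
                     quantity = unname(qty), unit = prod$unit,
                     age_category = cat_i,
                     year = cohort$config$year)
    })
    dplyr::bind_rows(rows)
  })
  out
}
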