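# Minimal in-code fixtures shared across tests.

tiny_formulary <- function() {
  new_formulary(
    weights = c(piglet = 4, weaner = 12, fattener = 50, sow = 220),
    dddch = tibble::tibble(
      ingredient = c("amoxicillin", "amoxicillin", "sulfadimidine",
                     "trimethoprim", "tylosin"),
      class = c("penicillins", "penicillins", "sulfonamides",
                "diaminopyrimidines", "macrolides"),
      route = c("injectable", "oral_other", "oral_premix", "oral_premix",
                "injectable"),
      dose_mg_per_kg = c(20, 40, 25, 5, 10),
      hpcia = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    products = tibble::tibble(
      product_id = c("amox_inj", "amox_oral", "combo_premix", "combo_premix",
                     "tylo_inj"),
      ingredient = c("amoxicillin", "amoxicillin", "sulfadimidine",
                     "trimethoprim", "tylosin"),
      concentration_mg_per_unit = c(100, 500, 100, 20, 200),
      unit = c("ml", "g", "g", "g", "ml"),
      route = c("injectable", "oral_other", "oral_premix", "oral_premix",
                "injectable")
    )
  )
}

tiny_census <- function(farms = c("A", "B")) {
  tidyr::expand_grid(farm_id = farms, age_category = age_categories()) |>
    dplyr::mutate(n_animals = dplyr::case_when(
      age_category == "piglet" ~ 2000,
      age_category == "weaner" ~ 1800,
      age_category == "fattener" ~ 800,
      age_category == "sow" ~ 70
    ))
}

usage_record <- function(farm_id, product_id, quantity, age_category,
                         year = 2017) {
  tibble::tibble(farm_id = farm_id, product_id = product_id,
                 quantity = quantity, age_category = age_category,
                 year = year)
}

# Independent brute-force quantification: one record and one component at a
# time, plain arithmetic, no grouping machinery.
brute_force_quantify <- function(records, formulary) {
  cells <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    comp <- formulary$products[
      formulary$products$product_id == rec$product_id, ]
    for (j in seq_len(nrow(comp))) {
      dose <- formulary$dddch$dose_mg_per_kg[
        formulary$dddch$ingredient == comp$ingredient[j] &
          formulary$dddch$route == comp$route[j]]
      cls <- formulary$dddch$class[
        formulary$dddch$ingredient == comp$ingredient[j] &
          formulary$dddch$route == comp$route[j]]
      amount <- comp$concentration_mg_per_unit[j] * rec$quantity
      nd <- amount / (dose * formulary$weights[[rec$age_category]])
      key <- paste(rec$farm_id, rec$age_category, cls, sep = "|")
      if (is.null(cells[[key]])) cells[[key]] <- c(mass = 0, ndddch = 0)
      cells[[key]] <- cells[[key]] + c(mass = amount, ndddch = nd)
    }
  }
  cells
}

# Kruskal-Wallis H computed from first principles (midranks, tie-corrected),
# independent of the package implementation.
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, grp, sum)
  ns <- lengths(groups)
  ties <- table(pooled)
  cdiv <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cdiv == 0) return(0)
  ((12 / (n * (n + 1))) * sum(rs^2 / ns) - 3 * (n + 1)) / cdiv
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis statistic.
oracle_kw_perm_p <- function(groups, n_perm = 1e4) {
  pooled <- unlist(groups)
  ns <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  hs <- replicate(n_perm, {
    shuffled <- sample(pooled)
    oracle_kw_h(split(shuffled, rep(seq_along(ns), ns)))
  })
  mean(hs >= h_obs - 1e-10)
}
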