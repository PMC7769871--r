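test_that("record_ndddch matches hand evaluations of the dose formula", {
  expect_equal(record_ndddch(8000, 20, 12), 8000 / 240,
               tolerance = 1e-12)
  expect_equal(record_ndddch(2200, 10, 220), 1.0, tolerance = 1e-12)
  expect_equal(record_ndddch(0, 5, 4), 0)
  expect_error(record_ndddch(100, 0, 12), "positive")
  expect_error(record_ndddch(100, 20, -4), "positive")
  expect_error(record_ndddch(-1, 20, 12), "non-negative")
})

test_that("quantify composes product resolution and the dose formula", {
  f <- tiny_formulary()
  # one record: 80 ml of 100 mg/ml amoxicillin to weaners = 8000 mg
  rec <- usage_record("A", "amox_inj", 80, "weaner")
  amu <- quantify(rec, f)
  expect_equal(nrow(amu$by_class), 1)
  expect_equal(amu$by_class$mass_mg, 8000)
  expect_equal(amu$by_class$ndddch, 8000 / (20 * 12), tolerance = 1e-12)
})

test_that("quantify is order-independent and linear in quantities", {
  f <- tiny_formulary()
  recs <- dplyr::bind_rows(
    usage_record("A", "amox_inj", 80, "weaner"),
    usage_record("A", "combo_premix", 10, "weaner"),
    usage_record("B", "tylo_inj", 5, "sow"),
    usage_record("A", "amox_inj", 20, "piglet"),
    usage_record("B", "amox_oral", 3, "fattener")
  )
  a1 <- quantify(recs, f)
  a2 <- quantify(recs[sample(nrow(recs)), ], f)
  expect_equal(a1$by_class, a2$by_class)

  doubled <- recs
  doubled$quantity <- doubled$quantity * 2
  a3 <- quantify(doubled, f)
  expect_equal(a3$by_class$mass_mg, a1$by_class$mass_mg * 2)
  expect_equal(a3$by_class$ndddch, a1$by_class$ndddch * 2)
})

test_that("quantify matches a brute-force per-record oracle", {
  f <- tiny_formulary()
  set.seed(11)
  recs <- tibble::tibble(
    farm_id = sample(c("A", "B"), 5, replace = TRUE),
    product_id = sample(c("amox_inj", "amox_oral", "combo_premix",
                          "tylo_inj"), 5, replace = TRUE),
    quantity = round(runif(5, 0, 50), 2),
    age_category = sample(age_categories(), 5, replace = TRUE),
    year = 2017
  )
  amu <- quantify(recs, f)
  oracle <- brute_force_quantify(recs, f)
  expect_equal(nrow(amu$by_class), length(oracle))
  for (i in seq_len(nrow(amu$by_class))) {
    key <- paste(amu$by_class$farm_id[i], amu$by_class$age_category[i],
                 amu$by_class$class[i], sep = "|")
    expect_equal(amu$by_class$mass_mg[i], unname(oracle[[key]]["mass"]),
                 tolerance = 1e-12)
    expect_equal(amu$by_class$ndddch[i], unname(oracle[[key]]["ndddch"]),
                 tolerance = 1e-12)
  }
})

test_that("nDDDch is conserved across class, category and farm roll-ups", {
  f <- demo_formulary()
  co <- generate_cohort(default_config(), 5)
  recs <- emit_usage_records(co, f, seed = 6)
  amu <- per_animal_year(quantify(recs, f), co$census)
  total <- sum(amu$by_class$ndddch)
  by_cat <- tapply(amu$by_class$ndddch,
                   amu$by_class$age_category, sum)
  by_farm <- tapply(amu$by_class$ndddch, amu$by_class$farm_id, sum)
  expect_equal(sum(by_cat), total)
  expect_equal(sum(by_farm), total)
  expect_equal(sum(amu$per_animal$ndddch), total)
  expect_equal(sum(amu$farm_totals$total_ndddch), total)
})

test_that("unresolvable records fail loudly, or are excluded on request", {
  f <- tiny_formulary()
  recs <- dplyr::bind_rows(
    usage_record("A", "amox_inj", 10, "weaner"),
    usage_record("A", "mystery_product", 5, "sow")
  )
  expect_error(quantify(recs, f), "mystery_product")
  expect_message(amu <- quantify(recs, f, on_error = "exclude"), "excluded")
  expect_equal(nrow(amu$by_class), 1)
  expect_equal(amu$excluded$product_id, "mystery_product")

  # registered product whose ingredient/route has no DDDch entry
  f2 <- tiny_formulary()
  f2$products <- dplyr::bind_rows(
    f2$products,
    tibble::tibble(product_id = "colistin_oral", ingredient = "colistin",
                   concentration_mg_per_unit = 50, unit = "g",
                   route = "oral_other"))
  expect_error(quantify(usage_record("A", "colistin_oral", 1, "piglet"), f2),
               "no DDDch entry")
})

test_that("year filtering excludes off-year records with a message", {
  f <- tiny_formulary()
  recs <- dplyr::bind_rows(
    usage_record("A", "amox_inj", 10, "weaner", year = 2017),
    usage_record("A", "amox_inj", 99, "weaner", year = 2016)
  )
  expect_message(amu <- quantify(recs, f, year = 2017), "1 record")
  expect_equal(amu$by_class$mass_mg, 1000)
})

test_that("empty record sets quantify to an all-zero result", {
  f <- tiny_formulary()
  amu <- quantify(usage_record(character(), character(), double(),
                               character()), f)
  expect_equal(nrow(amu$by_class), 0)
  amu <- per_animal_year(amu, tiny_census("A"))
  expect_equal(amu$per_animal$ndddch_per_animal_year, rep(0, 4))
  expect_equal(amu$farm_totals$total_ndddch_per_animal_year, 0)
})

test_that("per-animal values divide category totals by the census count", {
  f <- tiny_formulary()
  # 1000 nDDDch to weaners: 1000 * 20 * 12 mg amox = 240000 mg = 2400 ml
  rec <- usage_record("A", "amox_inj", 2400, "weaner")
  amu <- per_animal_year(quantify(rec, f), tiny_census("A"))
  w <- amu$per_animal
  expect_equal(w$ndddch[w$age_category == "weaner"], 1000, tolerance = 1e-12)
  expect_equal(w$ndddch_per_animal_year[w$age_category == "weaner"],
               1000 / 1800, tolerance = 1e-12)
  # zero-usage categories of the same farm stay at 0
  expect_equal(w$ndddch_per_animal_year[w$age_category != "weaner"],
               rep(0, 3))
})

test_that("the farm total is the plain sum of the four category values", {
  per_animal <- tibble::tibble(
    farm_id = "X", age_category = age_categories(),
    n_animals = c(2000, 1800, 800, 70),
    ndddch = c(0.5, 0.7, 0.04, 2.1) * c(2000, 1800, 800, 70)
  )
  amu <- structure(list(by_class = tibble::tibble(
    farm_id = "X", age_category = per_animal$age_category,
    class = "penicillins", mass_mg = 1, ndddch = per_animal$ndddch
  ), per_animal = NULL, farm_totals = NULL), class = "amu_result")
  amu <- per_animal_year(amu, per_animal[c("farm_id", "age_category",
                                           "n_animals")])
  expect_equal(amu$farm_totals$total_ndddch_per_animal_year, 3.34,
               tolerance = 1e-12)
})

test_that("zero animals with non-zero usage is undefined, not 0 or Inf", {
  f <- tiny_formulary()
  census <- tiny_census("A")
  census$n_animals[census$age_category == "fattener"] <- 0
  rec <- usage_record("A", "amox_oral", 10, "fattener")
  expect_warning(amu <- per_animal_year(quantify(rec, f), census),
                 "undefined")
  fa <- amu$per_animal[amu$per_animal$age_category == "fattener", ]
  expect_true(is.na(fa$ndddch_per_animal_year))
  # zero animals with zero usage is a clean 0
  census2 <- census
  rec2 <- usage_record("A", "amox_inj", 10, "weaner")
  amu2 <- per_animal_year(quantify(rec2, f), census2)
  expect_equal(amu2$per_animal$ndddch_per_animal_year[
    amu2$per_animal$age_category == "fattener"], 0)
})

test_that("usage on a farm missing from the census is a hard error", {
  f <- tiny_formulary()
  rec <- usage_record("GHOST", "amox_inj", 10, "weaner")
  expect_error(per_animal_year(quantify(rec, f), tiny_census("A")),
               "GHOST")
})
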