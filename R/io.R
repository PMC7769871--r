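#' Read usage records from CSV
#'
#' Expects a UTF-8 CSV with header
#' `farm_id,product_id,quantity,unit,age_category,year`. Every row is
#' validated; the first malformed row raises an error naming its line
#' number. Unknown age-category labels are rejected with the list of valid
#' labels (gilts and boars count as sows). An empty file with a header
#' yields an empty record set with a warning.
#'
#' @param path CSV file path.
#' @return Tibble of validated usage records.
#' @export
read_usage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types =
                                 readr::cols(.default = readr::col_character()),
                               show_col_types = FALSE))
  req <- c("farm_id", "product_id", "quantity", "age_category", "year")
  miss <- setdiff(req, hdr)
  if (length(miss) > 0) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    farm_id = readr::col_character(), product_id = readr::col_character(),
    quantity = readr::col_double(), unit = readr::col_character(),
    age_category = readr::col_character(), year = readr::col_integer()))
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop(path, " line ", prob$row[1] + 1, ": could not parse ",
         prob$col[1], " (expected ", prob$expected[1], ")", call. = FALSE)
  }
  if (nrow(x) == 0) {
    warning(path, ": no usage records", call. = FALSE)
    return(x)
  }
  bad_cat <- which(!x$age_category %in% age_categories())
  if (length(bad_cat) > 0) {
    stop(path, " line ", bad_cat[1] + 1, ": unknown age category '",
         x$age_category[bad_cat[1]], "'; valid labels are: ",
         paste(age_categories(), collapse = ", "),
         " (gilts and boars count as sows)", call. = FALSE)
  }
  bad_q <- which(is.na(x$quantity) | x$quantity < 0)
  if (length(bad_q) > 0) {
    stop(path, " line ", bad_q[1] + 1,
         ": quantity must be a non-negative number", call. = FALSE)
  }
  x
}

#' Read a farm census from CSV
#'
#' Expects `farm_id,piglets,weaners,fatteners,sows` with one row per farm:
#' sows kept, and piglets/weaners/fatteners produced per year. Returned in
#' long form (`farm_id`, `age_category`, `n_animals`) as consumed by
#' [per_animal_year()].
#'
#' @param path CSV file path.
#' @return Long census tibble.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types =
                                 readr::cols(.default = readr::col_character()),
                               show_col_types = FALSE))
  req <- c("farm_id", "piglets", "weaners", "fatteners", "sows")
  miss <- setdiff(req, hdr)
  if (length(miss) > 0) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    farm_id = readr::col_character(), piglets = readr::col_double(),
    weaners = readr::col_double(), fatteners = readr::col_double(),
    sows = readr::col_double()))
  dup <- which(duplicated(x$farm_id))
  if (length(dup) > 0) {
    stop(path, ": duplicate farm_id '", x$farm_id[dup[1]], "'",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(x, cols = -"farm_id",
                              names_to = "age_category",
                              values_to = "n_animals")
  long$age_category <- unname(c(piglets = "piglet", weaners = "weaner",
                                fatteners = "fattener",
                                sows = "sow")[long$age_category])
  validate_census(long)
}

#' Write a cohort's census in the wide CSV schema
#' @param censuses Long census tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(censuses, path) {
  wide <- tidyr::pivot_wider(censuses, names_from = "age_category",
                             values_from = "n_animals")
  wide <- wide[c("farm_id", "piglet", "weaner", "fattener", "sow")]
  names(wide) <- c("farm_id", "piglets", "weaners", "fatteners", "sows")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Simulate a cohort and write its input files
#'
#' Generates a synthetic cohort, emits its prescription records, and writes
#' `usage.csv`, `census.csv` and a `provenance.json` (configuration, seed,
#' package version) to a directory — the synthetic stand-in for a
#' monitoring-programme data export.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (cohort and record emission derive their own
#'   streams from it).
#' @param out_dir Output directory, created if needed.
#' @param formulary Formulary used for record emission.
#' @return Invisibly, a list with the cohort and the written paths.
#' @export
simulate_to_csv <- function(config = default_config(), seed, out_dir,
                            formulary = demo_formulary()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, seed)
  records <- emit_usage_records(cohort, formulary, seed = seed + 1L)
  usage_path <- file.path(out_dir, "usage.csv")
  census_path <- file.path(out_dir, "census.csv")
  readr::write_csv(records, usage_path)
  write_census(cohort$census, census_path)
  prov <- list(
    seed = seed,
    package = "pigamu",
    version = as.character(utils::packageVersion("pigamu")),
    config = unclass(config)
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(cohort = cohort, usage = usage_path, census = census_path,
                 provenance = prov_path))
}

#' Run the full monitoring pipeline on input files
#'
#' Reads a formulary, usage records and a census; quantifies usage as mass
#' and nDDDch; computes per-animal values; and writes the full report
#' bundle as tidy CSV files: quantification results, the age-category and
#' antimicrobial-class distribution tables, HPCIA shares, descriptive
#' statistics of herd sizes and per-animal usage, the Kruskal-Wallis test
#' with Bonferroni-corrected pairwise comparisons, the regression suite,
#' and a JSON manifest with input checksums. Outputs are deterministic:
#' identical inputs yield byte-identical files.
#'
#' @param formulary_dir Directory with the formulary CSVs.
#' @param usage_path Usage records CSV.
#' @param census_path Census CSV.
#' @param out_dir Output directory.
#' @param year Optional year filter for usage records.
#' @param pairwise `"rank_sum"` or `"signed_rank"` post-hoc flavour.
#' @param quartile_type Quantile convention for descriptive tables.
#' @param alpha Significance level recorded in the stats output.
#' @return Invisibly, a list with all computed objects and file paths.
#' @export
run_pipeline <- function(formulary_dir, usage_path, census_path, out_dir,
                         year = NULL, pairwise = "rank_sum",
                         quartile_type = 7, alpha = 0.05) {
  formulary <- load_formulary(formulary_dir)
  records <- read_usage(usage_path)
  censuses <- read_census(census_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  amu <- quantify(records, formulary, year = year)
  amu <- per_animal_year(amu, censuses)
  wide <- per_animal_wide(amu)

  cat_dist <- category_distribution(amu)
  cls_overall_n <- class_distribution(amu, "ndddch")
  cls_overall_m <- class_distribution(amu, "mass")
  hpcia <- tibble::tibble(
    metric = c("ndddch", "mass"),
    share_pct = c(hpcia_share(amu, formulary, "ndddch"),
                  hpcia_share(amu, formulary, "mass")))

  census_desc <- describe_by_category(censuses, "n_animals",
                                      quartile_type = quartile_type)
  usage_desc <- describe_by_category(
    amu$per_animal, "ndddch_per_animal_year",
    overall = wide$total, quartile_type = quartile_type)

  groups <- lapply(stats::setNames(age_categories(), age_categories()),
                   function(cat) {
    v <- amu$per_animal$ndddch_per_animal_year[
      amu$per_animal$age_category == cat]
    v[!is.na(v)]
  })
  kw <- kruskal_wallis(groups)
  posthoc <- pairwise_posthoc(groups, method = pairwise)
  posthoc$significant <- posthoc$p_adj <= alpha
  regressions <- regression_suite(wide)
  regressions$significant <- regressions$p_value <= alpha

  paths <- list(
    quantification = file.path(out_dir, "quantification.csv"),
    per_animal = file.path(out_dir, "per_animal.csv"),
    category_distribution = file.path(out_dir, "category_distribution.csv"),
    class_distribution_ndddch = file.path(out_dir,
                                          "class_distribution_ndddch.csv"),
    class_distribution_mass = file.path(out_dir,
                                        "class_distribution_mass.csv"),
    hpcia_share = file.path(out_dir, "hpcia_share.csv"),
    census_descriptives = file.path(out_dir, "census_descriptives.csv"),
    usage_descriptives = file.path(out_dir, "usage_descriptives.csv"),
    kruskal_wallis = file.path(out_dir, "kruskal_wallis.csv"),
    pairwise = file.path(out_dir, "pairwise_posthoc.csv"),
    regressions = file.path(out_dir, "regressions.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(amu$by_class, paths$quantification)
  readr::write_csv(amu$per_animal, paths$per_animal)
  readr::write_csv(cat_dist, paths$category_distribution)
  readr::write_csv(cls_overall_n, paths$class_distribution_ndddch)
  readr::write_csv(cls_overall_m, paths$class_distribution_mass)
  readr::write_csv(hpcia, paths$hpcia_share)
  readr::write_csv(census_desc, paths$census_descriptives)
  readr::write_csv(usage_desc, paths$usage_descriptives)
  readr::write_csv(tibble::tibble(H = kw$H, df = kw$df,
                                  p_value = kw$p_value),
                   paths$kruskal_wallis)
  readr::write_csv(posthoc, paths$pairwise)
  readr::write_csv(regressions, paths$regressions)

  manifest <- list(
    package = "pigamu",
    version = as.character(utils::packageVersion("pigamu")),
    inputs = list(
      formulary_dir = formulary_dir,
      usage = list(path = usage_path,
                   md5 = unname(tools::md5sum(usage_path))),
      census = list(path = census_path,
                    md5 = unname(tools::md5sum(census_path)))
    ),
    options = list(year = year, pairwise = pairwise,
                   quartile_type = quartile_type, alpha = alpha)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    formulary = formulary, amu = amu, wide = wide,
    category_distribution = cat_dist,
    class_distribution = list(ndddch = cls_overall_n, mass = cls_overall_m),
    hpcia_share = hpcia, census_descriptives = census_desc,
    usage_descriptives = usage_desc, kruskal_wallis = kw,
    pairwise = posthoc, regressions = regressions, paths = paths
  ))
}
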