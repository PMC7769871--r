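# Exact permutation distribution of sum(R_j^2 / n_j): enumerate every
# distinct assignment of the pooled (mid)ranks to groups of the given sizes.
enum_ranksq <- function(ranks, sizes) {
  if (length(sizes) == 1) {
    return(sum(ranks)^2 / sizes[1])
  }
  picks <- utils::combn(seq_along(ranks), sizes[1])
  out <- vector("list", ncol(picks))
  for (i in seq_len(ncol(picks))) {
    idx <- picks[, i]
    out[[i]] <- sum(ranks[idx])^2 / sizes[1] +
      enum_ranksq(ranks[-idx], sizes[-1])
  }
  unlist(out)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based omnibus comparison of two or more groups, as used to compare
#' per-animal usage across the four age categories. The statistic uses
#' midranks with the standard tie-correction divisor; the p-value comes from
#' the chi-square approximation with `k - 1` degrees of freedom. For small
#' samples (total N <= 10) an exact permutation p-value can be requested,
#' computed by full enumeration of all distinct assignments of the pooled
#' ranks to the groups. When every pooled observation is identical the
#' statistic is 0 and p is 1.
#'
#' @param groups List of numeric vectors, each of length >= 1, at least two
#'   groups and a pooled N >= 3.
#' @param exact If `TRUE`, also compute the exact permutation p-value
#'   (requires total N <= 10).
#' @return Object of class `group_comparison`: `H`, `df`, `p_value`
#'   (chi-square), `p_exact` (or `NA`), group sizes `n`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) < 3) {
    stop("each group needs n >= 1 and pooled N >= 3", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), ns))
  k <- length(groups)

  if (length(unique(pooled)) == 1) {
    h <- 0
    p_chisq <- 1
  } else {
    kt <- stats::kruskal.test(pooled, grp)
    h <- unname(kt$statistic)
    p_chisq <- kt$p.value
  }

  p_exact <- NA_real_
  if (exact) {
    n <- sum(ns)
    if (n > 10) {
      stop("exact permutation p only supported for total N <= 10",
           call. = FALSE)
    }
    if (length(unique(pooled)) == 1) {
      p_exact <- 1
    } else {
      r <- rank(pooled)
      ties <- table(pooled)
      tie_div <- 1 - sum(ties^3 - ties) / (n^3 - n)
      ssq <- enum_ranksq(r, as.integer(ns))
      h_all <- ((12 / (n * (n + 1))) * ssq - 3 * (n + 1)) / tie_div
      p_exact <- mean(h_all >= h - 1e-10)
    }
  }

  structure(
    list(H = h, df = k - 1L, p_value = p_chisq, p_exact = p_exact, n = ns),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$H, digits = 4), ", df =", x$df,
      ", p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.na(x$p_exact)) {
    cat("  exact permutation p =", format(x$p_exact, digits = 4), "\n")
  }
  invisible(x)
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' Two-sided rank-based tests for every pair of groups, with the raw
#' p-values multiplied by the number of pairs `k(k-1)/2` (capped at 1).
#' The default flavour is the unpaired Wilcoxon rank-sum test; the paired
#' signed-rank flavour is available for designs where the groups are
#' measurements on the same farms (requires equal lengths in aligned order).
#' Exact p-values are used for small tie-free samples, otherwise the normal
#' approximation with continuity correction (the [stats::wilcox.test()]
#' conventions).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param method `"rank_sum"` (unpaired, default) or `"signed_rank"`
#'   (paired).
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p_raw`, `p_adj`.
#' @export
pairwise_posthoc <- function(groups, method = c("rank_sum", "signed_rank")) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (method == "signed_rank" && length(unique(lengths(groups))) != 1) {
    stop("signed_rank requires equal group lengths (aligned farms)",
         call. = FALSE)
  }
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1, i]]]
    b <- groups[[pairs[2, i]]]
    if (method == "rank_sum") {
      if (length(unique(c(a, b))) == 1) {
        stat <- length(a) * length(b) / 2
        p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        stat <- unname(wt$statistic)
        p <- wt$p.value
      }
    } else {
      d <- a - b
      if (all(d == 0)) {
        stat <- 0
        p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
        stat <- unname(wt$statistic)
        p <- wt$p.value
      }
    }
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   statistic = stat, p_raw = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out
}

#' Simple linear regression
#'
#' Ordinary least squares of one response on one predictor, with the
#' two-sided t-test on the slope and the adjusted coefficient of
#' determination `adj_r2 = 1 - (1 - r2) (n - 1) / (n - 2)`.
#'
#' @param x Predictor values (not constant, n >= 3 complete pairs).
#' @param y Response values of the same length.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `slope_se`, `t_statistic`, `p_value`, `r2`, `adj_r2`, `n`, plus the
#'   `x`, `fitted` values and `residuals` for diagnostics.
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (any(!ok)) {
    message(sum(!ok), " incomplete pair(s) dropped")
    x <- x[ok]
    y <- y[ok]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: predictor is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # a noiseless linkage is a legitimate input; keep summary.lm quiet about it
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  co <- sm$coefficients
  structure(
    list(slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
         slope_se = co["x", "Std. Error"], t_statistic = co["x", "t value"],
         p_value = co["x", "Pr(>|t|)"], r2 = sm$r.squared,
         adj_r2 = sm$adj.r.squared, n = n,
         x = x, fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit))),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS: slope =", format(x$slope, digits = 4),
      "(SE", format(x$slope_se, digits = 3), "), p =",
      format.pval(x$p_value, digits = 3),
      ", R2 =", format(x$r2, digits = 3),
      ", adj R2 =", format(x$adj_r2, digits = 3),
      ", n =", x$n, "\n")
  invisible(x)
}

#' Regression suite over age categories and herd size
#'
#' Runs the seven simple linear regressions of the monitoring analysis on a
#' one-row-per-farm table: the six within-herd predictor-response pairs
#' among per-animal usage values (sows-piglets, sows-weaners, sows-fatteners,
#' piglets-weaners, piglets-fatteners, weaners-fatteners; the older category
#' is always the predictor), and the regression of the farm-total per-animal
#' usage on herd size (sows kept).
#'
#' @param wide Tibble as produced by [per_animal_wide()]: columns `piglet`,
#'   `weaner`, `fattener`, `sow`, `total`, `sows_kept`.
#' @return Tibble with one row per model (`predictor`, `response`, `n`,
#'   `slope`, `intercept`, `slope_se`, `t_statistic`, `p_value`, `r2`,
#'   `adj_r2`); the fitted `regression_result` objects are attached as the
#'   `"fits"` attribute.
#' @export
regression_suite <- function(wide) {
  wide <- tibble::as_tibble(wide)
  need <- c("piglet", "weaner", "fattener", "sow", "total", "sows_kept")
  miss <- setdiff(need, names(wide))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  models <- list(
    c("sow", "piglet"), c("sow", "weaner"), c("sow", "fattener"),
    c("piglet", "weaner"), c("piglet", "fattener"), c("weaner", "fattener"),
    c("sows_kept", "total")
  )
  fits <- lapply(models, function(m) {
    simple_regression(wide[[m[1]]], wide[[m[2]]])
  })
  out <- dplyr::bind_rows(lapply(seq_along(models), function(i) {
    f <- fits[[i]]
    tibble::tibble(predictor = models[[i]][1], response = models[[i]][2],
                   n = f$n, slope = f$slope, intercept = f$intercept,
                   slope_se = f$slope_se, t_statistic = f$t_statistic,
                   p_value = f$p_value, r2 = f$r2, adj_r2 = f$adj_r2)
  }))
  names(fits) <- paste(out$predictor, out$response, sep = "->")
  attr(out, "fits") <- fits
  out
}

#' Residual diagnostics for a fitted regression
#'
#' Advisory checks of the OLS assumptions; they never alter the estimates.
#' Normality of residuals is assessed with the Shapiro-Wilk test and
#' homoscedasticity with the studentized Breusch-Pagan statistic, i.e. the
#' auxiliary regression of the squared residuals on the predictor
#' (`LM = n R^2_aux`, chi-square with 1 df). Residual-versus-fitted data is
#' returned for plotting. With all-zero residuals (a perfect fit) the tests
#' are not assessable.
#'
#' @param fit A `regression_result` from [simple_regression()].
#' @param alpha Significance level for the verdict flags.
#' @return List: `assessable`, `normality` (`statistic`, `p_value`,
#'   `rejected`), `heteroscedasticity` (`statistic`, `df`, `p_value`,
#'   `flagged`), `resid_fitted` tibble.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "regression_result"))
  e <- fit$residuals
  rf <- tibble::tibble(fitted = fit$fitted, residual = e)
  # residuals indistinguishable from zero at double precision: perfect fit
  if (all(abs(e) < 1e-10 * max(1, max(abs(fit$fitted))))) {
    return(list(assessable = FALSE,
                normality = list(statistic = NA_real_, p_value = NA_real_,
                                 rejected = NA),
                heteroscedasticity = list(statistic = NA_real_, df = 1L,
                                          p_value = NA_real_, flagged = NA),
                resid_fitted = rf))
  }
  sw <- stats::shapiro.test(e)
  aux <- stats::lm(I(e^2) ~ fit$x)
  r2_aux <- summary(aux)$r.squared
  lm_stat <- fit$n * r2_aux
  p_bp <- stats::pchisq(lm_stat, df = 1, lower.tail = FALSE)
  list(
    assessable = TRUE,
    normality = list(statistic = unname(sw$statistic), p_value = sw$p.value,
                     rejected = sw$p.value <= alpha),
    heteroscedasticity = list(statistic = lm_stat, df = 1L, p_value = p_bp,
                              flagged = p_bp <= alpha),
    resid_fitted = rf
  )
}
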