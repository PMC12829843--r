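.trend_variables <- c(
  "overall_y", "collection_y", "description_y", "n_authors",
  "n_species_per_year", "n_papers_per_year", "n_species_per_paper",
  "n_types", "pct_genetics", "n_trips"
)

#' Yearly series of a tracked variable
#'
#' Aggregates a variable by publication year: per-species variables (the
#' three lag periods, numbers of authors, types and trips) are averaged over
#' the species described that year; `n_species_per_year` and
#' `n_papers_per_year` are counts (papers counted by distinct publication
#' id); `n_species_per_paper` is the mean over distinct papers;
#' `pct_genetics` is the percentage of that year's species whose description
#' used genetic data. Years with no described species are absent from the
#' series, not zero-filled.
#'
#' @param records A [new_records()] object.
#' @param lags The matching [compute_lags()] tibble.
#' @param variable One of `overall_y`, `collection_y`, `description_y`,
#'   `n_authors`, `n_species_per_year`, `n_papers_per_year`,
#'   `n_species_per_paper`, `n_types`, `pct_genetics`, `n_trips`.
#' @param scope `"global"` or a region name.
#' @return A tibble `year`, `value`, `n` (species contributing, or papers
#'   for the per-paper variables) with class `taxalag_series`; the variable
#'   name is kept in attribute `"variable"`.
#' @export
yearly_series <- function(records, lags, variable, scope = "global") {
  if (!variable %in% .trend_variables) {
    stop(sprintf("unknown variable '%s'", variable))
  }
  df <- dplyr::inner_join(records$species, lags[, c("species", "overall_y",
    "collection_y", "description_y", "n_trips")], by = "species")
  if (!identical(scope, "global")) df <- df[df$region == scope, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("no records in scope '%s'", scope))
  df$year <- as.integer(format(df$publication_date, "%Y"))
  out <- if (variable %in% c("overall_y", "collection_y", "description_y",
                             "n_authors", "n_types", "n_trips")) {
    dplyr::summarise(dplyr::group_by(df, .data$year),
      value = mean(.data[[variable]]), n = dplyr::n(), .groups = "drop")
  } else if (variable == "n_species_per_year") {
    dplyr::summarise(dplyr::group_by(df, .data$year),
      value = dplyr::n(), n = dplyr::n(), .groups = "drop")
  } else if (variable == "n_papers_per_year") {
    dplyr::summarise(dplyr::group_by(df, .data$year),
      value = dplyr::n_distinct(.data$publication_id),
      n = dplyr::n_distinct(.data$publication_id), .groups = "drop")
  } else if (variable == "n_species_per_paper") {
    papers <- dplyr::summarise(dplyr::group_by(df, .data$year, .data$publication_id),
      k = dplyr::n(), .groups = "drop")
    dplyr::summarise(dplyr::group_by(papers, .data$year),
      value = mean(.data$k), n = dplyr::n(), .groups = "drop")
  } else { # pct_genetics
    dplyr::summarise(dplyr::group_by(df, .data$year),
      value = 100 * mean(.data$genetics), n = dplyr::n(), .groups = "drop")
  }
  out <- dplyr::arrange(out, .data$year)
  attr(out, "variable") <- variable
  attr(out, "scope") <- scope
  class(out) <- c("taxalag_series", class(out))
  out
}

#' Trend test with linear-versus-additive model selection
#'
#' Fits an ordinary linear regression of the yearly values on year and a
#' penalized cubic-spline additive model (basis dimension `min(8, n - 1)`,
#' smoothness by generalized cross-validation), compares their unadjusted
#' R-squared, and reports the p-value of the better-fitting method: the
#' slope p for the linear model, the smooth-term p for the additive model.
#' With fewer than `min_gam` points only the linear model is fitted (with a
#' message). Ties in R-squared go to the simpler linear model.
#'
#' @param series A [yearly_series()] tibble (or any tibble with `year` and
#'   `value`).
#' @param min_gam Minimum number of yearly points for the additive model.
#' @return A list of class `taxalag_trend`: `method` (`"LM"` or `"GAM"`),
#'   `r2_lm`, `r2_gam`, `p_value`, `p_lm`, `p_gam_smooth`, `slope` (LM
#'   slope per year), `fitted` tibble (`year`, `fit_lm`, `fit_gam`).
#' @export
fit_trend <- function(series, min_gam = 5L) {
  stopifnot(all(c("year", "value") %in% names(series)))
  n <- nrow(series)
  if (n < 3L) stop("need at least 3 yearly points for a trend test")
  year <- as.numeric(series$year)
  value <- as.numeric(series$value)
  tss <- sum((value - mean(value))^2)
  lm_fit <- stats::lm(value ~ year)
  r2_lm <- if (tss > 0) 1 - sum(stats::resid(lm_fit)^2) / tss else 0
  p_lm <- stats::coef(summary(lm_fit))["year", "Pr(>|t|)"]
  gam_fit <- NULL
  r2_gam <- NA_real_
  p_gam <- NA_real_
  if (n >= min_gam) {
    k <- min(8L, n - 1L)
    gam_fit <- mgcv::gam(value ~ s(year, k = k, bs = "cr"), method = "GCV.Cp")
    r2_gam <- if (tss > 0) 1 - sum(stats::resid(gam_fit)^2) / tss else 0
    p_gam <- summary(gam_fit)$s.table[1, "p-value"]
  } else {
    message("fewer than ", min_gam, " yearly points; using the linear model only")
  }
  use_gam <- !is.na(r2_gam) && r2_gam > r2_lm
  structure(
    list(
      method = if (use_gam) "GAM" else "LM",
      r2_lm = r2_lm,
      r2_gam = r2_gam,
      p_value = if (use_gam) p_gam else p_lm,
      p_lm = p_lm,
      p_gam_smooth = p_gam,
      slope = unname(stats::coef(lm_fit)["year"]),
      fitted = tibble::tibble(
        year = series$year,
        fit_lm = unname(stats::fitted(lm_fit)),
        fit_gam = if (is.null(gam_fit)) rep(NA_real_, n) else unname(stats::fitted(gam_fit))
      )
    ),
    class = "taxalag_trend"
  )
}

#' @export
print.taxalag_trend <- function(x, ...) {
  cat(sprintf(
    "<taxalag_trend> chosen %s (R2 LM %.3f, GAM %s), p = %.4g\n",
    x$method, x$r2_lm,
    if (is.na(x$r2_gam)) "-" else sprintf("%.3f", x$r2_gam), x$p_value
  ))
  invisible(x)
}

#' Local-regression smoother for presentation
#'
#' Locally weighted quadratic regression (tricube weights, default span
#' 0.75) evaluated at the observed years. Used only to draw smooth curves;
#' never a source of p-values.
#'
#' @param series A [yearly_series()] tibble.
#' @param span LOESS span (fraction of points in each local window).
#' @return A tibble `year`, `fitted`.
#' @export
loess_smooth <- function(series, span = 0.75) {
  stopifnot(all(c("year", "value") %in% names(series)), nrow(series) >= 4L)
  fit <- stats::loess(value ~ year, data = series, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  tibble::tibble(year = series$year, fitted = unname(stats::fitted(fit)))
}
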