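#' Sample skewness and excess kurtosis
#'
#' Three conventional estimator families, indexed as in the classic
#' taxonomy of skewness/kurtosis estimators: type 1 is the moment
#' estimator (g1 = m3 / m2^1.5, g2 = m4 / m2^2 - 3), type 2 the
#' bias-adjusted variant (G1, G2), and type 3 the variant built on the
#' sample standard deviation (b1 = m3 / s^3, b2 = m4 / s^4 - 3) — the
#' default of the describe-style summary routines this battery mirrors.
#' Kurtosis is excess throughout: a normal sample scores about 0.
#'
#' @param x Numeric vector.
#' @param type Estimator family, 1, 2 or 3 (default 3).
#' @return A single numeric value.
#' @export
skewness <- function(x, type = 3L) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 2L, type %in% 1:3)
  m <- x - mean(x)
  m2 <- mean(m^2)
  m3 <- mean(m^3)
  g1 <- m3 / m2^1.5
  switch(type,
    g1,
    g1 * sqrt(n * (n - 1)) / (n - 2),
    g1 * ((n - 1) / n)^1.5
  )
}

#' @rdname skewness
#' @export
kurtosis <- function(x, type = 3L) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 2L, type %in% 1:3)
  m <- x - mean(x)
  m2 <- mean(m^2)
  m4 <- mean(m^4)
  g2 <- m4 / m2^2 - 3
  switch(type,
    g2,
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
    (g2 + 3) * ((n - 1) / n)^2 - 3
  )
}

#' Distributional summary of a set of lag values
#'
#' The statistic battery reported for each region and period: minimum, mean,
#' standard deviation, 10% trimmed mean (dropping `floor(trim * n)` values
#' from each end after sorting), median, median absolute deviation (scaled by
#' 1.4826 for normal consistency by default; set `mad_scale = 1` for the raw
#' median of absolute differences), maximum, range, skewness, excess
#' kurtosis, standard error of the mean, and the half-width of the normal
#' 95% confidence interval (1.96 standard errors).
#'
#' @param values Numeric vector of lags in years (n >= 2).
#' @param trim Fraction trimmed from each end for the trimmed mean.
#' @param mad_scale Scale constant for the MAD.
#' @param type Skewness/kurtosis estimator family (see [skewness()]).
#' @return A one-row tibble: `n`, `min_y`, `mean_y`, `sd_y`,
#'   `trimmed_mean_y`, `median_y`, `mad_y`, `max_y`, `range_y`, `skew`,
#'   `kurtosis`, `se_y`, `ci_halfwidth_y`.
#' @export
describe <- function(values, trim = 0.10, mad_scale = 1.4826, type = 3L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("describe() needs at least 2 values (SD undefined below that)")
  sd_y <- stats::sd(values)
  se_y <- sd_y / sqrt(n)
  tibble::tibble(
    n = n,
    min_y = min(values),
    mean_y = mean(values),
    sd_y = sd_y,
    trimmed_mean_y = mean(values, trim = trim),
    median_y = stats::median(values),
    mad_y = stats::mad(values, constant = mad_scale),
    max_y = max(values),
    range_y = max(values) - min(values),
    skew = skewness(values, type = type),
    kurtosis = kurtosis(values, type = type),
    se_y = se_y,
    ci_halfwidth_y = 1.96 * se_y
  )
}

.periods <- c(overall = "overall_y", description = "description_y", collection = "collection_y")

#' Summary-table battery per group and period
#'
#' Applies [describe()] to each of the three periods (overall description
#' process, description sensu stricto, collection) within each group —
#' regions, genera, or the pooled global set. Groups with fewer than two
#' species are emitted with the statistics marked unavailable (`NA`) rather
#' than dropped.
#'
#' @param lags The tibble returned by [compute_lags()].
#' @param group_by `"global"`, `"region"`, or `"genus"`.
#' @inheritParams describe
#' @return A tibble with columns `group`, `period`, then the [describe()]
#'   battery; periods ordered overall, description, collection.
#' @export
summary_table <- function(lags, group_by = c("global", "region", "genus"),
                          trim = 0.10, mad_scale = 1.4826, type = 3L) {
  group_by <- match.arg(group_by)
  stopifnot(nrow(lags) > 0L)
  groups <- switch(group_by,
    global = list(GLOBAL = lags),
    region = split(lags, lags$region),
    genus = split(lags, lags$genus)
  )
  purrr::imap_dfr(groups, function(g, name) {
    purrr::imap_dfr(.periods, function(col, period) {
      vals <- g[[col]]
      stats <- if (length(vals[!is.na(vals)]) >= 2L) {
        describe(vals, trim = trim, mad_scale = mad_scale, type = type)
      } else {
        na_row <- describe(c(0, 1))
        na_row[1, ] <- NA
        na_row$n <- length(vals)
        na_row
      }
      dplyr::bind_cols(tibble::tibble(group = name, period = period), stats)
    })
  })
}

#' Write the summary table as CSV
#'
#' Emits the full-precision table and, optionally, a 2-decimal presentation
#' variant alongside it.
#'
#' @param tab A [summary_table()] tibble.
#' @param path Output CSV path.
#' @param presentation_path Optional path for the rounded variant.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tab, path, presentation_path = NULL) {
  readr::write_csv(tab, path, progress = FALSE)
  if (!is.null(presentation_path)) {
    rounded <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))
    readr::write_csv(rounded, presentation_path, progress = FALSE)
  }
  invisible(path)
}
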