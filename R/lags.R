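#' Distinct, sorted collection dates for one species
#'
#' Multiple type specimens collected on the same day count as a single
#' collection event, so the event history of a species is the strictly
#' increasing sequence of its distinct resolved dates.
#'
#' @param dates A `Date` vector (any order, duplicates allowed).
#' @return A strictly increasing `Date` vector.
#' @export
unique_sorted_dates <- function(dates) {
  stopifnot(inherits(dates, "Date"), length(dates) >= 1L)
  sort(unique(dates))
}

#' Segment collection dates into field trips
#'
#' Consecutive collection events more than `gap_days` apart belong to
#' different field trips; events separated by `gap_days` or fewer days share
#' a trip. The default of 30 days encodes the "more than one month" rule, so
#' a 30-day gap still joins and a 31-day gap splits.
#'
#' @param dates Strictly increasing `Date` vector (see
#'   [unique_sorted_dates()]).
#' @param gap_days Strict gap threshold in days.
#' @return Integer vector of trip indices (1, 2, ...) parallel to `dates`.
#' @export
segment_trips <- function(dates, gap_days = 30L) {
  stopifnot(inherits(dates, "Date"), length(dates) >= 1L)
  d <- as.numeric(diff(dates))
  stopifnot(all(d > 0))
  cumsum(c(1L, as.integer(d > gap_days)))
}

#' Decompose the description timeline of each species into three periods
#'
#' For every retained species the interval from the collection of the first
#' (oldest) type specimen to the publication of the description — the overall
#' description process — is split into the collection period (first to last
#' collection event) and the description sensu stricto (last collection event
#' to publication). Day spans are counted on the calendar and converted to
#' years with a fixed 365.25-day year, so the three periods are additive by
#' construction. Field trips are counted with [segment_trips()].
#'
#' @param records A [new_records()] object.
#' @param gap_days Trip-segmentation threshold in days (default 30).
#' @return A tibble with one row per species: `species`, `region`, `genus`,
#'   `overall_y`, `collection_y`, `description_y`, `n_unique_dates`,
#'   `n_trips`.
#' @export
compute_lags <- function(records, gap_days = 30L) {
  stopifnot(inherits(records, "taxalag_records"))
  ev <- split(records$events$resolved,
              factor(records$events$species, levels = records$species$species))
  sp <- records$species
  n <- nrow(sp)
  first <- last <- numeric(n)
  n_unique <- n_trips <- integer(n)
  for (i in seq_len(n)) {
    u <- unique_sorted_dates(ev[[i]])
    first[i] <- as.numeric(u[1L])
    last[i] <- as.numeric(u[length(u)])
    n_unique[i] <- length(u)
    n_trips[i] <- max(segment_trips(u, gap_days))
  }
  pub <- as.numeric(sp$publication_date)
  if (any(pub <= last)) {
    bad <- sp$species[pub <= last]
    stop(sprintf("publication date not after last collection for: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  tibble::tibble(
    species = sp$species,
    region = sp$region,
    genus = sp$genus,
    overall_y = (pub - first) / 365.25,
    collection_y = (last - first) / 365.25,
    description_y = (pub - last) / 365.25,
    n_unique_dates = n_unique,
    n_trips = n_trips
  )
}

#' Fraction of species described within given time spans
#'
#' The cumulative-description curve: for each threshold, the fraction of
#' species whose overall description process took at most that many years.
#'
#' @param overall_y Numeric vector of overall lags in years (one per
#'   species), or the tibble returned by [compute_lags()].
#' @param thresholds Increasing numeric vector of spans in years.
#' @return A tibble with columns `threshold_y` and `fraction`.
#' @export
cumulative_within <- function(overall_y, thresholds) {
  if (is.data.frame(overall_y)) overall_y <- overall_y$overall_y
  if (!length(overall_y)) stop("no lag values supplied")
  stopifnot(is.numeric(thresholds), !is.unsorted(thresholds, strictly = TRUE))
  tibble::tibble(
    threshold_y = thresholds,
    fraction = vapply(thresholds, function(t) mean(overall_y <= t), numeric(1))
  )
}

#' Month-by-year matrix of collection events
#'
#' Counts unique per-species collection dates falling in each calendar month
#' of each year, the table behind the seasonal collection heatmaps. The same
#' calendar date shared by two species counts once per species (uniqueness is
#' per species only).
#'
#' @param records A [new_records()] object.
#' @param region Optional region name; `NULL` pools all regions.
#' @return A tibble in long format — `region`, `year`, `month`, `count` —
#'   zero-filled over months 1-12 of the observed year range.
#' @export
seasonality_matrix <- function(records, region = NULL) {
  stopifnot(inherits(records, "taxalag_records"))
  sp <- records$species
  if (!is.null(region)) sp <- sp[sp$region == region, , drop = FALSE]
  if (!nrow(sp)) stop(sprintf("no records for region '%s'", region %||% "<all>"))
  ev <- records$events[records$events$species %in% sp$species, , drop = FALSE]
  uniq <- dplyr::distinct(ev[, c("species", "resolved")])
  counts <- dplyr::count(
    tibble::tibble(
      year = as.integer(format(uniq$resolved, "%Y")),
      month = as.integer(format(uniq$resolved, "%m"))
    ),
    .data$year, .data$month, name = "count"
  )
  grid <- tidyr::expand_grid(
    year = seq(min(counts$year), max(counts$year)),
    month = 1:12
  )
  out <- dplyr::left_join(grid, counts, by = c("year", "month"))
  out$count <- ifelse(is.na(out$count), 0L, out$count)
  out <- dplyr::bind_cols(tibble::tibble(region = rep(region %||% "GLOBAL", nrow(out))), out)
  class(out) <- c("taxalag_seasonality", class(out))
  out
}

#' Test whether collection effort is spread evenly over the year
#'
#' Pools the month-by-year matrix over years and asks whether every month's
#' total reaches at least `min_ratio` of the peak month's total — the
#' criterion used to call a region's collection activity evenly distributed
#' rather than seasonal. The bound is inclusive ("at least 40%").
#'
#' @param matrix A [seasonality_matrix()] tibble.
#' @param min_ratio Fraction of the peak month's total every month must reach.
#' @return A list with `even` (logical), `ratios` (12 monthly totals divided
#'   by the peak total) and `monthly_totals`.
#' @export
is_evenly_distributed <- function(matrix, min_ratio = 0.40) {
  stopifnot(all(c("month", "count") %in% names(matrix)))
  totals <- vapply(1:12, function(m) sum(matrix$count[matrix$month == m]), numeric(1))
  names(totals) <- 1:12
  if (all(totals == 0)) stop("seasonality matrix has no events")
  ratios <- totals / max(totals)
  list(even = all(ratios >= min_ratio), ratios = ratios, monthly_totals = totals)
}
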