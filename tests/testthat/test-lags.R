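test_that("unique_sorted_dates deduplicates same-day events and sorts", {
  d <- as.Date(c("2005-01-01", "2007-06-10", "2005-01-01"))
  expect_equal(unique_sorted_dates(d), as.Date(c("2005-01-01", "2007-06-10")))
  expect_equal(unique_sorted_dates(as.Date("2001-02-03")), as.Date("2001-02-03"))
  expect_equal(unique_sorted_dates(rev(d)), as.Date(c("2005-01-01", "2007-06-10")))
})

test_that("trip segmentation applies the strict more-than-30-days rule", {
  jan1 <- as.Date("2020-01-01")
  expect_equal(max(segment_trips(jan1 + c(0, 30))), 1L)   # exactly 30 d joins
  expect_equal(max(segment_trips(jan1 + c(0, 31))), 2L)   # 31 d splits
  expect_equal(segment_trips(jan1 + c(0, 19, 74)), c(1L, 1L, 2L))
})

test_that("segmentation equals the connected-components oracle on exhaustive triples", {
  base <- as.Date("2015-03-01")
  offs <- t(utils::combn(1:60, 2))  # all 0 < a < b within a window
  for (i in seq_len(nrow(offs))) {
    dates <- base + c(0L, offs[i, ])
    expect_equal(max(segment_trips(dates)), oracle_trips(dates))
  }
  # random larger instances, several gap thresholds
  set.seed(12)
  for (i in 1:60) {
    dates <- base + sort(sample(0:250, sample(2:8, 1)))
    gap <- sample(c(10L, 30L, 45L), 1)
    expect_equal(max(segment_trips(dates, gap)), oracle_trips(dates, gap))
  }
})

test_that("increasing the gap threshold never increases the trip count", {
  set.seed(5)
  base <- as.Date("2010-01-01")
  for (i in 1:50) {
    dates <- base + sort(sample(0:500, sample(2:10, 1)))
    counts <- vapply(c(5L, 15L, 30L, 60L, 120L),
                     function(g) max(segment_trips(dates, g)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("compute_lags returns additive periods measured in 365.25-day years", {
  rec <- make_records(
    species = c("multi", "single"),
    pub = c("2010-01-01", "2010-06-01"),
    events = list(c("2000-01-01", "2005-01-01"), "2009-06-01")
  )
  lags <- compute_lags(rec)
  m <- lags[lags$species == "multi", ]
  expect_equal(m$collection_y, as.numeric(as.Date("2005-01-01") - as.Date("2000-01-01")) / 365.25)
  expect_equal(m$overall_y, m$collection_y + m$description_y, tolerance = 1e-9)
  s <- lags[lags$species == "single", ]
  expect_equal(s$collection_y, 0)
  expect_equal(s$n_unique_dates, 1L)
  expect_equal(s$n_trips, 1L)
})

test_that("event order never affects the lag decomposition", {
  gen <- generate_dataset(small_genconfig(n_per_region = 8L, seed = 21L))
  rec <- gen$records
  set.seed(77)
  shuffled <- new_records(
    species = rec$species,
    events = rec$events[sample(nrow(rec$events)), ],
    exclusions = rec$exclusions
  )
  expect_equal(compute_lags(shuffled), compute_lags(rec))
})

test_that("cumulative_within is monotone and matches hand counts", {
  lags <- tibble::tibble(overall_y = c(1, 6, 20))
  out <- cumulative_within(lags, c(5, 10))
  expect_equal(out$fraction, c(1 / 3, 2 / 3))
  expect_equal(cumulative_within(lags, c(25))$fraction, 1)
  full <- cumulative_within(lags, c(0.5, 5, 10, 25))
  expect_true(all(diff(full$fraction) >= 0))
  expect_error(cumulative_within(numeric(0), 5), "no lag values")
})

test_that("seasonality matrix counts unique per-species dates per month-year cell", {
  rec <- make_records(
    species = c("x", "y"),
    pub = c("2010-01-01", "2010-01-01"),
    events = list(c("2007-02-10", "2007-02-10", "2008-12-01"), "2008-12-20")
  )
  m <- seasonality_matrix(rec)
  expect_equal(sum(m$count), 3L)  # same-day duplicate collapsed
  expect_equal(m$count[m$year == 2007 & m$month == 2], 1L)
  expect_equal(m$count[m$year == 2008 & m$month == 12], 2L)
  # total over cells equals total unique (species, date) events
  gen <- generate_dataset(small_genconfig(n_per_region = 10L, seed = 9L))
  ms <- seasonality_matrix(gen$records)
  expect_equal(sum(ms$count),
               nrow(dplyr::distinct(gen$records$events[, c("species", "resolved")])))
})

test_that("evenness uses an inclusive 40%-of-peak rule on pooled monthly totals", {
  mk <- function(counts) tibble::tibble(region = "R", year = 2000L, month = 1:12, count = counts)
  expect_true(is_evenly_distributed(mk(rep(10L, 12)))$even)
  expect_false(is_evenly_distributed(mk(c(100L, rep(50L, 10), 39L)))$even)
  expect_true(is_evenly_distributed(mk(c(100L, rep(50L, 10), 40L)))$even)
  expect_error(is_evenly_distributed(mk(rep(0L, 12))), "no events")
  r <- is_evenly_distributed(mk(c(100L, rep(50L, 11))))
  expect_equal(unname(r$ratios[1]), 1)
  expect_equal(unname(r$ratios[2]), 0.5)
})

test_that("regional lag lists pool exactly to the global list", {
  gen <- generate_dataset(small_genconfig(n_per_region = 12L, seed = 14L))
  lags <- compute_lags(gen$records)
  pooled <- unlist(lapply(split(lags$overall_y, lags$region), sort))
  expect_equal(sort(unname(pooled)), sort(lags$overall_y))
  expect_equal(sum(table(lags$region)), nrow(lags))
})
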