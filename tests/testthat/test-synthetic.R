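test_that("invalid generator configurations are rejected before any draw", {
  expect_error(generator_config(sigma2_genus = -1), "non-negative")
  expect_error(generator_config(p_trip = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(p_day_range = 0.6, p_month = 0.5), "sum to at most 1")
  expect_error(generator_config(gap_buffer = 0), "gap_buffer")
  expect_error(generator_config(window = c(2020L, 2000L)), "increasing")
  expect_error(generator_config(beta = c(intercept = 1)), "beta must name")
})

test_that("the same seed reproduces the dataset exactly; different seeds differ", {
  a <- generate_dataset(small_genconfig(n_per_region = 10L, seed = 5L))
  b <- generate_dataset(small_genconfig(n_per_region = 10L, seed = 5L))
  expect_equal(a$records$species, b$records$species)
  expect_equal(a$records$events, b$records$events, ignore_attr = TRUE)
  expect_equal(a$truth, b$truth, ignore_attr = TRUE)
  c <- generate_dataset(small_genconfig(n_per_region = 10L, seed = 6L))
  expect_false(identical(a$records$events$resolved, c$records$events$resolved))
})

test_that("per-species seed streams leave earlier species unchanged when n grows", {
  small <- generate_dataset(small_genconfig(n_per_region = 8L, seed = 3L), mask = FALSE)
  big <- generate_dataset(generator_config(
    n_species = c(Ecuador = 20L, India = 8L, Madagascar = 8L, Melanesia = 8L),
    n_genera = c(Ecuador = 12L, India = 12L, Madagascar = 12L, Melanesia = 12L),
    seed = 3L
  ), mask = FALSE)
  # Ecuador comes first in the species layout: its first 8 species share the
  # per-species draws (paper grouping may differ, so compare collection spans)
  a <- small$truth[small$truth$region == "Ecuador", ]
  b <- big$truth[big$truth$region == "Ecuador", ][1:8, ]
  expect_equal(a$true_n_trips[1:8], b$true_n_trips)
  expect_equal(a$eps[1:8], b$eps)
})

test_that("generated histories respect the window, gap buffer and trip truth", {
  gen <- generate_dataset(small_genconfig(n_per_region = 25L, seed = 17L), mask = FALSE)
  yr <- as.integer(format(gen$records$species$publication_date, "%Y"))
  expect_true(all(yr >= 2000L & yr <= 2023L))
  lags <- compute_lags(gen$records)
  expect_equal(lags$n_trips, gen$truth$true_n_trips)
  expect_equal(lags$collection_y, gen$truth$true_collection_y, tolerance = 1e-9)
  expect_equal(lags$description_y, gen$truth$true_description_y, tolerance = 1e-9)
  # every consecutive gap is clearly on one side of the 30-day threshold
  gaps <- unlist(lapply(split(gen$records$events$resolved, gen$records$events$species),
                        function(d) diff(sort(unique(as.numeric(d))))))
  expect_true(all(gaps <= 27 | gaps >= 34))
})

test_that("with variance components and effects at zero, log lags are iid normal", {
  cfg <- small_genconfig(
    n_per_region = 50L, seed = 29L,
    beta = c(intercept = 1.6, genetics = 0, n_authors = 0, n_types = 0,
             n_species_in_paper = 0, n_trips = 0, genus_richness = 0),
    sigma2_genus = 0, sigma2_region = 0, sigma2_resid = 0.49
  )
  gen <- generate_dataset(cfg, mask = FALSE)
  x <- log(gen$truth$model_description_y)
  n <- length(x)
  expect_lt(abs(mean(x) - 1.6), 3 * 0.7 / sqrt(n))
  expect_lt(abs(sd(x) - 0.7), 3 * 0.7 / sqrt(2 * n))
  expect_gt(stats::shapiro.test(x)$p.value, 1e-4)
})

test_that("default lags are right-skewed with median below mean", {
  gen <- generate_dataset(small_genconfig(n_per_region = 50L, seed = 37L))
  lags <- compute_lags(gen$records)
  expect_gt(skewness(lags$overall_y), 0)
  expect_lt(median(lags$overall_y), mean(lags$overall_y))
  expect_gt(skewness(lags$collection_y), 0)
})

test_that("masking keeps midpoints within the emitted bound and off precision unchanged", {
  cfg <- small_genconfig(n_per_region = 20L, seed = 41L,
                         p_day_range = 0.3, p_month = 0.2, p_year = 0.1)
  clean <- generate_dataset(cfg, mask = FALSE)
  masked <- mask_imprecision(clean$records, cfg)
  bound <- attr(masked$events, "shift_bound_days")
  shift <- abs(as.numeric(masked$events$resolved - clean$records$events$resolved))
  expect_true(all(shift <= bound))
  # symmetric day ranges never shift the midpoint
  rng <- masked$events$precision == "day_range"
  expect_true(all(shift[rng] == 0))
  # month masking shifts at most 15 days, year masking at most 184
  expect_true(all(shift[masked$events$precision == "month"] <= 15))
  expect_true(all(shift[masked$events$precision == "year"] <= 184))
  # no masking probability: everything stays day precision
  cfg0 <- small_genconfig(n_per_region = 10L, seed = 43L,
                          p_day_range = 0, p_month = 0, p_year = 0)
  gen0 <- generate_dataset(cfg0)
  expect_true(all(gen0$records$events$precision == "day"))
  # end-to-end: lag shifts stay below the bound per affected endpoint
  lag_clean <- compute_lags(clean$records)
  lag_masked <- compute_lags(masked)
  expect_true(all(abs(lag_masked$description_y - lag_clean$description_y)
                  <= (max(bound) + 1e-9) / 365.25))
  expect_equal(lag_masked$n_trips, lag_clean$n_trips)
})

test_that("seasonal month weights leave their signature in collection months", {
  cfg <- small_genconfig(n_per_region = 60L, seed = 53L)
  gen <- generate_dataset(cfg, mask = FALSE)
  m_india <- seasonality_matrix(gen$records, "India")
  tot <- is_evenly_distributed(m_india)$monthly_totals
  # India's weights peak in June-August; the top month should sit there
  expect_true(which.max(tot) %in% 5:9)
})
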