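#' Configuration for the synthetic type-series generator
#'
#' Bundles and validates every parameter of the generative model used to
#' emulate type-series metadata: species counts per region, genus pools,
#' the fixed-effect truth on the log-years scale, variance components,
#' collection-history laws (trip counts, inter-trip and within-trip gaps),
#' date-imprecision masking probabilities, seasonal month weights, the
#' description-year window, and the seed. Defaults mirror the study
#' conditions the package analyzes: four regions with 208/204/215/269
#' species (896 total), right-skewed lags whose pooled summary is of the
#' same order as the published table (median overall about 7 years, mean
#' about 11), about half the species collected in a single field trip, and
#' an increasing use of genetics over 2000-2023. The gap laws keep a buffer
#' (default 3 days) on both sides of the 30-day trip threshold so the true
#' trip count of every species is unambiguously recoverable.
#'
#' @param n_species Named integer vector of species per region.
#' @param n_genera Named integer vector of genus-pool sizes per region.
#' @param beta Named numeric vector of fixed-effect truth on the log-years
#'   scale: `intercept`, `genetics`, `n_authors`, `n_types`,
#'   `n_species_in_paper`, `n_trips`, `genus_richness`.
#' @param sigma2_genus,sigma2_region,sigma2_resid Variance components of the
#'   genus and region random intercepts and the residual.
#' @param p_trip Geometric success probability for extra trips: a species
#'   makes `1 + Geometric(p_trip)` trips (capped at `max_trips`).
#' @param max_trips Cap on the number of trips.
#' @param lambda_within_dates Poisson mean of extra collection dates within a
#'   trip.
#' @param gap_days Trip threshold the generator must respect (30).
#' @param gap_buffer Safety margin in days around `gap_days`: within-trip
#'   gaps are at most `gap_days - gap_buffer`, inter-trip gaps at least
#'   `gap_days + gap_buffer + 1`.
#' @param between_gap_meanlog,between_gap_sdlog Lognormal law (days) added to
#'   the minimum inter-trip gap; its heavy right tail produces the old
#'   museum specimens behind collection lags of decades.
#' @param p_day_range,p_month,p_year Masking probabilities per event:
#'   rewrite an exact day as a symmetric 3-day range, a month, or a bare
#'   year. Month and year masking are applied only to species with a single
#'   collection event so the trip structure stays identifiable.
#' @param season_weights Named list (per region) of 12 month weights for
#'   collection activity; two regions default to near-uniform effort and two
#'   to strongly seasonal effort.
#' @param window Integer vector `c(first, last)` of description years.
#' @param authors_lambda_base,authors_lambda_trend Poisson mean of extra
#'   authors in 2000 and its additive yearly trend.
#' @param types_lambda_base,types_lambda_trend Same for extra type
#'   specimens (negative trend: type series are shrinking).
#' @param paper_lambda Poisson mean of extra species per paper.
#' @param genetics_logit_base,genetics_logit_trend Logit of the probability
#'   that a description uses genetics, in 2000 and per year.
#' @param seed Integer base seed; draws are split into one stream per
#'   species so adding species leaves earlier species unchanged.
#' @return A validated list of class `taxalag_genconfig`.
#' @export
generator_config <- function(
    n_species = c(Ecuador = 208L, India = 204L, Madagascar = 215L, Melanesia = 269L),
    n_genera = c(Ecuador = 30L, India = 30L, Madagascar = 30L, Melanesia = 30L),
    beta = c(intercept = 1.70, genetics = 0.25, n_authors = -0.05, n_types = 0,
             n_species_in_paper = 0.05, n_trips = -0.08, genus_richness = 0),
    sigma2_genus = 0.15, sigma2_region = 0.05, sigma2_resid = 0.55,
    p_trip = 0.53, max_trips = 23L, lambda_within_dates = 0.8,
    gap_days = 30L, gap_buffer = 3L,
    between_gap_meanlog = log(300), between_gap_sdlog = 1.7,
    p_day_range = 0.08, p_month = 0.03, p_year = 0.02,
    season_weights = NULL,
    window = c(2000L, 2023L),
    authors_lambda_base = 2, authors_lambda_trend = 0.10,
    types_lambda_base = 10, types_lambda_trend = -0.25,
    paper_lambda = 1,
    genetics_logit_base = -0.5, genetics_logit_trend = 0.15,
    seed = 1L) {
  if (is.null(season_weights)) {
    flat <- rep(1, 12)
    peaked <- c(0.2, 0.2, 0.3, 0.5, 1.0, 2.5, 3.0, 2.5, 1.5, 0.6, 0.3, 0.2)
    season_weights <- list(
      Ecuador = flat, India = peaked,
      Madagascar = c(2.5, 2.0, 1.5, 0.5, 0.2, 0.2, 0.2, 0.3, 0.5, 1.0, 1.8, 2.5),
      Melanesia = flat
    )
  }
  cfg <- list(
    n_species = n_species, n_genera = n_genera, beta = beta,
    sigma2_genus = sigma2_genus, sigma2_region = sigma2_region,
    sigma2_resid = sigma2_resid,
    p_trip = p_trip, max_trips = as.integer(max_trips),
    lambda_within_dates = lambda_within_dates,
    gap_days = as.integer(gap_days), gap_buffer = as.integer(gap_buffer),
    between_gap_meanlog = between_gap_meanlog,
    between_gap_sdlog = between_gap_sdlog,
    p_day_range = p_day_range, p_month = p_month, p_year = p_year,
    season_weights = season_weights,
    window = as.integer(window),
    authors_lambda_base = authors_lambda_base,
    authors_lambda_trend = authors_lambda_trend,
    types_lambda_base = types_lambda_base,
    types_lambda_trend = types_lambda_trend,
    paper_lambda = paper_lambda,
    genetics_logit_base = genetics_logit_base,
    genetics_logit_trend = genetics_logit_trend,
    seed = as.integer(seed)
  )
  validate_genconfig(cfg)
  structure(cfg, class = "taxalag_genconfig")
}

validate_genconfig <- function(cfg) {
  probs <- c(cfg$p_trip, cfg$p_day_range, cfg$p_month, cfg$p_year)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_day_range + cfg$p_month + cfg$p_year > 1) {
    stop("masking probabilities must sum to at most 1")
  }
  if (any(c(cfg$sigma2_genus, cfg$sigma2_region, cfg$sigma2_resid) < 0)) {
    stop("variance components must be non-negative")
  }
  if (cfg$gap_buffer < 1L || cfg$gap_buffer >= cfg$gap_days) {
    stop("gap_buffer must be in [1, gap_days)")
  }
  if (!identical(sort(names(cfg$n_species)), sort(names(cfg$n_genera))) ||
      !identical(sort(names(cfg$n_species)), sort(names(cfg$season_weights)))) {
    stop("n_species, n_genera and season_weights must name the same regions")
  }
  if (any(vapply(cfg$season_weights, length, integer(1)) != 12L)) {
    stop("season_weights needs 12 weights per region")
  }
  req <- c("intercept", "genetics", "n_authors", "n_types",
           "n_species_in_paper", "n_trips", "genus_richness")
  if (!all(req %in% names(cfg$beta))) {
    stop("beta must name: ", paste(req, collapse = ", "))
  }
  if (cfg$window[1] > cfg$window[2]) stop("window must be increasing")
  invisible(cfg)
}

# Deterministic per-entity seed stream below 2^31.
stream_seed <- function(base, i) {
  as.integer((as.numeric(base) * 1000003 + i) %% 2147483647)
}

#' Generate a synthetic type-series dataset with known ground truth
#'
#' Draws species description histories from the exact generative structure
#' the mixed model assumes: `description_y = exp(b0 + X b + u_genus +
#' v_region + e)` with Gaussian random intercepts and residual. The
#' publication date is drawn per paper (species described together share a
#' date), the last collection event sits `description_y` before it, and
#' earlier collection events are laid out backwards through the trip-gap
#' laws, with inter-trip gaps stretched so that trip-end months follow the
#' region's seasonal weights. Imprecision masking then degrades a subset of
#' the emitted date strings (see [mask_imprecision()]).
#'
#' @param config A [generator_config()].
#' @param mask If `FALSE`, skip imprecision masking (every emitted date has
#'   day precision).
#' @return A list: `records` (a [new_records()] object) and `truth` (a
#'   tibble with the per-species true trip count, realized collection and
#'   description lags in years, random-effect draws and linear predictor;
#'   the `beta` and variance components used are in attributes `beta` and
#'   `varcomp`).
#' @export
generate_dataset <- function(config = generator_config(), mask = TRUE) {
  validate_genconfig(config)
  regions <- names(config$n_species)
  years <- seq(config$window[1], config$window[2])

  # stream 0: genus pools and region effects
  set.seed(stream_seed(config$seed, 0L))
  pools <- lapply(regions, function(r) {
    n <- config$n_genera[[r]]
    richness <- pmax(1L, as.integer(round(stats::rlnorm(n, log(8), 1))))
    tibble::tibble(
      genus = sprintf("%s_genus_%02d", substr(r, 1, 3), seq_len(n)),
      richness = richness,
      u = stats::rnorm(n, 0, sqrt(config$sigma2_genus))
    )
  })
  names(pools) <- regions
  v_region <- stats::setNames(
    stats::rnorm(length(regions), 0, sqrt(config$sigma2_region)), regions)

  # per-species streams: everything except paper grouping
  sp_region <- rep(regions, times = config$n_species[regions])
  n_total <- length(sp_region)
  year_w <- 1 + 0.03 * (years - years[1])
  draws <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(stream_seed(config$seed, i))
    r <- sp_region[i]
    pool <- pools[[r]]
    g <- sample.int(nrow(pool), 1L, prob = pool$richness)
    pub_year <- sample(years, 1L, prob = year_w)
    t_yr <- pub_year - config$window[1]
    genetics <- stats::runif(1) < stats::plogis(
      config$genetics_logit_base + config$genetics_logit_trend * t_yr)
    n_authors <- 1L + stats::rpois(1L, config$authors_lambda_base +
                                     config$authors_lambda_trend * t_yr)
    n_types <- 1L + stats::rpois(1L, max(0.5, config$types_lambda_base +
                                           config$types_lambda_trend * t_yr))
    n_trips <- 1L + min(stats::rgeom(1L, config$p_trip), config$max_trips - 1L)
    trip_sizes <- 1L + stats::rpois(n_trips, config$lambda_within_dates)
    within_gaps <- lapply(trip_sizes, function(k) {
      if (k <= 1L) integer() else sample(0:9, k - 1L, replace = TRUE)
    })
    between_gaps <- if (n_trips > 1L) {
      config$gap_days + config$gap_buffer + 1L +
        as.integer(round(stats::rlnorm(n_trips - 1L, config$between_gap_meanlog,
                                       config$between_gap_sdlog)))
    } else integer()
    season_months <- if (n_trips > 1L) {
      sample(1:12, n_trips - 1L, replace = TRUE, prob = config$season_weights[[r]])
    } else integer()
    eps <- stats::rnorm(1, 0, sqrt(config$sigma2_resid))
    mask_u <- stats::runif(sum(trip_sizes))
    draws[[i]] <- list(
      region = r, genus_idx = g, pub_year = pub_year, genetics = genetics,
      n_authors = n_authors, n_types = n_types, n_trips = n_trips,
      trip_sizes = trip_sizes, within_gaps = within_gaps,
      between_gaps = between_gaps, season_months = season_months,
      eps = eps, mask_u = mask_u
    )
  }

  # paper stream: group species described in the same region and year
  set.seed(stream_seed(config$seed, n_total + 1L))
  pub_id <- character(n_total)
  pub_date <- rep(as.Date(NA), n_total)
  n_in_paper <- integer(n_total)
  key <- paste(sp_region, vapply(draws, `[[`, integer(1), "pub_year"))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) idx <- sample(idx)  # shuffle before greedy grouping
    p <- 0L
    while (length(idx)) {
      p <- p + 1L
      size <- min(1L + stats::rpois(1L, config$paper_lambda), length(idx))
      members <- idx[seq_len(size)]
      idx <- idx[-seq_len(size)]
      yr <- draws[[members[1]]]$pub_year
      day <- sample.int(365L, 1L)
      pid <- sprintf("%s_%d_p%02d", substr(sp_region[members[1]], 1, 3), yr, p)
      pub_id[members] <- pid
      pub_date[members] <- as.Date(sprintf("%d-01-01", yr)) + (day - 1L)
      n_in_paper[members] <- size
    }
  }

  # deterministic assembly (vectorized accumulators; one tibble at the end)
  name <- character(n_total); genus <- character(n_total)
  richness <- integer(n_total); u_genus <- numeric(n_total)
  eta <- numeric(n_total); desc_y <- numeric(n_total)
  desc_days <- integer(n_total)
  coll_y <- numeric(n_total)
  event_dates <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    d <- draws[[i]]
    pool <- pools[[d$region]]
    richness[i] <- pool$richness[d$genus_idx]
    genus[i] <- pool$genus[d$genus_idx]
    u_genus[i] <- pool$u[d$genus_idx]
    x <- c(genetics = as.numeric(d$genetics), n_authors = d$n_authors,
           n_types = d$n_types, n_species_in_paper = n_in_paper[i],
           n_trips = d$n_trips, genus_richness = richness[i])
    eta[i] <- config$beta[["intercept"]] +
      sum(config$beta[names(x)] * x) +
      u_genus[i] + v_region[[d$region]]
    desc_y[i] <- exp(eta[i] + d$eps)
    desc_days[i] <- max(1L, as.integer(round(desc_y[i] * 365.25)))
    last_coll <- pub_date[i] - desc_days[i]
    dates <- layout_collection_dates(last_coll, d$trip_sizes, d$within_gaps,
                                     d$between_gaps, d$season_months)
    event_dates[[i]] <- dates
    coll_y[i] <- as.numeric(max(dates) - min(dates)) / 365.25
    name[i] <- sprintf("sp_%s_%03d", substr(d$region, 1, 3), i)
  }
  n_ev <- lengths(event_dates)
  all_dates <- as.Date(unlist(lapply(event_dates, as.numeric)), origin = "1970-01-01")
  records <- new_records(
    species = tibble::tibble(
      species = name, genus = genus, region = sp_region,
      publication_date = pub_date, publication_id = pub_id,
      n_authors = vapply(draws, `[[`, integer(1), "n_authors"),
      n_types = vapply(draws, `[[`, integer(1), "n_types"),
      n_species_in_paper = n_in_paper,
      genetics = vapply(draws, `[[`, logical(1), "genetics"),
      genus_richness = richness
    ),
    events = tibble::tibble(
      species = rep(name, n_ev),
      raw_text = format(all_dates, "%Y-%m-%d"),
      resolved = all_dates,
      precision = rep("day", sum(n_ev)),
      span_days = rep(0L, sum(n_ev))
    )
  )
  truth <- tibble::tibble(
    species = name, region = sp_region, genus = genus,
    true_n_trips = vapply(draws, `[[`, integer(1), "n_trips"),
    true_collection_y = coll_y,
    true_description_y = desc_days / 365.25,
    model_description_y = desc_y,
    u_genus = u_genus,
    v_region = unname(v_region[sp_region]),
    eps = vapply(draws, `[[`, numeric(1), "eps"),
    eta = eta
  )
  attr(truth, "beta") <- config$beta
  attr(truth, "varcomp") <- c(genus = config$sigma2_genus,
                              region = config$sigma2_region,
                              residual = config$sigma2_resid)
  if (mask) records <- mask_imprecision(records, config)
  list(records = records, truth = truth)
}

# Lay collection dates out backwards from the (anchored) last event.
# Trip sizes/gaps are ordered first trip .. last trip; the last trip ends at
# `last_coll`. Inter-trip gaps are stretched (never shrunk) so the earlier
# trip's final event lands in the drawn seasonal month.
layout_collection_dates <- function(last_coll, trip_sizes, within_gaps,
                                    between_gaps, season_months) {
  n_trips <- length(trip_sizes)
  offset <- 0L
  dates <- last_coll
  for (t in rev(seq_len(n_trips))) {
    gaps <- within_gaps[[t]]
    for (g in rev(gaps)) {
      offset <- offset + g
      dates <- c(dates, last_coll - offset)
    }
    if (t > 1L) {
      g <- between_gaps[t - 1L]
      target <- season_months[t - 1L]
      cand <- last_coll - offset - (g + 0:366)
      hit <- which(as.integer(format(cand, "%m")) == target)[1]
      offset <- offset + g + (hit - 1L)
      dates <- c(dates, last_coll - offset)
    }
  }
  sort(as.Date(dates, origin = "1970-01-01"))
}

#' Degrade exact collection dates to imprecise strings
#'
#' Rewrites a random subset of day-precision events in the dialects the
#' parser accepts: a symmetric three-day range (midpoint unchanged), the
#' month (midpoint shift at most 15 days) or the bare year (shift at most
#' 184 days). Month and year masking are restricted to species with a
#' single collection event, and range masking to days away from month
#' edges, so the true trip segmentation of every species survives masking
#' exactly. The per-event shift bound in days is recorded in the
#' `shift_bound_days` attribute of the returned events table, giving
#' downstream comparisons a known tolerance.
#'
#' @param records A [new_records()] object with day-precision events.
#' @param config A [generator_config()] carrying the masking probabilities.
#' @param seed Optional seed for standalone use; by default the decisions
#'   reuse the per-event uniform draws already implied by `config$seed`.
#' @return The records with degraded `raw_text` (re-parsed, so `resolved`,
#'   `precision` and `span_days` reflect the masked strings).
#' @export
mask_imprecision <- function(records, config = generator_config(), seed = NULL) {
  stopifnot(inherits(records, "taxalag_records"))
  if (!is.null(seed)) set.seed(stream_seed(seed, 999L)) else
    set.seed(stream_seed(config$seed, 998L))
  ev <- records$events
  n_ev_per_sp <- table(ev$species)
  single <- ev$species %in% names(n_ev_per_sp)[n_ev_per_sp == 1L]
  u <- stats::runif(nrow(ev))
  p1 <- config$p_day_range
  p2 <- p1 + config$p_month
  p3 <- p2 + config$p_year
  cat_raw <- ifelse(u < p1, "day_range", ifelse(u < p2, "month", ifelse(u < p3, "year", "day")))
  cat_eff <- ifelse(cat_raw %in% c("month", "year") & !single, "day", cat_raw)
  day <- as.integer(format(ev$resolved, "%d"))
  mon <- as.integer(format(ev$resolved, "%m"))
  yr <- as.integer(format(ev$resolved, "%Y"))
  dim_last <- vapply(seq_along(yr), function(i) days_in_month(yr[i], mon[i]), integer(1))
  can_range <- day >= 2L & day <= dim_last - 1L
  cat_eff[cat_eff == "day_range" & !can_range] <- "day"
  month_name <- function(m) {
    paste0(toupper(substr(.months[m], 1, 1)), substr(.months[m], 2, nchar(.months[m])))
  }
  new_raw <- ev$raw_text
  bound <- integer(nrow(ev))
  rng <- cat_eff == "day_range"
  new_raw[rng] <- sprintf("%d\u2013%d %s %d", day[rng] - 1L, day[rng] + 1L,
                          month_name(mon[rng]), yr[rng])
  mth <- cat_eff == "month"
  new_raw[mth] <- sprintf("%s %d", month_name(mon[mth]), yr[mth])
  bound[mth] <- 15L
  yonly <- cat_eff == "year"
  new_raw[yonly] <- sprintf("%d", yr[yonly])
  bound[yonly] <- 184L
  reparsed <- parse_date_text(new_raw)
  reparsed$species <- ev$species
  # revert any mask whose shifted midpoint would reach the publication date
  pub <- records$species$publication_date[match(reparsed$species, records$species$species)]
  unsafe <- reparsed$resolved >= pub
  if (any(unsafe)) {
    reparsed$raw_text[unsafe] <- ev$raw_text[unsafe]
    reparsed$resolved[unsafe] <- ev$resolved[unsafe]
    reparsed$precision[unsafe] <- ev$precision[unsafe]
    reparsed$span_days[unsafe] <- ev$span_days[unsafe]
    bound[unsafe] <- 0L
  }
  out <- reparsed[, c("species", "raw_text", "resolved", "precision", "span_days")]
  attr(out, "shift_bound_days") <- bound
  new_records(species = records$species, events = out,
              exclusions = records$exclusions)
}
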