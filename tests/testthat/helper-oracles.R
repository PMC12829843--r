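# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately uses a different mechanism than the implementation
# it checks.

# Midpoint of a day interval by explicit enumeration of every day in it.
oracle_midpoint <- function(first, last) {
  days <- seq(as.Date(first), as.Date(last), by = "day")
  days[floor((1 + length(days)) / 2)]
}

# Trip grouping as connected components of the consecutive-date adjacency
# relation, found by boolean reachability (matrix powers), not by the
# cumulative-sum rule the implementation uses.
oracle_trips <- function(dates, gap_days = 30) {
  dates <- sort(unique(as.numeric(dates)))
  n <- length(dates)
  if (n == 1) return(1L)
  A <- diag(TRUE, n)
  for (i in seq_len(n - 1)) {
    adj <- (dates[i + 1] - dates[i]) <= gap_days
    A[i, i + 1] <- A[i + 1, i] <- adj
  }
  reach <- A
  for (k in seq_len(n)) reach <- (reach %*% A) > 0 | reach
  comps <- unique(apply(reach, 1, function(r) min(which(r))))
  length(comps)
}

# Two-pass textbook implementation of the summary battery.
oracle_describe <- function(x, trim = 0.10, mad_scale = 1.4826, type = 3) {
  n <- length(x)
  mu <- sum(x) / n
  ss <- sum((x - mu)^2)
  s2 <- ss / (n - 1)
  xs <- sort(x)
  k <- floor(n * trim)
  trimmed <- xs[(k + 1):(n - k)]
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  ad <- sort(abs(x - med))
  mad_raw <- if (n %% 2 == 1) ad[(n + 1) / 2] else (ad[n / 2] + ad[n / 2 + 1]) / 2
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  skew <- switch(type,
    g1,
    g1 * sqrt(n * (n - 1)) / (n - 2),
    g1 * ((n - 1) / n)^1.5
  )
  kurt <- switch(type,
    g2,
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
    (g2 + 3) * ((n - 1) / n)^2 - 3
  )
  list(
    n = n, min = xs[1], mean = mu, sd = sqrt(s2),
    trimmed_mean = sum(trimmed) / length(trimmed),
    median = med, mad = mad_scale * mad_raw, max = xs[n],
    range = xs[n] - xs[1], skew = skew, kurtosis = kurt,
    se = sqrt(s2 / n), ci = 1.96 * sqrt(s2 / n)
  )
}

# Hand-built records object: one species per row of `pub`, events given as a
# list of date vectors (character or Date).
make_records <- function(species, pub, events, region = "Ecuador",
                         genus = "GenusA", publication_id = NULL,
                         n_authors = 2L, n_types = 3L,
                         n_species_in_paper = 1L, genetics = FALSE,
                         genus_richness = 10L) {
  n <- length(species)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- as.Date(events[[i]])
    data.frame(species = species[i], raw_text = format(d, "%Y-%m-%d"),
               resolved = d, precision = "day", span_days = 0L)
  }))
  new_records(
    species = tibble::tibble(
      species = species,
      genus = rep_len(genus, n),
      region = rep_len(region, n),
      publication_date = as.Date(pub),
      publication_id = publication_id %||% paste0("pub_", seq_len(n)),
      n_authors = rep_len(as.integer(n_authors), n),
      n_types = rep_len(as.integer(n_types), n),
      n_species_in_paper = rep_len(as.integer(n_species_in_paper), n),
      genetics = rep_len(genetics, n),
      genus_richness = rep_len(as.integer(genus_richness), n)
    ),
    events = tibble::as_tibble(ev)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small generator config used where full study size is not needed.
small_genconfig <- function(n_per_region = 30L, seed = 1L, ...) {
  generator_config(
    n_species = c(Ecuador = n_per_region, India = n_per_region,
                  Madagascar = n_per_region, Melanesia = n_per_region),
    n_genera = c(Ecuador = 12L, India = 12L, Madagascar = 12L, Melanesia = 12L),
    seed = seed, ...
  )
}
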