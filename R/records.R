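#' Type-series record container
#'
#' A `taxalag_records` object holds the curated type-series metadata for a set
#' of species descriptions as two tidy tables plus an exclusion log:
#'
#' * `species`: one row per retained species with its covariates — `species`,
#'   `genus`, `region`, `publication_date` (`Date`), `publication_id`,
#'   `n_authors`, `n_types`, `n_species_in_paper`, `genetics` (logical),
#'   `genus_richness`.
#' * `events`: one row per (species, collection-date string) with the parsed
#'   midpoint date — `species`, `raw_text`, `resolved`, `precision`,
#'   `span_days`.
#' * `exclusions`: one row per excluded species — `species`, `reason`, one of
#'   `missing_publication_date`, `missing_collection_dates`,
#'   `unparseable_date`, `out_of_window`, `pub_before_collection`.
#'
#' Every species of the ingested input appears either in `species` or exactly
#' once in `exclusions`.
#'
#' @param species,events,exclusions Tibbles with the columns listed above.
#' @return An object of class `taxalag_records`.
#' @export
new_records <- function(species, events,
                        exclusions = tibble::tibble(species = character(), reason = character())) {
  stopifnot(
    all(c("species", "genus", "region", "publication_date", "publication_id",
          "n_authors", "n_types", "n_species_in_paper", "genetics",
          "genus_richness") %in% names(species)),
    all(c("species", "raw_text", "resolved", "precision", "span_days") %in% names(events)),
    all(c("species", "reason") %in% names(exclusions))
  )
  stopifnot(!anyDuplicated(species$species))
  stopifnot(all(events$species %in% species$species))
  structure(
    list(
      species = tibble::as_tibble(species),
      events = tibble::as_tibble(events),
      exclusions = tibble::as_tibble(exclusions)
    ),
    class = "taxalag_records"
  )
}

#' @export
print.taxalag_records <- function(x, ...) {
  cat(sprintf(
    "<taxalag_records> %d species, %d collection events, %d excluded\n",
    nrow(x$species), nrow(x$events), nrow(x$exclusions)
  ))
  if (nrow(x$species)) {
    reg <- table(x$species$region)
    cat("  regions:", paste(sprintf("%s (%d)", names(reg), reg), collapse = ", "), "\n")
  }
  invisible(x)
}

.canonical_cols <- c(
  "species", "genus", "region", "publication_date", "publication_id",
  "n_authors", "n_types", "n_species_in_paper", "genetics", "genus_richness"
)

#' Read type-series metadata from CSV or XLSX
#'
#' Accepts the canonical schema in either a long layout (one row per species
#' and collection-date string, column `collection_date_raw`) or a wide layout
#' (one row per species, collection dates spread over columns named
#' `collection_date*`). A column `mapping` renames source columns to the
#' canonical schema, which is how supplementary spreadsheets with their own
#' headers are ingested.
#'
#' Rows are grouped by species; collection-date strings are parsed to midpoint
#' dates; species with missing or unparseable fields are routed to the
#' exclusion log rather than dropped silently, and a publication date on or
#' before the last resolved collection date excludes the species with reason
#' `pub_before_collection` (negative lags are meaningless under the period
#' definitions used here).
#'
#' @param path Path to a CSV or XLSX file.
#' @param format `"csv"` or `"xlsx"` (default guessed from the extension).
#' @param mapping Optional named character vector `c(canonical = "source")`
#'   renaming source columns to the canonical schema.
#' @param sheet Sheet number for XLSX input.
#' @return A [new_records()] object.
#' @export
read_records <- function(path, format = c("auto", "csv", "xlsx"), mapping = NULL,
                         sheet = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  df <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx input requires the 'readxl' package")
      }
      x <- readxl::read_excel(path, sheet = sheet, col_types = "text")
      tibble::as_tibble(x)
    }
  )
  build_records(df, mapping = mapping)
}

#' Build a records object from an in-memory data frame
#'
#' The data-frame twin of [read_records()]; exported so generated and
#' programmatic inputs skip the file system.
#'
#' @param df Data frame in the canonical long or wide layout (all columns may
#'   be character; types are coerced).
#' @inheritParams read_records
#' @return A [new_records()] object.
#' @export
build_records <- function(df, mapping = NULL) {
  df <- tibble::as_tibble(df)
  if (!is.null(mapping)) {
    stopifnot(!is.null(names(mapping)))
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df)) stop(sprintf("mapped column '%s' not found in input", src))
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(setdiff(.canonical_cols, "publication_date"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"publication_date" %in% names(df)) stop("missing mandatory column(s): publication_date")

  # wide layout: gather collection_date* columns into collection_date_raw
  if (!"collection_date_raw" %in% names(df)) {
    wide <- grep("^collection_date", names(df), value = TRUE)
    if (!length(wide)) stop("missing collection dates: need collection_date_raw or collection_date* columns")
    df <- tidyr::pivot_longer(df, dplyr::all_of(wide),
      names_to = NULL, values_to = "collection_date_raw", values_drop_na = TRUE
    )
  }

  df$collection_date_raw <- trimws(as.character(df$collection_date_raw))
  df$species <- as.character(df$species)

  sp_split <- split(df, factor(df$species, levels = unique(df$species)))
  species_rows <- list()
  event_rows <- list()
  excl <- list()
  for (sp in names(sp_split)) {
    rows <- sp_split[[sp]]
    cov <- unique(rows[, setdiff(.canonical_cols, "species"), drop = FALSE])
    if (nrow(cov) > 1L) {
      stop(sprintf("inconsistent covariates across rows for species '%s'", sp))
    }
    pub_raw <- as.character(cov$publication_date)
    if (is.na(pub_raw) || !nzchar(trimws(pub_raw))) {
      excl[[sp]] <- "missing_publication_date"
      next
    }
    pub <- parse_date_quietly(trimws(pub_raw))
    if (!pub$ok) {
      excl[[sp]] <- "missing_publication_date"
      next
    }
    raws <- rows$collection_date_raw
    raws <- raws[!is.na(raws) & nzchar(raws)]
    if (!length(raws)) {
      excl[[sp]] <- "missing_collection_dates"
      next
    }
    ev <- parse_date_quietly(raws)
    if (any(!ev$ok)) {
      excl[[sp]] <- "unparseable_date"
      next
    }
    if (pub$resolved <= max(ev$resolved)) {
      excl[[sp]] <- "pub_before_collection"
      next
    }
    ev$ok <- NULL
    event_rows[[sp]] <- dplyr::bind_cols(tibble::tibble(species = sp), ev)
    species_rows[[sp]] <- tibble::tibble(
      species = sp,
      genus = as.character(cov$genus),
      region = as.character(cov$region),
      publication_date = pub$resolved,
      publication_id = as.character(cov$publication_id),
      n_authors = as.integer(cov$n_authors),
      n_types = as.integer(cov$n_types),
      n_species_in_paper = as.integer(cov$n_species_in_paper),
      genetics = parse_logical(cov$genetics),
      genus_richness = as.integer(cov$genus_richness)
    )
  }
  new_records(
    species = dplyr::bind_rows(species_rows),
    events = dplyr::bind_rows(event_rows),
    exclusions = tibble::tibble(
      species = as.character(names(excl) %||% character()),
      reason = as.character(unlist(excl, use.names = FALSE) %||% character())
    )
  )
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(up))
  out[up %in% c("TRUE", "T", "YES", "Y", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "NO", "N", "0")] <- FALSE
  as.logical(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict records to a description-year window
#'
#' Retains species whose publication year falls in `[first_year, last_year]`
#' (both inclusive); the rest move to the exclusion log with reason
#' `out_of_window`. The default window covers descriptions from 2000 to 2023.
#'
#' @param records A [new_records()] object.
#' @param first_year,last_year Integer bounds of the window (inclusive).
#' @return A [new_records()] object with the window applied.
#' @export
filter_window <- function(records, first_year = 2000L, last_year = 2023L) {
  stopifnot(inherits(records, "taxalag_records"), first_year <= last_year)
  yr <- as.integer(format(records$species$publication_date, "%Y"))
  keep <- yr >= first_year & yr <= last_year
  dropped <- records$species$species[!keep]
  new_records(
    species = records$species[keep, , drop = FALSE],
    events = records$events[records$events$species %in% records$species$species[keep], , drop = FALSE],
    exclusions = dplyr::bind_rows(
      records$exclusions,
      tibble::tibble(species = dropped, reason = rep("out_of_window", length(dropped)))
    )
  )
}

#' Serialize records to the canonical CSV schema
#'
#' Writes the long-layout canonical CSV (one row per species and collection
#' date) and, alongside it, the exclusion log. Reading the written file back
#' reproduces resolved dates, precisions and covariates exactly.
#'
#' @param records A [new_records()] object.
#' @param path Output CSV path for the records.
#' @param exclusions_path Optional output CSV path for the exclusion log.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, exclusions_path = NULL) {
  stopifnot(inherits(records, "taxalag_records"))
  ev <- records$events
  ev$collection_date_raw <- format_date_text(ev)
  long <- dplyr::inner_join(
    records$species, ev[, c("species", "collection_date_raw")],
    by = "species"
  )
  long$publication_date <- format(long$publication_date, "%Y-%m-%d")
  readr::write_csv(long[, c(.canonical_cols, "collection_date_raw")], path, progress = FALSE)
  if (!is.null(exclusions_path)) {
    readr::write_csv(records$exclusions, exclusions_path, progress = FALSE)
  }
  invisible(path)
}
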