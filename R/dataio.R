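# Reading, validating and reshaping tidy monthly fishery records.
#
# The unit of exchange is the "long record": one measured quantity for one
# (region, year, month, species) cell.  Absence of a row is *absence of an
# observation*, never an implicit zero; a closed-season harvest of zero must
# be recorded as an explicit 0.

LONG_FIELDS <- c("region", "year", "month", "species", "quantity_kind", "value")

#' Validate a set of long monthly records
#'
#' Checks column presence, coded quantity kinds, month and year ranges,
#' non-negativity, and uniqueness of the
#' (region, year, month, species, quantity_kind) key.
#'
#' @param records data frame with columns `region`, `year`, `month`,
#'   `species`, `quantity_kind`, `value`.  Extra columns are dropped.
#' @return the validated records (extra columns removed, types normalised),
#'   invisibly classed as they came in.
#' @export
validate_long <- function(records) {
  if (!is.data.frame(records)) {
    stop_validation("records must be a data frame")
  }
  missing_cols <- setdiff(LONG_FIELDS, names(records))
  if (length(missing_cols)) {
    stop_validation(paste0(
      "missing required columns: ", paste(missing_cols, collapse = ", ")
    ), code = "missing_columns")
  }
  x <- records[LONG_FIELDS]
  x$region <- as.character(x$region)
  x$species <- as.character(x$species)
  x$quantity_kind <- as.character(x$quantity_kind)

  bad_kind <- which(!x$quantity_kind %in% QUANTITY_KINDS)
  if (length(bad_kind)) {
    stop_validation(
      paste0("unknown quantity_kind in rows: ",
             paste(head(bad_kind, 10L), collapse = ", ")),
      code = "bad_kind", data = bad_kind
    )
  }

  year_n <- suppressWarnings(as.numeric(x$year))
  month_n <- suppressWarnings(as.numeric(x$month))
  value_n <- suppressWarnings(as.numeric(x$value))
  bad_year <- which(is.na(year_n) | year_n != round(year_n))
  bad_month <- which(is.na(month_n) | month_n != round(month_n) |
                       month_n < 1 | month_n > 12)
  bad_value <- which(is.na(value_n) | value_n < 0)
  if (length(bad_year)) {
    stop_validation(paste0("malformed year in rows: ",
                           paste(head(bad_year, 10L), collapse = ", ")),
                    code = "bad_year", data = bad_year)
  }
  if (length(bad_month)) {
    stop_validation(paste0("month outside 1..12 in rows: ",
                           paste(head(bad_month, 10L), collapse = ", ")),
                    code = "bad_month", data = bad_month)
  }
  if (length(bad_value)) {
    stop_validation(paste0("missing or negative value in rows: ",
                           paste(head(bad_value, 10L), collapse = ", ")),
                    code = "bad_value", data = bad_value)
  }
  x$year <- as.integer(year_n)
  x$month <- as.integer(month_n)
  x$value <- value_n

  key <- paste(x$region, x$year, x$month, x$species, x$quantity_kind,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_validation(
      paste0("duplicate (region, year, month, species, quantity_kind) key ",
             "in rows: ", paste(head(dup, 10L), collapse = ", ")),
      code = "duplicate_key", data = dup
    )
  }
  x
}

#' Read long monthly records from a delimited text file
#'
#' Expects a header row naming at least the six canonical fields
#' (`region,year,month,species,quantity_kind,value`); unknown columns are
#' ignored.  Malformed months or years, negative values and duplicate keys
#' raise a validation error naming the offending rows.
#'
#' @param path path to a CSV file (UTF-8).
#' @return data frame of validated long records.
#' @export
read_long <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- validate_long(raw)
  fs_log("read_long: ", nrow(out), " records from ", path)
  out
}

#' Write long monthly records to CSV
#'
#' @param records validated long records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long <- function(records, path) {
  records <- validate_long(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a species-by-month panel for one region-year
#'
#' Pivots long records into the n-species x T-months matrix consumed by the
#' stability partitioning.  Every (species, month) cell must be present:
#' a missing cell is an error listing the gaps, never an implicit zero
#' (missing survey cruises must be handled upstream).
#'
#' @param records validated long records.
#' @param region,year,quantity_kind panel key.
#' @param months ordered integer vector of months (default: all months
#'   present for this key, sorted).
#' @param species ordered character vector of species (default: all species
#'   present for this key, sorted).
#' @return an object of class `monthly_panel`: list with elements `region`,
#'   `year`, `quantity_kind`, `species`, `months` and the matrix `x`
#'   (rows = species in the declared order, columns = months).
#' @export
to_panel <- function(records, region, year, quantity_kind,
                     months = NULL, species = NULL) {
  records <- validate_long(records)
  sel <- records$region == region & records$year == year &
    records$quantity_kind == quantity_kind
  sub <- records[sel, , drop = FALSE]
  if (is.null(species)) species <- sort(unique(sub$species))
  if (is.null(months)) months <- sort(unique(sub$month))
  months <- as.integer(months)
  if (length(months) < 1L || !length(species)) {
    stop_validation(paste0("no records for ", region, "/", year, "/",
                           quantity_kind), code = "empty_panel")
  }
  sub <- sub[sub$species %in% species & sub$month %in% months, , drop = FALSE]

  x <- matrix(NA_real_, nrow = length(species), ncol = length(months),
              dimnames = list(species, months))
  idx <- cbind(match(sub$species, species), match(sub$month, months))
  x[idx] <- sub$value
  if (anyNA(x)) {
    gaps <- which(is.na(x), arr.ind = TRUE)
    gap_lab <- paste0(species[gaps[, 1L]], "@m", months[gaps[, 2L]])
    stop_degenerate(
      paste0("incomplete panel ", region, "/", year, "/", quantity_kind,
             "; missing cells: ", paste(head(gap_lab, 12L), collapse = ", ")),
      code = "incomplete_panel", data = gap_lab
    )
  }
  structure(
    list(region = region, year = as.integer(year),
         quantity_kind = quantity_kind, species = species,
         months = months, x = x),
    class = "monthly_panel"
  )
}

#' @export
print.monthly_panel <- function(x, ...) {
  cat("<monthly_panel> ", x$region, "/", x$year, " [", x$quantity_kind, "] ",
      nrow(x$x), " species x ", ncol(x$x), " months\n", sep = "")
  print(x$x, ...)
  invisible(x)
}

#' Flatten a panel back to long records
#'
#' Inverse of [to_panel()]: reproduces the input record multiset exactly.
#'
#' @param panel a `monthly_panel`.
#' @return data frame of long records.
#' @export
panel_to_long <- function(panel) {
  stopifnot(inherits(panel, "monthly_panel"))
  data.frame(
    region = panel$region,
    year = panel$year,
    month = rep(panel$months, each = length(panel$species)),
    species = rep(panel$species, times = length(panel$months)),
    quantity_kind = panel$quantity_kind,
    value = as.vector(panel$x),
    stringsAsFactors = FALSE
  )
}

#' Deflate nominal dockside values to a base period
#'
#' Converts `value_usd` records to real terms using a monthly price index
#' (e.g., the BLS CPI-U): `real = nominal * index(base) / index(period)`.
#' Records of other kinds pass through unchanged.
#'
#' @param records validated long records.
#' @param deflator data frame with columns `year`, `month`, `index`
#'   (index > 0 throughout).
#' @param base base period as `c(year, month)`.
#' @return records with `value_usd` rows re-expressed in base-period terms.
#' @export
deflate_values <- function(records, deflator, base) {
  records <- validate_long(records)
  stopifnot(is.data.frame(deflator),
            all(c("year", "month", "index") %in% names(deflator)))
  if (any(deflator$index <= 0)) {
    stop_validation("deflator index values must be positive",
                    code = "bad_deflator")
  }
  dkey <- paste(deflator$year, deflator$month, sep = "-")
  base_i <- match(paste(base[1L], base[2L], sep = "-"), dkey)
  if (is.na(base_i)) {
    stop_validation("base period not covered by deflator series",
                    code = "missing_deflator_period")
  }
  is_val <- records$quantity_kind == "value_usd"
  per_i <- match(paste(records$year[is_val], records$month[is_val], sep = "-"),
                 dkey)
  if (anyNA(per_i)) {
    miss <- unique(paste(records$year[is_val], records$month[is_val],
                         sep = "-")[is.na(per_i)])
    stop_validation(paste0("deflator does not cover periods: ",
                           paste(head(miss, 10L), collapse = ", ")),
                    code = "missing_deflator_period", data = miss)
  }
  records$value[is_val] <- records$value[is_val] *
    deflator$index[base_i] / deflator$index[per_i]
  records
}

# ---- closure calendars ------------------------------------------------------

# Number of days of each month (non-leap year); month-resolved closures are
# derived from day ranges, so February 29 never decides a closure.
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

parse_month_day <- function(s) {
  parts <- as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
  if (length(parts) != 2L || anyNA(parts) || parts[1L] < 1L || parts[1L] > 12L ||
      parts[2L] < 1L || parts[2L] > DAYS_IN_MONTH[parts[1L]]) {
    stop_validation(paste0("cannot parse month-day '", s, "' (want 'MM-DD')"),
                    code = "bad_date")
  }
  parts
}

#' Months covered by a within-year closure date range
#'
#' Maps a day-resolved closure (possibly wrapping the year end, e.g.
#' December 8 to April 15) onto whole months.  A month counts as closed when
#' at least `min_days` of its days fall inside the range, so a closure over
#' January 1-15 closes January while one over January 1-10 does not.
#'
#' @param start,end closure bounds as `"MM-DD"` strings (inclusive).
#' @param min_days minimum closed days for a month to count (default 15).
#' @return integer vector of closed months.
#' @export
closure_months <- function(start, end, min_days = 15L) {
  s <- parse_month_day(start)
  e <- parse_month_day(end)
  doy <- cumsum(c(0L, DAYS_IN_MONTH))[1:12]  # day-of-year offset per month
  s_d <- doy[s[1L]] + s[2L]
  e_d <- doy[e[1L]] + e[2L]
  days <- rep(FALSE, 365L)
  if (s_d <= e_d) {
    days[s_d:e_d] <- TRUE
  } else {                       # wraps the year end
    days[s_d:365L] <- TRUE
    days[1L:e_d] <- TRUE
  }
  closed_per_month <- vapply(1:12, function(m) {
    sum(days[(doy[m] + 1L):(doy[m] + DAYS_IN_MONTH[m])])
  }, integer(1L))
  which(closed_per_month >= min_days)
}

#' Build a closure calendar
#'
#' @param closures data frame with columns `region`, `species`, `start`,
#'   `end` (`"MM-DD"` bounds); may have zero rows.
#' @param survey_months ordered months in which the trawl survey runs
#'   (default March, May, July, September, November).
#' @return object of class `closure_calendar`: `survey_months` plus a list
#'   of closed-month vectors keyed `region/species`.
#' @export
closure_calendar <- function(closures = NULL,
                             survey_months = DEFAULT_SURVEY_MONTHS) {
  survey_months <- as.integer(survey_months)
  if (!length(survey_months) || any(survey_months < 1L | survey_months > 12L)) {
    stop_validation("survey_months must be a non-empty subset of 1..12",
                    code = "bad_survey_months")
  }
  closed <- list()
  if (!is.null(closures) && nrow(closures)) {
    stopifnot(all(c("region", "species", "start", "end") %in% names(closures)))
    for (i in seq_len(nrow(closures))) {
      key <- paste(closures$region[i], closures$species[i], sep = "/")
      cm <- closure_months(closures$start[i], closures$end[i])
      closed[[key]] <- sort(unique(c(closed[[key]], cm)))
    }
  }
  structure(list(survey_months = survey_months, closed = closed),
            class = "closure_calendar")
}

#' Closed months for one region-species
#'
#' @param calendar a `closure_calendar`.
#' @param region,species fishery key.
#' @return integer vector of closed months (possibly empty).
#' @export
closed_months <- function(calendar, region, species) {
  stopifnot(inherits(calendar, "closure_calendar"))
  cm <- calendar$closed[[paste(region, species, sep = "/")]]
  if (is.null(cm)) integer(0) else cm
}

#' Chesapeake-style default closure calendar
#'
#' Striped bass closed March-May in the northern (MD) region; in the
#' southern (VA) region Atlantic croaker is closed January 1-15, spot
#' December 8-April 15, and striped bass January 1-16.
#'
#' @param survey_months see [closure_calendar()].
#' @return a `closure_calendar`.
#' @export
default_calendar <- function(survey_months = DEFAULT_SURVEY_MONTHS) {
  closure_calendar(
    closures = data.frame(
      region = c("MD", "VA", "VA", "VA"),
      species = c("striped_bass", "atlantic_croaker", "spot", "striped_bass"),
      start = c("03-01", "01-01", "12-08", "01-01"),
      end = c("05-31", "01-15", "04-15", "01-16"),
      stringsAsFactors = FALSE
    ),
    survey_months = survey_months
  )
}

#' Read a closure calendar from YAML
#'
#' Expected layout:
#' ```yaml
#' survey_months: [3, 5, 7, 9, 11]
#' closures:
#'   - {region: MD, species: striped_bass, start: "03-01", end: "05-31"}
#' ```
#'
#' @param path YAML file path.
#' @return a `closure_calendar`.
#' @export
read_calendar <- function(path) {
  y <- yaml::read_yaml(path)
  closures <- NULL
  if (!is.null(y$closures) && length(y$closures)) {
    closures <- do.call(rbind, lapply(y$closures, function(cl) {
      data.frame(region = cl$region, species = cl$species,
                 start = cl$start, end = cl$end, stringsAsFactors = FALSE)
    }))
  }
  sm <- if (is.null(y$survey_months)) DEFAULT_SURVEY_MONTHS else y$survey_months
  closure_calendar(closures, survey_months = sm)
}
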