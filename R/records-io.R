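#' Is a year a Gregorian leap year?
#' @param year integer vector.
#' @return logical vector.
#' @keywords internal
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Leap-scaled day of year
#'
#' Ordinal day within the year (Jan 1 = 1). In leap years the ordinal day is
#' rescaled by 365/366 so that the output always lies in (0, 365] and
#' Dec 31 maps to 365 in every year. This keeps the radian conversion (which
#' divides by 365) consistent across leap and common years: dates in a leap
#' year are treated as fractions of a 366-day year, then expressed on the
#' common 365-day scale.
#'
#' @param year,month,day integer date parts of a valid Gregorian date.
#' @return numeric day-of-year in (0, 365].
#' @export
#' @examples
#' day_of_year(2023, 1, 1)   # 1
#' day_of_year(2024, 2, 29)  # 60 * 365/366
day_of_year <- function(year, month, day) {
  d <- as.Date(sprintf("%04d-%02d-%02d", year, month, day), format = "%Y-%m-%d")
  bad <- is.na(d) |
    as.integer(format(d, "%m")) != month | as.integer(format(d, "%d")) != day
  if (any(bad)) {
    stop("invalid date(s): ",
         paste(sprintf("%04d-%02d-%02d", year[bad], month[bad], day[bad]),
               collapse = ", "))
  }
  ord <- as.numeric(d - as.Date(sprintf("%04d-01-01", year))) + 1
  ifelse(is_leap_year(year), ord * 365 / 366, ord)
}

#' Convert day-of-year to a circular angle
#'
#' theta = 2 * pi * doy / 365 - pi, mapping (0, 365] onto (-pi, pi].
#'
#' @param doy numeric day-of-year in (0, 365].
#' @return angle in radians in (-pi, pi].
#' @export
day_to_radians <- function(doy) {
  if (any(doy <= 0 | doy > 365)) {
    stop("doy must lie in (0, 365]; got ",
         paste(utils::head(doy[doy <= 0 | doy > 365], 3), collapse = ", "))
  }
  2 * pi * doy / 365 - pi
}

#' Convert a circular angle back to day-of-year
#'
#' Inverse of [day_to_radians()]; angles outside (-pi, pi] are wrapped first.
#'
#' @param theta numeric angle in radians.
#' @return day-of-year in (0, 365].
#' @export
radians_to_day <- function(theta) {
  th <- wrap_angle(theta)
  365 * (th + pi) / (2 * pi)
}

# column-name synonyms accepted in Darwin Core style occurrence files
.dwc_species_cols <- c("scientificName", "species")

#' Read a Darwin Core style occurrence table
#'
#' Reads a tab- or comma-separated occurrence file, keeps preserved-specimen
#' rows, parses collection dates from split year/month/day columns and/or an
#' ISO `eventDate`, and drops (with a log) rows that cannot contribute to a
#' phenology series: unparseable or incomplete dates, missing species, and
#' rows whose `basisOfRecord` is not a preserved specimen (field observations
#' are excluded because the analysis is about museum specimens).
#'
#' When both split columns and `eventDate` are present they must agree;
#' conflicting rows are dropped and logged. Rows with a year but no
#' month/day are dropped rather than imputed: imputing a mid-year date would
#' bias circular means toward mid-year.
#'
#' @param path file path to a delimited occurrence table.
#' @param preserved_values `basisOfRecord` values treated as preserved
#'   specimens.
#' @param quiet suppress the drop-log message.
#' @return data.frame of specimen records with columns `species`,
#'   `occurrence_id`, `event_year`, `event_month`, `event_day`,
#'   `basis_of_record`, `latitude`, `longitude`; the drop log is attached as
#'   attribute `"drop_log"`.
#' @export
read_occurrences <- function(path,
                             preserved_values = c("PRESERVED_SPECIMEN",
                                                  "PreservedSpecimen"),
                             quiet = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           na.strings = c("NA", ""))
  sp_col <- intersect(.dwc_species_cols, names(raw))[1]
  if (is.na(sp_col)) {
    stop("missing mandatory column: scientificName (or species)")
  }
  has_split <- all(c("year", "month", "day") %in% names(raw))
  has_iso <- "eventDate" %in% names(raw)
  if (!has_split && !has_iso) {
    stop("missing mandatory column: eventDate (or year/month/day)")
  }
  for (col in c("basisOfRecord", "occurrenceID")) {
    if (!col %in% names(raw)) stop("missing mandatory column: ", col)
  }

  n <- nrow(raw)
  log <- c(missing_species = 0L, non_preserved = 0L, invalid_date = 0L,
           date_conflict = 0L)
  species <- raw[[sp_col]]
  keep <- !is.na(species)
  log["missing_species"] <- sum(!keep)

  basis <- raw[["basisOfRecord"]]
  pres <- !is.na(basis) & basis %in% preserved_values
  log["non_preserved"] <- sum(keep & !pres)
  keep <- keep & pres

  # parse ISO eventDate (date part only) when present
  iso_y <- iso_m <- iso_d <- rep(NA_integer_, n)
  if (has_iso) {
    iso <- sub("T.*$", "", raw[["eventDate"]])
    m <- regmatches(iso, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", iso))
    ok <- lengths(m) == 4
    iso_y[ok] <- as.integer(vapply(m[ok], `[`, "", 2))
    iso_m[ok] <- as.integer(vapply(m[ok], `[`, "", 3))
    iso_d[ok] <- as.integer(vapply(m[ok], `[`, "", 4))
  }
  sp_y <- sp_m <- sp_d <- rep(NA_integer_, n)
  if (has_split) {
    sp_y <- suppressWarnings(as.integer(raw[["year"]]))
    sp_m <- suppressWarnings(as.integer(raw[["month"]]))
    sp_d <- suppressWarnings(as.integer(raw[["day"]]))
  }
  split_full <- !is.na(sp_y) & !is.na(sp_m) & !is.na(sp_d)
  iso_full <- !is.na(iso_y)

  conflict <- split_full & iso_full &
    (sp_y != iso_y | sp_m != iso_m | sp_d != iso_d)
  log["date_conflict"] <- sum(keep & conflict)
  keep <- keep & !conflict

  # split columns win when both present and consistent
  yy <- ifelse(split_full, sp_y, iso_y)
  mm <- ifelse(split_full, sp_m, iso_m)
  dd <- ifelse(split_full, sp_d, iso_d)

  valid <- !is.na(yy) & !is.na(mm) & !is.na(dd) &
    mm >= 1 & mm <= 12 & dd >= 1 & dd <= 31
  valid[valid] <- !is.na(as.Date(
    sprintf("%04d-%02d-%02d", yy[valid], mm[valid], dd[valid]),
    format = "%Y-%m-%d"))
  log["invalid_date"] <- sum(keep & !valid)
  keep <- keep & valid

  num_or_na <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]][keep]))
    else rep(NA_real_, sum(keep))
  }
  out <- data.frame(
    species = species[keep],
    occurrence_id = raw[["occurrenceID"]][keep],
    event_year = yy[keep],
    event_month = mm[keep],
    event_day = dd[keep],
    basis_of_record = basis[keep],
    latitude = num_or_na("decimalLatitude"),
    longitude = num_or_na("decimalLongitude"),
    stringsAsFactors = FALSE
  )
  attr(out, "drop_log") <- log
  if (!quiet && sum(log) > 0) {
    message("read_occurrences: dropped ", sum(log), " of ", n, " rows (",
            paste(names(log), log, sep = "=", collapse = ", "), ")")
  }
  out
}

#' Write specimen records as a Darwin Core style CSV
#'
#' Inverse of [read_occurrences()]: emits the column names that reader
#' accepts (both split date columns and an ISO eventDate).
#'
#' @param records specimen-record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  out <- data.frame(
    scientificName = records$species,
    eventDate = sprintf("%04d-%02d-%02d", records$event_year,
                        records$event_month, records$event_day),
    year = records$event_year,
    month = records$event_month,
    day = records$event_day,
    basisOfRecord = records$basis_of_record,
    occurrenceID = records$occurrence_id,
    decimalLatitude = records$latitude,
    decimalLongitude = records$longitude
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Build the circular observation series for one species
#'
#' One observation per retained record: the predictor is the collection
#' year, the response is the leap-scaled day-of-year converted to an angle.
#'
#' @param records specimen-record data.frame (as from [read_occurrences()]).
#' @param species species label to extract.
#' @return data.frame with columns `year`, `doy`, `theta`, `occurrence_id`.
#' @export
build_series <- function(records, species) {
  rows <- records[records$species == species, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no records for species '", species, "'")
  }
  doy <- day_of_year(rows$event_year, rows$event_month, rows$event_day)
  data.frame(
    year = rows$event_year,
    doy = doy,
    theta = day_to_radians(doy),
    occurrence_id = rows$occurrence_id,
    stringsAsFactors = FALSE
  )
}
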