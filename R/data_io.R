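# Tabular input/output and validation for camera-trap survey data.
#
# All files are comma-separated with a header row.  Timestamps are local,
# naive, ISO 8601 to the minute ("YYYY-MM-DDTHH:MM"); dates are
# "YYYY-MM-DD".  Operation-log date intervals are inclusive on both ends
# (the camera ran on that day).

TIMESTAMP_FMT <- "%Y-%m-%dT%H:%M"

#' Parse ISO 8601 minute-precision timestamps
#'
#' Timestamps are treated as naive local time (no timezone); internally a
#' fixed UTC representation is used so arithmetic is free of DST artefacts.
#'
#' @param x character vector, "YYYY-MM-DDTHH:MM".
#' @return POSIXct vector; NA where unparseable.
#' @keywords internal
parse_timestamp <- function(x) {
  as.POSIXct(as.character(x), format = TIMESTAMP_FMT, tz = "UTC")
}

format_timestamp <- function(x) format(x, TIMESTAMP_FMT, tz = "UTC")

#' Read detection records
#'
#' Reads a comma-separated file of photographic records. Required columns:
#' \code{station_id}, \code{species}, \code{timestamp}, \code{n_individuals}.
#' Species names are trimmed and matched case-insensitively (stored
#' lower-case); row order is preserved.
#'
#' @param path file path.
#' @param stations optional character vector of valid station ids (for
#'   example from an operation log); unknown stations raise an error.
#' @param species_list optional controlled vocabulary of species names;
#'   records with other species raise an error.
#' @return data.frame with columns \code{station_id}, \code{species},
#'   \code{timestamp} (POSIXct), \code{n_individuals}.
#' @export
read_records <- function(path, stations = NULL, species_list = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("station_id", "species", "timestamp", "n_individuals")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("records file missing column(s): ", paste(miss, collapse = ", "))
  validate_records(data.frame(
    station_id    = trimws(raw$station_id),
    species       = normalize_species(raw$species),
    timestamp     = parse_timestamp(raw$timestamp),
    n_individuals = suppressWarnings(as.integer(raw$n_individuals)),
    stringsAsFactors = FALSE
  ), stations = stations, species_list = species_list)
}

normalize_species <- function(x) tolower(trimws(x))

#' Validate a detection-record table
#'
#' @inheritParams read_records
#' @param records data.frame as returned by \code{\link{read_records}}.
#' @return the validated records, invisibly unchanged.
#' @export
validate_records <- function(records, stations = NULL, species_list = NULL) {
  bad <- which(is.na(records$timestamp))
  if (length(bad))
    stop("malformed timestamp in record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(!nzchar(records$station_id)))
    stop("empty station_id in records")
  if (any(!nzchar(records$species)))
    stop("empty species name in records")
  if (any(is.na(records$n_individuals) | records$n_individuals < 0L))
    stop("n_individuals must be a non-negative integer")
  if (!is.null(stations)) {
    unknown <- setdiff(unique(records$station_id), stations)
    if (length(unknown))
      stop("records reference station(s) absent from the operation log: ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(species_list)) {
    unknown <- setdiff(unique(records$species),
                       normalize_species(species_list))
    if (length(unknown))
      stop("records contain species outside the controlled list: ",
           paste(unknown, collapse = ", "))
  }
  records
}

#' Write detection records
#'
#' Inverse of \code{\link{read_records}}: writing then re-reading gives a
#' value-identical table.
#'
#' @param records record data.frame.
#' @param path output file path.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    station_id    = records$station_id,
    species       = records$species,
    timestamp     = format_timestamp(records$timestamp),
    n_individuals = records$n_individuals,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a station operation log
#'
#' Columns: \code{station_id}, \code{start_date}, \code{end_date}; several
#' rows per station describe disjoint operational intervals. Dates are
#' inclusive on both ends.
#'
#' @param path file path.
#' @return data.frame with Date columns \code{start_date}, \code{end_date}.
#' @export
read_operation_log <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "start_date", "end_date")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("operation log missing column(s): ", paste(miss, collapse = ", "))
  log <- data.frame(
    station_id = trimws(as.character(raw$station_id)),
    start_date = as.Date(raw$start_date),
    end_date   = as.Date(raw$end_date),
    stringsAsFactors = FALSE
  )
  if (any(is.na(log$start_date)) || any(is.na(log$end_date)))
    stop("operation log contains unparseable dates")
  if (any(log$end_date < log$start_date))
    stop("operation log interval with end before start")
  log
}

#' @rdname read_operation_log
#' @param log operation-log data.frame.
#' @param path output file path.
#' @export
write_operation_log <- function(log, path) {
  utils::write.csv(
    data.frame(station_id = log$station_id,
               start_date = as.character(log$start_date),
               end_date   = as.character(log$end_date)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Normalize one station's intervals: sort and merge overlapping/adjacent.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {          # overlap or adjacency: merge
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = as.Date(c(out_s, ms), origin = "1970-01-01"),
       end   = as.Date(c(out_e, me), origin = "1970-01-01"))
}

#' Operational effort in camera-trap days
#'
#' Intersects each station's operational intervals with the survey window
#' and counts whole days (a day any part of which is covered counts as
#' effort). Intervals are merged first, so overlapping log rows are not
#' double-counted.
#'
#' @param log operation-log data.frame (\code{\link{read_operation_log}}).
#' @param window length-2 Date vector \code{c(start, end)}, inclusive.
#' @return list with \code{per_station} (named integer vector) and
#'   \code{total}.
#' @export
effort_days <- function(log, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !any(is.na(window)))
  if (window[2] < window[1]) stop("survey window end precedes start")
  if (nrow(log) == 0L) {
    warning("empty operation log: total effort is 0")
    return(list(per_station = integer(0), total = 0L))
  }
  per <- vapply(split(log, log$station_id), function(d) {
    iv <- merge_intervals(d$start_date, d$end_date)
    s <- pmax(iv$start, window[1])
    e <- pmin(iv$end, window[2])
    keep <- e >= s
    sum(as.integer(e[keep] - s[keep]) + 1L)
  }, integer(1))
  list(per_station = per, total = sum(per))
}

#' Days on which a station was operational
#'
#' @inheritParams effort_days
#' @param station_id station to query.
#' @return Date vector of operational days inside the window.
#' @keywords internal
operational_days <- function(log, station_id, window) {
  window <- as.Date(window)
  d <- log[log$station_id == station_id, , drop = FALSE]
  if (nrow(d) == 0L) return(as.Date(character(0)))
  iv <- merge_intervals(d$start_date, d$end_date)
  out <- lapply(seq_along(iv$start), function(i) {
    s <- max(iv$start[i], window[1]); e <- min(iv$end[i], window[2])
    if (e < s) as.Date(character(0)) else seq(s, e, by = "day")
  })
  as.Date(unlist(out), origin = "1970-01-01")
}

#' Read a station covariate table
#'
#' One row per station; \code{type_map} declares each covariate as
#' \code{"continuous"}, \code{"categorical"} or \code{"binary"}. Missing
#' values are a hard error: covariates are recorded exhaustively at every
#' station, so a gap indicates a data-entry fault, not a sampling one.
#'
#' @param path file path.
#' @param type_map named character vector, column name -> type. Columns not
#'   named are inferred (numeric -> continuous, 0/1 -> binary,
#'   otherwise categorical).
#' @return data.frame with attribute \code{"type_map"}.
#' @export
read_covariates <- function(path, type_map = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"station_id" %in% names(raw))
    stop("covariate table missing station_id column")
  raw$station_id <- trimws(as.character(raw$station_id))
  validate_covariates(raw, type_map)
}

#' @rdname read_covariates
#' @param covs covariate data.frame including \code{station_id}.
#' @export
validate_covariates <- function(covs, type_map = NULL) {
  if (anyDuplicated(covs$station_id))
    stop("covariate table has duplicated station_id rows")
  vars <- setdiff(names(covs), "station_id")
  na_cols <- vars[vapply(covs[vars], anyNA, logical(1))]
  if (length(na_cols))
    stop("missing covariate value(s) in column(s): ",
         paste(na_cols, collapse = ", "))
  inferred <- vapply(vars, function(v) {
    x <- covs[[v]]
    if (is.numeric(x)) {
      if (all(x %in% c(0, 1))) "binary" else "continuous"
    } else "categorical"
  }, character(1))
  if (!is.null(type_map)) {
    bad <- setdiff(names(type_map), vars)
    if (length(bad)) stop("type_map names unknown column(s): ",
                          paste(bad, collapse = ", "))
    inferred[names(type_map)] <- unname(type_map)
  }
  ok <- inferred %in% c("continuous", "categorical", "binary")
  if (!all(ok)) stop("invalid covariate type(s): ",
                     paste(unique(inferred[!ok]), collapse = ", "))
  for (v in vars[inferred == "categorical"])
    covs[[v]] <- as.character(covs[[v]])
  attr(covs, "type_map") <- inferred
  covs
}

#' Read species traits
#'
#' Columns: \code{species}, \code{body_mass_kg}, \code{guild}
#' (carnivore/herbivore/omnivore). The analysis is restricted to
#' terrestrial mammals heavier than 0.5 kg, so lighter entries are
#' rejected.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_traits <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "body_mass_kg", "guild")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("traits file missing column(s): ", paste(miss, collapse = ", "))
  tr <- data.frame(
    species      = normalize_species(raw$species),
    body_mass_kg = as.numeric(raw$body_mass_kg),
    guild        = tolower(trimws(raw$guild)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(tr$body_mass_kg) | tr$body_mass_kg <= 0.5))
    stop("body_mass_kg must exceed 0.5 (analysis covers mammals > 0.5 kg)")
  bad <- setdiff(unique(tr$guild), c("carnivore", "herbivore", "omnivore"))
  if (length(bad))
    stop("unknown guild(s): ", paste(bad, collapse = ", "))
  tr
}

#' Read a plain-text key/value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment.
#' Comma-separated values become vectors; numeric-looking values are
#' converted. Recognised keys (with defaults) cover the whole pipeline:
#' \code{event_interval_min} (60), \code{occasion_lengths} (5:11),
#' \code{min_operational_fraction} (0.80), \code{vif_threshold} (3),
#' \code{n_boot} (1000), \code{max_terms} (4), \code{survey_start},
#' \code{survey_end}, \code{species_blocklist} (livestock and other
#' domestic species to drop from community metrics).
#'
#' @param path file path, or NULL for pure defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(
    event_interval_min       = 60,
    occasion_lengths         = 5:11,
    min_operational_fraction = 0.80,
    vif_threshold            = 3,
    n_boot                   = 1000,
    max_terms                = 4,
    survey_start             = NA,
    survey_end               = NA,
    species_blocklist        = character(0)
  )
  if (is.null(path)) return(cfg)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(strsplit(kv[2], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (length(val) == 2L && is.numeric(val) &&
        key == "occasion_lengths") val <- val[1]:val[2]
    cfg[[key]] <- val
  }
  cfg
}
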