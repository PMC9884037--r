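# Independent-event extraction and relative abundance indices.
#
# An "event" is an image sequence of one species at one station separated
# from the previous sequence of that species by at least the independence
# interval (60 min by default).  The gap is measured from the most recent
# image of the ongoing sequence, the standard camera-trap convention; a gap
# exactly equal to the interval opens a new event.

#' Collapse records into independent events
#'
#' Within each (station, species) stream, sorted by time, a new event
#' starts when the gap from the previous retained image is greater than or
#' equal to \code{interval_minutes}. Images never merge across stations or
#' species, and the rule does not reset at midnight or camera visits.
#' Identical duplicate timestamps fall into one event.
#'
#' @param records record data.frame (\code{\link{read_records}}).
#' @param interval_minutes independence interval in minutes (default 60).
#' @return data.frame of events: \code{station_id}, \code{species},
#'   \code{start_time}, \code{end_time}, \code{n_images},
#'   \code{n_individuals} (maximum per-image count within the event).
#' @export
deduplicate_events <- function(records, interval_minutes = 60) {
  stopifnot(is.numeric(interval_minutes), interval_minutes > 0)
  if (nrow(records) == 0L)
    return(data.frame(station_id = character(0), species = character(0),
                      start_time = parse_timestamp(character(0)),
                      end_time = parse_timestamp(character(0)),
                      n_images = integer(0), n_individuals = integer(0)))
  key <- interaction(records$station_id, records$species, drop = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    gap_min <- c(Inf, diff(as.numeric(d$timestamp)) / 60)
    event_id <- cumsum(gap_min >= interval_minutes)
    agg <- lapply(split(seq_len(nrow(d)), event_id), function(ix) {
      data.frame(station_id = d$station_id[ix[1]],
                 species    = d$species[ix[1]],
                 start_time = min(d$timestamp[ix]),
                 end_time   = max(d$timestamp[ix]),
                 n_images   = length(ix),
                 n_individuals = max(d$n_individuals[ix]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  ev <- do.call(rbind, pieces)
  ev <- ev[order(ev$station_id, ev$species, ev$start_time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Relative abundance indices (events per 100 trap-days)
#'
#' RAI = 100 x events / effort. Computed per (species, station) and
#' globally per species, the global index using the summed effort across
#' all stations. A station with zero effort but recorded events signals an
#' inconsistent operation log and is an error; zero effort with zero
#' events yields an NA index, flagged in the output.
#'
#' @param events event data.frame (\code{\link{deduplicate_events}}).
#' @param effort named numeric vector of trap-days per station (typically
#'   \code{effort_days(log, window)$per_station}). Stations with no events
#'   still contribute effort.
#' @return object of class \code{rai_table}: list with \code{by_station}
#'   and \code{global} data.frames (columns \code{station_id},
#'   \code{species}, \code{events}, \code{effort_days}, \code{rai}).
#' @export
compute_rai <- function(events, effort) {
  stopifnot(!is.null(names(effort)) || length(effort) == 0L)
  missing_st <- setdiff(unique(events$station_id), names(effort))
  if (length(missing_st))
    stop("event station(s) absent from effort: ",
         paste(missing_st, collapse = ", "))
  zero_eff <- names(effort)[effort == 0]
  if (any(events$station_id %in% zero_eff))
    stop("station with zero effort has recorded events: ",
         paste(intersect(unique(events$station_id), zero_eff),
               collapse = ", "))
  species <- sort(unique(events$species))
  stations <- names(effort)
  counts <- table(factor(events$species, species),
                  factor(events$station_id, stations))
  by_station <- data.frame(
    station_id  = rep(stations, each = length(species)),
    species     = rep(species, times = length(stations)),
    events      = as.integer(counts[cbind(
      rep(seq_along(species), times = length(stations)),
      rep(seq_along(stations), each = length(species)))]),
    effort_days = rep(unname(effort), each = length(species)),
    stringsAsFactors = FALSE
  )
  by_station$rai <- ifelse(by_station$effort_days > 0,
                           100 * by_station$events / by_station$effort_days,
                           NA_real_)
  tot_eff <- sum(effort)
  glob_events <- as.integer(rowSums(counts))
  global <- data.frame(
    species     = species,
    events      = glob_events,
    effort_days = rep(tot_eff, length(species)),
    rai         = if (tot_eff > 0) 100 * glob_events / tot_eff else NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(by_station = by_station, global = global),
            class = "rai_table")
}

#' @export
print.rai_table <- function(x, ...) {
  cat("Relative abundance indices (events per 100 trap-days)\n")
  cat(sprintf("  %d species, %d stations, %.0f total trap-days\n",
              nrow(x$global),
              length(unique(x$by_station$station_id)),
              if (nrow(x$global)) x$global$effort_days[1] else 0))
  g <- x$global
  g$rai <- round(g$rai, 2)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Write an RAI table
#'
#' Emits the per-station block followed by global per-species rows
#' (station_id \code{"(global)"}), with indices rounded to 2 decimal
#' places, in fixed column order (station, species, events, effort_days,
#' rai).
#'
#' @param rai \code{rai_table} object.
#' @param path output file path.
#' @export
write_rai <- function(rai, path) {
  g <- cbind(station_id = "(global)", rai$global)
  out <- rbind(rai$by_station, g[names(rai$by_station)])
  out$rai <- round(out$rai, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
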