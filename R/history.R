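# Detection-history construction: daily site x day matrices, collapse to
# multi-day sampling occasions, and the station operationality filter.

new_detection_history <- function(y, occasion_length, window,
                                  occasion_days) {
  structure(list(y = y,
                 occasion_length = occasion_length,
                 n_occasions = ncol(y),
                 window = as.Date(window),
                 site_ids = rownames(y),
                 occasion_days = occasion_days),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf(
    "Detection history: %d sites x %d occasions (occasion length %d d)\n",
    nrow(x$y), x$n_occasions, x$occasion_length))
  cat(sprintf("  survey window %s .. %s\n", x$window[1], x$window[2]))
  cat(sprintf("  cells: %d detections, %d zeros, %d missing\n",
              sum(x$y == 1, na.rm = TRUE), sum(x$y == 0, na.rm = TRUE),
              sum(is.na(x$y))))
  invisible(x)
}

#' Daily detection history for one species
#'
#' Builds a site x day matrix over the survey window: 1 if at least one
#' event of the species occurred at the station that calendar day, 0 if
#' the camera was operational that day with no event, missing (NA) if the
#' camera was not operational. A day counts as operational if the log
#' covers any part of it; at most one detection is scored per 24-h period.
#'
#' @param events event data.frame (\code{\link{deduplicate_events}}).
#' @param log operation log (\code{\link{read_operation_log}}).
#' @param species species name.
#' @param window length-2 Date vector, inclusive survey window.
#' @return \code{detection_history} with occasion length 1; sites are all
#'   stations in the log.
#' @export
daily_history <- function(events, log, species, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[2] >= window[1])
  days <- seq(window[1], window[2], by = "day")
  sites <- sort(unique(log$station_id))
  y <- matrix(NA_integer_, nrow = length(sites), ncol = length(days),
              dimnames = list(sites, as.character(days)))
  for (s in sites) {
    op <- operational_days(log, s, window)
    y[s, as.character(op)] <- 0L
  }
  ev <- events[normalize_species(events$species) ==
                 normalize_species(species), , drop = FALSE]
  ev <- ev[as.Date(ev$start_time) >= window[1] &
             as.Date(ev$start_time) <= window[2], , drop = FALSE]
  if (nrow(ev)) {
    unknown <- setdiff(unique(ev$station_id), sites)
    if (length(unknown))
      stop("events at station(s) absent from the operation log: ",
           paste(unknown, collapse = ", "))
    ix <- cbind(match(ev$station_id, sites),
                match(as.character(as.Date(ev$start_time)),
                      as.character(days)))
    off <- is.na(y[ix])
    if (any(off))
      stop("event on a non-operational day at station(s): ",
           paste(unique(ev$station_id[off]), collapse = ", "),
           " (operation log and records disagree)")
    y[ix] <- 1L
  }
  new_detection_history(y, 1L, window, rep(1L, length(days)))
}

#' Collapse a daily history into multi-day occasions
#'
#' Occasion blocks of k consecutive days are anchored at the survey start
#' date; the final partial block is kept as a shorter occasion. An
#' occasion scores 1 if any constituent day scored 1; 0 if at least one
#' day was operational and none scored 1; missing if no day was
#' operational.
#'
#' @param daily \code{detection_history} with occasion length 1.
#' @param k occasion length in days (typically 5..11).
#' @return \code{detection_history} with \code{ceiling(n_days / k)}
#'   occasions.
#' @export
collapse_occasions <- function(daily, k) {
  stopifnot(inherits(daily, "detection_history"))
  if (daily$occasion_length != 1L)
    stop("collapse_occasions expects a daily (occasion length 1) history")
  n_days <- ncol(daily$y)
  if (k < 1L || k > n_days)
    stop("occasion length k outside 1..survey length")
  if (k == 1L) return(daily)
  block <- (seq_len(n_days) - 1L) %/% as.integer(k) + 1L
  n_occ <- max(block)
  y <- matrix(NA_integer_, nrow = nrow(daily$y), ncol = n_occ,
              dimnames = list(rownames(daily$y),
                              paste0("occ", seq_len(n_occ))))
  for (b in seq_len(n_occ)) {
    sub <- daily$y[, block == b, drop = FALSE]
    any1 <- rowSums(sub == 1L, na.rm = TRUE) > 0
    anyop <- rowSums(!is.na(sub)) > 0
    y[, b] <- ifelse(any1, 1L, ifelse(anyop, 0L, NA_integer_))
  }
  new_detection_history(y, as.integer(k), daily$window,
                        as.integer(table(block)))
}

#' Filter stations by operational fraction
#'
#' Removes sites whose fraction of non-missing occasions falls below the
#' threshold (default 0.80, i.e. cameras operational for at least 80% of
#' occasions). The fraction is computed on the collapsed history.
#'
#' @param h \code{detection_history}.
#' @param min_operational_fraction threshold in (0, 1].
#' @return list with \code{history} (filtered) and \code{excluded}
#'   (character vector of dropped site ids).
#' @export
filter_stations <- function(h, min_operational_fraction = 0.80) {
  stopifnot(inherits(h, "detection_history"))
  if (!(min_operational_fraction > 0 && min_operational_fraction <= 1))
    stop("min_operational_fraction must lie in (0, 1]")
  frac <- rowMeans(!is.na(h$y))
  keep <- frac >= min_operational_fraction
  if (!any(keep))
    stop("all sites excluded by the operationality filter")
  out <- h
  out$y <- h$y[keep, , drop = FALSE]
  out$site_ids <- rownames(out$y)
  list(history = out, excluded = rownames(h$y)[!keep])
}

#' Naive occupancy
#'
#' Proportion of sampled sites with at least one detection; ignores
#' imperfect detection.
#'
#' @param h \code{detection_history}.
#' @return list with \code{n_detected_sites}, \code{n_sampled_sites},
#'   \code{psi_naive}.
#' @export
naive_occupancy <- function(h) {
  stopifnot(inherits(h, "detection_history"))
  if (nrow(h$y) == 0L) stop("empty detection history")
  det <- rowSums(h$y == 1L, na.rm = TRUE) > 0
  list(n_detected_sites = sum(det),
       n_sampled_sites = nrow(h$y),
       psi_naive = sum(det) / nrow(h$y))
}

#' Write a detection history matrix
#'
#' Rows are sites, columns occasions, cells 0/1/NA.
#'
#' @param h \code{detection_history}.
#' @param path output file path.
#' @export
write_history <- function(h, path) {
  out <- data.frame(station_id = rownames(h$y), h$y, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
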