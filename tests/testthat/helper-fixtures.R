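# Shared fixture builders: everything is generated in code.

# Records data.frame from parallel vectors of ISO strings.
make_records <- function(station, species, ts, n = 1L) {
  data.frame(station_id = station, species = species,
             timestamp = camoccu:::parse_timestamp(ts),
             n_individuals = rep_len(as.integer(n), length(ts)),
             stringsAsFactors = FALSE)
}

# Detection history straight from a 0/1/NA matrix.
make_history <- function(y, k = 1L, start = "2020-01-01") {
  if (is.null(rownames(y)))
    rownames(y) <- sprintf("S%03d", seq_len(nrow(y)))
  window <- as.Date(start) + c(0L, ncol(y) * k - 1L)
  camoccu:::new_detection_history(y, as.integer(k), window,
                                  rep(as.integer(k), ncol(y)))
}

# Simulate a site x occasion matrix from constant (psi, p).
sim_y <- function(n_sites, n_occ, psi, p) {
  z <- stats::rbinom(n_sites, 1L, psi)
  matrix(stats::rbinom(n_sites * n_occ, 1L, rep(p * z, n_occ)),
         nrow = n_sites,
         dimnames = list(sprintf("S%03d", seq_len(n_sites)), NULL))
}

# Brute-force single-pass oracle for the 60-min rule: walk the sorted
# timestamps of one (station, species) stream and count events.
event_count_oracle <- function(times, interval_minutes) {
  times <- sort(times)
  n_ev <- 0L; last <- NULL
  for (t in as.list(times)) {
    if (is.null(last) ||
        as.numeric(difftime(t, last, units = "mins")) >= interval_minutes)
      n_ev <- n_ev + 1L
    last <- t
  }
  n_ev
}

# Dense grid search over (psi, p) for the intercept-only occupancy
# likelihood: coarse 0.01 pass, then refinement at 1e-3 and 1e-4 around
# the running optimum.
grid_mle <- function(y) {
  nll <- function(psi, p)
    camoccu::occu_negloglik(c(stats::qlogis(psi), stats::qlogis(p)),
                            y, matrix(1, nrow(y)), matrix(1, nrow(y)))
  gp <- gq <- seq(0.01, 0.99, by = 0.01)
  vals <- outer(gp, gq, Vectorize(nll))
  ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  best <- c(psi = gp[ix[1]], p = gq[ix[2]])
  for (step in c(1e-3, 1e-4)) {
    gp <- seq(max(1e-4, best[1] - 12 * step),
              min(1 - 1e-4, best[1] + 12 * step), by = step)
    gq <- seq(max(1e-4, best[2] - 12 * step),
              min(1 - 1e-4, best[2] + 12 * step), by = step)
    vals <- outer(gp, gq, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(psi = gp[ix[1]], p = gq[ix[2]])
  }
  best
}

# Probability of one detection history under constant (psi, p).
history_prob_oracle <- function(v, psi, p) {
  if (any(v == 1)) psi * prod(p^v * (1 - p)^(1 - v))
  else psi * prod(1 - p) + (1 - psi)
}
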