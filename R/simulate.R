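# Synthetic camera-trap surveys with known parameters.
#
# The generator emulates a single dry-season survey: stations with mixed
# continuous/categorical/binary site covariates, per-species occupancy
# and daily detection governed by logit-linear coefficients, within-day
# image bursts (so the 60-min independence rule is exercised), and random
# mid-survey station failures.  Two default configurations mirror a
# two-region design: 73 stations over 151 days with a low failure rate,
# and 64 stations over 132 days with a higher one.

default_covariate_spec <- function() {
  list(
    altitude          = list(type = "continuous", dist = "normal",
                             mean = 800, sd = 250),
    dist_water_m      = list(type = "continuous", dist = "lognormal",
                             meanlog = 6.2, sdlog = 0.8),
    dist_road_m       = list(type = "continuous", dist = "lognormal",
                             meanlog = 6.8, sdlog = 0.9),
    dist_habitation_m = list(type = "continuous", dist = "lognormal",
                             meanlog = 7.5, sdlog = 0.7),
    vegetation        = list(type = "categorical",
                             levels = c("fynbos", "karoo", "renoster"),
                             probs = c(0.5, 0.3, 0.2)),
    livestock         = list(type = "binary", prob = 0.30),
    disturbance       = list(type = "binary", prob = 0.25)
  )
}

#' Specify a synthetic camera-trap survey
#'
#' Defaults describe a 73-station, 151-day dry-season survey with about
#' one expected station failure; \code{sim_spec(n_stations = 64,
#' survey_days = 132, failure_rate = 3/64)} gives the companion
#' configuration of the paired-region design.
#'
#' @param n_stations number of camera-trap stations.
#' @param survey_days survey length in days.
#' @param start_date first survey day.
#' @param covariates per-covariate specification list; each entry has a
#'   \code{type} ("continuous"/"categorical"/"binary") and distribution
#'   parameters (\code{dist} + \code{mean}/\code{sd},
#'   \code{meanlog}/\code{sdlog} or \code{min}/\code{max} for continuous;
#'   \code{levels} + \code{probs}; \code{prob}).
#' @param species named list of per-species process parameters: each a
#'   list with \code{beta_psi} and \code{beta_p} (named coefficient
#'   vectors on the logit scale over the simulation design columns —
#'   \code{"(Intercept)"}, z-scored continuous names, binary names, and
#'   categorical dummies like \code{"vegetation_karoo"}) and optional
#'   \code{extra_images} (Poisson mean of extra images per detected day,
#'   default 1.5).
#' @param failure_rate per-station probability of a mid-survey failure
#'   that truncates its operation interval.
#' @return object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_stations = 73, survey_days = 151,
                     start_date = "2017-11-01",
                     covariates = default_covariate_spec(),
                     species = list(), failure_rate = 1 / 73) {
  stopifnot(n_stations >= 1, survey_days >= 1,
            failure_rate >= 0, failure_rate <= 1)
  for (nm in names(covariates)) {
    cs <- covariates[[nm]]
    if (!cs$type %in% c("continuous", "categorical", "binary"))
      stop("invalid covariate type for ", nm)
    if (cs$type == "categorical" &&
        (length(cs$levels) != length(cs$probs) ||
         abs(sum(cs$probs) - 1) > 1e-8))
      stop("categorical levels/probs mismatch for ", nm)
    if (cs$type == "binary" && (cs$prob < 0 || cs$prob > 1))
      stop("binary prob outside [0,1] for ", nm)
  }
  structure(list(n_stations = n_stations, survey_days = survey_days,
                 start_date = as.Date(start_date),
                 covariates = covariates, species = species,
                 failure_rate = failure_rate),
            class = "sim_spec")
}

sim_window <- function(spec) {
  c(spec$start_date, spec$start_date + spec$survey_days - 1L)
}

draw_covariate <- function(cs, n) {
  switch(cs$type,
    continuous = switch(if (is.null(cs$dist)) "normal" else cs$dist,
      normal    = stats::rnorm(n, cs$mean, cs$sd),
      lognormal = stats::rlnorm(n, cs$meanlog, cs$sdlog),
      uniform   = stats::runif(n, cs$min, cs$max),
      stop("unknown continuous distribution: ", cs$dist)),
    categorical = sample(cs$levels, n, replace = TRUE, prob = cs$probs),
    binary = stats::rbinom(n, 1L, cs$prob))
}

# Simulation design matrix: intercept, z-scored continuous columns,
# binary columns, categorical dummies named <var>_<level> (reference =
# first level in sort order) — the same naming screen_covariates() uses.
sim_design <- function(covs, type_map) {
  n <- nrow(covs)
  X <- list("(Intercept)" = rep(1, n))
  for (v in setdiff(names(covs), "station_id")) {
    x <- covs[[v]]
    if (type_map[[v]] == "continuous") {
      X[[v]] <- (x - mean(x)) / stats::sd(x)
    } else if (type_map[[v]] == "binary") {
      X[[v]] <- as.numeric(x)
    } else {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1]) X[[paste0(v, "_", l)]] <- as.numeric(x == l)
    }
  }
  do.call(cbind, X)
}

linear_predictor <- function(X, beta) {
  miss <- setdiff(names(beta), colnames(X))
  if (length(miss))
    stop("coefficient name(s) not in simulation design: ",
         paste(miss, collapse = ", "))
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Generate station covariates and an operation log
#'
#' Continuous covariates are drawn from their stated distributions,
#' categoricals from their level probabilities, binaries as Bernoulli.
#' Each station fails mid-survey with probability \code{failure_rate};
#' failed stations get an operation interval truncated at a uniformly
#' drawn day.
#'
#' @param spec \code{sim_spec}.
#' @param seed RNG seed (identical spec + seed gives identical output).
#' @return list with \code{covariates} (data.frame, typed via its
#'   \code{type_map} attribute) and \code{oplog}.
#' @export
generate_landscape <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_stations
  ids <- sprintf("ST%03d", seq_len(n))
  covs <- data.frame(station_id = ids, stringsAsFactors = FALSE)
  for (v in names(spec$covariates))
    covs[[v]] <- draw_covariate(spec$covariates[[v]], n)
  tm <- vapply(spec$covariates, `[[`, character(1), "type")
  covs <- validate_covariates(covs, tm)
  win <- sim_window(spec)
  fail <- stats::rbinom(n, 1L, spec$failure_rate) == 1L
  end <- rep(win[2], n)
  if (any(fail) && spec$survey_days > 1L)
    end[fail] <- win[1] +
      sample.int(spec$survey_days - 1L, sum(fail), replace = TRUE) - 1L
  oplog <- data.frame(station_id = ids, start_date = win[1],
                      end_date = end, stringsAsFactors = FALSE)
  list(covariates = covs, oplog = oplog)
}

#' Generate detection records for one species
#'
#' Site occupancy is drawn Bernoulli(psi_i) with
#' psi_i = plogis(x_i' beta_psi); occupied sites then yield daily
#' Bernoulli(p_i) detections over their operational days. A detected day
#' receives 1 + Poisson(extra_images) image timestamps inside a 2-hour
#' burst window starting at a random time of day, so both sub-60-min and
#' over-60-min gaps occur.
#'
#' @param spec \code{sim_spec} with the species in \code{spec$species}.
#' @param landscape output of \code{\link{generate_landscape}}.
#' @param species species name.
#' @param seed RNG seed (NULL to continue the current stream).
#' @return record data.frame with attribute \code{"truth"} (per-site
#'   \code{psi}, \code{p}, latent occupancy \code{z}).
#' @export
generate_detections <- function(spec, landscape, species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- spec$species[[species]]
  if (is.null(sp)) stop("species not in spec: ", species)
  covs <- landscape$covariates
  X <- sim_design(covs, attr(covs, "type_map"))
  psi <- stats::plogis(linear_predictor(X, sp$beta_psi))
  p <- stats::plogis(linear_predictor(X, sp$beta_p))
  extra <- if (is.null(sp$extra_images)) 1.5 else sp$extra_images
  z <- stats::rbinom(nrow(covs), 1L, psi)
  win <- sim_window(spec)
  recs <- list()
  for (i in seq_len(nrow(covs))) {
    if (z[i] == 0L) next
    days <- operational_days(landscape$oplog, covs$station_id[i], win)
    hit <- days[stats::rbinom(length(days), 1L, p[i]) == 1L]
    for (d in as.list(hit)) {
      n_img <- 1L + stats::rpois(1L, extra)
      burst0 <- stats::runif(1, 0, 22 * 3600)
      offs <- sort(stats::runif(n_img, 0, 2 * 3600))
      tt <- as.POSIXct(paste0(format(d), "T00:00"),
                       format = TIMESTAMP_FMT, tz = "UTC") + burst0 + offs
      recs[[length(recs) + 1L]] <- data.frame(
        station_id = covs$station_id[i], species = species,
        timestamp = tt, n_individuals = 1L + stats::rpois(n_img, 0.2),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(station_id = character(0), species = character(0),
               timestamp = parse_timestamp(character(0)),
               n_individuals = integer(0))
  # minute precision, matching the on-disk timestamp format
  out$timestamp <- as.POSIXct(trunc(out$timestamp, "mins"))
  out <- out[order(out$station_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(psi = psi, p = p, z = z,
                             station_id = covs$station_id)
  out
}

#' Generate a complete synthetic survey
#'
#' Draws a landscape and detection records for every species in the
#' spec. Fully reproducible: identical spec + seed gives identical
#' output.
#'
#' @param spec \code{sim_spec}.
#' @param seed RNG seed.
#' @return list with \code{records}, \code{covariates}, \code{oplog},
#'   \code{window}, and \code{truth} (per-species generator state).
#' @export
generate_survey <- function(spec, seed = 1L) {
  set.seed(seed)
  landscape <- generate_landscape(spec, seed = NULL)
  recs <- list(); truth <- list()
  for (s in names(spec$species)) {
    r <- generate_detections(spec, landscape, s, seed = NULL)
    truth[[s]] <- attr(r, "truth")
    attr(r, "truth") <- NULL
    recs[[s]] <- r
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    generate_detections_empty()
  rownames(records) <- NULL
  list(records = records, covariates = landscape$covariates,
       oplog = landscape$oplog, window = sim_window(spec),
       truth = truth)
}

generate_detections_empty <- function() {
  data.frame(station_id = character(0), species = character(0),
             timestamp = parse_timestamp(character(0)),
             n_individuals = integer(0))
}

# Default per-species process parameters for community-level fixtures:
# moderate occupancy and daily detection so that, at survey scale, every
# species in the pool is detected at least once with near certainty.
default_species_params <- function(names) {
  out <- list()
  for (nm in names) {
    out[[nm]] <- list(
      beta_psi = c("(Intercept)" = stats::rnorm(1, stats::qlogis(0.6), 0.4),
                   altitude = stats::rnorm(1, 0, 0.3)),
      beta_p = c("(Intercept)" = stats::rnorm(1, stats::qlogis(0.12), 0.3)),
      extra_images = 1.5)
  }
  out
}

#' Generate a paired two-community survey
#'
#' Builds two full synthetic surveys whose species pools overlap exactly
#' as specified (shared plus community-unique species), so downstream
#' similarity metrics have exact expectations. Species without explicit
#' parameters in the specs get defaults with occupancy and detection high
#' enough that every pool member is detected at survey scale.
#'
#' @param spec_a,spec_b \code{sim_spec} for each community; defaults
#'   mirror the two-region design (73 stations x 151 days with about one
#'   expected failure; 64 x 132 with about three).
#' @param shared_species character vector of species present in both.
#' @param unique_a,unique_b species found only in one community; must be
#'   disjoint from each other and from \code{shared_species}.
#' @param seed RNG seed.
#' @return list with surveys \code{a} and \code{b}
#'   (\code{\link{generate_survey}} outputs) and the three species lists.
#' @export
generate_two_communities <- function(
    spec_a = sim_spec(),
    spec_b = sim_spec(n_stations = 64, survey_days = 132,
                      start_date = "2019-11-01", failure_rate = 3 / 64),
    shared_species, unique_a = character(0), unique_b = character(0),
    seed = 1L) {
  pools <- list(shared_species, unique_a, unique_b)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(pools[[i]], pools[[j]])))
      stop("species lists overlap: ",
           paste(intersect(pools[[i]], pools[[j]]), collapse = ", "))
  set.seed(seed)
  fill <- function(spec, pool) {
    missing <- setdiff(pool, names(spec$species))
    spec$species <- c(spec$species[intersect(names(spec$species), pool)],
                      default_species_params(missing))
    spec
  }
  spec_a <- fill(spec_a, c(shared_species, unique_a))
  spec_b <- fill(spec_b, c(shared_species, unique_b))
  seeds <- sample.int(.Machine$integer.max, 2L)
  list(a = generate_survey(spec_a, seed = seeds[1]),
       b = generate_survey(spec_b, seed = seeds[2]),
       shared_species = shared_species,
       unique_a = unique_a, unique_b = unique_b)
}
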