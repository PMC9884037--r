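# Community structure: richness, rarefaction, diversity, similarity.
#
# All metrics are incidence- or RAI-based; livestock and other domestic
# species are expected to be removed upstream via the config blocklist.

#' Species-by-station incidence matrix
#'
#' @param events event data.frame (\code{\link{deduplicate_events}}).
#' @param stations character vector of all surveyed stations (stations with
#'   no detections still count as sampling units).
#' @param blocklist species to exclude (e.g. livestock/domestic species).
#' @return binary matrix, species rows x station columns.
#' @export
incidence_matrix <- function(events, stations,
                             blocklist = character(0)) {
  stopifnot(length(stations) > 0L)
  keep <- !(events$species %in% normalize_species(blocklist))
  events <- events[keep, , drop = FALSE]
  species <- sort(unique(events$species))
  m <- matrix(0L, nrow = length(species), ncol = length(stations),
              dimnames = list(species, stations))
  if (nrow(events)) {
    ix <- cbind(match(events$species, species),
                match(events$station_id, stations))
    if (anyNA(ix[, 2]))
      stop("event at station absent from the station list")
    m[ix] <- 1L
  }
  m
}

#' First-order Jackknife richness estimate
#'
#' S_jack1 = S_obs + f1 (n - 1) / n, where f1 is the number of species
#' detected at exactly one station and n the number of stations.
#'
#' @param inc incidence matrix (\code{\link{incidence_matrix}}).
#' @return list with \code{S_obs}, \code{f1}, \code{S_jack1},
#'   \code{n_stations}.
#' @export
jackknife1 <- function(inc) {
  if (is.null(dim(inc)) || ncol(inc) < 1L || nrow(inc) < 1L)
    stop("empty incidence matrix")
  n <- ncol(inc)
  occ <- rowSums(inc > 0)
  S_obs <- sum(occ >= 1)
  f1 <- sum(occ == 1)
  list(S_obs = S_obs, f1 = f1,
       S_jack1 = S_obs + f1 * (n - 1) / n, n_stations = n)
}

#' Sample-based rarefaction curve
#'
#' Analytic (hypergeometric) expected richness when h of the n stations
#' are drawn without replacement:
#' E[S_h] = sum_j (1 - C(n - n_j, h) / C(n, h)), n_j the number of
#' stations at which species j was detected. A seeded resampling mode is
#' provided for cross-checks.
#'
#' @param inc incidence matrix.
#' @param h subsample sizes (default 1..n_stations).
#' @param method "analytic" (default) or "resample".
#' @param n_perm permutations for the resampling mode.
#' @param seed RNG seed for the resampling mode.
#' @return data.frame with columns \code{h}, \code{expected_S}.
#' @export
rarefaction_curve <- function(inc, h = seq_len(ncol(inc)),
                              method = c("analytic", "resample"),
                              n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  n <- ncol(inc)
  if (n < 1L) stop("empty incidence matrix")
  if (any(h < 1L) || any(h > n))
    stop("subsample size h outside 1..n_stations")
  occ <- rowSums(inc > 0)
  occ <- occ[occ > 0]
  if (method == "analytic") {
    es <- vapply(h, function(hh) {
      # log-scale ratio C(n - n_j, h) / C(n, h); 0 when n - n_j < h
      p_absent <- ifelse(n - occ < hh, 0,
                         exp(lchoose(n - occ, hh) - lchoose(n, hh)))
      sum(1 - p_absent)
    }, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    es <- vapply(h, function(hh) {
      mean(replicate(n_perm, {
        cols <- sample.int(n, hh)
        sum(rowSums(inc[, cols, drop = FALSE]) > 0)
      }))
    }, numeric(1))
  }
  data.frame(h = h, expected_S = es)
}

#' Shannon-Wiener and Simpson diversity
#'
#' Weights (typically global RAI values) are normalized internally to
#' proportions p_i. H' = -sum p_i log p_i (nats); Simpson's index is the
#' Gini-Simpson form Ds = 1 - sum p_i^2 by default, with the inverse form
#' 1 / sum p_i^2 available.
#'
#' @param weights non-negative per-species abundance weights; at least one
#'   must be positive.
#' @param simpson "gini" (default) or "inverse".
#' @return list with \code{H_shannon} and \code{D_simpson}.
#' @export
diversity_indices <- function(weights, simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  if (any(weights < 0) || anyNA(weights)) stop("weights must be >= 0")
  if (sum(weights) <= 0) stop("all-zero weights: diversity undefined")
  p <- weights[weights > 0] / sum(weights)
  H <- -sum(p * log(p))
  D <- if (simpson == "gini") 1 - sum(p^2) else 1 / sum(p^2)
  list(H_shannon = H, D_simpson = D)
}

#' Incidence-based similarity between two communities
#'
#' A = shared species, B and C = species unique to each community.
#' Jaccard J = A/(A+B+C); Sorensen CC = 2A/(2A+B+C); the Sorensen
#' ecological distance is D_CC = 1 - CC.
#'
#' @param species_1,species_2 character vectors of species names (matched
#'   case-insensitively after trimming).
#' @return list with \code{A}, \code{B}, \code{C}, \code{J}, \code{CC},
#'   \code{D_CC}.
#' @export
community_similarity <- function(species_1, species_2) {
  s1 <- unique(normalize_species(species_1))
  s2 <- unique(normalize_species(species_2))
  if (length(s1) == 0L && length(s2) == 0L)
    stop("similarity undefined for two empty communities")
  A <- length(intersect(s1, s2))
  B <- length(setdiff(s1, s2))
  C <- length(setdiff(s2, s1))
  J <- A / (A + B + C)
  CC <- 2 * A / (2 * A + B + C)
  list(A = A, B = B, C = C, J = J, CC = CC, D_CC = 1 - CC)
}

#' Community-structure table (guild x body mass x trap rate)
#'
#' One row per species with its trophic guild, mean adult body mass and
#' global RAI, plus each species' share of the total trap rate and a flag
#' for dominance (share strictly greater than 50%). Sorted by guild then
#' mass.
#'
#' @param rai \code{rai_table} object (\code{\link{compute_rai}}).
#' @param traits traits data.frame (\code{\link{read_traits}}).
#' @return data.frame with columns \code{species}, \code{guild},
#'   \code{body_mass_kg}, \code{events}, \code{rai}, \code{share},
#'   \code{dominant}.
#' @export
community_structure_table <- function(rai, traits) {
  g <- rai$global
  if (nrow(g) == 0L)
    return(data.frame(species = character(0), guild = character(0),
                      body_mass_kg = numeric(0), events = integer(0),
                      rai = numeric(0), share = numeric(0),
                      dominant = logical(0)))
  ix <- match(g$species, traits$species)
  if (anyNA(ix))
    stop("species without traits: ",
         paste(g$species[is.na(ix)], collapse = ", "))
  out <- data.frame(
    species = g$species,
    guild = traits$guild[ix],
    body_mass_kg = traits$body_mass_kg[ix],
    events = g$events,
    rai = g$rai,
    stringsAsFactors = FALSE
  )
  tot <- sum(out$rai)
  out$share <- if (tot > 0) out$rai / tot else NA_real_
  out$dominant <- !is.na(out$share) & out$share > 0.5
  out <- out[order(out$guild, out$body_mass_kg), , drop = FALSE]
  rownames(out) <- NULL
  out
}
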